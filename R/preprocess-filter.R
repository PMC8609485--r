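#' Zero-phase band-pass filter
#'
#' Butterworth high-pass and low-pass sections applied forward-backward
#' (`signal::filtfilt`), so the phase response is zero and the magnitude
#' roll-off of each single-pass section is doubled. Section orders are
#' chosen from the requested roll-offs (12 dB/octave per effective
#' second-order pair): the default 12 dB/oct high-pass is a first-order
#' section run twice, the 48 dB/oct low-pass a fourth-order section run
#' twice.
#'
#' @param rec an [new_recording()].
#' @param low_hz,high_hz band edges (Hz); must satisfy
#'   `0 < low_hz < high_hz < fs/2`.
#' @param low_rolloff_db_oct,high_rolloff_db_oct requested stop-band
#'   roll-offs in dB per octave.
#' @return the filtered recording.
#' @export
bandpass_filter <- function(rec, low_hz = 0.1, high_hz = 30,
                            low_rolloff_db_oct = 12,
                            high_rolloff_db_oct = 48) {
  nyq <- rec$fs / 2
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  }
  if (high_hz >= nyq) stop("high cutoff must be below Nyquist", call. = FALSE)
  n_low <- max(1L, round(low_rolloff_db_oct / 12))
  n_high <- max(1L, round(high_rolloff_db_oct / 12))
  hp <- signal::butter(n_low, low_hz / nyq, type = "high")
  lp <- signal::butter(n_high, high_hz / nyq, type = "low")
  out <- rec
  for (ch in seq_len(nrow(rec$data))) {
    y <- signal::filtfilt(hp, rec$data[ch, ])
    out$data[ch, ] <- signal::filtfilt(lp, y)
  }
  out
}
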