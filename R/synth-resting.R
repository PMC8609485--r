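#' Generate one subject's resting-state recording
#'
#' Emulates the recording protocol of the study: alternating eyes-open /
#' eyes-closed blocks (EO, EC, EO, EC; 8 simulated minutes at the defaults)
#' with boundary markers. Each channel is a 1/f background plus one
#' narrowband oscillator per frequency band (random frequency within the
#' band per subject, random phase per channel, optional slow amplitude
#' modulation). The beta1 oscillator amplitude carries the injected
#' brain-behavior link:
#' `A_beta1 = band_amplitudes["beta1"] + beta1_aptitude_slope * aptitude`.
#'
#' Scripted artifacts are injected at the configured rates and logged:
#' `blink` (biphasic low-frequency deflection on the designated frontal
#' channels), `step` (transient DC shift bounded by sharp edges) and `flat`
#' (a segment overwritten by its constant mean). The log is the ground
#' truth against which detector recall is tested.
#'
#' @param cfg a [sim_config()].
#' @param subject 1-based subject index.
#' @param session `"T1"` (pre-training) or `"T2"` (post-training; beta1
#'   power shifted by `beta1_t2_log10_change`).
#' @param montage optional montage; defaults to `build_montage(cfg$n_channels)`.
#' @return list with `recording` (an [new_recording()]) and `ground_truth`
#'   (aptitude, injected beta1 amplitude, oscillator frequencies, artifact
#'   log with columns `channel`, `start`, `end`, `kind`).
#' @export
generate_resting_eeg <- function(cfg, subject, session = c("T1", "T2"),
                                 montage = NULL) {
  session <- match.arg(session)
  stopifnot(subject >= 1L, subject <= cfg$n_subjects)
  if (is.null(montage)) montage <- build_montage(cfg$n_channels)
  aptitude <- latent_aptitudes(cfg)[subject]
  stream <- if (session == "T1") 1L else 2L
  withr_seed(subject_seed(cfg$seed, subject, stream = stream), {
    fs <- cfg$fs
    block_n <- round_half_even(cfg$ec_segment_seconds * fs)
    n <- 4L * block_n
    n_ch <- nrow(montage)
    t <- (seq_len(n) - 1) / fs

    gain <- subject_gain(cfg, subject)
    amps <- cfg$band_amplitudes * gain
    if ("beta1" %in% names(amps)) {
      amps["beta1"] <- gain *
        max(0.05, cfg$band_amplitudes["beta1"] +
              cfg$beta1_aptitude_slope * aptitude)
      if (session == "T2") {
        amps["beta1"] <- amps["beta1"] * 10^(cfg$beta1_t2_log10_change / 2)
      }
    }
    ## oscillator peak frequencies are a stable subject trait: drawn from a
    ## session-independent stream so T1/T2 band power differs only through
    ## the injected longitudinal change (plus noise)
    edges <- band_scheme()
    osc_freq <- withr_seed(subject_seed(cfg$seed, subject, stream = 7L), {
      vapply(names(amps), function(b) {
        stats::runif(1, edges[b, "low"] + 0.1, edges[b, "high"] - 0.1)
      }, 1.0)
    })

    ## carrier and (slow) modulator waveforms are shared across channels;
    ## per-channel random phases enter through the angle-addition identity,
    ## which keeps the per-channel work down to a few vector operations
    mod_freq <- vapply(names(amps), function(b) stats::runif(1, 0.05, 0.15), 1.0)
    carrier_s <- lapply(osc_freq, function(f) sin(2 * pi * f * t))
    carrier_c <- lapply(osc_freq, function(f) cos(2 * pi * f * t))
    mod_s <- lapply(mod_freq, function(f) sin(2 * pi * f * t))
    mod_c <- lapply(mod_freq, function(f) cos(2 * pi * f * t))
    bg <- pink_noise_matrix(n, n_ch, fs, sd = cfg$noise_sd * gain)
    data <- matrix(0, n_ch, n)
    for (ch in seq_len(n_ch)) {
      x <- bg[, ch]
      for (b in names(amps)) {
        if (amps[b] <= 0) next
        phase <- stats::runif(1, 0, 2 * pi)
        osc <- amps[b] * (carrier_s[[b]] * cos(phase) + carrier_c[[b]] * sin(phase))
        if (cfg$osc_mod_depth > 0) {
          psi <- stats::runif(1, 0, 2 * pi)
          osc <- osc * (1 + cfg$osc_mod_depth *
                          (mod_s[[b]] * cos(psi) + mod_c[[b]] * sin(psi)))
        }
        x <- x + osc
      }
      data[ch, ] <- x
    }

    minutes <- n / fs / 60
    log <- list()
    frontal <- which(montage$frontal)

    n_blink <- stats::rpois(1, cfg$artifact_rates["blink"] * minutes)
    if (n_blink > 0 && length(frontal) > 0) {
      dur <- round(0.6 * fs)
      main <- round(0.4 * fs)
      starts <- sort(sample.int(n - dur, n_blink))
      shape <- c(sin(pi * seq_len(main) / main)^2,
                 -0.25 * sin(pi * seq_len(dur - main) / (dur - main))^2)
      for (s in starts) {
        idx <- s:(s + dur - 1L)
        for (ch in frontal) {
          data[ch, idx] <- data[ch, idx] + cfg$blink_peak_uv * shape
          log[[length(log) + 1L]] <- data.frame(
            channel = montage$label[ch], start = s - 1L,
            end = s - 1L + dur, kind = "blink")
        }
      }
    }

    n_step <- stats::rpois(1, cfg$artifact_rates["step"] * minutes)
    if (n_step > 0) {
      dur <- round(0.5 * fs)
      for (i in seq_len(n_step)) {
        ch <- sample.int(n_ch, 1)
        s <- sample.int(n - dur, 1)
        data[ch, s:(s + dur - 1L)] <- data[ch, s:(s + dur - 1L)] +
          sample(c(-1, 1), 1) * cfg$step_uv
        log[[length(log) + 1L]] <- data.frame(
          channel = montage$label[ch], start = s - 1L, end = s - 1L + dur,
          kind = "step")
      }
    }

    n_flat <- stats::rpois(1, cfg$artifact_rates["flat"] * minutes)
    if (n_flat > 0) {
      dur <- round(0.4 * fs) # >= 300 ms
      for (i in seq_len(n_flat)) {
        ch <- sample.int(n_ch, 1)
        s <- sample.int(n - dur, 1)
        data[ch, s:(s + dur - 1L)] <- mean(data[ch, s:(s + dur - 1L)])
        log[[length(log) + 1L]] <- data.frame(
          channel = montage$label[ch], start = s - 1L, end = s - 1L + dur,
          kind = "flat")
      }
    }

    events <- data.frame(
      sample = as.integer((0:3) * block_n),
      kind = rep(c("eyes_open", "eyes_closed"), 2L),
      payload = "",
      stringsAsFactors = FALSE
    )
    rec <- new_recording(data, fs, montage, events)
    gt <- list(
      subject = subject, session = session, aptitude = aptitude,
      gain = gain,
      beta1_amplitude = unname(amps["beta1"]),
      oscillator_freqs = osc_freq,
      artifact_log = if (length(log)) do.call(rbind, log) else
        data.frame(channel = character(0), start = integer(0),
                   end = integer(0), kind = character(0))
    )
    list(recording = rec, ground_truth = gt)
  })
}
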