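#' Frequency-band scheme
#'
#' Band edges in Hz; membership of a spectral bin is half-open `(low, high]`
#' on the bin centre frequency, so 12.5 Hz belongs to alpha, not beta1.
#' The gamma band is optional because the default 30 Hz low-pass in the
#' preprocessing chain attenuates it; enable it only with a matching filter
#' chain.
#'
#' @param include_gamma include the 30-40 Hz band.
#' @return matrix with rownames `theta`, `alpha`, `beta1`, `beta2`, `beta3`
#'   (and optionally `gamma`), columns `low`, `high`.
#' @export
band_scheme <- function(include_gamma = FALSE) {
  b <- rbind(theta = c(4, 7.5), alpha = c(8, 12.5), beta1 = c(13, 14.5),
             beta2 = c(15, 17.5), beta3 = c(18, 29.5))
  if (include_gamma) b <- rbind(b, gamma = c(30, 40))
  colnames(b) <- c("low", "high")
  b
}

#' Epoch-averaged power spectra
#'
#' Per-channel periodograms averaged across epochs (Welch-style over the
#' 50%-overlap resting epochs, unweighted). One-sided normalization such
#' that a sinusoid of amplitude A contributes total power A^2/2 (uV^2) at
#' its frequency, and the bin sum of a taper-free periodogram equals the
#' signal's mean square (Parseval). The optional Hann taper is compensated
#' for amplitude loss (divided by its coherent gain).
#'
#' @param epochs an [new_epoch_set()] with at least one epoch.
#' @param taper `"hann"` or `"none"`.
#' @return list of class `psd`: `freqs` (Hz), `power` (channels x bins,
#'   uV^2 per bin), `labels`, `n_epochs`, `taper`.
#' @export
epoch_psd <- function(epochs, taper = c("hann", "none")) {
  taper <- match.arg(taper)
  d <- dim(epochs$epochs)
  if (d[3L] == 0L) stop("empty epoch set", call. = FALSE)
  n <- d[2L]
  w <- if (taper == "hann") {
    h <- 0.5 * (1 - cos(2 * pi * seq.int(0L, n - 1L) / n))
    h / mean(h)
  } else rep(1, n)
  n2 <- n %/% 2L
  freqs <- (0:n2) * epochs$fs / n
  scale <- c(1, rep(2, n2 - 1L), if (n %% 2L == 0L) 1 else 2)
  power <- matrix(0, d[1L], n2 + 1L, dimnames = list(epochs$labels, NULL))
  for (ch in seq_len(d[1L])) {
    mat <- epochs$epochs[ch, , , drop = TRUE]
    if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1L)
    F <- stats::mvfft(mat * w)
    P <- (Mod(F[seq_len(n2 + 1L), , drop = FALSE])^2) / n^2
    power[ch, ] <- scale * rowMeans(P)
  }
  structure(list(freqs = freqs, power = power, labels = epochs$labels,
                 n_epochs = d[3L], taper = taper), class = "psd")
}

#' @export
print.psd <- function(x, ...) {
  cat("<psd> ", nrow(x$power), " channels x ", ncol(x$power),
      " bins (0-", max(x$freqs), " Hz, ", x$freqs[2L] - x$freqs[1L],
      " Hz resolution), averaged over ", x$n_epochs, " epochs, taper ",
      x$taper, "\n", sep = "")
  invisible(x)
}

#' Band x electrode-pool power means
#'
#' For every pool and band, the mean of the spectral values over member
#' channels and over bins whose centre frequency lies in `(low, high]`, plus
#' its log10. Errors if a band catches no bin at the current resolution or
#' a pool has no channel in the spectra.
#'
#' @param psd a `psd` from [epoch_psd()].
#' @param bands band matrix from [band_scheme()].
#' @param pools named list of channel-label vectors.
#' @return data.frame of class `band_power_table` with `pool`, `band`,
#'   `power` (uV^2), `log_power` (log10 uV^2).
#' @export
band_pool_means <- function(psd, bands = band_scheme(), pools) {
  rows <- list()
  for (p in names(pools)) {
    ch <- match(pools[[p]], psd$labels)
    ch <- ch[!is.na(ch)]
    if (!length(ch)) stop("pool '", p, "' has no channels in the spectra",
                          call. = FALSE)
    for (b in rownames(bands)) {
      bins <- which(psd$freqs > bands[b, "low"] & psd$freqs <= bands[b, "high"])
      if (!length(bins)) {
        stop("band '", b, "' contains no spectral bin at resolution ",
             psd$freqs[2L] - psd$freqs[1L], " Hz", call. = FALSE)
      }
      pw <- mean(psd$power[ch, bins, drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        pool = p, band = b, power = pw,
        log_power = log10(pw), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("band_power_table", "data.frame")
  out
}

#' Per-subject band-power change between sessions
#'
#' For the given band, the per-subject mean over pools of
#' `log_power(T2) - log_power(T1)`.
#'
#' @param table_t1,table_t2 long band-power tables with columns `subject`,
#'   `pool`, `band`, `log_power`.
#' @param band band name.
#' @return data.frame with `subject`, `delta_log10`.
#' @export
band_power_change <- function(table_t1, table_t2, band = "beta1") {
  s1 <- sort(unique(table_t1$subject))
  s2 <- sort(unique(table_t2$subject))
  if (!identical(s1, s2)) stop("subjects differ between sessions", call. = FALSE)
  t1 <- table_t1[table_t1$band == band, ]
  t2 <- table_t2[table_t2$band == band, ]
  d <- vapply(s1, function(s) {
    a <- t1[t1$subject == s, ]
    b <- t2[t2$subject == s, ]
    if (!nrow(a) || !nrow(b)) stop("subject ", s, " missing a session",
                                   call. = FALSE)
    m <- merge(a[, c("pool", "log_power")], b[, c("pool", "log_power")],
               by = "pool", suffixes = c("_t1", "_t2"))
    mean(m$log_power_t2 - m$log_power_t1)
  }, 1.0)
  data.frame(subject = s1, delta_log10 = d)
}
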