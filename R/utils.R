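#' @keywords internal
"_PACKAGE"

## Interval convention used throughout the package: artifact intervals are
## half-open [start, end) in 0-based sample coordinates, stored as two-column
## integer matrices cbind(start, end).

#' Merge overlapping or touching half-open intervals
#'
#' @param iv two-column matrix of `[start, end)` intervals (0-based samples).
#' @return matrix of sorted, disjoint intervals.
#' @keywords internal
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]
  out <- matrix(iv[1L, ], ncol = 2L)
  for (i in seq_len(nrow(iv))[-1L]) {
    if (iv[i, 1L] <= out[nrow(out), 2L]) {
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], iv[i, 2L])
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

#' Clip intervals to `[0, n)` and drop empties
#' @keywords internal
clip_intervals <- function(iv, n) {
  if (nrow(iv) == 0L) return(iv)
  iv[, 1L] <- pmax(iv[, 1L], 0L)
  iv[, 2L] <- pmin(iv[, 2L], n)
  iv[iv[, 2L] > iv[, 1L], , drop = FALSE]
}

#' Logical membership vector for a set of intervals
#' @keywords internal
intervals_to_flags <- function(iv, n) {
  flags <- logical(n)
  for (i in seq_len(nrow(iv))) flags[(iv[i, 1L] + 1L):iv[i, 2L]] <- TRUE
  flags
}

#' Convert a logical flag vector (1-based) to 0-based half-open intervals
#' @keywords internal
flags_to_intervals <- function(flags) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  iv <- cbind(start = starts[r$values], end = ends[r$values])
  storage.mode(iv) <- "integer"
  iv
}

#' Rolling extreme over all windows of length `w`
#'
#' Sparse-table (doubling) scheme: O(n log w) with vectorized `pmax`/`pmin`.
#' Element `i` of the result is the extreme of `x[i:(i + w - 1)]`,
#' `i = 1..(n - w + 1)`.
#'
#' @keywords internal
roll_extreme <- function(x, w, fun = pmax) {
  n <- length(x)
  stopifnot(w >= 1L, w <= n)
  if (w == 1L) return(x)
  len <- 1L
  cur <- x
  while (len * 2L <= w) {
    m <- length(cur) - len
    cur <- fun(cur[seq_len(m)], cur[(len + 1L):length(cur)])
    len <- len * 2L
  }
  s <- n - w + 1L
  if (len == w) return(cur[seq_len(s)])
  fun(cur[seq_len(s)], cur[(w - len + 1L):(w - len + s)])
}

#' Rolling peak-to-peak range over all windows of length `w`
#' @keywords internal
roll_range <- function(x, w) {
  roll_extreme(x, w, pmax) - roll_extreme(x, w, pmin)
}

#' 1/f ("pink") noise via spectral shaping
#'
#' White Gaussian noise is shaped in the frequency domain with amplitude
#' proportional to 1/sqrt(f) (power ~ 1/f) above `f_floor`, then rescaled to
#' the requested standard deviation. Deterministic given the calling RNG
#' state.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param sd target standard deviation (uV).
#' @param f_floor frequency (Hz) below which the 1/f shaping is capped, so
#'   power does not diverge at DC.
#' @return numeric vector of length `n`.
#' @keywords internal
pink_noise <- function(n, fs, sd = 1, f_floor = 0.5) {
  if (sd == 0) return(numeric(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  freqs <- seq(0, fs - fs / n, length.out = n)
  freqs <- pmin(freqs, fs - freqs) # fold to two-sided magnitude axis
  shape <- 1 / sqrt(pmax(freqs, f_floor))
  shape[1L] <- 0 # no DC
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(numeric(n))
  y * (sd / s)
}

#' Multichannel 1/f noise
#'
#' Batched variant of [pink_noise()]: columns are independent channels, all
#' shaped in one forward/inverse `mvfft` pair. Internally padded to the next
#' highly-composite length (`stats::nextn`) for FFT speed, then truncated.
#'
#' @inheritParams pink_noise
#' @param n_ch number of channels.
#' @return `n` x `n_ch` matrix.
#' @keywords internal
pink_noise_matrix <- function(n, n_ch, fs, sd = 1, f_floor = 0.5) {
  if (sd == 0) return(matrix(0, n, n_ch))
  m <- stats::nextn(n, c(2L, 3L, 5L))
  ## draw the spectrum directly: white noise has an i.i.d. complex Gaussian
  ## Hermitian spectrum, so shaping that draw and inverting is equivalent to
  ## (and cheaper than) transforming white noise forward and back
  h <- m %/% 2L
  freqs <- (0:h) * fs / m
  shape <- 1 / sqrt(pmax(freqs, f_floor))
  shape[1L] <- 0
  Z <- matrix(0, m, n_ch)
  mode(Z) <- "complex"
  re <- matrix(stats::rnorm((h - 1L) * n_ch), h - 1L, n_ch)
  im <- matrix(stats::rnorm((h - 1L) * n_ch), h - 1L, n_ch)
  body <- complex(real = re, imaginary = im) * shape[2:h]
  Z[2:h, ] <- body
  Z[m:(m - h + 2L), ] <- Conj(body)
  Z[h + 1L, ] <- stats::rnorm(n_ch) * shape[h + 1L]
  Y <- Re(stats::mvfft(Z, inverse = TRUE))
  Y <- Y[seq_len(n), , drop = FALSE]
  s <- apply(Y, 2L, stats::sd)
  s[s == 0] <- 1
  sweep(Y, 2L, sd / s, "*")
}

#' Round half to even (banker's rounding), as used for epoch lengths
#' @keywords internal
round_half_even <- function(x) round(x)

#' Derive a per-subject integer seed below 2^31
#' @keywords internal
subject_seed <- function(seed, subject, stream = 0L) {
  (as.integer(seed) + 104729L * as.integer(subject) + 7919L * as.integer(stream)) %% 2147483629L
}
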