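## Independent reference implementations used as oracles. These are written
## as plain, slow loops/summations on purpose: they must not share code with
## the package's vectorized implementations.

## Naive artifact detector: applies the three rejection rules sample by
## sample / window start by window start on a single trace, then pads and
## merges. Intervals are half-open [start, end) in 0-based samples.
naive_detect_trace <- function(x, fs, gradient_uv = 50, maxdiff_uv = 200,
                               maxdiff_window_ms = 200, lowact_uv = 0.5,
                               lowact_window_ms = 100, pad_ms = 200) {
  n <- length(x)
  w_md <- round(maxdiff_window_ms / 1000 * fs)
  w_la <- round(lowact_window_ms / 1000 * fs)
  flags <- logical(n)
  for (t in 2:n) {
    if (abs(x[t] - x[t - 1]) > gradient_uv) flags[t] <- TRUE
  }
  for (s in seq_len(n - w_md + 1L)) {
    win <- x[s:(s + w_md - 1L)]
    if (max(win) - min(win) > maxdiff_uv) flags[s:(s + w_md - 1L)] <- TRUE
  }
  for (s in seq_len(n - w_la + 1L)) {
    win <- x[s:(s + w_la - 1L)]
    if (max(win) - min(win) < lowact_uv) flags[s:(s + w_la - 1L)] <- TRUE
  }
  pad <- pad_ms / 1000 * fs
  padded <- logical(n)
  for (t in which(flags)) {
    lo <- max(1L, as.integer(ceiling(t - pad)))
    hi <- min(n, as.integer(floor(t + pad)))
    padded[lo:hi] <- TRUE
  }
  r <- rle(padded)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  iv <- cbind(start = starts[r$values], end = ends[r$values])
  storage.mode(iv) <- "integer"
  iv
}

## Brute-force DFT, one-sided power per bin with the package's stated
## normalization (sinusoid of amplitude A -> A^2/2 at its bin), computed by
## direct summation.
brute_dft_power <- function(x) {
  n <- length(x)
  n2 <- n %/% 2L
  k <- 0:n2
  p <- vapply(k, function(kk) {
    ang <- -2 * pi * kk * (0:(n - 1)) / n
    re <- sum(x * cos(ang))
    im <- sum(x * sin(ang))
    (re^2 + im^2) / n^2
  }, 1.0)
  scale <- c(1, rep(2, n2 - 1L), if (n %% 2L == 0L) 1 else 2)
  scale * p
}

## Small, fast simulation configs for unit tests.
quick_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects = 2, n_channels = 16, ec_segment_seconds = 8,
                   seed = 123)
  sim <- utils::modifyList(defaults, args)
  do.call(sim_config, sim)
}

## Recording from a plain matrix, with a matching synthetic montage.
toy_recording <- function(data, fs = 512, events = NULL) {
  m <- build_montage(max(16L, nrow(data)))[seq_len(nrow(data)), ]
  new_recording(data, fs, m, events)
}
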