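#' Threshold-based artifact detection
#'
#' Flags a sample on a channel when any of three criteria holds:
#' \describe{
#'   \item{gradient}{the sample-to-sample voltage step
#'     `|x[t] - x[t-1]|` exceeds `gradient_uv`;}
#'   \item{max-difference}{the peak-to-peak range within *any* enclosing
#'     window of `maxdiff_window_ms` exceeds `maxdiff_uv`;}
#'   \item{low activity}{the peak-to-peak range within any enclosing window
#'     of `lowact_window_ms` stays below `lowact_uv` (flatline).}
#' }
#' Sliding windows advance sample by sample. Flagged samples are expanded
#' by `pad_ms` on each side and merged into disjoint half-open intervals
#' `[start, end)` in 0-based sample coordinates, per channel.
#'
#' @param rec an [new_recording()].
#' @param gradient_uv,maxdiff_uv,lowact_uv voltage thresholds (uV).
#' @param maxdiff_window_ms,lowact_window_ms window lengths (ms).
#' @param pad_ms padding applied on both sides of flagged samples (ms).
#' @return object of class `artifact_mask`: list with `intervals` (named
#'   per-channel list of two-column matrices), `n_samples`, `pad_ms`.
#' @export
detect_artifacts <- function(rec, gradient_uv = 50, maxdiff_uv = 200,
                             maxdiff_window_ms = 200, lowact_uv = 0.5,
                             lowact_window_ms = 100, pad_ms = 200) {
  stopifnot(gradient_uv > 0, maxdiff_uv > 0, lowact_uv > 0)
  fs <- rec$fs
  n <- ncol(rec$data)
  w_md <- round_half_even(maxdiff_window_ms / 1000 * fs)
  w_la <- round_half_even(lowact_window_ms / 1000 * fs)
  if (w_md > n || w_la > n) {
    stop("artifact window longer than the recording", call. = FALSE)
  }
  pad_s <- pad_ms / 1000 * fs

  intervals <- lapply(seq_len(nrow(rec$data)), function(ch) {
    x <- rec$data[ch, ]
    flags <- logical(n)
    grad_idx <- which(abs(diff(x)) > gradient_uv) + 1L
    flags[grad_idx] <- TRUE
    flags <- flags | window_flags(x, w_md, function(r) r > maxdiff_uv, n)
    flags <- flags | window_flags(x, w_la, function(r) r < lowact_uv, n)
    iv <- flags_to_intervals(flags)
    if (nrow(iv)) {
      iv[, 1L] <- as.integer(ceiling(iv[, 1L] - pad_s))
      iv[, 2L] <- as.integer(floor((iv[, 2L] - 1L) + pad_s)) + 1L
      iv <- clip_intervals(merge_intervals(iv), n)
    }
    iv
  })
  names(intervals) <- rec$montage$label
  structure(list(intervals = intervals, n_samples = n, pad_ms = pad_ms),
            class = "artifact_mask")
}

## Flag all samples covered by any window of length `w` whose peak-to-peak
## range satisfies `pred`.
window_flags <- function(x, w, pred, n) {
  r <- roll_range(x, w)
  starts <- which(pred(r)) # 1-based window starts
  if (!length(starts)) return(logical(n))
  a <- tabulate(starts, nbins = n)
  b <- tabulate(starts + w, nbins = n)
  cumsum(a - b) > 0
}

#' @export
print.artifact_mask <- function(x, ...) {
  fr <- mask_fraction(x)
  cat("<artifact_mask> ", length(x$intervals), " channels, ",
      sum(vapply(x$intervals, nrow, 1L)), " intervals, mean flagged fraction ",
      round(mean(fr), 4), "\n", sep = "")
  invisible(x)
}

#' Flagged fraction of the recording, per channel
#' @param mask an `artifact_mask`.
#' @return named numeric vector of per-channel flagged fractions.
#' @export
mask_fraction <- function(mask) {
  vapply(mask$intervals, function(iv) {
    if (nrow(iv) == 0L) return(0)
    sum(iv[, 2L] - iv[, 1L]) / mask$n_samples
  }, 1.0)
}

#' Replace channels with excessive artifact load by neighbour averages
#'
#' Channels whose flagged fraction exceeds `reject_fraction` are replaced by
#' the unweighted mean of their `k_neighbors` nearest good channels
#' (Euclidean distance on montage positions); other bad channels are
#' excluded from the neighbour set. Errors if more than `max_interp`
#' channels qualify.
#'
#' @param rec an [new_recording()].
#' @param mask an `artifact_mask` for `rec`.
#' @param reject_fraction flagged-fraction threshold above which a channel
#'   is replaced.
#' @param max_interp hard cap on the number of replaced channels.
#' @param k_neighbors neighbours averaged into the replacement.
#' @return list with `recording` and `report` (data.frame of replaced
#'   channels, their flagged fraction and the neighbours used).
#' @export
interpolate_bad_channels <- function(rec, mask, reject_fraction = 0.10,
                                     max_interp = 5, k_neighbors = 4) {
  frac <- mask_fraction(mask)
  bad <- which(frac > reject_fraction)
  if (length(bad) > max_interp) {
    stop(length(bad), " channels exceed the rejection threshold (cap ",
         max_interp, ")", call. = FALSE)
  }
  report <- data.frame(channel = character(0), fraction = numeric(0),
                       neighbors = character(0), stringsAsFactors = FALSE)
  if (!length(bad)) return(list(recording = rec, report = report))
  xyz <- as.matrix(rec$montage[, c("x", "y", "z")])
  good <- setdiff(seq_len(nrow(xyz)), bad)
  if (length(good) < k_neighbors) {
    stop("not enough good channels for interpolation", call. = FALSE)
  }
  out <- rec
  for (ch in bad) {
    d <- sqrt(rowSums(sweep(xyz[good, , drop = FALSE], 2L, xyz[ch, ])^2))
    nb <- good[order(d)[seq_len(k_neighbors)]]
    out$data[ch, ] <- colMeans(rec$data[nb, , drop = FALSE])
    report <- rbind(report, data.frame(
      channel = rec$montage$label[ch], fraction = frac[ch],
      neighbors = paste(rec$montage$label[nb], collapse = ","),
      stringsAsFactors = FALSE))
  }
  list(recording = out, report = report)
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the instantaneous mean across all channels
#' (interpolated channels included), so column means become zero.
#'
#' @param rec an [new_recording()].
#' @return the re-referenced recording.
#' @export
rereference_average <- function(rec) {
  if (nrow(rec$data) < 2L) stop("need >= 2 channels", call. = FALSE)
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data))
  rec
}

#' Ocular-artifact correction (pluggable stage)
#'
#' The default `"template"` method detects high-amplitude low-frequency
#' excursions on the designated frontal channels (zero-phase low-pass below
#' `lowpass_hz`, threshold `threshold_uv`, padded and merged) and subtracts
#' the low-frequency component from the frontal channels within those
#' intervals, with short raised-cosine ramps to avoid boundary jumps.
#' Non-frontal channels are untouched. `"none"` passes the recording
#' through and raises a warning flag in the report.
#'
#' @param rec an [new_recording()].
#' @param method `"template"` or `"none"`.
#' @param threshold_uv blink-detection threshold on the low-passed frontal
#'   signal (uV).
#' @param lowpass_hz cut-off of the blink-band extraction (Hz).
#' @return list with `recording` and `report` (`method`, `intervals` of the
#'   corrected stretches in 0-based samples, `passthrough` flag).
#' @export
correct_ocular <- function(rec, method = c("template", "none"),
                           threshold_uv = 75, lowpass_hz = 6) {
  method <- match.arg(method)
  if (method == "none") {
    warning("ocular correction skipped: pass-through", call. = FALSE)
    return(list(recording = rec,
                report = list(method = method,
                              intervals = matrix(integer(0), ncol = 2L),
                              passthrough = TRUE)))
  }
  frontal <- which(rec$montage$frontal)
  if (!length(frontal)) stop("no frontal channels designated", call. = FALSE)
  fs <- rec$fs
  n <- ncol(rec$data)
  lp <- signal::butter(2, lowpass_hz / (fs / 2), type = "low")
  pad <- round(0.1 * fs)
  ramp_n <- round(0.05 * fs)
  low <- matrix(0, length(frontal), n)
  flags <- logical(n)
  for (i in seq_along(frontal)) {
    low[i, ] <- signal::filtfilt(lp, rec$data[frontal[i], ])
    flags <- flags | (abs(low[i, ]) > threshold_uv)
  }
  iv <- flags_to_intervals(flags)
  out <- rec
  if (nrow(iv)) {
    iv[, 1L] <- pmax(iv[, 1L] - pad, 0L)
    iv[, 2L] <- pmin(iv[, 2L] + pad, n)
    iv <- merge_intervals(iv)
    for (r in seq_len(nrow(iv))) {
      idx <- (iv[r, 1L] + 1L):iv[r, 2L]
      m <- length(idx)
      ramp <- rep(1, m)
      k <- min(ramp_n, floor(m / 2))
      if (k > 0) {
        edge <- 0.5 * (1 - cos(pi * seq_len(k) / k))
        ramp[seq_len(k)] <- edge
        ramp[(m - k + 1L):m] <- rev(edge)
      }
      for (i in seq_along(frontal)) {
        out$data[frontal[i], idx] <- rec$data[frontal[i], idx] - ramp * low[i, idx]
      }
    }
  }
  list(recording = out,
       report = list(method = method, intervals = iv, passthrough = FALSE))
}
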