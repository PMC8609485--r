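#' Extract trimmed eyes-closed segments
#'
#' Cuts the recording at the `eyes_closed` boundary markers (each segment
#' runs to the next event or the end of the recording), removes `trim_s`
#' seconds at both ends as an adjustment interval, and returns the segments
#' in temporal order. Segments shorter than `2 * trim_s` are dropped with a
#' warning.
#'
#' @param rec an [new_recording()] with eyes-closed boundary events.
#' @param trim_s seconds trimmed from each end of each segment.
#' @return list of segments, each a list with `data` (channels x samples),
#'   `fs`, `labels` and `offset` (0-based start sample in the original
#'   recording, after trimming).
#' @export
extract_ec_segments <- function(rec, trim_s = 5) {
  ev <- rec$events
  ec <- which(ev$kind == "eyes_closed")
  if (!length(ec)) stop("no eyes-closed events in recording", call. = FALSE)
  n <- ncol(rec$data)
  trim_n <- round_half_even(trim_s * rec$fs)
  segs <- list()
  for (i in ec) {
    s0 <- ev$sample[i]
    later <- ev$sample[ev$sample > s0]
    e0 <- if (length(later)) min(later) else n
    s <- s0 + trim_n
    e <- e0 - trim_n
    if (e - s < 1L) {
      warning("eyes-closed segment at sample ", s0,
              " shorter than 2*trim_s: dropped", call. = FALSE)
      next
    }
    segs[[length(segs) + 1L]] <- list(
      data = rec$data[, (s + 1L):e, drop = FALSE], fs = rec$fs,
      labels = rec$montage$label, offset = as.integer(s))
  }
  segs[order(vapply(segs, `[[`, 1L, "offset"))]
}

## TRUE if the global half-open interval [a, b) hits any masked interval on
## any channel.
overlaps_mask <- function(mask, a, b) {
  for (iv in mask$intervals) {
    if (nrow(iv) && any(iv[, 1L] < b & iv[, 2L] > a)) return(TRUE)
  }
  FALSE
}

#' Tile segments with fixed-length overlapping epochs
#'
#' Epochs of `epoch_s` seconds tile each segment with stride
#' `epoch_s * (1 - overlap)`; the per-epoch sample count is
#' `round(epoch_s * fs)` (round-half-to-even). Any candidate epoch that
#' overlaps a masked interval on any channel is skipped.
#'
#' @param segments list from [extract_ec_segments()].
#' @param mask an `artifact_mask` in the coordinates of the original
#'   recording, or `NULL` for no skipping.
#' @param epoch_s epoch length (seconds).
#' @param overlap fractional overlap in `[0, 1)`.
#' @return an [new_epoch_set()]; attribute `n_skipped` counts masked-out
#'   candidates.
#' @export
epoch_fixed_overlap <- function(segments, mask = NULL, epoch_s = 2,
                                overlap = 0.5) {
  stopifnot(overlap >= 0, overlap < 1, length(segments) >= 1L)
  fs <- segments[[1L]]$fs
  len <- round_half_even(epoch_s * fs)
  stride <- max(1L, round_half_even(epoch_s * (1 - overlap) * fs))
  keep <- list()
  n_skipped <- 0L
  for (seg in segments) {
    L <- ncol(seg$data)
    if (L < len) next
    for (s in seq.int(0L, L - len, by = stride)) {
      g <- seg$offset + s
      if (!is.null(mask) && overlaps_mask(mask, g, g + len)) {
        n_skipped <- n_skipped + 1L
        next
      }
      keep[[length(keep) + 1L]] <- seg$data[, (s + 1L):(s + len), drop = FALSE]
    }
  }
  if (!length(keep)) {
    epochs <- array(0, dim = c(nrow(segments[[1L]]$data), len, 0L))
  } else {
    epochs <- array(unlist(keep, use.names = FALSE),
                    dim = c(dim(keep[[1L]]), length(keep)))
  }
  es <- new_epoch_set(epochs, fs, times = (seq_len(len) - 1) / fs * 1000,
                      labels = segments[[1L]]$labels)
  attr(es, "n_skipped") <- n_skipped
  es
}

#' Cut event-locked epochs with baseline correction
#'
#' One epoch per anchor event, spanning `window_ms` around the anchor
#' (sample offsets `round(w * fs)`, both ends inclusive). Epochs running
#' outside the recording or overlapping the artifact mask are dropped (a
#' count is attached). Each epoch is baseline-corrected by subtracting the
#' per-channel mean over `baseline_ms`; the condition tag is copied from
#' the event payload.
#'
#' @param rec an [new_recording()].
#' @param mask an `artifact_mask` or `NULL`.
#' @param anchor_kind event kind to lock to.
#' @param window_ms length-2 window around the anchor (ms).
#' @param baseline_ms length-2 baseline window (ms).
#' @return an [new_epoch_set()] with condition tags; attributes
#'   `n_dropped_bounds` and `n_dropped_mask`.
#' @export
epoch_events <- function(rec, mask = NULL, anchor_kind = "target",
                         window_ms = c(-100, 1000),
                         baseline_ms = c(-100, 0)) {
  ev <- rec$events[rec$events$kind == anchor_kind, , drop = FALSE]
  if (!nrow(ev)) stop("no anchor events of kind '", anchor_kind, "'",
                      call. = FALSE)
  fs <- rec$fs
  n <- ncol(rec$data)
  offs <- seq.int(round_half_even(window_ms[1L] / 1000 * fs),
                  round_half_even(window_ms[2L] / 1000 * fs))
  keep <- list()
  tags <- character(0)
  n_bounds <- 0L
  n_masked <- 0L
  for (i in seq_len(nrow(ev))) {
    a <- ev$sample[i]
    idx0 <- a + offs # 0-based
    if (idx0[1L] < 0L || idx0[length(idx0)] >= n) {
      n_bounds <- n_bounds + 1L
      next
    }
    if (!is.null(mask) &&
        overlaps_mask(mask, idx0[1L], idx0[length(idx0)] + 1L)) {
      n_masked <- n_masked + 1L
      next
    }
    keep[[length(keep) + 1L]] <- rec$data[, idx0 + 1L, drop = FALSE]
    tags <- c(tags, ev$payload[i])
  }
  if (!length(keep)) stop("all epochs dropped", call. = FALSE)
  epochs <- array(unlist(keep, use.names = FALSE),
                  dim = c(dim(keep[[1L]]), length(keep)))
  es <- new_epoch_set(epochs, fs, times = offs / fs * 1000,
                      labels = rec$montage$label, conditions = tags)
  es <- baseline_correct(es, baseline_ms)
  attr(es, "n_dropped_bounds") <- n_bounds
  attr(es, "n_dropped_mask") <- n_masked
  es
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per channel and epoch, the mean over the samples whose time
#' falls inside `baseline_ms` (inclusive).
#'
#' @param epochs an [new_epoch_set()].
#' @param baseline_ms length-2 window (ms) on the epoch time axis.
#' @return the corrected epoch set.
#' @export
baseline_correct <- function(epochs, baseline_ms = c(-100, 0)) {
  sel <- epochs$times >= baseline_ms[1L] & epochs$times <= baseline_ms[2L]
  if (!any(sel)) stop("baseline window outside the epoch span", call. = FALSE)
  bl <- apply(epochs$epochs[, sel, , drop = FALSE], c(1L, 3L), mean)
  epochs$epochs <- sweep(epochs$epochs, c(1L, 3L), bl)
  epochs
}
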