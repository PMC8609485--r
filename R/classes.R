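#' Construct a continuous multichannel recording
#'
#' The basic container for continuous EEG: a channels x samples matrix in
#' microvolts with a sampling rate, channel labels, 3-D montage positions
#' and typed event markers (0-based sample coordinates).
#'
#' @param data numeric matrix, channels x samples (uV).
#' @param fs sampling rate (Hz).
#' @param montage data.frame with at least `label`, `x`, `y`, `z`, `frontal`.
#' @param events data.frame with columns `sample` (0-based), `kind`,
#'   `payload` (character).
#' @return object of class `eeg_recording`.
#' @export
new_recording <- function(data, fs, montage, events = NULL) {
  stopifnot(is.matrix(data), fs > 0)
  if (nrow(data) != nrow(montage)) {
    stop("montage must describe every data channel", call. = FALSE)
  }
  if (anyDuplicated(montage$label)) stop("channel labels must be unique", call. = FALSE)
  if (is.null(events)) {
    events <- data.frame(sample = integer(0), kind = character(0),
                         payload = character(0), stringsAsFactors = FALSE)
  }
  if (nrow(events) && (any(events$sample < 0) ||
                       any(events$sample >= ncol(data)))) {
    stop("event samples must lie within [0, n_samples)", call. = FALSE)
  }
  rownames(data) <- montage$label
  structure(list(data = data, fs = fs, montage = montage, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(ncol(x$data) / x$fs, 1), " s), ",
      nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' Construct an epoch set
#'
#' @param epochs numeric array, channels x samples x trials (uV).
#' @param fs sampling rate (Hz).
#' @param times numeric vector of sample times (ms) relative to the anchor.
#' @param labels channel labels.
#' @param conditions character vector, one tag per epoch (optional).
#' @return object of class `epoch_set`.
#' @export
new_epoch_set <- function(epochs, fs, times, labels, conditions = NULL) {
  stopifnot(length(dim(epochs)) == 3L, dim(epochs)[2L] == length(times),
            dim(epochs)[1L] == length(labels))
  if (!is.null(conditions)) stopifnot(length(conditions) == dim(epochs)[3L])
  dimnames(epochs) <- list(labels, NULL, NULL)
  structure(list(epochs = epochs, fs = fs, times = times, labels = labels,
                 conditions = conditions),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat("<epoch_set> ", d[3L], " epochs x ", d[1L], " channels x ", d[2L],
      " samples @ ", x$fs, " Hz", sep = "")
  if (!is.null(x$conditions)) {
    tab <- table(x$conditions)
    cat(" (", paste(names(tab), tab, sep = ": ", collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
print.model_result <- function(x, ...) {
  cat("<model_result> ", x$n_obs, " observations, ", x$n_subjects,
      " subjects\n", sep = "")
  print(format(x$coefficients, digits = 3), ...)
  cat("ICC(1) = ", round(x$icc1, 3),
      "; marginal pseudo-R2 = ", round(x$pseudo_r2_marginal, 3), "\n", sep = "")
  if (isTRUE(x$singular)) cat("note: singular fit\n")
  if (!is.null(x$flags) && length(x$flags)) {
    cat("flags:", paste(x$flags, collapse = ", "), "\n")
  }
  invisible(x)
}
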