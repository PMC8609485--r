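#' Percentile score of a language test
#'
#' @param raw number of correct items (0..`max_raw`).
#' @param max_raw maximum attainable raw score (> 0).
#' @return `100 * raw / max_raw`.
#' @export
percentile_score <- function(raw, max_raw) {
  if (any(max_raw <= 0)) stop("max_raw must be positive", call. = FALSE)
  if (any(raw < 0) || any(raw > max_raw)) {
    stop("raw score must lie in [0, max_raw]", call. = FALSE)
  }
  100 * raw / max_raw
}

#' Composite L2 proficiency
#'
#' The unweighted mean of the three test percentiles of one session.
#'
#' @param percentiles numeric vector (or matrix with one column per test).
#' @return the mean percentile.
#' @export
composite_score <- function(percentiles) {
  if (is.matrix(percentiles)) {
    if (anyNA(percentiles)) stop("missing test score", call. = FALSE)
    return(rowMeans(percentiles))
  }
  if (anyNA(percentiles)) stop("missing test score", call. = FALSE)
  mean(percentiles)
}

#' Corrected learning progress (CorP)
#'
#' Learning gain rescaled as the percentage of the maximum attainable
#' improvement, so progress at higher starting levels counts for more:
#' `CorP = (t2 - t1) * max_score / (max_score - t1)`.
#' Negative when `t2 < t1`. Undefined (error) at `t1 = max_score`.
#'
#' @param t1,t2 scores before / after training (same 0..`max_score` scale).
#' @param max_score maximum attainable score (100 for percentile scales).
#' @return CorP in percent of maximum attainable improvement.
#' @export
corrected_progress <- function(t1, t2, max_score = 100) {
  if (any(t1 > max_score) || any(t1 < 0) || any(t2 < 0) || any(t2 > max_score)) {
    stop("scores must lie in [0, max_score]", call. = FALSE)
  }
  if (any(t1 == max_score)) {
    stop("CorP undefined when the T1 score equals the maximum", call. = FALSE)
  }
  (t2 - t1) * max_score / (max_score - t1)
}

#' Variance share of the first principal component
#'
#' Largest eigenvalue of the correlation matrix of the score matrix,
#' expressed as a percentage of the number of tests. Used to justify
#' collapsing the three language tests into one composite.
#'
#' @param scores subjects x tests numeric matrix.
#' @return percent of variance carried by the first component.
#' @export
first_pc_variance_share <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L || ncol(scores) < 2L) {
    stop("need >= 2 subjects and >= 2 tests", call. = FALSE)
  }
  v <- apply(scores, 2L, stats::var)
  if (any(v == 0)) stop("constant test column", call. = FALSE)
  ev <- eigen(stats::cor(scores), symmetric = TRUE, only.values = TRUE)$values
  100 * max(ev) / ncol(scores)
}

#' Read / write L2 assessment tables as TSV
#' @param x assessment data.frame.
#' @param path file path.
#' @export
write_assessment <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assessment
#' @export
read_assessment <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("l2_assessment", "data.frame")
  out
}
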