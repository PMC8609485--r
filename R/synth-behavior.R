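#' Generate the behavioral L2 assessment table
#'
#' Three language-test percentiles (C-Test, course-book assessment,
#' listening comprehension) per subject at T1 and T2. The three T1 tests
#' share a common factor with pairwise correlation
#' `test_intercorrelation`, so one principal component dominates. The true
#' corrected learning gain follows the configured monotone (logistic) link
#' to latent aptitude,
#' `CorP_true = base + range * plogis(slope * aptitude) + noise`,
#' and T2 percentiles are built so the composite corrected-progress score
#' recovers that gain:
#' `T2_j = T1_j + CorP_true/100 * (100 - T1_j) + jitter`.
#' T1 level is generated independently of aptitude (initial knowledge and
#' development were unrelated in the emulated cohort).
#'
#' @param cfg a [sim_config()].
#' @param aptitudes optional latent aptitudes (defaults to
#'   [latent_aptitudes()] of `cfg`).
#' @return data.frame of class `l2_assessment` with per-test percentiles at
#'   T1/T2, composites, `corp` (computed from the composites via
#'   [corrected_progress()]) and the generating `true_corp` and `aptitude`.
#' @export
generate_behavioral_scores <- function(cfg, aptitudes = NULL) {
  if (is.null(aptitudes)) aptitudes <- latent_aptitudes(cfg)
  n <- length(aptitudes)
  tests <- c("c_test", "course_test", "listening")
  withr_seed(subject_seed(cfg$seed, 0L, stream = 3L), {
    rho <- cfg$test_intercorrelation
    common <- stats::rnorm(n)
    t1 <- sapply(tests, function(j) {
      z <- sqrt(rho) * common + sqrt(1 - rho) * stats::rnorm(n)
      pmin(pmax(cfg$t1_mean + cfg$t1_sd * z, 0), 95)
    })
    true_corp <- cfg$corp_base +
      cfg$corp_range * stats::plogis(cfg$corp_slope * aptitudes) +
      stats::rnorm(n, sd = cfg$corp_noise_sd)
    true_corp <- pmin(pmax(true_corp, 1), 99)
    t2 <- sapply(seq_along(tests), function(j) {
      v <- t1[, j] + true_corp / 100 * (100 - t1[, j]) +
        stats::rnorm(n, sd = cfg$test_noise_sd)
      pmin(pmax(v, 0), 100)
    })
    out <- data.frame(subject = seq_len(n))
    for (j in seq_along(tests)) {
      out[[paste0(tests[j], "_T1")]] <- t1[, j]
      out[[paste0(tests[j], "_T2")]] <- t2[, j]
    }
    out$composite_T1 <- rowMeans(t1)
    out$composite_T2 <- rowMeans(t2)
    out$corp <- corrected_progress(out$composite_T1, out$composite_T2, 100)
    out$true_corp <- true_corp
    out$aptitude <- aptitudes
    class(out) <- c("l2_assessment", "data.frame")
    out
  })
}
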