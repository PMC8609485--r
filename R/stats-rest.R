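#' Spearman screen of band power against learning gain, with FDR control
#'
#' One Spearman correlation (average ranks for ties) per electrode pool x
#' frequency band between T1 log band power and the behavioral outcome,
#' with a Fisher-z 95% confidence interval (SE `sqrt(1.06/(n-3))`) and
#' Benjamini-Hochberg adjustment across all pool x band cells. Cells with a
#' constant column are recorded as missing and excluded from the BH family.
#'
#' @param power_table long table with `subject`, `pool`, `band`, `log_power`.
#' @param outcomes data.frame with `subject` and `corp` (or any outcome in a
#'   column named by `outcome_col`).
#' @param outcome_col outcome column name in `outcomes`.
#' @return data.frame of class `correlation_table`: `pool`, `band`, `n`,
#'   `rho`, `ci_lo`, `ci_hi`, `p`, `q`.
#' @export
spearman_fdr <- function(power_table, outcomes, outcome_col = "corp") {
  cells <- unique(power_table[, c("pool", "band")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- power_table$pool == cells$pool[i] & power_table$band == cells$band[i]
    d <- merge(power_table[sel, c("subject", "log_power")],
               outcomes[, c("subject", outcome_col)], by = "subject")
    n <- nrow(d)
    x <- d$log_power
    y <- d[[outcome_col]]
    if (n < 4L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(pool = cells$pool[i], band = cells$band[i], n = n,
                        rho = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    rho <- stats::cor(x, y, method = "spearman")
    p <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))$p.value
    ci <- if (n > 3L && abs(rho) < 1) {
      z <- atanh(rho)
      se <- sqrt(1.06 / (n - 3))
      tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
    } else c(NA_real_, NA_real_)
    data.frame(pool = cells$pool[i], band = cells$band[i], n = n, rho = rho,
               ci_lo = ci[1L], ci_hi = ci[2L], p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' One-way intraclass correlation, ICC(1)
#'
#' One-way random-effects ANOVA ICC with the harmonic-mean-adjusted group
#' size for unbalanced data:
#' `ICC = (MSB - MSW) / (MSB + (k0 - 1) MSW)`, `F = MSB / MSW`, with
#' `k0 = (N - sum(n_i^2)/N) / (g - 1)`. May be negative when subject means
#' are more alike than chance; the computed value is reported as is.
#'
#' @param values numeric vector of observations.
#' @param groups grouping factor (subjects).
#' @return list with `icc`, `f`, `df1`, `df2`, `k0`.
#' @export
icc1 <- function(values, groups) {
  groups <- factor(groups)
  g <- nlevels(groups)
  if (g < 2L) stop("need >= 2 groups", call. = FALSE)
  n_i <- tabulate(groups)
  N <- length(values)
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  msb <- ssb / (g - 1)
  msw <- ssw / (N - g)
  k0 <- (N - sum(n_i^2) / N) / (g - 1)
  icc <- if (msw == 0 && msb == 0) NaN else {
    (msb - msw) / (msb + (k0 - 1) * msw)
  }
  list(icc = icc, f = msb / msw, df1 = g - 1L, df2 = N - g, k0 = k0)
}

#' Mixed model of band power on learning gain
#'
#' Linear mixed model `log_power ~ corp_z * band + (1 | subject)` fitted by
#' maximum likelihood, with treatment coding and the alpha band as the
#' reference level, Wald 95% confidence intervals, and the marginal
#' pseudo-R^2 `var(fixed)/(var(fixed) + var(intercept) + var(residual))`.
#' The outcome is z-scored over the analyzed subjects before entering the
#' model. With a zero-variance outcome the model falls back to a band-only
#' fit (flag `degenerate_outcome`); with a single subject it falls back to
#' OLS on that subject's rows (flag `single_subject`, variance component 0).
#'
#' @param power_table long table with `subject`, `pool`, `band`, `log_power`
#'   (one row per subject x pool x band).
#' @param outcomes data.frame with `subject` and the outcome column.
#' @param outcome_col outcome column name.
#' @param reference_band reference level for the band factor.
#' @return object of class `model_result`: coefficient table (`term`,
#'   `estimate`, `se`, `t`, `ci_lo`, `ci_hi`), variance components, ICC(1)
#'   of the modelled values, marginal pseudo-R^2, flags.
#' @export
fit_power_model <- function(power_table, outcomes, outcome_col = "corp",
                            reference_band = "alpha") {
  d <- merge(power_table, outcomes[, c("subject", outcome_col)], by = "subject")
  d$band <- stats::relevel(factor(d$band), ref = reference_band)
  d$subject <- factor(d$subject)
  flags <- character(0)
  out_sd <- stats::sd(tapply(d[[outcome_col]], d$subject, mean))
  if (is.na(out_sd) || out_sd == 0) {
    flags <- c(flags, "degenerate_outcome")
    d$corp_z <- 0
    form_fix <- log_power ~ band
  } else {
    mu <- mean(tapply(d[[outcome_col]], d$subject, mean))
    d$corp_z <- (d[[outcome_col]] - mu) / out_sd
    form_fix <- log_power ~ corp_z * band
  }
  single <- nlevels(d$subject) < 2L
  if (single) flags <- c(flags, "single_subject")
  if (single) {
    fit <- stats::lm(form_fix, data = d)
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    tau2 <- 0
    sig2 <- stats::sigma(fit)^2
    fixed_pred <- stats::fitted(fit)
    singular <- FALSE
  } else {
    form <- stats::update(form_fix, . ~ . + (1 | subject))
    fit <- lme4::lmer(form, data = d, REML = FALSE)
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    tau2 <- vc$vcov[vc$grp == "subject"]
    sig2 <- vc$vcov[vc$grp == "Residual"]
    fixed_pred <- as.vector(stats::model.matrix(fit) %*% beta)
    singular <- lme4::isSingular(fit)
  }
  if (singular) flags <- c(flags, "singular_fit")
  z <- stats::qnorm(0.975)
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se), t = unname(beta / se),
                      ci_lo = unname(beta - z * se),
                      ci_hi = unname(beta + z * se),
                      stringsAsFactors = FALSE)
  var_fix <- stats::var(fixed_pred)
  res <- structure(list(
    coefficients = coefs,
    varcomp = c(subject_intercept = tau2, residual = sig2),
    icc1 = if (single) NA_real_ else icc1(d$log_power, d$subject)$icc,
    pseudo_r2_marginal = var_fix / (var_fix + tau2 + sig2),
    n_obs = nrow(d), n_subjects = nlevels(d$subject),
    singular = singular, flags = flags, fit = fit
  ), class = "model_result")
  res
}

#' Paired Wilcoxon signed-rank test with effect size
#'
#' Zero differences are dropped before ranking. The test statistic is the
#' positive-rank sum; the p-value is exact when the sample is small and has
#' no ties. The default effect size is the matched-rank correlation
#' `r = |Z|/sqrt(n)` with Z from the normal approximation of the rank sum;
#' the rank-biserial alternative `(W+ - W-)/(n(n+1)/2)` is available. The
#' confidence interval is the Hodges-Lehmann interval for the median
#' difference.
#'
#' @param x_t1,x_t2 paired measurements.
#' @param alternative passed to [stats::wilcox.test()] (on the differences
#'   `x_t2 - x_t1`).
#' @param effect `"r"` or `"rank_biserial"`.
#' @param conf_level confidence level for the Hodges-Lehmann interval.
#' @return list: `statistic` (W+), `p`, `z`, `effect_size`, `effect_type`,
#'   `ci`, `n` (nonzero pairs), `alternative`.
#' @export
wilcoxon_paired <- function(x_t1, x_t2,
                            alternative = c("two.sided", "greater", "less"),
                            effect = c("r", "rank_biserial"),
                            conf_level = 0.95) {
  alternative <- match.arg(alternative)
  effect <- match.arg(effect)
  stopifnot(length(x_t1) == length(x_t2))
  d <- x_t2 - x_t1
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero", call. = FALSE)
  if (n < 5L) stop("need >= 5 nonzero pairs", call. = FALSE)
  ht <- suppressWarnings(stats::wilcox.test(
    d, alternative = alternative, conf.int = TRUE, conf.level = conf_level))
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                  sum(ties^3 - ties) / 48)
  z <- (w_pos - mu) / sigma
  es <- if (effect == "r") abs(z) / sqrt(n) else {
    (2 * w_pos - n * (n + 1) / 2) / (n * (n + 1) / 2)
  }
  list(statistic = unname(w_pos), p = ht$p.value, z = z, effect_size = es,
       effect_type = effect, ci = unname(ht$conf.int), n = n,
       alternative = alternative)
}

#' Regression of an outcome on a predictor, both standardized
#'
#' Ordinary least squares on z-scored variables with a Wald (t-based) 95%
#' confidence interval. Used for the change-in-power vs learning-gain
#' association and for the ERP-effect vs proficiency association. With two
#' points the fit is perfect and the interval undefined; this is flagged
#' rather than silently reported.
#'
#' @param x predictor, `y` outcome (equal length, n >= 2).
#' @param y outcome.
#' @return list: `slope`, `se`, `t`, `ci`, `n`, `flags`.
#' @export
standardized_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2L) stop("need >= 2 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero-variance predictor", call. = FALSE)
  if (stats::sd(y) == 0) stop("zero-variance outcome", call. = FALSE)
  xz <- as.vector(scale(x))
  yz <- as.vector(scale(y))
  fit <- stats::lm(yz ~ xz)
  flags <- character(0)
  if (n <= 2L) {
    flags <- c(flags, "degenerate_n2")
    ci <- c(NA_real_, NA_real_)
    se <- NA_real_
    tval <- NA_real_
  } else {
    se <- sqrt(diag(stats::vcov(fit)))[["xz"]]
    tval <- stats::coef(fit)[["xz"]] / se
    ci <- stats::confint(fit)["xz", ]
  }
  list(slope = stats::coef(fit)[["xz"]], se = se, t = tval,
       ci = unname(ci), n = n, flags = flags)
}

#' @rdname standardized_regression
#' @param delta_power per-subject band-power change (log10 units).
#' @param outcome per-subject learning gain.
#' @export
change_outcome_regression <- function(delta_power, outcome) {
  standardized_regression(delta_power, outcome)
}
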