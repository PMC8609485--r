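erp_conditions <- c("no_switch_congruent", "no_switch_incongruent",
                    "switch_congruent", "switch_incongruent")

#' Condition averages of an epoch set
#'
#' Pointwise mean over trials within each condition of the 2x2 design,
#' with trial counts recorded. Epochs are expected to be baseline-corrected
#' and condition-tagged.
#'
#' @param epochs an [new_epoch_set()] with condition tags.
#' @param expected conditions that must be present (error if any has zero
#'   trials).
#' @return object of class `erp_set`: `averages` (channels x samples x
#'   conditions), `counts`, `fs`, `times`, `labels`.
#' @export
condition_average <- function(epochs, expected = erp_conditions) {
  if (is.null(epochs$conditions)) stop("epochs carry no condition tags",
                                       call. = FALSE)
  missing <- setdiff(expected, unique(epochs$conditions))
  if (length(missing)) {
    stop("condition(s) with zero trials: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  conds <- expected
  d <- dim(epochs$epochs)
  avg <- array(0, dim = c(d[1L], d[2L], length(conds)),
               dimnames = list(epochs$labels, NULL, conds))
  counts <- integer(length(conds))
  names(counts) <- conds
  for (k in seq_along(conds)) {
    sel <- epochs$conditions == conds[k]
    counts[k] <- sum(sel)
    avg[, , k] <- rowMeans(epochs$epochs[, , sel, drop = FALSE], dims = 2L)
  }
  structure(list(averages = avg, counts = counts, fs = epochs$fs,
                 times = epochs$times, labels = epochs$labels),
            class = "erp_set")
}

#' @export
print.erp_set <- function(x, ...) {
  cat("<erp_set> ", length(x$labels), " channels x ", length(x$times),
      " samples, conditions: ",
      paste(dimnames(x$averages)[[3L]], x$counts, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Window-mean amplitudes at an electrode pool
#'
#' Mean voltage over the pool channels and the samples whose time falls in
#' `window_ms` (inclusive), per condition.
#'
#' @param erps an `erp_set` from [condition_average()].
#' @param pool character vector of channel labels.
#' @param window_ms length-2 window (ms) on the epoch time axis.
#' @param component label attached to the rows (e.g. `"N400"`, `"LPC"`).
#' @return data.frame with `condition`, `switch`, `congruency`,
#'   `component`, `amplitude` (uV).
#' @export
window_mean <- function(erps, pool, window_ms, component = "N400") {
  ch <- match(pool, erps$labels)
  ch <- ch[!is.na(ch)]
  if (!length(ch)) stop("empty electrode pool", call. = FALSE)
  sel <- erps$times >= window_ms[1L] & erps$times <= window_ms[2L]
  if (!any(sel)) stop("window outside the epoch span", call. = FALSE)
  conds <- dimnames(erps$averages)[[3L]]
  amp <- vapply(seq_along(conds), function(k) {
    mean(erps$averages[ch, sel, k])
  }, 1.0)
  data.frame(condition = conds,
             switch = ifelse(grepl("^switch", conds), "switch", "no_switch"),
             congruency = ifelse(grepl("incongruent$", conds),
                                 "incongruent", "congruent"),
             component = component, amplitude = amp,
             stringsAsFactors = FALSE)
}

#' Mixed model of window amplitudes on Switch x Congruency with age
#'
#' For one component, fits
#' `amplitude_z ~ switch * congruency + age_z + (1 | subject)` by maximum
#' likelihood (treatment coding, reference no-switch / congruent), with
#' Wald 95% confidence intervals -- the same result contract as
#' [fit_power_model()]. Amplitudes and age are z-scored across the analyzed
#' rows. Singular fits are flagged, not hidden.
#'
#' @param amplitudes data.frame with `subject`, `switch`, `congruency`,
#'   `amplitude` (4 rows per subject).
#' @param ages data.frame with `subject`, `age`.
#' @return a `model_result`.
#' @export
fit_erp_model <- function(amplitudes, ages) {
  d <- merge(amplitudes, ages, by = "subject")
  d$switch <- stats::relevel(factor(d$switch), ref = "no_switch")
  d$congruency <- stats::relevel(factor(d$congruency), ref = "congruent")
  d$subject <- factor(d$subject)
  d$amp_z <- as.vector(scale(d$amplitude))
  d$age_z <- if (stats::sd(d$age) == 0) 0 else as.vector(scale(d$age))
  flags <- character(0)
  if (stats::sd(d$age) == 0) flags <- c(flags, "constant_age")
  fit <- lme4::lmer(amp_z ~ switch * congruency + age_z + (1 | subject),
                    data = d, REML = FALSE)
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[vc$grp == "subject"]
  sig2 <- vc$vcov[vc$grp == "Residual"]
  singular <- lme4::isSingular(fit)
  if (singular) flags <- c(flags, "singular_fit")
  z <- stats::qnorm(0.975)
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se), t = unname(beta / se),
                      ci_lo = unname(beta - z * se),
                      ci_hi = unname(beta + z * se),
                      stringsAsFactors = FALSE)
  fixed_pred <- as.vector(stats::model.matrix(fit) %*% beta)
  var_fix <- stats::var(fixed_pred)
  structure(list(
    coefficients = coefs,
    varcomp = c(subject_intercept = tau2, residual = sig2),
    icc1 = icc1(d$amp_z, d$subject)$icc,
    pseudo_r2_marginal = var_fix / (var_fix + tau2 + sig2),
    n_obs = nrow(d), n_subjects = nlevels(d$subject),
    singular = singular, flags = flags, fit = fit
  ), class = "model_result")
}

#' Per-subject N400 effect
#'
#' Mean over congruency levels of (no-switch minus switch) window
#' amplitude, so a stronger switch negativity yields a *positive* effect.
#'
#' @param amplitudes data.frame with `subject`, `switch`, `congruency`,
#'   `amplitude` (the N400-window rows).
#' @return data.frame with `subject`, `effect` (uV).
#' @export
n400_effect <- function(amplitudes) {
  subs <- sort(unique(amplitudes$subject))
  eff <- vapply(subs, function(s) {
    d <- amplitudes[amplitudes$subject == s, ]
    if (!all(c("switch", "no_switch") %in% d$switch)) {
      stop("subject ", s, " missing a switch condition", call. = FALSE)
    }
    by_cg <- tapply(d$amplitude, list(d$switch, d$congruency), mean)
    mean(by_cg["no_switch", ] - by_cg["switch", ])
  }, 1.0)
  data.frame(subject = subs, effect = eff)
}

#' @rdname standardized_regression
#' @param effects per-subject ERP effect sizes.
#' @param proficiency per-subject L2 proficiency (post-training).
#' @export
effect_proficiency_regression <- function(effects, proficiency) {
  standardized_regression(proficiency, effects)
}

#' Peak latency within a component window
#'
#' Latency (ms) of the extreme value of the pool-mean waveform of one
#' condition within the window; `direction = "min"` for negative
#' components. Reported descriptively.
#'
#' @param erps an `erp_set`.
#' @param condition condition name.
#' @inheritParams window_mean
#' @param direction `"min"` or `"max"`.
#' @return latency in ms.
#' @export
peak_latency <- function(erps, condition, pool, window_ms,
                         direction = c("min", "max")) {
  direction <- match.arg(direction)
  ch <- match(pool, erps$labels)
  ch <- ch[!is.na(ch)]
  if (!length(ch)) stop("empty electrode pool", call. = FALSE)
  sel <- which(erps$times >= window_ms[1L] & erps$times <= window_ms[2L])
  wave <- colMeans(erps$averages[ch, sel, condition, drop = FALSE][, , 1L,
                                                                   drop = FALSE])
  i <- if (direction == "min") which.min(wave) else which.max(wave)
  erps$times[sel[i]]
}

#' Comprehension accuracy
#'
#' Percent correct per subject and the group mean over subjects.
#'
#' @param responses data.frame with `subject` and logical `correct`.
#' @return list with `per_subject` (data.frame `subject`, `accuracy`) and
#'   `group` (percent).
#' @export
comprehension_accuracy <- function(responses) {
  if (!nrow(responses)) stop("no answered questions", call. = FALSE)
  acc <- tapply(responses$correct, responses$subject, function(x) {
    100 * sum(x) / length(x)
  })
  per <- data.frame(subject = as.integer(names(acc)), accuracy = as.vector(acc))
  list(per_subject = per, group = mean(per$accuracy))
}
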