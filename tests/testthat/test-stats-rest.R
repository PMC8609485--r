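make_power_table <- function(log_power, subjects, pool = "p1", band = "beta1") {
  data.frame(subject = subjects, pool = pool, band = band,
             log_power = log_power, stringsAsFactors = FALSE)
}

test_that("spearman screen recovers hand-computed rank correlations", {
  ## 5-subject hand table: ranks of x = (1,2,3,4,5), y = (2,1,4,3,5)
  x <- c(0.1, 0.5, 0.9, 1.4, 2.0)
  y <- c(20, 10, 40, 30, 50)
  tab <- make_power_table(x, 1:5)
  out <- spearman_fdr(tab, data.frame(subject = 1:5, corp = y))
  d <- rank(x) - rank(y)
  rho_hand <- 1 - 6 * sum(d^2) / (5 * (5^2 - 1))
  expect_equal(out$rho, rho_hand)
  expect_true(out$q >= out$p)
})

test_that("a monotone outcome gives rho = 1 in every pool x band cell", {
  cells <- expand.grid(pool = c("p1", "p2"), band = c("alpha", "beta1"),
                       stringsAsFactors = FALSE)
  tab <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    make_power_table(1:6 + i, 1:6, cells$pool[i], cells$band[i])
  }))
  out <- spearman_fdr(tab, data.frame(subject = 1:6, corp = exp(1:6)))
  expect_true(all(out$rho == 1))
})

test_that("degenerate spearman cells are recorded as missing, not dropped", {
  tab <- rbind(make_power_table(rep(1, 5), 1:5, "p1"),
               make_power_table(1:5, 1:5, "p2"))
  out <- spearman_fdr(tab, data.frame(subject = 1:5, corp = c(3, 1, 4, 1, 5)))
  expect_equal(nrow(out), 2L)
  expect_true(is.na(out$rho[out$pool == "p1"]))
  expect_false(is.na(out$q[out$pool == "p2"]))
})

test_that("BH q-values are monotone in p and bounded by 1", {
  set.seed(10)
  cells <- expand.grid(pool = paste0("p", 1:5),
                       band = c("theta", "alpha", "beta1", "beta2", "beta3"),
                       stringsAsFactors = FALSE)
  tab <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    make_power_table(rnorm(8), 1:8, cells$pool[i], cells$band[i])
  }))
  out <- spearman_fdr(tab, data.frame(subject = 1:8, corp = rnorm(8)))
  o <- order(out$p)
  expect_true(all(diff(out$q[o]) >= -1e-12))
  expect_true(all(out$q <= 1))
})

test_that("ICC(1) matches a hand ANOVA table and its boundary cases", {
  ## 3 subjects x 4 values, worked by hand in the comments
  vals <- c(1, 2, 3, 2,   5, 6, 5, 6,   9, 8, 9, 10)
  grp <- rep(1:3, each = 4)
  ## grand mean 5.5; group means 2, 5.5, 9 -> SSB = 4*(12.25+0+12.25) = 98
  ## SSW = (1+0.25+...)= sum within: subj1: (1,0,1,0)->2? compute directly
  msb <- 98 / 2
  ssw <- sum((vals - rep(c(2, 5.5, 9), each = 4))^2)
  msw <- ssw / 9
  out <- icc1(vals, grp)
  expect_equal(out$f, msb / msw)
  expect_equal(out$icc, (msb - msw) / (msb + 3 * msw))
  expect_equal(out$k0, 4)

  ## zero within-subject variance -> ICC 1
  expect_equal(icc1(rep(c(1, 5, 9), each = 3), rep(1:3, each = 3))$icc, 1)
  ## identical group means, positive within variance -> ICC <= 0
  expect_lte(icc1(c(1, -1, 2, -2, 3, -3), rep(1:3, each = 2))$icc, 0)
  expect_error(icc1(1:4, rep(1, 4)), "groups")
})

test_that("noise-free mixed-model data is interpolated exactly", {
  bands <- c("alpha", "theta", "beta1")
  subjects <- 1:6
  corp <- c(-1.5, -0.9, -0.3, 0.3, 0.9, 1.5)
  b0 <- 0.6
  bband <- c(alpha = 0, theta = -0.39, beta1 = -0.37)
  bint <- c(alpha = 0, theta = 0.06, beta1 = 0.11)
  bcorp <- -0.05
  d <- expand.grid(subject = subjects, pool = c("p1", "p2"), band = bands,
                   stringsAsFactors = FALSE)
  corp_z <- (corp - mean(corp)) / sd(corp)
  d$log_power <- b0 + bband[d$band] + bcorp * corp_z[d$subject] +
    bint[d$band] * corp_z[d$subject]
  ## zero residual variance: lme4 emits convergence chatter, irrelevant here
  fit <- suppressWarnings(
    fit_power_model(d, data.frame(subject = subjects, corp = corp)))
  co <- fit$coefficients
  get <- function(term) co$estimate[co$term == term]
  expect_equal(get("(Intercept)"), b0, tolerance = 1e-6)
  expect_equal(get("corp_z"), bcorp, tolerance = 1e-6)
  expect_equal(get("bandbeta1"), -0.37, tolerance = 1e-6)
  expect_equal(get("corp_z:bandbeta1"), 0.11, tolerance = 1e-6)
})

test_that("degenerate outcomes fall back to a flagged band-only model", {
  d <- expand.grid(subject = 1:4, pool = "p1",
                   band = c("alpha", "beta1"), stringsAsFactors = FALSE)
  set.seed(1)
  d$log_power <- rnorm(nrow(d))
  fit <- fit_power_model(d, data.frame(subject = 1:4, corp = rep(5, 4)))
  expect_true("degenerate_outcome" %in% fit$flags)
  expect_false(any(grepl("corp_z", fit$coefficients$term)))
})

test_that("a single subject reduces to OLS with a zero variance component", {
  d <- data.frame(subject = 1, pool = rep(c("p1", "p2"), 3),
                  band = rep(c("alpha", "beta1", "theta"), each = 2),
                  log_power = c(1, 1.2, 0.4, 0.5, 0.8, 0.7))
  fit <- fit_power_model(d, data.frame(subject = 1, corp = 10))
  expect_true("single_subject" %in% fit$flags)
  expect_equal(unname(fit$varcomp["subject_intercept"]), 0)
  ols <- lm(log_power ~ relevel(factor(band), "alpha"), data = d)
  expect_equal(sort(fit$coefficients$estimate), sort(unname(coef(ols))),
               tolerance = 1e-10)
})

test_that("mixed-model CIs cover generating values at the nominal rate", {
  set.seed(20)
  bands <- c("alpha", "theta", "beta1", "beta2", "beta3")
  bmeans <- c(alpha = 0.6, theta = 0.21, beta1 = 0.23, beta2 = 0.16,
              beta3 = 0.09)
  bint <- c(alpha = 0, theta = 0.06, beta1 = 0.11, beta2 = 0.06,
            beta3 = 0.06)
  covered <- replicate(50, {
    n <- 40
    u <- rnorm(n, sd = sqrt(0.05))
    corp <- rnorm(n)
    d <- expand.grid(subject = 1:n, pool = paste0("p", 1:5), band = bands,
                     stringsAsFactors = FALSE)
    cz <- (corp - mean(corp)) / sd(corp)
    d$log_power <- bmeans[d$band] + bint[d$band] * cz[d$subject] +
      u[d$subject] + rnorm(nrow(d), sd = sqrt(0.3))
    fit <- fit_power_model(d, data.frame(subject = 1:n, corp = corp))
    co <- fit$coefficients[fit$coefficients$term == "corp_z:bandbeta1", ]
    co$ci_lo <= 0.11 && co$ci_hi >= 0.11
  })
  expect_gte(mean(covered), 0.85) # nominal 95%, binomial slack at 50 reps
})

test_that("wilcoxon signed-rank handles the exact and boundary cases", {
  x1 <- 1:10
  res <- wilcoxon_paired(x1, x1 + c(1, 2.2, 1.5, 3, 2.5, 1.1, 2, 4, 3.5, 0.5),
                         alternative = "greater")
  expect_equal(res$statistic, 55)
  expect_equal(res$p, 1 / 1024)
  ## all-positive shifts give the rank-biserial boundary value 1
  rb <- wilcoxon_paired(x1, x1 + 2, effect = "rank_biserial")
  expect_equal(rb$effect_size, 1)
  ## matched-rank r for the all-positive case: Z = 27.5/sqrt(96.25)
  expect_equal(res$effect_size, (27.5 / sqrt(96.25)) / sqrt(10),
               tolerance = 1e-10)
  ## antisymmetric differences: two-sided p near 1
  d <- c(3, -3, 5, -5, 7, -7, 2, -2, 9, -9)
  sym <- wilcoxon_paired(rep(0, 10), d)
  expect_gt(sym$p, 0.9)
  expect_error(wilcoxon_paired(1:4, 1:4), "zero")
  expect_error(wilcoxon_paired(1:4, c(2, 3, 4, 5)), ">= 5")
})

test_that("standardized regression recovers exact and null relationships", {
  x <- c(1, 3, 2, 5, 4, 7)
  perfect <- suppressWarnings(change_outcome_regression(x, x * 2 + 1))
  expect_equal(perfect$slope, 1, tolerance = 1e-12)
  expect_gt(perfect$ci[1], 0)

  set.seed(8)
  null <- change_outcome_regression(rnorm(1000), rnorm(1000))
  expect_lt(abs(null$slope), 0.1)

  two <- standardized_regression(c(1, 2), c(5, 9))
  expect_true("degenerate_n2" %in% two$flags)
  expect_true(is.na(two$ci[1]))
  expect_error(standardized_regression(rep(1, 5), 1:5), "zero-variance")
})
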