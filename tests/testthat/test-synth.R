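test_that("resting-state generation is deterministic given config and seed", {
  cfg <- quick_cfg()
  a <- generate_resting_eeg(cfg, 1)
  b <- generate_resting_eeg(cfg, 1)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$ground_truth, b$ground_truth)
  c2 <- generate_resting_eeg(quick_cfg(seed = 124), 1)
  expect_false(identical(a$recording$data, c2$recording$data))
})

test_that("degenerate config yields a pure sinusoid of the set amplitude", {
  cfg <- quick_cfg(noise_sd = 0, osc_mod_depth = 0, subject_gain_log10_sd = 0,
                   artifact_rates = c(blink = 0, step = 0, flat = 0),
                   band_amplitudes = c(alpha = 2))
  rec <- generate_resting_eeg(cfg, 1)$recording
  for (ch in c(1L, nrow(rec$data))) {
    x <- rec$data[ch, ]
    expect_equal(max(abs(x)), 2, tolerance = 1e-3)
    expect_equal(sqrt(mean(x^2)), 2 / sqrt(2), tolerance = 1e-3)
  }
})

test_that("injected artifacts are logged within bounds and realized in the data", {
  cfg <- quick_cfg(artifact_rates = c(blink = 6, step = 6, flat = 3),
                   seed = 5)
  out <- generate_resting_eeg(cfg, 1)
  log <- out$ground_truth$artifact_log
  n <- ncol(out$recording$data)
  expect_gt(nrow(log), 0)
  expect_true(all(log$start >= 0 & log$end <= n))
  flats <- log[log$kind == "flat", ]
  for (i in seq_len(nrow(flats))) {
    seg <- out$recording$data[match(flats$channel[i],
                                    out$recording$montage$label),
                              (flats$start[i] + 1L):flats$end[i]]
    expect_lt(diff(range(seg)), 0.5)
  }
  steps <- log[log$kind == "step", ]
  for (i in seq_len(nrow(steps))) {
    ch <- match(steps$channel[i], out$recording$montage$label)
    s <- steps$start[i] # 0-based; jump between samples s-1 and s
    jump <- abs(out$recording$data[ch, s + 1L] - out$recording$data[ch, s])
    expect_gt(jump, 50)
  }
})

test_that("oscillator peaks fall in their configured bands (brute-force DFT)", {
  cfg <- quick_cfg(artifact_rates = c(blink = 0, step = 0, flat = 0),
                   noise_sd = 0.5, seed = 31)
  out <- generate_resting_eeg(cfg, 1)
  x <- out$recording$data[1, 1:1024]
  p <- brute_dft_power(x)
  freqs <- (0:(length(p) - 1)) * cfg$fs / 1024
  bands <- band_scheme()
  for (b in rownames(bands)) {
    sel <- freqs > bands[b, "low"] & freqs <= bands[b, "high"]
    peak <- freqs[sel][which.max(p[sel])]
    expect_lt(abs(peak - out$ground_truth$oscillator_freqs[b]), 1)
  }
})

test_that("stimulus table has the full 2x2 design and respects switch eligibility", {
  stim <- generate_stimulus_list(80)
  expect_equal(nrow(stim), 320)
  expect_equal(as.integer(table(stim$condition)), rep(80L, 4L))
  expect_true(all(stim$n_words >= 9 & stim$n_words <= 12))
  lex <- default_lexicon()
  inelig <- lex$nouns$l2[!lex$nouns$switch_eligible]
  expect_gt(length(inelig), 0) # e.g. house/Haus differs in one letter
  expect_false(any(stim$target_l2 %in% inelig))
  ## every sentence appears once per condition with a stable target
  per_sentence <- tapply(stim$condition, stim$sentence_id,
                         function(x) length(unique(x)))
  expect_true(all(per_sentence == 4))
})

test_that("a single sentence yields one row per condition", {
  stim <- generate_stimulus_list(1)
  expect_equal(nrow(stim), 4)
  expect_setequal(stim$condition,
                  c("no_switch_congruent", "no_switch_incongruent",
                    "switch_congruent", "switch_incongruent"))
})

test_that("an impoverished lexicon is rejected with a deficit message", {
  nouns <- data.frame(l2 = c("house", "man"), l1 = c("Haus", "Mann"))
  verbs <- data.frame(l2 = "see", l1 = "sehen")
  expect_error(generate_stimulus_list(10, nouns, verbs), "switch-eligible")
})

test_that("identical aptitude and zero noise give identical CorP", {
  cfg <- quick_cfg(n_subjects = 5, corp_noise_sd = 0, test_noise_sd = 0)
  beh <- generate_behavioral_scores(cfg, aptitudes = rep(0.4, 5))
  expect_equal(max(beh$corp) - min(beh$corp), 0, tolerance = 1e-9)
})

test_that("three correlated tests put >80% of T1 variance on the first PC", {
  cfg <- quick_cfg(n_subjects = 200)
  beh <- generate_behavioral_scores(cfg)
  share <- first_pc_variance_share(
    as.matrix(beh[, c("c_test_T1", "course_test_T1", "listening_T1")]))
  expect_gt(share, 80) # population value 100*(1+2*0.85)/3 = 90
})

test_that("generated CorP tracks latent aptitude monotonically", {
  cfg <- quick_cfg(n_subjects = 50)
  beh <- generate_behavioral_scores(cfg)
  expect_gt(cor(beh$aptitude, beh$corp, method = "spearman"), 0.9)
})

test_that("CorP moments match the configured generating link at n = 200", {
  cfg <- quick_cfg(n_subjects = 200)
  beh <- generate_behavioral_scores(cfg)
  ## oracle: analytic moments of base + range*plogis(slope*Z) + noise
  ef <- stats::integrate(function(z) plogis(cfg$corp_slope * z) * dnorm(z),
                         -Inf, Inf)$value
  ef2 <- stats::integrate(function(z) plogis(cfg$corp_slope * z)^2 * dnorm(z),
                          -Inf, Inf)$value
  mu <- cfg$corp_base + cfg$corp_range * ef
  sd_th <- sqrt(cfg$corp_range^2 * (ef2 - ef^2) + cfg$corp_noise_sd^2)
  se <- sd_th / sqrt(200)
  expect_lt(abs(mean(beh$true_corp) - mu), 2 * se)
  expect_lt(abs(sd(beh$true_corp) - sd_th), 2 * sd_th / sqrt(2 * 199))
})

test_that("ERP generation is deterministic and carries the 2x2 design", {
  cfg <- quick_cfg(erp_trials_per_condition = 4)
  a <- generate_erp_dataset(cfg, 1)
  b <- generate_erp_dataset(cfg, 1)
  expect_identical(a$epochs$epochs, b$epochs$epochs)
  expect_equal(as.integer(table(a$epochs$conditions)), rep(4L, 4L))
  expect_equal(dim(a$epochs$epochs)[2L], length(a$epochs$times))
})

test_that("noise-free ERP switch contrast equals the template window mean", {
  cfg <- quick_cfg(erp_noise_sd = 0, erp_trials_per_condition = 2,
                   n400_proficiency_attenuation = 0,
                   n400_incongruent_boost_uv = 0)
  out <- generate_erp_dataset(cfg, 1)
  eps <- baseline_correct(out$epochs)
  erps <- condition_average(eps)
  wm <- window_mean(erps, erp_pool_labels()$central, c(300, 450), "N400")
  sw <- mean(wm$amplitude[wm$switch == "switch"])
  ns <- mean(wm$amplitude[wm$switch == "no_switch"])
  ## oracle: discrete mean of the Gaussian template over the window samples,
  ## at the logged injected peak (subject gain included)
  times <- eps$times
  sel <- times >= 300 & times <= 450
  expect_equal(out$ground_truth$injected_n400_peak_uv,
               -2 * out$ground_truth$gain)
  expected <- out$ground_truth$injected_n400_peak_uv *
    mean(exp(-(times[sel] - 375)^2 / (2 * 40^2)))
  expect_equal(sw - ns, expected, tolerance = 1e-8)
})

test_that("with no injected components all condition averages are near zero", {
  cfg <- quick_cfg(erp_trials_per_condition = 40,
                   n400_template = list(latency_ms = 375, sd_ms = 40, peak_uv = 0),
                   lpc_template = list(latency_ms = 700, sd_ms = 50, peak_uv = 0),
                   n400_incongruent_boost_uv = 0)
  out <- generate_erp_dataset(cfg, 1)
  erps <- condition_average(baseline_correct(out$epochs))
  wm <- window_mean(erps, erp_pool_labels()$central, c(300, 450))
  ## pool/window mean of white noise: tolerance ~4 SEM
  sem <- cfg$erp_noise_sd / sqrt(40 * sum(erps$times >= 300 & erps$times <= 450))
  expect_true(all(abs(wm$amplitude) < 4 * sem * 3))
})

test_that("comprehension accuracy is centred on the configured rate", {
  cfg <- quick_cfg(n_subjects = 40)
  resp <- do.call(rbind, lapply(1:40, function(s) {
    generate_comprehension_responses(cfg, s)
  }))
  acc <- comprehension_accuracy(resp)
  expect_equal(nrow(resp) / 40, floor(4 * cfg$erp_trials_per_condition / 3))
  expect_lt(abs(acc$group - 81), 8)
})
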