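#' Simulated participant ages
#'
#' Uniform over the recruited range (65-74 years), drawn once from the
#' master seed.
#' @param cfg a [sim_config()].
#' @return data.frame with `subject`, `age`.
#' @export
subject_ages <- function(cfg) {
  withr_seed(subject_seed(cfg$seed, 0L, stream = 6L), {
    data.frame(subject = seq_len(cfg$n_subjects),
               age = round(stats::runif(cfg$n_subjects, 65, 74)))
  })
}

#' Preprocess one resting recording and extract band-pool power
#'
#' The fixed stage order: band-pass filter, ocular correction, artifact
#' detection, bad-channel interpolation, average re-reference, artifact
#' re-detection on the re-referenced data, eyes-closed segment extraction,
#' overlapping epoching with mask skipping, epoch-averaged spectra, band x
#' pool means. Stage toggles allow cheaper runs (e.g. simulation studies
#' with artifact injection disabled).
#'
#' @param rec an [new_recording()].
#' @param params analysis parameters, see [default_analysis_params()].
#' @param pools resting pools (default from the recording's montage).
#' @param stages named logical list; `filter`, `ocular` and `artifacts` can
#'   be toggled (e.g. simulation studies generated without artifact
#'   injection skip the vacuous detection passes).
#' @return list with `band_power` (a `band_power_table`), `mask`,
#'   `interp_report`, `n_epochs`.
#' @export
preprocess_resting <- function(rec, params = default_analysis_params(),
                               pools = NULL,
                               stages = list(filter = TRUE, ocular = TRUE,
                                             artifacts = TRUE)) {
  if (is.null(pools)) pools <- resting_pools(rec$montage)
  if (isTRUE(stages$filter)) {
    rec <- bandpass_filter(rec, params$low_hz, params$high_hz,
                           params$low_rolloff_db_oct,
                           params$high_rolloff_db_oct)
  }
  oc_report <- NULL
  if (isTRUE(stages$ocular)) {
    oc <- correct_ocular(rec)
    rec <- oc$recording
    oc_report <- oc$report
  }
  do_artifacts <- !isFALSE(stages$artifacts)
  det <- function(r) detect_artifacts(
    r, params$gradient_uv, params$maxdiff_uv, params$maxdiff_window_ms,
    params$lowact_uv, params$lowact_window_ms, params$pad_ms)
  if (do_artifacts) {
    mask0 <- det(rec)
    interp <- interpolate_bad_channels(rec, mask0, params$reject_fraction,
                                       params$max_interp, params$k_neighbors)
    rec <- rereference_average(interp$recording)
    mask <- det(rec)
  } else {
    interp <- list(report = NULL)
    rec <- rereference_average(rec)
    mask <- NULL
  }
  segs <- extract_ec_segments(rec, params$trim_s)
  eps <- epoch_fixed_overlap(segs, mask, params$epoch_s, params$overlap)
  psd <- epoch_psd(eps, taper = params$taper)
  bp <- band_pool_means(psd, band_scheme(params$include_gamma), pools)
  list(band_power = bp, mask = mask, interp_report = interp$report,
       ocular_report = oc_report, n_epochs = dim(eps$epochs)[3L])
}

#' Run the resting-state experiment end to end
#'
#' Simulates the cohort (pre- and post-training resting EEG plus the
#' behavioral assessments), preprocesses every recording, extracts band x
#' pool log power, and runs the Experiment-1 inference: the Spearman/FDR
#' screen, ICC(1), the mixed model of log power on standardized learning
#' gain, paired Wilcoxon tests of the L2 composite and of beta1 power, and
#' the power-change vs gain regression.
#'
#' @param cfg a [sim_config()].
#' @param params analysis parameters, see [default_analysis_params()].
#' @param out_dir optional output directory; when given, tables, reports
#'   and a `MANIFEST.json` (config hash, seed, file list) are written.
#' @param stages stage toggles forwarded to [preprocess_resting()].
#' @param sessions sessions to simulate (`c("T1", "T2")`; dropping `"T2"`
#'   skips the pre/post comparisons).
#' @return list of class `exp1_report` with elements `band_power`,
#'   `behavior`, `correlations`, `icc`, `model`, `wilcoxon_l2`,
#'   `wilcoxon_beta1`, `change_regression`, `qc`.
#' @export
run_experiment1 <- function(cfg, params = default_analysis_params(),
                            out_dir = NULL,
                            stages = list(filter = TRUE, ocular = TRUE),
                            sessions = c("T1", "T2")) {
  montage <- build_montage(cfg$n_channels)
  pools <- resting_pools(montage)
  tables <- list()
  qc <- list()
  for (session in sessions) {
    rows <- vector("list", cfg$n_subjects)
    for (s in seq_len(cfg$n_subjects)) {
      gen <- generate_resting_eeg(cfg, s, session, montage)
      pp <- preprocess_resting(gen$recording, params, pools, stages)
      bp <- pp$band_power
      bp$subject <- s
      bp$session <- session
      rows[[s]] <- bp
      qc[[paste0(session, "_s", s)]] <- list(
        n_epochs = pp$n_epochs,
        interpolated = pp$interp_report$channel,
        masked_fraction = if (is.null(pp$mask)) NA_real_ else
          mean(mask_fraction(pp$mask)))
    }
    tables[[session]] <- do.call(rbind, rows)
  }
  behavior <- generate_behavioral_scores(cfg)
  t1 <- tables$T1
  correlations <- spearman_fdr(t1, behavior)
  icc <- icc1(t1$log_power, t1$subject)
  model <- fit_power_model(t1, behavior)
  wilcoxon_l2 <- wilcoxon_paired(behavior$composite_T1, behavior$composite_T2,
                                 alternative = "greater")
  wilcoxon_beta1 <- NULL
  change_reg <- NULL
  if ("T2" %in% sessions) {
    b1_t1 <- tapply(t1$log_power[t1$band == "beta1"],
                    t1$subject[t1$band == "beta1"], mean)
    t2 <- tables$T2
    b1_t2 <- tapply(t2$log_power[t2$band == "beta1"],
                    t2$subject[t2$band == "beta1"], mean)
    wilcoxon_beta1 <- wilcoxon_paired(as.vector(b1_t1), as.vector(b1_t2))
    delta <- band_power_change(t1, t2, "beta1")
    change_reg <- change_outcome_regression(delta$delta_log10, behavior$corp)
  }
  report <- structure(list(
    band_power = do.call(rbind, tables), behavior = behavior,
    correlations = correlations, icc = icc, model = model,
    wilcoxon_l2 = wilcoxon_l2, wilcoxon_beta1 = wilcoxon_beta1,
    change_regression = change_reg, qc = qc, config = unclass(cfg)
  ), class = "exp1_report")
  if (!is.null(out_dir)) write_exp1_bundle(report, out_dir)
  report
}

#' Run the language-switching ERP experiment end to end
#'
#' Simulates the post-training ERP session for every subject (trial epochs
#' in the 2x2 switch x congruency design plus comprehension responses and
#' the stimulus table), baseline-corrects and averages by condition,
#' extracts N400 (Central pool) and LPC (Parietal pool) window means, and
#' runs the Experiment-2 inference: the Switch x Congruency mixed model
#' with age per component, the per-subject N400 effect and its regression
#' on post-training proficiency, the LPC congruency effect regression, and
#' comprehension accuracy (with the proficiency-vs-accuracy BIC check).
#'
#' @inheritParams run_experiment1
#' @param behavior optional behavioral table (defaults to the cfg cohort);
#'   must contain `subject` and `composite_T2`.
#' @return list of class `exp2_report`.
#' @export
run_experiment2 <- function(cfg, params = default_analysis_params(),
                            out_dir = NULL, behavior = NULL) {
  if (is.null(behavior)) behavior <- generate_behavioral_scores(cfg)
  if (!all(c("subject", "composite_T2") %in% names(behavior))) {
    stop("behavior table must contain 'subject' and 'composite_T2'",
         call. = FALSE)
  }
  montage <- build_montage(cfg$n_channels)
  pools <- erp_pool_labels()
  amp_rows <- list()
  resp_rows <- list()
  latencies <- list()
  for (s in seq_len(cfg$n_subjects)) {
    gen <- generate_erp_dataset(cfg, s, montage)
    eps <- baseline_correct(gen$epochs, params$erp_baseline_ms)
    erps <- condition_average(eps)
    wm_n4 <- window_mean(erps, pools$central, params$n400_window_ms, "N400")
    wm_lpc <- window_mean(erps, pools$parietal, params$lpc_window_ms, "LPC")
    wm <- rbind(wm_n4, wm_lpc)
    wm$subject <- s
    amp_rows[[s]] <- wm
    resp_rows[[s]] <- generate_comprehension_responses(cfg, s)
    latencies[[s]] <- data.frame(
      subject = s,
      n400_latency_ms = peak_latency(erps, "switch_congruent", pools$central,
                                     params$n400_window_ms, "min"),
      lpc_latency_ms = peak_latency(erps, "no_switch_incongruent",
                                    pools$parietal, params$lpc_window_ms,
                                    "max"))
  }
  amplitudes <- do.call(rbind, amp_rows)
  ages <- subject_ages(cfg)
  model_n400 <- fit_erp_model(amplitudes[amplitudes$component == "N400", ], ages)
  model_lpc <- fit_erp_model(amplitudes[amplitudes$component == "LPC", ], ages)
  effects <- n400_effect(amplitudes[amplitudes$component == "N400", ])
  prof <- behavior$composite_T2[match(effects$subject, behavior$subject)]
  n400_reg <- effect_proficiency_regression(effects$effect, prof)
  lpc_eff <- vapply(split(amplitudes[amplitudes$component == "LPC", ],
                          amplitudes$subject[amplitudes$component == "LPC"]),
                    function(d) {
                      mean(d$amplitude[d$congruency == "incongruent"]) -
                        mean(d$amplitude[d$congruency == "congruent"])
                    }, 1.0)
  lpc_reg <- standardized_regression(prof, as.vector(lpc_eff))
  responses <- do.call(rbind, resp_rows)
  accuracy <- comprehension_accuracy(responses)
  acc <- accuracy$per_subject$accuracy[match(effects$subject,
                                             accuracy$per_subject$subject)]
  acc_prof_cor <- stats::cor(acc, prof)
  bic_prof <- stats::BIC(stats::lm(scale(effects$effect) ~ scale(prof)))
  bic_acc <- stats::BIC(stats::lm(scale(effects$effect) ~ scale(acc)))
  stimuli <- generate_stimulus_list(cfg$erp_trials_per_condition,
                                    seed = cfg$seed)
  report <- structure(list(
    amplitudes = amplitudes, effects = effects,
    model_n400 = model_n400, model_lpc = model_lpc,
    n400_proficiency_regression = n400_reg,
    lpc_proficiency_regression = lpc_reg,
    latencies = do.call(rbind, latencies),
    accuracy = accuracy, accuracy_proficiency_cor = acc_prof_cor,
    bic = c(proficiency = bic_prof, accuracy = bic_acc),
    stimuli = stimuli, behavior = behavior, config = unclass(cfg)
  ), class = "exp2_report")
  if (!is.null(out_dir)) write_exp2_bundle(report, out_dir)
  report
}

serialize_report <- function(report) {
  keep <- report
  ## drop non-serializable fitted-model objects
  for (nm in c("model", "model_n400", "model_lpc")) {
    if (!is.null(keep[[nm]])) keep[[nm]]$fit <- NULL
  }
  keep$qc <- NULL
  jsonlite::toJSON(keep, auto_unbox = TRUE, digits = 10, dataframe = "columns",
                   force = TRUE, na = "null")
}

write_manifest <- function(out_dir, files, cfg) {
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = cfg$seed,
    files = basename(c(cfg_path, files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE)
}

write_exp1_bundle <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(out_dir, "band_power.tsv")
  write_band_power(report$band_power, f1)
  f2 <- file.path(out_dir, "behavior.tsv")
  write_assessment(report$behavior, f2)
  f3 <- file.path(out_dir, "correlations.tsv")
  utils::write.table(report$correlations, f3, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f4 <- file.path(out_dir, "exp1_report.json")
  writeLines(serialize_report(report), f4)
  write_manifest(out_dir, c(f1, f2, f3, f4), report$config)
  invisible(out_dir)
}

write_exp2_bundle <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(out_dir, "window_amplitudes.tsv")
  utils::write.table(report$amplitudes, f1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f2 <- file.path(out_dir, "stimuli.tsv")
  utils::write.table(report$stimuli, f2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f3 <- file.path(out_dir, "exp2_report.json")
  writeLines(serialize_report(report), f3)
  write_manifest(out_dir, c(f1, f2, f3), report$config)
  invisible(out_dir)
}

#' @export
print.exp1_report <- function(x, ...) {
  cat("<exp1_report> ", length(unique(x$behavior$subject)), " subjects\n",
      sep = "")
  cat("ICC(1) =", round(x$icc$icc, 3), "\n")
  cat("mixed model (alpha reference):\n")
  print(x$model)
  invisible(x)
}

#' @export
print.exp2_report <- function(x, ...) {
  cat("<exp2_report> ", length(unique(x$effects$subject)), " subjects\n",
      sep = "")
  cat("N400 effect ~ proficiency: slope ",
      round(x$n400_proficiency_regression$slope, 3), " [",
      round(x$n400_proficiency_regression$ci[1L], 3), ", ",
      round(x$n400_proficiency_regression$ci[2L], 3), "]\n", sep = "")
  cat("comprehension accuracy ", round(x$accuracy$group, 2), "%\n", sep = "")
  invisible(x)
}
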