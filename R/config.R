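#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort: the resting-state recording
#' protocol (alternating eyes-open/eyes-closed blocks), the oscillatory
#' content per frequency band, the strength of the latent-aptitude link into
#' beta1 amplitude and into the corrected learning gain, artifact rates, and
#' the 2x2 language-switching ERP design.
#'
#' Defaults mirror the emulated study protocol: 128 channels at 512 Hz,
#' two 2-minute eyes-closed segments inside an 8-minute alternating
#' recording, and 80 trials per ERP condition.
#'
#' @param n_subjects number of simulated subjects.
#' @param n_channels electrode count (>= 16; pools must be representable).
#' @param fs sampling rate, samples/second.
#' @param ec_segment_seconds duration of one eyes-closed block (two blocks
#'   are recorded, alternating with eyes-open blocks of the same length).
#' @param band_amplitudes named numeric vector of mean oscillator amplitudes
#'   (uV) per band (`theta`, `alpha`, `beta1`, `beta2`, `beta3`).
#' @param beta1_aptitude_slope uV of beta1 oscillator amplitude per unit
#'   latent aptitude (z-score). This is the injected brain-behavior link.
#' @param beta1_t2_log10_change log10 band-power change of beta1 from the
#'   pre-training (T1) to the post-training (T2) recording.
#' @param artifact_rates named numeric vector, events/minute, for `blink`,
#'   `step` and `flat` artifact kinds.
#' @param blink_peak_uv peak amplitude of the biphasic blink template (uV).
#' @param step_uv DC shift magnitude of a step artifact (uV).
#' @param osc_mod_depth depth (0..1) of the slow random amplitude modulation
#'   applied to every oscillator; 0 gives pure sinusoids.
#' @param subject_gain_log10_sd standard deviation (log10 uV^2 units) of the
#'   per-subject global power offset. EEG amplitudes vary substantially
#'   between individuals (skull thickness, electrode coupling); this stable
#'   trait multiplies every amplitude by `10^(offset/2)`, makes power values
#'   cluster within subjects (a positive ICC(1)), and is what motivates the
#'   subject random intercept downstream. Set 0 for exact closed-form checks.
#' @param noise_sd standard deviation of the 1/f background (uV).
#' @param erp_trials_per_condition trials per cell of the 2x2 design.
#' @param erp_noise_sd standard deviation of the ERP single-trial background
#'   (uV); the background is 1/f-shaped, sliced from a continuous stream.
#' @param n400_template,lpc_template lists with `latency_ms`, `sd_ms`,
#'   `peak_uv` describing the Gaussian-windowed components injected for
#'   language switch (negative, central pool) and semantic incongruence
#'   (positive, parietal pool).
#' @param n400_proficiency_attenuation per-SD shrinkage of the switch
#'   component with proficiency: the injected peak is scaled by
#'   `1 - attenuation * proficiency_z` (floored at 0).
#' @param n400_incongruent_boost_uv extra negativity (uV) of the N400-window
#'   component on incongruent trials, independent of switching -- produces
#'   the graded condition ordering (switch-incongruent most negative,
#'   no-switch-congruent least) without a reliable congruency main effect.
#' @param corp_base,corp_range,corp_slope,corp_noise_sd parameters of the
#'   monotone (logistic) link from latent aptitude to the true corrected
#'   learning gain: `CorP = base + range * plogis(slope * aptitude) + noise`.
#' @param t1_mean,t1_sd location/scale of the T1 composite percentile.
#' @param test_intercorrelation common correlation among the three language
#'   tests (drives the dominant first principal component).
#' @param test_noise_sd per-test percentile jitter at T2 (percent points).
#' @param comprehension_accuracy group-level target probability of a correct
#'   comprehension answer; per-subject accuracy shifts with aptitude.
#' @param seed integer master seed; per-subject streams are derived from it.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 10,
                       n_channels = 128,
                       fs = 512,
                       ec_segment_seconds = 120,
                       band_amplitudes = c(theta = 3, alpha = 6, beta1 = 1.5,
                                           beta2 = 1.2, beta3 = 1.0),
                       beta1_aptitude_slope = 0.5,
                       beta1_t2_log10_change = -0.04,
                       artifact_rates = c(blink = 4, step = 0.5, flat = 0.2),
                       blink_peak_uv = 250,
                       step_uv = 80,
                       osc_mod_depth = 0.2,
                       subject_gain_log10_sd = 0.2,
                       noise_sd = 5,
                       erp_trials_per_condition = 80,
                       erp_noise_sd = 10,
                       n400_template = list(latency_ms = 375, sd_ms = 40, peak_uv = -2),
                       lpc_template = list(latency_ms = 700, sd_ms = 50, peak_uv = 1.5),
                       n400_proficiency_attenuation = 0.3,
                       n400_incongruent_boost_uv = 0.5,
                       corp_base = 15,
                       corp_range = 75,
                       corp_slope = 1.2,
                       corp_noise_sd = 3,
                       t1_mean = 40,
                       t1_sd = 15,
                       test_intercorrelation = 0.85,
                       test_noise_sd = 2,
                       comprehension_accuracy = 0.81,
                       seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_channels = as.integer(n_channels),
    fs = fs, ec_segment_seconds = ec_segment_seconds,
    band_amplitudes = band_amplitudes,
    beta1_aptitude_slope = beta1_aptitude_slope,
    beta1_t2_log10_change = beta1_t2_log10_change,
    artifact_rates = artifact_rates, blink_peak_uv = blink_peak_uv,
    step_uv = step_uv, osc_mod_depth = osc_mod_depth,
    subject_gain_log10_sd = subject_gain_log10_sd, noise_sd = noise_sd,
    erp_trials_per_condition = as.integer(erp_trials_per_condition),
    erp_noise_sd = erp_noise_sd,
    n400_template = n400_template, lpc_template = lpc_template,
    n400_proficiency_attenuation = n400_proficiency_attenuation,
    n400_incongruent_boost_uv = n400_incongruent_boost_uv,
    corp_base = corp_base, corp_range = corp_range, corp_slope = corp_slope,
    corp_noise_sd = corp_noise_sd, t1_mean = t1_mean, t1_sd = t1_sd,
    test_intercorrelation = test_intercorrelation,
    test_noise_sd = test_noise_sd,
    comprehension_accuracy = comprehension_accuracy,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  if (cfg$fs <= 0) stop("fs must be positive", call. = FALSE)
  if (cfg$ec_segment_seconds <= 0) {
    stop("ec_segment_seconds must be positive", call. = FALSE)
  }
  if (any(cfg$band_amplitudes < 0)) {
    stop("band amplitudes must be non-negative", call. = FALSE)
  }
  if (any(cfg$artifact_rates < 0)) {
    stop("artifact rates must be non-negative", call. = FALSE)
  }
  if (cfg$erp_trials_per_condition < 1L) {
    stop("need at least one trial per condition", call. = FALSE)
  }
  if (cfg$noise_sd < 0 || cfg$erp_noise_sd < 0) {
    stop("noise standard deviations must be non-negative", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_subjects, " subjects, ", x$n_channels,
      " channels @ ", x$fs, " Hz, 2 x ", x$ec_segment_seconds,
      " s eyes-closed, ", x$erp_trials_per_condition,
      " trials/condition, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Latent aptitude of every simulated subject
#'
#' One z-scored latent trait per subject drives the injected beta1 amplitude,
#' the true corrected gain, the ERP switch-component attenuation and the
#' comprehension accuracy. Drawn once from the master seed so all generators
#' agree on the same cohort.
#'
#' @param cfg a [sim_config()].
#' @return numeric vector of length `n_subjects`.
#' @export
latent_aptitudes <- function(cfg) {
  withr_seed(subject_seed(cfg$seed, 0L, stream = 99L), {
    stats::rnorm(cfg$n_subjects)
  })
}

#' Per-subject global amplitude gain
#'
#' The multiplicative amplitude factor `10^(offset/2)` implied by the
#' subject's global log10-power offset; session-independent (a stable
#' trait).
#' @param cfg a [sim_config()].
#' @param subject 1-based subject index.
#' @return scalar gain.
#' @export
subject_gain <- function(cfg, subject) {
  if (cfg$subject_gain_log10_sd == 0) return(1)
  withr_seed(subject_seed(cfg$seed, subject, stream = 8L), {
    10^(stats::rnorm(1, sd = cfg$subject_gain_log10_sd) / 2)
  })
}

## Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Read a pipeline run configuration from YAML
#'
#' Unknown keys are rejected so typos in a config file fail loudly instead of
#' silently falling back to defaults. Keys under `simulation` are passed to
#' [sim_config()]; `analysis` holds thresholds of the preprocessing and
#' statistics stages.
#'
#' @param path YAML file.
#' @return list with elements `simulation` (a `sim_config`) and `analysis`.
#' @export
run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed_top <- c("simulation", "analysis")
  extra <- setdiff(names(raw), allowed_top)
  if (length(extra)) {
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  sim_args <- raw$simulation %||% list()
  known <- names(formals(sim_config))
  bad <- setdiff(names(sim_args), known)
  if (length(bad)) {
    stop("unknown simulation keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ana_defaults <- default_analysis_params()
  ana <- raw$analysis %||% list()
  bad <- setdiff(names(ana), names(ana_defaults))
  if (length(bad)) {
    stop("unknown analysis keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ana <- utils::modifyList(ana_defaults, ana)
  list(simulation = do.call(sim_config, sim_args), analysis = ana)
}

#' Default analysis-stage parameters
#'
#' The thresholds of the artifact-rejection and epoching stages, mirroring
#' the emulated preprocessing protocol.
#' @return named list.
#' @export
default_analysis_params <- function() {
  list(
    low_hz = 0.1, high_hz = 30, low_rolloff_db_oct = 12, high_rolloff_db_oct = 48,
    gradient_uv = 50, maxdiff_uv = 200, maxdiff_window_ms = 200,
    lowact_uv = 0.5, lowact_window_ms = 100, pad_ms = 200,
    reject_fraction = 0.10, max_interp = 5, k_neighbors = 4,
    trim_s = 5, epoch_s = 2, overlap = 0.5, taper = "hann",
    include_gamma = FALSE,
    erp_window_ms = c(-100, 1000), erp_baseline_ms = c(-100, 0),
    n400_window_ms = c(300, 450), lpc_window_ms = c(600, 800)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
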