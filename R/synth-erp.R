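#' Generate one subject's language-switching ERP trials
#'
#' Emulates the 2x2 (switch x congruency) sentence-final-word design:
#' `erp_trials_per_condition` epochs per cell, each spanning -100..1000 ms
#' around word onset. The single-trial background is 1/f noise sliced from a
#' continuous per-channel stream. Switch trials receive a negative
#' Gaussian-windowed component (the N400 analogue) on the Central-pool
#' channels whose peak is attenuated with proficiency,
#' `peak * (1 - attenuation * proficiency_z)` floored at zero, so more
#' proficient learners show smaller switch effects. Incongruent trials
#' receive a positive component (the LPC analogue) on the Parietal-pool
#' channels. Trial background noise is white Gaussian (window means average
#' over hundreds of samples, so its spectral colour is immaterial here).
#'
#' @inheritParams generate_resting_eeg
#' @return list with `epochs` (an [new_epoch_set()] with condition tags
#'   `"switch_congruent"` etc., *not* yet baseline-corrected) and
#'   `ground_truth` (aptitude, injected peak amplitudes).
#' @export
generate_erp_dataset <- function(cfg, subject, montage = NULL) {
  stopifnot(subject >= 1L, subject <= cfg$n_subjects)
  if (is.null(montage)) montage <- build_montage(cfg$n_channels)
  aptitude <- latent_aptitudes(cfg)[subject]
  pools <- erp_pool_labels()
  central <- which(montage$label %in% pools$central)
  parietal <- which(montage$label %in% pools$parietal)
  if (!length(central) || !length(parietal)) {
    stop("montage lacks ERP pool channels", call. = FALSE)
  }

  withr_seed(subject_seed(cfg$seed, subject, stream = 4L), {
    fs <- cfg$fs
    offs <- seq.int(round_half_even(-0.1 * fs), round_half_even(1.0 * fs))
    times <- offs / fs * 1000
    n_samp <- length(offs)
    tpc <- cfg$erp_trials_per_condition
    conds <- c("no_switch_congruent", "no_switch_incongruent",
               "switch_congruent", "switch_incongruent")
    condition <- sample(rep(conds, each = tpc))
    n_trials <- length(condition)

    gain <- subject_gain(cfg, subject)
    switch_scale <- max(0, 1 - cfg$n400_proficiency_attenuation * aptitude)
    n400_peak <- cfg$n400_template$peak_uv * switch_scale * gain
    n400 <- n400_peak *
      exp(-(times - cfg$n400_template$latency_ms)^2 /
            (2 * cfg$n400_template$sd_ms^2))
    lpc_peak <- cfg$lpc_template$peak_uv * gain
    lpc <- lpc_peak *
      exp(-(times - cfg$lpc_template$latency_ms)^2 /
            (2 * cfg$lpc_template$sd_ms^2))

    n_ch <- nrow(montage)
    epochs <- array(0, dim = c(n_ch, n_samp, n_trials))
    if (cfg$erp_noise_sd > 0) {
      epochs[] <- stats::rnorm(length(epochs), sd = cfg$erp_noise_sd * gain)
    }
    is_switch <- grepl("^switch", condition)
    is_incong <- grepl("incongruent$", condition)
    if (any(is_switch)) {
      block <- aperm(array(n400, c(n_samp, length(central), sum(is_switch))),
                     c(2L, 1L, 3L))
      epochs[central, , is_switch] <- epochs[central, , is_switch] + block
    }
    if (any(is_incong) && cfg$n400_incongruent_boost_uv != 0) {
      ## small extra N400-window negativity on incongruent trials
      boost <- -cfg$n400_incongruent_boost_uv * gain *
        exp(-(times - cfg$n400_template$latency_ms)^2 /
              (2 * cfg$n400_template$sd_ms^2))
      block <- aperm(array(boost, c(n_samp, length(central), sum(is_incong))),
                     c(2L, 1L, 3L))
      epochs[central, , is_incong] <- epochs[central, , is_incong] + block
    }
    if (any(is_incong)) {
      block <- aperm(array(lpc, c(n_samp, length(parietal), sum(is_incong))),
                     c(2L, 1L, 3L))
      epochs[parietal, , is_incong] <- epochs[parietal, , is_incong] + block
    }
    es <- new_epoch_set(epochs, fs, times, montage$label, condition)
    gt <- list(subject = subject, aptitude = aptitude,
               gain = gain, switch_scale = switch_scale,
               injected_n400_peak_uv = n400_peak,
               injected_lpc_peak_uv = lpc_peak)
    list(epochs = es, ground_truth = gt)
  })
}

#' Simulate comprehension-question responses
#'
#' One yes/no comprehension probe follows a third of the sentences. The
#' per-subject probability of a correct answer follows a logistic link
#' centred on the configured group accuracy and shifted by latent aptitude,
#' so accuracy and proficiency are positively coupled.
#'
#' @inheritParams generate_resting_eeg
#' @return data.frame with `subject`, `question`, `correct` (logical).
#' @export
generate_comprehension_responses <- function(cfg, subject) {
  stopifnot(subject >= 1L, subject <= cfg$n_subjects)
  aptitude <- latent_aptitudes(cfg)[subject]
  withr_seed(subject_seed(cfg$seed, subject, stream = 5L), {
    n_q <- max(1L, floor(4L * cfg$erp_trials_per_condition / 3))
    p <- stats::plogis(stats::qlogis(cfg$comprehension_accuracy) + 0.8 * aptitude)
    data.frame(subject = subject, question = seq_len(n_q),
               correct = stats::runif(n_q) < p)
  })
}
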