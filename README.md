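# l2eeg

Simulation and analysis pipeline for two electrophysiological experiments
on second-language (L2) learning in older adults: does resting-state EEG
band power before a three-week intensive language course predict who
improves most, and how does the brain of a late-life beginner respond when
a sentence switches back into the native language?

The package is written for cognitive-neurophysiology researchers who want
the full analysis chain — from raw multichannel EEG to mixed-model
coefficients — as tested, reproducible code. Because no participant data
are distributable, a first-class synthetic cohort generator stands in for
the recordings: it produces 128-channel resting EEG (1/f background plus
band-limited oscillators), a 2×2 language-switching ERP session, behavioral
scores, and stimulus lists, all with recorded ground truth so every
pipeline stage is validated against what was injected.

## The quantities at the core

**Corrected progress (CorP).** Learning gain rescaled as the percentage of
the maximum attainable improvement,

    CorP = (T2 − T1) · max / (max − T1),

so gains at higher starting levels count for more. A learner rising from 30
to 50 points scores 28.57; one rising from 0 to 20 scores 20.00.

**Experiment 1.** Eyes-closed resting EEG is band-passed (0.1–30 Hz,
zero-phase), cleaned by threshold artifact rejection (50 µV gradient,
200 µV/200 ms max-difference, 0.5 µV/100 ms flatline, 200 ms padding),
bad-channel interpolation and average reference, cut into 2-s epochs with
50% overlap, and reduced to log₁₀ mean power per frequency band (theta,
alpha, beta1 13–14.5 Hz, beta2, beta3) × five electrode pools. Inference:
Spearman screen with Benjamini–Hochberg FDR, ICC(1), and the linear mixed
model `log power ~ CorP_z × band + (1 | subject)` (alpha band reference,
maximum likelihood, Wald CIs) — the beta1 × gain interaction is the
headline coefficient. Paired Wilcoxon tests compare L2 scores and beta1
power across sessions.

**Experiment 2.** Sentence-final words in the 2×2 switch × congruency
design are epoched (−100…1000 ms, 100-ms baseline), averaged by condition,
and summarized as window means: N400 (300–450 ms, Central pool) and LPC
(600–800 ms, Parietal pool). Inference: `amplitude_z ~ switch × congruency
+ age_z + (1 | subject)` per component, the per-subject N400 effect
(no-switch minus switch) regressed on post-training proficiency, and
comprehension accuracy.

## Worked example

```r
library(l2eeg)

cfg <- sim_config(n_subjects = 10, n_channels = 32,
                  ec_segment_seconds = 60, seed = 20260101)
rep1 <- run_experiment1(cfg, out_dir = "results/exp1")
co <- rep1$model$coefficients
co[co$term == "corp_z:bandbeta1", ]
```

```
             term estimate     se      t  ci_lo  ci_hi
 corp_z:bandbeta1  0.15495 0.0117 13.298 0.1321 0.1778
```

The interaction says: one standard deviation more corrected learning gain
corresponds to about +0.15 log₁₀ units of beta1 power relative to the alpha
reference — the simulated cohort's injected beta1→learning link, recovered
through the full preprocessing chain. The same run reports the Spearman
screen (`rep1$correlations` — medial-frontal beta1 is its top cell, rho
0.60, and does not survive FDR at n = 10), ICC(1) (`rep1$icc$icc` = 0.11,
power values cluster within subjects), the pre/post Wilcoxon summaries
(L2 composite T2 > T1: W = 55, one-sided p = 0.00098, r = 0.89) and the
beta1-change regression.

The ERP side:

```r
rep2 <- run_experiment2(cfg, out_dir = "results/exp2")
rep2$n400_proficiency_regression  # slope -0.81 [-1.29, -0.33]: proficient
                                  # learners show smaller switch effects
rep2$accuracy$group               # 83.68% comprehension accuracy
```

The numbered drivers under `analysis/` run the same steps as a narrative
workflow (`01_simulate.R` → `04_recovery_checks.R`), writing tables under
`results/`.

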