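---
title: "Methods: simulated EEG markers of late-life language learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated EEG markers of late-life language learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`l2eeg` implements a two-experiment analysis of second-language (L2)
learning in older adults as a fully testable pipeline: resting-state EEG
band power as a predictor of learning gain (Experiment 1), and N400/LPC
quantification in a language-switching ERP paradigm (Experiment 2). No
human data ship with the package; every input is produced by the synthetic
cohort generator with recorded ground truth, so each downstream stage can
be validated against what was injected.

## The behavioral outcome: corrected progress

Gain on a 0--100 composite is rescaled as the percentage of the maximum
attainable improvement,

$$\mathrm{CorP} = \frac{(T_2 - T_1)\cdot \mathrm{max}}{\mathrm{max} - T_1},$$

so a learner rising 30 to 50 scores higher (28.57) than a learner rising 0
to 20 (20.00). `corrected_progress()` is strictly increasing in $T_2$ and,
for a fixed absolute gain, in $T_1$; it is undefined at $T_1 =
\mathrm{max}$ and errors there. The composite is the unweighted mean of
the three language-test percentiles; the first principal component of the
three tests dominates by construction (common-factor correlation 0.85,
population first-PC share 90%). CorP is computed on the composite with
`max = 100`; computing it per test and averaging is a near-identical
alternative the package does not adopt, because the worked example operates
on a single 0--100 "points" scale.

## The synthetic cohort

One latent aptitude z-score per subject drives all brain-behavior links:

* beta1 oscillator amplitude: $A_{\beta_1} = 1.5 + 0.5\,a$ (microvolts,
  floored at 0.05);
* true gain: $\mathrm{CorP} = 15 + 75\,\mathrm{logis}(1.2\,a) + \epsilon$,
  $\epsilon\sim N(0, 3^2)$, which reproduces a realistic spread (mean
  about 52, SD about 19, range covering roughly 17--92);
* ERP switch-component attenuation: the injected N400 peak is scaled by
  $1 - 0.3\,a$ (floored at 0), so proficient learners show smaller switch
  effects;
* comprehension accuracy: logistic link centred on 81% correct.

The slope values linking aptitude to beta1 amplitude and to CorP are free
parameters of the simulation (no empirical effect size is available for
them); they were fixed once at values that give a clearly detectable but
not deterministic association at the cohort sizes used here, and are not
study-tuning knobs.

A second, independent subject trait is a global amplitude gain
(`subject_gain_log10_sd`, default 0.2 log10-power units): EEG amplitudes
vary substantially between individuals through skull thickness and
electrode coupling, and this offset is what makes power values cluster
within subjects — the positive ICC(1) that motivates the subject random
intercept in the mixed models. It multiplies every amplitude (background,
oscillators, ERP components) by `10^(offset/2)`, is constant across
sessions, and cancels from within-subject band contrasts, so it adds
realism without touching the injected brain-behavior links.

**Resting recordings.** Eight minutes of alternating 2-min eyes-open /
eyes-closed blocks at 512 Hz, 128 channels by default. Each channel is 1/f
("pink") background noise (SD 5 uV) plus one narrowband oscillator per
band (theta 4--7.5, alpha 8--12.5, beta1 13--14.5, beta2 15--17.5, beta3
18--29.5 Hz). Oscillators are sinusoids with a slow (0.05--0.15 Hz) random
amplitude modulation of depth 0.2 rather than filtered noise, so band
power has a closed form ($A^2/2\,(1 + d^2/2)$ plus the noise floor) and
spectral tests can be exact. Peak frequencies are drawn per subject but
held fixed across sessions -- an individual's spectral peaks are a stable
trait, and redrawing them would confound the injected longitudinal beta1
change (-0.04 log10 units at T2) with leakage differences. The montage is
a deterministic spiral layout with BioSemi-style A/B/C/D labels, not real
electrode geometry; positions only support neighbour interpolation,
frontal-channel designation and region-based pools.

**Artifacts.** Three scripted kinds, all logged with channel and sample
extent: blinks (biphasic 250-uV low-frequency deflections on the three
most frontal channels), steps (transient 80-uV DC shifts bounded by sharp
edges), and flats (400-ms segments overwritten by their mean). Rates are
events/minute. The log is the recall oracle: detector output is compared
against the injected footprint, not against another detector.

**ERP trials.** 80 trials per cell of the switch x congruency design,
-100..1000 ms at 512 Hz. Switch trials receive a negative Gaussian
component (peak -2 uV, centre 375 ms, SD 40 ms) on the Central pool;
incongruent trials a positive one (peak 1.5 uV, centre 700 ms, SD 50 ms)
on the Parietal pool, plus a small (0.5 uV) extra N400-window negativity
that produces the graded condition ordering without a reliable congruency
main effect. Trial background is white Gaussian noise (10 uV): window
means average over hundreds of samples, so the spectral colour of the
background is immaterial for amplitude statistics, unlike in the resting
analysis where it sets the 1/f floor.

**Stimulus lists.** Sentences are rebuilt from small noun/verb lexicons
and emitted in all four conditions (so 80 sentences yield 320 rows).
Sentence-final targets come only from nouns whose English and German forms
differ by at least two letters (case-insensitive Levenshtein), so a switch
is always orthographically detectable; pairs such as *house*/*Haus* are
excluded automatically. The literal per-item usage quotas quoted for the
original material (each noun four times, each verb twice, 80 two-noun
sentences) are arithmetically over-constrained -- 160 noun slots cannot be
filled by 20 nouns used four times each while also satisfying the
eligibility restriction -- so items are assigned by balanced round-robin
reuse instead, which keeps usage counts within one of the attainable
minimum imbalance.

## Preprocessing decisions

The rejection criteria mirror threshold-based artifact rejection in
commercial EEG software, with ambiguities resolved as follows:

* **Gradient** is the absolute sample-to-sample difference, threshold
  50 uV.
* **Max-difference** flags every sample covered by *any* 200-ms window
  whose peak-to-peak range exceeds 200 uV; windows slide sample by sample
  (strictly more conservative than disjoint blocks).
* **Low activity** is read as a flatline rejector: any 100-ms window whose
  peak-to-peak range stays *below* 0.5 uV is flagged. Read literally
  ("activity not lower than 0.5 uV") the criterion would reject all
  normal EEG; the flatline reading is the standard meaning of this
  criterion in practice.
* Flagged samples are padded by 200 ms on both sides; intervals are kept
  half-open `[start, end)` in 0-based sample coordinates.
* The review step that a human operator would apply on top of the
  automatic flags is omitted: the three criteria are applied fully
  automatically, for reproducibility.

Channels whose flagged fraction exceeds 10% are replaced by the unweighted
mean of their 4 nearest good neighbours (Euclidean distance on montage
positions, other bad channels excluded); more than 5 such channels is a
hard error, since a recording that bad should not pass silently. The
pipeline order is fixed: filter, ocular correction, detect, interpolate,
average-reference, re-detect, segment, epoch. Interpolation and average
referencing only commute when nothing is replaced, so the order matters
and is asserted rather than left to the caller.

The band-pass is realized as zero-phase Butterworth sections run
forward-backward (`signal::filtfilt`). Because two passes double the
magnitude roll-off, the 12 dB/octave high-pass at 0.1 Hz is a first-order
section and the 48 dB/octave low-pass at 30 Hz a fourth-order section.
Requested roll-offs are therefore met exactly at the section orders used,
and the zero-phase property preserves ERP latencies.

Ocular correction is a pluggable contract, not a commitment to a specific
algorithm: the default template method detects high-amplitude
low-frequency excursions on the designated frontal channels and subtracts
the sub-6-Hz component inside those stretches (with raised-cosine ramps),
which satisfies the contract -- blink-interval frontal variance reduced by
at least half, everything else essentially untouched. A blind-source
separation stage could be dropped in behind the same interface.

Epoch lengths are `round(epoch_s * fs)` with round-half-to-even; a 110-s
clean segment yields exactly 109 two-second epochs at 50% overlap. The
eyes-closed segments are trimmed by 5 s at each end before epoching (two
120-s blocks give two 110-s segments), and any epoch overlapping a masked
interval on any channel is skipped.

## Spectral decisions

Per-epoch periodograms are averaged Welch-style (50%-overlap epochs,
unweighted). The one-sided normalization is fixed so a sinusoid of
amplitude $A$ carries total power $A^2/2$ (uV^2) at its bin, and the
taper-free bin sum equals the signal mean square (Parseval) -- both are
asserted against a brute-force DFT oracle in the tests. The default taper
is Hann with amplitude-loss compensation; the emulated analysis chain does
not state a taper, so `taper = "none"` is available and is what the exact
oracle checks use. Band membership is half-open `(low, high]` on bin
centres, so 12.5 Hz belongs to alpha and not beta1. Band means are the
*mean* over bins and member channels, computed on raw power, with log10
applied after pooling (log-after-pool; the alternative order is not
exposed because mixing the two silently changes every downstream
coefficient). A gamma band (30--40 Hz) exists but is off by default: it
conflicts with the 30-Hz low-pass in the standard chain, and enabling it
without changing the filter would quantify stop-band leakage, not brain
signal.

Resting pools partition the montage into five regions (medial-frontal,
left/right frontotemporal, left/right posterior) by nearest-centroid
assignment on electrode positions, approximating the schematic pool
figure; exact memberships are configurable. The ERP pools are frozen label
sets (Central: A1, A2, A3, D1, D14, D15, D16; Parietal: A3, A4, A5, A6,
A20, A21, D16, D17). The source figure lists D16 both as a central-pool
member and with a prefrontal site name in the parietal pool; the listed
labels are used as-is and the conflict is surfaced here rather than
silently resolved.

## Statistical decisions

* Mixed models (`log_power ~ CorP_z x band + (1 | subject)` with the alpha
  band as reference; `amplitude_z ~ switch x congruency + age_z +
  (1 | subject)` per ERP component) are fitted by maximum likelihood, not
  REML, so nested-model comparisons (random intercept vs
  intercept-and-slope, proficiency vs accuracy BIC check) are valid.
  Confidence intervals are Wald; the null calibration in the test suite
  checks that the beta1-interaction CI excludes zero in a narrow band
  around the nominal 5% of null replicates at the study's sample size.
* The marginal pseudo-R^2 is
  $\mathrm{var}(X\hat\beta) / (\mathrm{var}(X\hat\beta) + \tau^2 +
  \sigma^2)$.
* Electrode pools enter the power model as replicate rows per subject and
  band (the alternative -- averaging pools out first -- halves the data
  without changing the estimand; the replicate-rows reading is adopted).
* Spearman correlations use average ranks; their CIs use the Fisher-z
  approximation with $\mathrm{SE} = \sqrt{1.06/(n-3)}$;
  Benjamini-Hochberg adjustment runs across all pool x band cells, with
  undefined cells excluded from the family rather than imputed.
* ICC(1) is the one-way ANOVA form with the adjusted group size
  $k_0 = (N - \sum n_i^2/N)/(g-1)$; negative values are reported as
  computed.
* The Wilcoxon effect size is the matched-rank correlation $r = |Z| /
  \sqrt{n}$ by default (the emulated report gives effect sizes without a
  formula; the rank-biserial alternative is available via an argument).
  Zero differences are dropped before ranking; the p-value is exact in
  small tie-free samples (the all-positive $n = 10$ case gives one-sided
  $p = 1/1024$).
* Degrees of freedom for reported t-values use the residual approximation;
  the original's df conventions are not reproduced exactly and no p-values
  are attached to mixed-model coefficients.
* Regressions on standardized variables (power change vs gain, ERP effect
  vs proficiency) are OLS with t-based CIs; the two-point case is flagged
  as degenerate instead of reporting an undefined interval.
* N400 latency is extracted as the within-window local minimum of the
  pool-mean waveform and reported descriptively only.

## Problem sizes and what the tests show

The replicated simulation studies in the test suite run at reduced size:
16 channels and 16-s eyes-closed blocks for the 100-cohort beta1-link
recovery (40 subjects per cohort), and 10-subject cohorts for the
100-replicate N400-slope study. These sizes keep the full suite within a
routine test run while leaving the estimators' behaviour unchanged -- the
spectral estimates just carry more variance than the full 2x4-min
protocol, which works against the recovery checks, not for them. The
analysis scripts use 32 channels and 60-s blocks; only memory and patience
argue against the full 128 x 120-s configuration.

Passing tests demonstrate internal validity: the pipeline recovers what
the generator injected, at the configured effect sizes, through the full
preprocessing and inference chain. They do not demonstrate that real
resting beta1 power predicts real L2 learning -- the generator's artifact
morphology is schematic (no muscle or line noise, no drifting electrodes),
its oscillators are stationary narrowband tones rather than bursty rhythms,
its ERP background lacks phase-locked alpha, and its brain-behavior links
are injected rather than discovered. Conclusions about real cohorts need
real recordings; the package's claim is that, given data with the assumed
structure, every number it reports is computed correctly.

## Known limitations

* No EDF or real-BrainVision-coordinate support: the BrainVision
  writer/reader covers the multiplexed float32 subset this package
  produces.
* Ocular correction is template regression, not ICA; the contract (and the
  tests) are method-agnostic.
* The semi-automatic review of flagged segments is deliberately fully
  automatic here.
* Latency statistics are descriptive; no latency model is fitted.
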