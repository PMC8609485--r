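Package: l2eeg
Title: Resting-State EEG and ERP Markers of Second-Language Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for two electrophysiological
    experiments on second-language (L2) learning in older adults. Provides a
    synthetic multichannel EEG generator (1/f background, band-limited
    oscillators, scripted artifacts, a 2x2 language-switching ERP design and
    linked behavioral scores), threshold-based artifact detection with
    bad-channel interpolation and average re-referencing, FFT band-power
    extraction over electrode pools, corrected learning-gain (CorP) scoring,
    and the corresponding inference: Spearman screens with FDR control,
    one-way intraclass correlation, linear mixed models of band power on
    learning gain, Wilcoxon signed-rank comparisons, and N400/LPC window
    amplitude models with proficiency regressions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
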