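#!/usr/bin/env Rscript

## Step 1 -- simulate the cohort and write the shareable inputs.
##
## Builds the synthetic study cohort (10 older learners) and exports what a
## real study would have on disk: one subject's resting-state recording as
## a BrainVision triplet, the montage, the stimulus table of the 2x2
## language-switching design, the behavioral score table, and the
## ground-truth log that downstream steps can be validated against.
##
## Problem size: 32 channels and 60-s eyes-closed blocks -- smaller than the
## full 128-channel protocol but structurally identical (see the methods
## vignette for the scaling rationale).

suppressMessages(library(l2eeg))

out_dir <- "results/simulated"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_subjects = 10, n_channels = 32, ec_segment_seconds = 60,
                  seed = 20260101)

montage <- build_montage(cfg$n_channels)
write_montage(montage, file.path(out_dir, "montage.tsv"))

gen <- generate_resting_eeg(cfg, 1, "T1", montage)
write_brainvision(gen$recording, file.path(out_dir, "sub01_T1_rest"))
write_ground_truth(gen$ground_truth, file.path(out_dir, "sub01_T1_truth.json"))
cat("subject 1 resting EEG:", nrow(gen$recording$data), "channels,",
    ncol(gen$recording$data) / gen$recording$fs, "s,",
    nrow(gen$ground_truth$artifact_log), "injected artifact events\n")

beh <- generate_behavioral_scores(cfg)
write_assessment(beh, file.path(out_dir, "behavior.tsv"))
cat(sprintf("behavior: CorP mean %.1f, range %.1f-%.1f\n",
            mean(beh$corp), min(beh$corp), max(beh$corp)))

stim <- generate_stimulus_list(cfg$erp_trials_per_condition, seed = cfg$seed)
write.table(stim, file.path(out_dir, "stimuli.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("stimuli:", nrow(stim), "rows (", cfg$erp_trials_per_condition,
    "sentences x 4 conditions )\n")

cat("wrote", out_dir, "\n")
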