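#!/usr/bin/env Rscript

## Step 3 -- the language-switching ERP experiment.
##
## Simulates the post-training ERP session (80 trials per cell of the
## switch x congruency design, -100..1000 ms epochs), averages by
## condition, extracts N400 (300-450 ms, Central pool) and LPC (600-800 ms,
## Parietal pool) window amplitudes, and fits the Experiment-2 statistics:
## the Switch x Congruency mixed model with age per component, the
## per-subject N400 effect regressed on post-training proficiency, and
## comprehension accuracy.

suppressMessages(library(l2eeg))

cfg <- sim_config(n_subjects = 10, n_channels = 32, seed = 20260101)

t0 <- Sys.time()
rep2 <- run_experiment2(cfg, out_dir = "results/exp2")
cat(sprintf("experiment 2 finished in %.1f min\n",
            as.numeric(Sys.time() - t0, units = "mins")))

cat("\n-- N400 model (switch x congruency + age) --\n")
print(rep2$model_n400)
cat("\n-- LPC model --\n")
print(rep2$model_lpc)

nr <- rep2$n400_proficiency_regression
cat(sprintf("\nN400 effect ~ proficiency: slope %.2f [%.2f, %.2f], t = %.2f\n",
            nr$slope, nr$ci[1], nr$ci[2], nr$t))
lr <- rep2$lpc_proficiency_regression
cat(sprintf("LPC effect ~ proficiency: slope %.2f [%.2f, %.2f]\n",
            lr$slope, lr$ci[1], lr$ci[2]))

cat(sprintf("\ncomprehension accuracy: %.2f%% (correlation with proficiency %.2f)\n",
            rep2$accuracy$group, rep2$accuracy_proficiency_cor))
cat(sprintf("BIC, proficiency vs accuracy as predictor: %.1f vs %.1f\n",
            rep2$bic["proficiency"], rep2$bic["accuracy"]))
cat(sprintf("median N400 peak latency: %.0f ms\n",
            median(rep2$latencies$n400_latency_ms)))
cat("\noutputs under results/exp2\n")
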