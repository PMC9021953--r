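#!/usr/bin/env Rscript
# Step 1: generate the synthetic study the rest of the workflow analyses.
#
# Two model-driven cohorts play 100 trials of the four-deck gambling task:
# 25 healthy controls and 20 chronic-pain subjects whose generating ORL
# parameters differ in the reward learning rate (higher under pain) and the
# perseverance weight (lower under pain). Each subject also answers the
# BPI-SF, with item responses linked to their true parameters.

suppressPackageStartupMessages(library(igtbayes))

data_seed <- 1L
out_dir <- "results/study"

study <- generate_study(default_regimes(), n_trials = 100, seed = data_seed)
write_study(study, out_dir)

print(study)
tg <- vapply(study$sessions, total_gain, numeric(1))
grp <- vapply(study$sessions, function(s) s$group, character(1))
cat(sprintf("mean total gain: healthy %.0f, chronic pain %.0f (EUR)\n",
            mean(tg[grp == "healthy"]), mean(tg[grp == "chronic_pain"])))
cat(sprintf("true A_rew locations: healthy %.2f, chronic pain %.2f\n",
            default_regimes()$healthy$param_mean[["A_rew"]],
            default_regimes()$chronic_pain$param_mean[["A_rew"]]))
cat("study written to", out_dir, "\n")
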