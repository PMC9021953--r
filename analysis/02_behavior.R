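#!/usr/bin/env Rscript
# Step 2: standard behavioral analysis of the simulated study.
#
# Computes each subject's total gain, per-block learning scores and good-deck
# proportions (5 blocks of 20 trials), compares total gain across groups with
# a pooled-variance t test, scores the BPI-SF, and correlates pain severity
# with task performance.

suppressPackageStartupMessages(library(igtbayes))

study_dir <- "results/study"
out_dir <- "results/behavior"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

sessions <- read_trial_logs(file.path(study_dir, "trial_logs.csv"))
bpisf <- read.csv(file.path(study_dir, "bpisf.csv"))

summ <- behavioral_summary(sessions)
write.csv(summ, file.path(out_dir, "behavioral_summary.csv"), row.names = FALSE)

grp <- vapply(sessions, function(s) s$group, character(1))
cmp <- compare_groups(summ$total_gain, grp)
cat(sprintf("total gain: healthy %.0f vs chronic pain %.0f, t(%d) = %.2f, p = %.3f, d = %.2f\n",
            cmp$means[["healthy"]], cmp$means[["chronic_pain"]], cmp$df,
            cmp$t, cmp$p, cmp$d))

profiles <- score_bpisf_table(bpisf)
write.csv(profiles, file.path(out_dir, "pain_profiles.csv"), row.names = FALSE)
sev <- profiles$severity[match(summ$subject_id, profiles$subject_id)]
for (m in c("severity")) {
  r <- correlate(summ$total_gain, sev)
  cat(sprintf("total gain vs pain %s: r(%d) = %.2f, 95%% CI [%.2f, %.2f], p = %.3g\n",
              m, r$df, r$r, r$ci[1], r$ci[2], r$p))
}

# group-mean learning curve across the 5 blocks
lc <- aggregate(summ[paste0("learning_b", 1:5)], by = list(group = grp), mean)
write.csv(lc, file.path(out_dir, "learning_curves.csv"), row.names = FALSE)
cat("mean learning scores by block:\n")
print(lc, digits = 3)

writeLines(jsonlite::toJSON(list(
  step = "behavior", study_dir = study_dir,
  package_version = as.character(packageVersion("igtbayes")),
  timestamp = format(Sys.time(), tz = "UTC")
), auto_unbox = TRUE, pretty = TRUE), file.path(out_dir, "provenance.json"))
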