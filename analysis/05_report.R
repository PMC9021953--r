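#!/usr/bin/env Rscript
# Step 5: group contrasts and parameter-pain correlations.
#
# For the ORL and VPP fits: the 95% HDI of the draw-wise difference in
# group-level means (chronic pain minus healthy) per parameter, flagging those
# whose interval excludes zero; then each individual's posterior-mean
# parameters are correlated with the four pain measures over the pooled
# sample.

suppressPackageStartupMessages(library(igtbayes))

fits_dir <- "results/fits"
study_dir <- "results/study"
out_dir <- "results/report"
pairing_seed <- 7L
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

profiles <- score_bpisf_table(read.csv(file.path(study_dir, "bpisf.csv")))

contrast_rows <- list()
cor_rows <- list()
for (model in c("orl", "vpp")) {
  fp <- read_fit_archive(file.path(fits_dir, paste0(model, "_chronic_pain")))
  fh <- read_fit_archive(file.path(fits_dir, paste0(model, "_healthy")))
  for (p in fp$param_names) {
    gd <- group_difference(fp, fh, p, seed = pairing_seed)
    contrast_rows[[paste(model, p)]] <- data.frame(
      model = model, param = p, mean_diff = gd$mean_diff,
      hdi_lower = gd$hdi$lower, hdi_upper = gd$hdi$upper,
      excludes_zero = gd$exceeds_zero
    )
  }
  tab <- parameter_pain_report(list(fh, fp), profiles)
  tab <- cbind(model = model, tab)
  cor_rows[[model]] <- tab
}

contrasts <- do.call(rbind, contrast_rows)
write.csv(contrasts, file.path(out_dir, "group_contrasts.csv"),
          row.names = FALSE)
cat("group-level contrasts (chronic pain - healthy), 95% HDI:\n")
print(contrasts, digits = 3, row.names = FALSE)
cat("parameters whose 95% HDI excludes zero:",
    paste(with(contrasts, paste0(model, ":", param))[contrasts$excludes_zero],
          collapse = ", "), "\n")

cors <- do.call(rbind, cor_rows)
write.csv(cors, file.path(out_dir, "parameter_pain_correlations.csv"),
          row.names = FALSE)
sig <- cors[cors$p < 0.05, c("model", "param", "measure", "r", "p", "n")]
cat(sprintf("\n%d of %d parameter-pain correlations significant at p < 0.05:\n",
            nrow(sig), nrow(cors)))
print(sig, digits = 2, row.names = FALSE)

writeLines(jsonlite::toJSON(list(
  step = "report", fits_dir = fits_dir, study_dir = study_dir,
  pairing_seed = pairing_seed,
  package_version = as.character(packageVersion("igtbayes")),
  timestamp = format(Sys.time(), tz = "UTC")
), auto_unbox = TRUE, pretty = TRUE), file.path(out_dir, "provenance.json"))
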