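#!/usr/bin/env Rscript
# Step 3: hierarchical Bayesian fits of all four cognitive models.
#
# Each model (PVL-Delta, PVL-Decay, VPP, ORL) is fitted separately to each
# group with its own hierarchical prior, and every fit is archived (draws,
# pointwise log-likelihoods, manifest) for the comparison and report steps.
# Chain settings here are reduced from the package defaults to keep the
# workflow quick; convergence diagnostics are printed per fit.

suppressPackageStartupMessages(library(igtbayes))

study_dir <- "results/study"
out_dir <- "results/fits"
sampler_seed <- 42L
mc <- mcmc_config(chains = 2, warmup = 1500, draws = 500, thin = 3)

sessions <- read_trial_logs(file.path(study_dir, "trial_logs.csv"))
grp <- split(sessions, vapply(sessions, function(s) s$group, character(1)))

k <- 0L
for (model in c("pvl_delta", "pvl_decay", "vpp", "orl")) {
  for (g in names(grp)) {
    k <- k + 1L
    fit <- suppressWarnings(
      fit_group(grp[[g]], model, mcmc = mc, seed = sampler_seed + k, group = g)
    )
    dir <- file.path(out_dir, paste(model, g, sep = "_"))
    write_fit_archive(fit, dir)
    cat(sprintf("%-10s %-13s max split-Rhat %.3f%s\n", model, g,
                max(fit$rhat, na.rm = TRUE),
                if (is.null(fit$convergence_warning)) "" else "  [convergence warning]"))
  }
}

writeLines(jsonlite::toJSON(list(
  step = "fit", study_dir = study_dir, sampler_seed = sampler_seed,
  mcmc = unclass(mc),
  package_version = as.character(packageVersion("igtbayes")),
  timestamp = format(Sys.time(), tz = "UTC")
), auto_unbox = TRUE, pretty = TRUE), file.path(out_dir, "provenance.json"))
cat("fit archives written to", out_dir, "\n")
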