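#' Prior specification for hierarchical fits
#'
#' Group means get normal priors on the unconstrained scale and group spreads
#' half-normal priors; individual deviations are standard-normal under the
#' non-centered parameterization. Bounded parameters reach their natural range
#' through the scaled probit link (see [param_info()]).
#'
#' @param model Model id.
#' @param mu_sd Prior SD of each group-level mean (recycled; default 1).
#' @param sigma_sd Half-normal scale of each group-level spread (default 1).
#' @return List of class `igt_priors`.
#' @export
prior_spec <- function(model, mu_sd = 1, sigma_sd = 1) {
  info <- param_info(model)
  structure(list(
    model = model,
    mu_sd = rep_len(mu_sd, nrow(info)),
    sigma_sd = rep_len(sigma_sd, nrow(info))
  ), class = "igt_priors")
}

#' MCMC configuration
#'
#' @param chains Number of chains (default 4).
#' @param warmup Warmup (adaptation) iterations per chain (default 1000).
#' @param draws Retained iterations per chain (default 1000).
#' @param thin Keep every `thin`-th post-warmup iteration (default 1), so
#'   `draws * thin` post-warmup iterations are run per chain.
#' @return List of class `igt_mcmc_config`.
#' @export
mcmc_config <- function(chains = 4L, warmup = 1000L, draws = 1000L, thin = 1L) {
  stopifnot(chains >= 1, warmup >= 0, draws >= 1, thin >= 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), thin = as.integer(thin)),
            class = "igt_mcmc_config")
}

sessions_to_matrices <- function(sessions, scale) {
  n_per <- vapply(sessions, function(s) nrow(s$trials), integer(1))
  maxn <- max(n_per)
  ch <- matrix(1L, length(sessions), maxn)
  x <- matrix(0, length(sessions), maxn)
  for (i in seq_along(sessions)) {
    ci <- match(sessions[[i]]$trials$deck, c("A", "B", "C", "D"))
    if (anyNA(ci)) stop("subject ", sessions[[i]]$subject_id,
                        " has deck ids outside A-D")
    ch[i, seq_len(n_per[i])] <- ci
    x[i, seq_len(n_per[i])] <- sessions[[i]]$trials$net / scale
  }
  list(choices = ch, x = x, n_per = n_per)
}

#' Fit one cognitive model to one group of sessions
#'
#' Hierarchical Bayesian estimation by adaptive Metropolis-within-Gibbs on the
#' non-centered parameterization: individual unconstrained parameters are
#' `mu + sigma * z` with `z ~ N(0,1)`, mapped to their bounded range by the
#' scaled probit link. Split-R-hat is computed for every group-level quantity;
#' values above 1.05 attach a convergence warning to the fit (never dropped).
#'
#' @param sessions List of `igt_session` objects (>= 2 subjects; equal trial
#'   counts not required).
#' @param model Model id.
#' @param priors An `igt_priors` from [prior_spec()] (default for the model).
#' @param mcmc An `igt_mcmc_config`.
#' @param seed Sampler seed (drives initialisation and all proposals).
#' @param scale Outcome divisor applied before modeling (default 100).
#' @param group Group label stored with the fit (default taken from the first
#'   session).
#' @param orl_fictive Fictive-rate convention for ORL.
#' @return An `igt_fit`: list with draw matrices `mu` (unconstrained),
#'   `mu_nat` (group-level means on the natural scale), `sigma`, `theta`
#'   (individual natural-scale draws, draws x (subject x param)), the
#'   pointwise log-likelihood matrix (draws x trials, column map in
#'   `point_map`), split-R-hat values and metadata.
#' @export
fit_group <- function(sessions, model, priors = prior_spec(model),
                      mcmc = mcmc_config(), seed = 1L, scale = 100,
                      group = NULL, orl_fictive = c("opposite", "same")) {
  model <- match.arg(model, names(MODEL_IDS))
  orl_fictive <- match.arg(orl_fictive)
  if (length(sessions) < 2) stop("need at least 2 subjects to fit a group")
  stopifnot(inherits(mcmc, "igt_mcmc_config"))
  info <- param_info(model)
  dat <- sessions_to_matrices(sessions, scale)
  if (is.null(group)) group <- sessions[[1]]$group
  subject_ids <- vapply(sessions, function(s) s$subject_id, character(1))

  set.seed(seed)
  chains <- vector("list", mcmc$chains)
  for (k in seq_len(mcmc$chains)) {
    chains[[k]] <- cpp_fit_chain(
      MODEL_IDS[[model]], dat$choices, dat$x, dat$n_per, info$link_U,
      priors$mu_sd, priors$sigma_sd, mcmc$warmup, mcmc$draws, mcmc$thin,
      as.integer(orl_fictive == "same")
    )
  }
  mu <- do.call(rbind, lapply(chains, `[[`, "mu"))
  sigma <- do.call(rbind, lapply(chains, `[[`, "sigma"))
  theta <- do.call(rbind, lapply(chains, `[[`, "theta"))
  ptw <- do.call(rbind, lapply(chains, `[[`, "pointwise"))
  colnames(mu) <- colnames(sigma) <- info$name
  colnames(theta) <- paste0(rep(subject_ids, each = nrow(info)), ".", info$name)
  mu_nat <- vapply(seq_len(nrow(info)), function(p) {
    if (info$link_U[p] > 0) info$link_U[p] * stats::pnorm(mu[, p]) else mu[, p]
  }, numeric(nrow(mu)))
  colnames(mu_nat) <- info$name
  point_map <- data.frame(
    subject_id = rep(subject_ids, dat$n_per),
    trial = unlist(lapply(dat$n_per, seq_len))
  )

  rh <- c(
    stats::setNames(apply_rhat(mu, mcmc$chains), paste0("mu.", info$name)),
    stats::setNames(apply_rhat(sigma, mcmc$chains), paste0("sigma.", info$name))
  )
  conv_warning <- NULL
  if (any(rh > 1.05, na.rm = TRUE)) {
    conv_warning <- paste0(
      "split-Rhat > 1.05 for: ",
      paste(names(rh)[which(rh > 1.05)], collapse = ", ")
    )
    warning(conv_warning, call. = FALSE)
  }

  structure(list(
    model = model, group = group, subject_ids = subject_ids,
    param_names = info$name, link_U = info$link_U,
    mu = mu, mu_nat = mu_nat, sigma = sigma, theta = theta,
    pointwise_loglik = ptw, point_map = point_map,
    n_chains = mcmc$chains, n_draws_per_chain = mcmc$draws,
    rhat = rh, convergence_warning = conv_warning,
    accept_rate = mean(vapply(chains, `[[`, numeric(1), "accept_rate")),
    seed = seed, scale = scale, priors = priors
  ), class = "igt_fit")
}

#' @export
print.igt_fit <- function(x, ...) {
  cat(sprintf("Hierarchical %s fit: group '%s', %d subjects, %d draws (%d chains)\n",
              x$model, x$group, length(x$subject_ids), nrow(x$mu), x$n_chains))
  cat(sprintf("max split-Rhat %.3f; mean acceptance %.2f\n",
              max(x$rhat, na.rm = TRUE), x$accept_rate))
  if (!is.null(x$convergence_warning)) cat("WARNING:", x$convergence_warning, "\n")
  invisible(x)
}

# split-Rhat per column of a (chains stacked) draw matrix
apply_rhat <- function(draws, n_chains) {
  apply(draws, 2, function(v) split_rhat(v, n_chains))
}

#' Split-R-hat convergence diagnostic
#'
#' Each chain is split in half and the standard potential-scale-reduction
#' statistic computed over the resulting sub-chains.
#'
#' @param v Draws from all chains, stacked chain by chain.
#' @param n_chains Number of chains in `v`.
#' @return The split-R-hat value (NA for constant draws).
#' @export
split_rhat <- function(v, n_chains) {
  n <- length(v) %/% n_chains
  half <- n %/% 2
  if (half < 2) return(NA_real_)
  sub <- list()
  for (k in seq_len(n_chains)) {
    cv <- v[((k - 1) * n + 1):(k * n)]
    sub <- c(sub, list(cv[seq_len(half)], cv[(half + 1):(2 * half)]))
  }
  m <- length(sub)
  means <- vapply(sub, mean, numeric(1))
  vars <- vapply(sub, stats::var, numeric(1))
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Highest-posterior-density interval
#'
#' The narrowest contiguous interval containing `ceiling(mass * n)` of the
#' sorted samples.
#'
#' @param samples Numeric vector of draws (>= 10).
#' @param mass Credibility level in (0,1); default 0.95.
#' @return List of class `igt_hdi` with `lower`, `upper`, `mass`.
#' @export
hdi <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 10) stop("need at least 10 samples for an HDI")
  stopifnot(mass > 0, mass < 1)
  s <- sort(samples)
  n <- length(s)
  k <- ceiling(mass * n)
  if (k >= n) k <- n
  widths <- s[k:n] - s[1:(n - k + 1)]
  i <- which.min(widths)
  structure(list(lower = s[i], upper = s[i + k - 1], mass = mass),
            class = "igt_hdi")
}

#' @export
print.igt_hdi <- function(x, ...) {
  cat(sprintf("%.0f%% HDI [%.4g, %.4g]\n", 100 * x$mass, x$lower, x$upper))
  invisible(x)
}

#' Group contrast of a group-level mean parameter
#'
#' Computes the HDI of the draw-wise difference (a minus b) of the
#' natural-scale group means of two independent fits. Draws are paired after
#' an independent seeded shuffle per fit; if the fits retain different numbers
#' of draws, the larger is subsampled (seeded).
#'
#' @param fit_a,fit_b Two `igt_fit` objects for the same model.
#' @param param Parameter name.
#' @param mass Credibility level (default 0.95).
#' @param seed Seed for the pairing shuffle.
#' @return List with the `igt_hdi`, the posterior mean difference
#'   `mean_diff`, and `exceeds_zero` (TRUE iff 0 is outside the HDI).
#' @export
group_difference <- function(fit_a, fit_b, param, mass = 0.95, seed = 1L) {
  if (!identical(fit_a$model, fit_b$model)) {
    stop("fits are for different models: ", fit_a$model, " vs ", fit_b$model)
  }
  if (!param %in% fit_a$param_names) stop("unknown parameter: ", param)
  a <- fit_a$mu_nat[, param]
  b <- fit_b$mu_nat[, param]
  set.seed(seed)
  n <- min(length(a), length(b))
  a <- a[sample.int(length(a), n)]
  b <- b[sample.int(length(b), n)]
  d <- a - b
  h <- hdi(d, mass)
  list(param = param, hdi = h, mean_diff = mean(d),
       exceeds_zero = (h$lower > 0 || h$upper < 0))
}

#' Posterior summary table
#'
#' One row per parameter per level: the two group levels (mean and spread) and
#' each subject's individual parameter, with posterior mean, SD and HDI.
#'
#' @param fit An `igt_fit`.
#' @param mass HDI mass (default 0.95).
#' @return Data frame with columns `level`, `subject_id`, `param`, `mean`,
#'   `sd`, `hdi_lower`, `hdi_upper`.
#' @export
posterior_summary <- function(fit, mass = 0.95) {
  summarize <- function(v, level, sid, param) {
    h <- hdi(v, mass)
    data.frame(level = level, subject_id = sid, param = param,
               mean = mean(v), sd = stats::sd(v),
               hdi_lower = h$lower, hdi_upper = h$upper,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (p in fit$param_names) {
    rows[[length(rows) + 1]] <- summarize(fit$mu_nat[, p], "group_mean", NA, p)
    rows[[length(rows) + 1]] <- summarize(fit$sigma[, p], "group_sd", NA, p)
  }
  for (i in seq_along(fit$subject_ids)) {
    for (p in fit$param_names) {
      col <- paste0(fit$subject_ids[i], ".", p)
      rows[[length(rows) + 1]] <- summarize(fit$theta[, col], "subject",
                                            fit$subject_ids[i], p)
    }
  }
  do.call(rbind, rows)
}

#' Individual posterior means as a subject-by-parameter table
#'
#' @param fit An `igt_fit`.
#' @return Data frame with `subject_id` and one column per parameter.
#' @export
individual_means <- function(fit) {
  out <- data.frame(subject_id = fit$subject_ids, stringsAsFactors = FALSE)
  for (p in fit$param_names) {
    out[[p]] <- vapply(fit$subject_ids, function(id) {
      mean(fit$theta[, paste0(id, ".", p)])
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Per-subject maximum-likelihood fits
#'
#' Independent (non-hierarchical) optimisation of each subject's session
#' log-likelihood on the unconstrained scale, used as the unshrunk baseline
#' when demonstrating hierarchical shrinkage.
#'
#' @param sessions List of `igt_session` objects.
#' @param model Model id.
#' @param scale Outcome divisor.
#' @param n_starts Random restarts per subject (default 3).
#' @param seed Seed for the restarts.
#' @return Data frame with `subject_id` and the natural-scale ML estimates.
#' @export
ml_fit_subjects <- function(sessions, model, scale = 100, n_starts = 3L,
                            seed = 1L) {
  model <- match.arg(model, names(MODEL_IDS))
  info <- param_info(model)
  set.seed(seed)
  rows <- lapply(sessions, function(s) {
    choices <- match(s$trials$deck, c("A", "B", "C", "D"))
    x <- s$trials$net / scale
    nll <- function(u) {
      nat <- ifelse(info$link_U > 0, info$link_U * stats::pnorm(u), u)
      -sum(cpp_session_logp(MODEL_IDS[[model]], nat, choices, x, 0L))
    }
    # screen random candidates first: the likelihood has a flat region at
    # zero consistency where gradient methods stall, so only promising starts
    # are optimised
    cand <- matrix(stats::rnorm(30 * nrow(info), 0, 1), 30)
    cand_val <- apply(cand, 1, nll)
    starts <- cand[order(cand_val)[seq_len(n_starts)], , drop = FALSE]
    best <- NULL
    for (k in seq_len(nrow(starts))) {
      opt <- tryCatch(
        stats::optim(starts[k, ], nll, method = "L-BFGS-B",
                     lower = rep(-6, nrow(info)), upper = rep(6, nrow(info))),
        error = function(e) NULL
      )
      if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
    }
    if (is.null(best)) best <- list(par = starts[1, ], value = cand_val[1])
    nat <- ifelse(info$link_U > 0, info$link_U * stats::pnorm(best$par), best$par)
    out <- data.frame(subject_id = s$subject_id, stringsAsFactors = FALSE)
    for (j in seq_len(nrow(info))) out[[info$name[j]]] <- nat[j]
    out
  })
  do.call(rbind, rows)
}

#' Write a fit archive to disk
#'
#' Draw matrices as CSV, the pointwise log-likelihood matrix as CSV, and a JSON
#' manifest with model, group, seeds, MCMC settings and diagnostics.
#'
#' @param fit An `igt_fit`.
#' @param dir Directory to create.
#' @export
write_fit_archive <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cbind(as.data.frame(fit$mu_nat),
                         stats::setNames(as.data.frame(fit$sigma),
                                         paste0("sigma.", fit$param_names))),
                   file.path(dir, "group_draws.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(fit$theta),
                   file.path(dir, "individual_draws.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(fit$pointwise_loglik),
                   file.path(dir, "pointwise_loglik.csv"), row.names = FALSE)
  utils::write.csv(fit$point_map, file.path(dir, "point_map.csv"),
                   row.names = FALSE)
  manifest <- list(
    model = fit$model, group = fit$group, subject_ids = fit$subject_ids,
    n_chains = fit$n_chains, n_draws_per_chain = fit$n_draws_per_chain,
    seed = fit$seed, scale = fit$scale, rhat = as.list(fit$rhat),
    convergence_warning = fit$convergence_warning,
    accept_rate = fit$accept_rate,
    package_version = as.character(utils::packageVersion("igtbayes")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read a fit archive back from disk
#'
#' Restores the parts of a fit that the reporting functions need: group-level
#' natural-scale draws, individual draws, the pointwise log-likelihood matrix
#' and the manifest metadata.
#'
#' @param dir Directory written by [write_fit_archive()].
#' @return An `igt_fit` (without the unconstrained-scale group draws).
#' @export
read_fit_archive <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  gd <- utils::read.csv(file.path(dir, "group_draws.csv"), check.names = FALSE)
  info <- param_info(man$model)
  theta <- as.matrix(utils::read.csv(file.path(dir, "individual_draws.csv"),
                                     check.names = FALSE))
  ptw <- as.matrix(utils::read.csv(file.path(dir, "pointwise_loglik.csv"),
                                   check.names = FALSE))
  structure(list(
    model = man$model, group = man$group, subject_ids = man$subject_ids,
    param_names = info$name, link_U = info$link_U,
    mu = NULL, mu_nat = as.matrix(gd[info$name]),
    sigma = as.matrix(stats::setNames(gd[paste0("sigma.", info$name)],
                                      info$name)),
    theta = theta, pointwise_loglik = ptw,
    point_map = utils::read.csv(file.path(dir, "point_map.csv")),
    n_chains = man$n_chains, n_draws_per_chain = man$n_draws_per_chain,
    rhat = unlist(man$rhat), convergence_warning = man$convergence_warning,
    accept_rate = man$accept_rate, seed = man$seed, scale = man$scale
  ), class = "igt_fit")
}
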