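#' Define a cohort-generating regime
#'
#' A regime specifies how one group of synthetic subjects is produced: the
#' generating cognitive model, the group-level location of every parameter
#' (natural scale), the between-subject spread (on the unconstrained scale, so
#' bounded parameters respect their range through the probit link), and the
#' linear linkage from true parameters to pain subscores.
#'
#' @param group Group label.
#' @param n_subjects Number of subjects.
#' @param model Generating model id.
#' @param param_mean Named numeric vector of natural-scale parameter locations
#'   (all of `param_info(model)$name`).
#' @param param_spread Named numeric vector of unconstrained-scale SDs
#'   (recycled from a scalar).
#' @param pain_linkage List with elements `severity`, `REM`, `WASW`, each a
#'   list of `intercept`, `slopes` (named by parameter; missing = 0) and
#'   `noise_sd`, all on the 0-10 pain scale.
#' @param item_noise_sd SD of the extra item-level noise added before items
#'   are rounded and clipped to 0-10.
#' @return List of class `cohort_regime`.
#' @export
cohort_regime <- function(group, n_subjects, model, param_mean, param_spread,
                          pain_linkage, item_noise_sd = 0.8) {
  info <- param_info(model)
  miss <- setdiff(info$name, names(param_mean))
  if (length(miss)) stop("param_mean missing: ", paste(miss, collapse = ", "))
  validate_params(model, as.list(param_mean))
  if (length(param_spread) == 1 && is.null(names(param_spread))) {
    param_spread <- stats::setNames(rep(param_spread, nrow(info)), info$name)
  }
  structure(list(
    group = group, n_subjects = as.integer(n_subjects), model = model,
    param_mean = param_mean[info$name], param_spread = param_spread[info$name],
    pain_linkage = pain_linkage, item_noise_sd = item_noise_sd
  ), class = "cohort_regime")
}

#' Default healthy / chronic-pain generating regimes
#'
#' Two ORL regimes (a VPP pair is available via `model = "vpp"`) differing in
#' the directions reported for chronic pain: a higher reward learning rate and
#' a lower perseverance weight in the symptomatic group, all other parameters
#' shared. The numeric locations are SYNTHETIC package constants chosen to
#' yield realistic group separation and 0-10 pain scores; they are not
#' estimates from any empirical cohort. Pain subscores rise with the true
#' reward learning rate (and, for interference, fall mildly with
#' perseverance), so the parameter-pain linkage is recoverable downstream.
#'
#' @param model `"orl"` (default) or `"vpp"`.
#' @return Named list with `healthy` (n = 25) and `chronic_pain` (n = 20)
#'   regimes.
#' @export
default_regimes <- function(model = c("orl", "vpp")) {
  model <- match.arg(model)
  if (model == "orl") {
    shared <- c(A_pun = 0.10, K_prime = 1.0, beta_F = 1.5)
    spread <- c(A_rew = 0.4, A_pun = 0.4, K_prime = 0.4, beta_F = 0.8,
                beta_P = 0.8)
    linkage <- list(
      severity = list(intercept = 1.0, slopes = c(A_rew = 8), noise_sd = 1.2),
      REM = list(intercept = 0.8, slopes = c(A_rew = 8, beta_P = -0.3),
                 noise_sd = 1.5),
      WASW = list(intercept = 0.8, slopes = c(A_rew = 8, beta_P = -0.3),
                  noise_sd = 1.5)
    )
    healthy <- cohort_regime(
      "healthy", 25L, "orl",
      c(A_rew = 0.15, shared, beta_P = 1.25), spread, linkage
    )
    pain <- cohort_regime(
      "chronic_pain", 20L, "orl",
      c(A_rew = 0.45, shared, beta_P = -0.75), spread, linkage
    )
  } else {
    shared <- c(alpha = 0.40, lam = 1.5, c = 1.0, K = 0.3, ep_p = 1.0,
                ep_n = 0.5, w = 0.65)
    spread <- c(alpha = 0.4, lam = 0.4, A = 0.4, c = 0.4, K = 0.4, ep_p = 0.8,
                ep_n = 0.8, w = 0.4)
    linkage <- list(
      severity = list(intercept = 1.0, slopes = c(A = 6), noise_sd = 1.2),
      REM = list(intercept = 0.8, slopes = c(A = 6), noise_sd = 1.5),
      WASW = list(intercept = 0.8, slopes = c(A = 6), noise_sd = 1.5)
    )
    healthy <- cohort_regime(
      "healthy", 25L, "vpp", c(A = 0.20, shared), spread, linkage
    )
    pain <- cohort_regime(
      "chronic_pain", 20L, "vpp", c(A = 0.55, shared), spread, linkage
    )
  }
  list(healthy = healthy, chronic_pain = pain)
}

draw_regime_params <- function(regime) {
  info <- param_info(regime$model)
  mu_u <- link_to_unconstrained(regime$model, as.numeric(regime$param_mean))
  u <- stats::rnorm(nrow(info), mu_u, as.numeric(regime$param_spread))
  link_to_natural(regime$model, u)
}

generate_pain_items <- function(regime, params) {
  lk <- regime$pain_linkage
  latent <- function(spec) {
    sl <- spec$slopes
    val <- spec$intercept + sum(sl * as.numeric(params[names(sl)])) +
      stats::rnorm(1, 0, spec$noise_sd)
    val
  }
  sev <- latent(lk$severity)
  rem <- latent(lk$REM)
  wasw <- latent(lk$WASW)
  item <- function(target, n) {
    pmin(pmax(round(target + stats::rnorm(n, 0, regime$item_noise_sd)), 0), 10)
  }
  out <- c(
    stats::setNames(item(sev, 4), BPISF_SEVERITY_ITEMS),
    stats::setNames(item(rem, 3), BPISF_REM_ITEMS),
    stats::setNames(item(wasw, 4), BPISF_WASW_ITEMS)
  )
  out[c(BPISF_SEVERITY_ITEMS, BPISF_INTERFERENCE_ITEMS)]
}

#' Generate a complete synthetic study
#'
#' Draws each subject's true parameters from its regime, simulates a full IGT
#' session per subject with the model-driven agent, and generates linked
#' BPI-SF item responses, all reproducibly from one seed. The manifest records
#' the regimes, seed and true parameters so downstream recovery is checkable
#' with no other input.
#'
#' @param regimes Named list of `cohort_regime` objects (e.g.
#'   [default_regimes()]).
#' @param n_trials Trials per session (>= 10; default 100).
#' @param seed Master seed.
#' @param scheme Payoff scheme.
#' @return List of class `igt_study`: `sessions` (list of `igt_session`),
#'   `true_params` (data frame), `bpisf` (data frame of item responses),
#'   `manifest`.
#' @export
generate_study <- function(regimes, n_trials = 100L, seed = 1L,
                           scheme = build_payoff_scheme()) {
  stopifnot(n_trials >= 10)
  set.seed(seed)
  sessions <- list()
  tp_rows <- list()
  bp_rows <- list()
  sid_counter <- 0L
  for (rg in regimes) {
    prefix <- substr(gsub("[^a-z]", "", tolower(rg$group)), 1, 2)
    for (i in seq_len(rg$n_subjects)) {
      sid_counter <- sid_counter + 1L
      sid <- sprintf("%s%03d", prefix, i)
      params <- draw_regime_params(rg)
      items <- generate_pain_items(rg, params)
      sess_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      # simulate_agent reseeds internally; restore the master stream after
      rs <- get(".Random.seed", envir = globalenv())
      sess <- simulate_agent(rg$model, params, scheme, n_trials,
                             seed = sess_seed, subject_id = sid,
                             group = rg$group)
      assign(".Random.seed", rs, envir = globalenv())
      sessions[[length(sessions) + 1]] <- sess
      tp_rows[[length(tp_rows) + 1]] <- cbind(
        data.frame(subject_id = sid, group = rg$group, model = rg$model,
                   session_seed = sess_seed, stringsAsFactors = FALSE),
        as.data.frame(as.list(params))
      )
      bp_rows[[length(bp_rows) + 1]] <- cbind(
        data.frame(subject_id = sid, group = rg$group, stringsAsFactors = FALSE),
        as.data.frame(as.list(items))
      )
    }
  }
  manifest <- list(
    label = "SYNTHETIC",
    seed = seed, n_trials = n_trials,
    regimes = lapply(regimes, function(rg) {
      list(group = rg$group, n_subjects = rg$n_subjects, model = rg$model,
           param_mean = as.list(rg$param_mean),
           param_spread = as.list(rg$param_spread),
           pain_linkage = rg$pain_linkage, item_noise_sd = rg$item_noise_sd)
    }),
    package_version = as.character(utils::packageVersion("igtbayes"))
  )
  structure(list(
    sessions = sessions,
    true_params = do.call(rbind, tp_rows),
    bpisf = do.call(rbind, bp_rows),
    manifest = manifest
  ), class = "igt_study")
}

#' @export
print.igt_study <- function(x, ...) {
  tab <- table(vapply(x$sessions, function(s) s$group, character(1)))
  cat(sprintf("Synthetic IGT study: %d subjects (%s), %d trials each\n",
              length(x$sessions),
              paste(names(tab), tab, sep = " = ", collapse = ", "),
              nrow(x$sessions[[1]]$trials)))
  invisible(x)
}

#' Write a study to a directory
#'
#' Trial logs, BPI-SF responses and true parameters as CSV; the manifest
#' (including the full regime echo and seed) as JSON.
#'
#' @param study An `igt_study`.
#' @param dir Output directory (created if needed).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trial_logs(study$sessions, file.path(dir, "trial_logs.csv"))
  utils::write.csv(study$bpisf, file.path(dir, "bpisf.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(study$true_params, file.path(dir, "true_params.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(jsonlite::toJSON(study$manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}
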