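test_that("hdi is the narrowest interval with the requested mass", {
  expect_error(hdi(rnorm(5)), "at least 10")
  h0 <- hdi(rep(3.7, 50))
  expect_equal(h0$lower, 3.7)
  expect_equal(h0$upper, 3.7)

  set.seed(14)
  h <- hdi(rnorm(10000), 0.95)
  expect_lt(abs(h$lower - (-1.96)), 0.08)
  expect_lt(abs(h$upper - 1.96), 0.08)

  hu <- hdi(runif(10000), 0.5)
  expect_lt(abs((hu$upper - hu$lower) - 0.5), 0.03)

  # mass coverage and monotone widening
  x <- rexp(5000)
  h80 <- hdi(x, 0.8)
  h99 <- hdi(x, 0.99)
  expect_gte(mean(x >= h80$lower & x <= h80$upper), 0.8)
  expect_gt(h99$upper - h99$lower, h80$upper - h80$lower)
})

test_that("prior draws pushed through the links never leave the bounds", {
  set.seed(15)
  for (model in c("pvl_delta", "vpp", "orl")) {
    info <- param_info(model)
    n <- 10000
    for (p in seq_len(nrow(info))) {
      mu <- rnorm(n)
      sigma <- abs(rnorm(n))
      u <- mu + sigma * rnorm(n)
      nat <- if (info$link_U[p] > 0) info$link_U[p] * pnorm(u) else u
      expect_true(all(nat >= info$lower[p] & nat <= info$upper[p]))
    }
  }
})

test_that("fit bookkeeping: retained draws, summary rows, input checks", {
  sess <- make_small_cohort(n_subj = 4, n_trials = 40)
  fit <- suppressWarnings(
    fit_group(sess, "pvl_delta", mcmc = mcmc_config(2, 100, 200), seed = 5)
  )
  expect_equal(nrow(fit$mu), 400L)       # 2 chains x 200 retained
  expect_equal(ncol(fit$pointwise_loglik), 4L * 40L)
  summ <- posterior_summary(fit)
  expect_equal(nrow(summ), 4L * (4L + 2L))  # params x (subjects + 2 group rows)
  expect_true(all(summ$hdi_lower <= summ$mean & summ$mean <= summ$hdi_upper))
  expect_error(fit_group(sess[1], "pvl_delta"), "at least 2")
})

test_that("fits are reproducible under the sampler seed", {
  sess <- make_small_cohort(n_subj = 3, n_trials = 30)
  f1 <- suppressWarnings(fit_group(sess, "pvl_delta",
                                   mcmc = mcmc_config(1, 50, 50), seed = 99))
  f2 <- suppressWarnings(fit_group(sess, "pvl_delta",
                                   mcmc = mcmc_config(1, 50, 50), seed = 99))
  expect_identical(f1$mu, f2$mu)
  expect_identical(f1$theta, f2$theta)
})

test_that("data concentrate the posterior relative to the prior", {
  # identical deterministic sessions: strong evidence for extreme consistency
  base <- make_fixed_session(rep("D", 60))
  sess <- lapply(1:4, function(i) {
    s <- base
    s$subject_id <- paste0("dup", i)
    s
  })
  fit <- suppressWarnings(
    fit_group(sess, "pvl_delta", mcmc = mcmc_config(2, 300, 300), seed = 8)
  )
  set.seed(1)
  prior_mu <- rnorm(4000)
  info <- param_info("pvl_delta")
  for (p in seq_len(4)) {
    prior_nat_sd <- sd(info$link_U[p] * pnorm(prior_mu))
    expect_lt(sd(fit$mu_nat[, p]), prior_nat_sd)
  }
})

test_that("exchangeable subjects get matching individual estimates", {
  base <- simulate_agent("pvl_delta", pvl_params(0.4, 1.5, 0.3, 1),
                         n_trials = 80, seed = 3)
  twin <- base
  twin$subject_id <- "twin"
  filler <- make_small_cohort(n_subj = 3, n_trials = 80)
  fit <- suppressWarnings(
    fit_group(c(list(base, twin), filler), "pvl_delta",
              mcmc = mcmc_config(2, 400, 600), seed = 21)
  )
  for (p in fit$param_names) {
    d1 <- fit$theta[, paste0("sim1.", p)]
    d2 <- fit$theta[, paste0("twin.", p)]
    # batch-means MCSE of the difference
    dd <- d1 - d2
    nb <- 20
    bm <- tapply(dd, rep(seq_len(nb), each = length(dd) / nb), mean)
    mcse <- sd(bm) / sqrt(nb)
    expect_lt(abs(mean(dd)), 4 * mcse + 0.02)
  }
})

test_that("hierarchical estimates shrink relative to per-subject ML", {
  sess <- make_small_cohort(n_subj = 10, n_trials = 100)
  fit <- suppressWarnings(
    fit_group(sess, "pvl_delta", mcmc = mcmc_config(2, 400, 400), seed = 31)
  )
  post <- individual_means(fit)
  ml <- ml_fit_subjects(sess, "pvl_delta", seed = 2)
  shrunk <- vapply(fit$param_names, function(p) {
    var(post[[p]]) <= var(ml[[p]])
  }, logical(1))
  # shrinkage must hold for the clear majority of parameters
  expect_gte(sum(shrunk), 3L)
})

test_that("well-posed data yield converged group-level chains", {
  sess <- make_small_cohort(n_subj = 10, n_trials = 100)
  fit <- fit_group(sess, "pvl_delta", mcmc = mcmc_config(4, 2000, 500, thin = 6),
                   seed = 17)
  expect_true(all(fit$rhat < 1.05, na.rm = TRUE))
  expect_null(fit$convergence_warning)
})

test_that("group contrasts: null self-contrast, monotone mass, model check", {
  sess <- make_small_cohort(n_subj = 6, n_trials = 60)
  fit <- suppressWarnings(
    fit_group(sess, "pvl_delta", mcmc = mcmc_config(2, 300, 400), seed = 41)
  )
  self <- group_difference(fit, fit, "A", seed = 7)
  expect_false(self$exceeds_zero)
  wide <- group_difference(fit, fit, "A", mass = 0.999, seed = 7)
  narrow <- group_difference(fit, fit, "A", mass = 0.5, seed = 7)
  expect_gt(wide$hdi$upper - wide$hdi$lower,
            narrow$hdi$upper - narrow$hdi$lower)

  fit_orl <- suppressWarnings(
    fit_group(make_small_cohort(4, 40, seed = 9), "orl",
              mcmc = mcmc_config(1, 100, 100), seed = 2)
  )
  expect_error(group_difference(fit, fit_orl, "A"), "different models")
  expect_error(group_difference(fit, fit, "nope"), "unknown parameter")
})

test_that("subject order does not change group-level inference", {
  sess <- make_small_cohort(n_subj = 6, n_trials = 80)
  f1 <- suppressWarnings(fit_group(sess, "pvl_delta",
                                   mcmc = mcmc_config(2, 400, 600), seed = 13))
  f2 <- suppressWarnings(fit_group(rev(sess), "pvl_delta",
                                   mcmc = mcmc_config(2, 400, 600), seed = 14))
  for (p in f1$param_names) {
    m1 <- mean(f1$mu_nat[, p])
    m2 <- mean(f2$mu_nat[, p])
    pooled_sd <- sqrt((var(f1$mu_nat[, p]) + var(f2$mu_nat[, p])) / 2)
    expect_lt(abs(m1 - m2), 4 * pooled_sd / sqrt(20) + 0.05 * pooled_sd + 1e-6)
  }
})

test_that("fit archives carry draws, pointwise likelihoods and a manifest", {
  sess <- make_small_cohort(n_subj = 3, n_trials = 30)
  fit <- suppressWarnings(fit_group(sess, "pvl_delta",
                                    mcmc = mcmc_config(1, 50, 60), seed = 1))
  dir <- tempfile()
  write_fit_archive(fit, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "group_draws.csv", "individual_draws.csv", "pointwise_loglik.csv",
    "point_map.csv", "manifest.json"
  )))))
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(man$model, "pvl_delta")
  expect_equal(man$n_draws_per_chain, 60)
  expect_equal(man$seed, 1)

  back <- read_fit_archive(dir)
  expect_equal(unname(back$mu_nat), unname(fit$mu_nat), tolerance = 1e-8)
  expect_equal(unname(back$pointwise_loglik), unname(fit$pointwise_loglik),
               tolerance = 1e-8)
  expect_equal(pointwise_elpd(back)$elpd, pointwise_elpd(fit)$elpd,
               tolerance = 1e-6)
  expect_equal(individual_means(back), individual_means(fit), tolerance = 1e-8)
})
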