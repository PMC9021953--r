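test_that("prospect utility follows the gain/loss branches", {
  expect_equal(prospect_utility(0, 0.5, 2.5), 0)
  expect_equal(prospect_utility(1, 0.37, 2.5), 1)
  expect_equal(prospect_utility(-1, 0.8, 2.5), -2.5)
  expect_equal(prospect_utility(4, 0.5, 1), 2)
  expect_equal(prospect_utility(-4, 0.5, 3), -6)
})

test_that("delta rule moves only the chosen deck", {
  E <- c(0.2, -0.1, 0, 1)
  expect_equal(delta_update(E, 2, 5, 0), E)
  expect_equal(delta_update(E, 2, 5, 1)[2], 5)
  expect_equal(delta_update(c(0, 0, 0, 0), 1, 1, 0.5)[1], 0.5)
  expect_equal(delta_update(E, 3, 2, 0.25)[-3], E[-3])
})

test_that("decay rule discounts everything and credits the chosen deck", {
  expect_equal(decay_update(c(1, 1, 1, 1), 1, 2, 0.5), c(2.5, 0.5, 0.5, 0.5))
  expect_equal(decay_update(c(1, 2, 3, 4), 2, 5, 1), c(1, 7, 3, 4))
  expect_equal(decay_update(c(1, 2, 3, 4), 2, 5, 0), c(0, 5, 0, 0))
})

test_that("softmax probabilities are stable, normalised and limit correctly", {
  expect_equal(softmax_probs(c(3, 3, 3, 3), 2), rep(0.25, 4))
  expect_equal(softmax_probs(c(-5, 0, 2, 9), 0), rep(0.25, 4))  # c = 0
  p <- softmax_probs(c(1, 0, 0, 0), 1000)
  expect_gt(p[1], 0.999)
  for (V in list(c(350, -350, 0, 1), c(-700, -700, -700, -700),
                 rnorm(4, 0, 100))) {
    pr <- softmax_probs(V, 1)
    expect_true(all(pr > 0))
    expect_lt(abs(sum(pr) - 1), 1e-12)
  }
  # beyond the representable range the distribution still normalises
  expect_lt(abs(sum(softmax_probs(c(900, -900, 0, 1), 1)) - 1), 1e-12)
  expect_error(softmax_probs(c(Inf, 0, 0, 0), 1), "non-finite")
})

test_that("VPP perseverance decays and credits by outcome sign", {
  expect_equal(vpp_perseverance_update(c(5, 5, 5, 5), 2, 10, 0, 3, -1),
               c(0, 3, 0, 0))
  expect_equal(vpp_perseverance_update(c(2, 4, 6, 8), 1, 10, 0.5, 0, 0),
               c(1, 2, 3, 4))
  expect_equal(vpp_perseverance_update(c(1, 0, 0, 0), 1, -50, 0.5, 9, -2),
               c(-1.5, 0, 0, 0))
  expect_equal(vpp_value(c(2, 0, 0, 0), c(0, 2, 0, 0), 0.5), c(1, 1, 0, 0))
  expect_equal(vpp_value(c(2, 0, 0, 0), c(0, 2, 0, 0), 1), c(2, 0, 0, 0))
  expect_equal(vpp_value(c(2, 0, 0, 0), c(0, 2, 0, 0), 0), c(0, 2, 0, 0))
})

test_that("ORL update matches hand-evaluated targets", {
  p <- orl_params(0.5, 0.25, 0, 1, 1)
  zero <- list(EV = rep(0, 4), EF = rep(0, 4), PS = rep(0, 4))

  st <- orl_update(zero, 1, 1, p)
  expect_equal(st$EV[1], 0.5)
  expect_equal(st$EF[1], 0.5)
  expect_equal(st$EF[2:4], rep(0.25 * (-1 / 3), 3))
  expect_equal(st$PS, c(1, 0, 0, 0))  # K' = 0 so K = 0

  full <- orl_update(zero, 2, 1, orl_params(1, 0.3, 0, 0, 0))
  expect_equal(full$EV[2], 1)
  expect_equal(full$EF[2], 1)

  # zero outcome: sgn = 0, so every frequency target is 0
  st0 <- orl_update(list(EV = rep(0.5, 4), EF = rep(0.5, 4), PS = rep(0, 4)),
                    3, 0, p)
  expect_equal(st0$EF[3], 0.5 + 0.5 * (0 - 0.5))
  expect_equal(st0$EF[1], 0.5 + 0.25 * (0 - 0.5))

  # same-rate fictive variant uses the chosen-deck rate everywhere
  st_same <- orl_update(zero, 1, 1, p, fictive = "same")
  expect_equal(st_same$EF[2:4], rep(0.5 * (-1 / 3), 3))

  expect_equal(orl_value(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), -1, 2),
               c(1, -1, 2, 0))
  expect_equal(orl_value(c(1, 2, 3, 4), rep(1, 4), rep(1, 4), 0, 0),
               c(1, 2, 3, 4))
})

test_that("perseverance decay bound 3^K' - 1 reaches 242 at the K' cap", {
  p <- orl_params(0.5, 0.5, 5, 0, 0)
  expect_equal(3^p[["K_prime"]] - 1, 242)
  expect_error(orl_params(0.5, 0.5, 5.01, 0, 0), "out of bounds")
  st <- orl_update(list(EV = rep(0, 4), EF = rep(0, 4), PS = rep(0, 4)),
                   1, 1, p)
  expect_equal(st$PS[1], 1 / 243)
})

test_that("first-trial choice probability is uniform for every model", {
  s1 <- make_fixed_session("B")
  expect_equal(session_loglik("pvl_delta", pvl_params(0.5, 1, 0.3, 1), s1),
               log(0.25))
  expect_equal(session_loglik("pvl_decay",
                              pvl_params(0.5, 1, 0.3, 1, rule = "decay"), s1),
               log(0.25))
  expect_equal(session_loglik("vpp", vpp_params(0.5, 1, 0.3, 1, 0.5, 1, -1, 0.5),
                              s1), log(0.25))
  expect_equal(session_loglik("orl", orl_params(0.3, 0.3, 1, 1, 1), s1),
               log(0.25))
})

test_that("compiled likelihoods match the independent scalar oracles", {
  set.seed(202)
  for (rep in 1:10) {
    decks <- sample(c("A", "B", "C", "D"), 20, replace = TRUE)
    s <- make_fixed_session(decks, seed = rep)
    for (model in c("pvl_delta", "pvl_decay", "vpp", "orl")) {
      p <- random_params(model)
      expect_lt(max(abs(session_loglik(model, p, s) - oracle_loglik(model, p, s))),
                1e-10)
    }
  }
})

test_that("VPP with w = 1 and zero impacts reduces to PVL-Delta", {
  set.seed(7)
  for (rep in 1:5) {
    s <- make_fixed_session(sample(c("A", "B", "C", "D"), 30, replace = TRUE),
                            seed = rep)
    base <- c(alpha = runif(1, 0.2, 0.8), lam = runif(1, 0.5, 3),
              A = runif(1), c = runif(1, 0, 2))
    ll_vpp <- session_loglik("vpp", vpp_params(base["alpha"], base["lam"],
                                               base["A"], base["c"], K = 0.5,
                                               ep_p = 0, ep_n = 0, w = 1), s)
    ll_pvl <- session_loglik("pvl_delta", pvl_params(base["alpha"], base["lam"],
                                                     base["A"], base["c"]), s)
    expect_lt(max(abs(ll_vpp - ll_pvl)), 1e-10)
  }
})

test_that("ORL with zero weights and equal rates is a raw-outcome delta rule", {
  set.seed(8)
  for (rep in 1:5) {
    s <- make_fixed_session(sample(c("A", "B", "C", "D"), 30, replace = TRUE),
                            seed = rep)
    A <- runif(1, 0.1, 0.9)
    ll_orl <- session_loglik("orl", orl_params(A, A, 1.3, 0, 0), s)
    # oracle: delta rule on raw scaled outcomes, unit-sensitivity softmax
    E <- rep(0, 4)
    choices <- match(s$trials$deck, c("A", "B", "C", "D"))
    ll_ref <- numeric(30)
    for (t in 1:30) {
      ll_ref[t] <- oracle_softmax_logp(E, 1, choices[t])
      E[choices[t]] <- E[choices[t]] + A * (s$trials$net[t] / 100 - E[choices[t]])
    }
    expect_lt(max(abs(ll_orl - ll_ref)), 1e-10)
  }
})

test_that("simulated agents are reproducible and respect the payoff cycles", {
  p <- orl_params(0.3, 0.2, 1, 2, 1)
  a <- simulate_agent("orl", p, n_trials = 100, seed = 33)
  b <- simulate_agent("orl", p, n_trials = 100, seed = 33)
  expect_identical(a$trials, b$trials)

  # per-deck cycle conservation within the simulated session
  sch <- build_payoff_scheme()
  for (d in c("A", "B", "C", "D")) {
    spec <- sch$decks[sch$decks$deck == d, ]
    ls <- a$trials$loss[a$trials$deck == d]
    n_full <- length(ls) %/% spec$cycle_length
    if (n_full >= 1) {
      for (cy in seq_len(n_full)) {
        idx <- ((cy - 1) * spec$cycle_length + 1):(cy * spec$cycle_length)
        expect_equal(sum(ls[idx]), spec$total_loss_per_cycle)
      }
    }
  }
})

test_that("an indifferent agent chooses decks uniformly", {
  # c = 0 makes the softmax sensitivity 3^0 - 1 = 0
  s <- simulate_agent("pvl_delta", pvl_params(0.5, 1.5, 0.3, 0),
                      n_trials = 10000, seed = 12)
  freqs <- table(factor(s$trials$deck, levels = c("A", "B", "C", "D"))) / 10000
  expect_true(all(abs(freqs - 0.25) < 0.02))
})

test_that("a perseverance-dominated ORL agent repeats its previous deck", {
  s <- simulate_agent("orl", orl_params(0.2, 0.2, 0, 0, 50),
                      n_trials = 500, seed = 9)
  repeats <- mean(s$trials$deck[-1] == s$trials$deck[-500])
  expect_gt(repeats, 0.9)
})

test_that("an agent's own parameters outscore strongly perturbed ones", {
  for (model in c("pvl_delta", "orl")) {
    true <- switch(model,
      pvl_delta = pvl_params(0.4, 1.5, 0.25, 1.2),
      orl = orl_params(0.2, 0.15, 1, 2, 1.5)
    )
    pert <- switch(model,
      pvl_delta = pvl_params(0.9, 6, 0.95, 0.1),
      orl = orl_params(0.9, 0.85, 4, -2, -1.5)
    )
    s <- simulate_agent(model, true, n_trials = 2000, seed = 77)
    expect_gt(mean(session_loglik(model, true, s)),
              mean(session_loglik(model, pert, s)))
  }
})

test_that("parameter validation and data validation reject bad input", {
  expect_error(pvl_params(1.2, 1, 0.5, 1), "out of bounds")
  expect_error(pvl_params(0.5, 11, 0.5, 1), "out of bounds")
  expect_error(vpp_params(0.5, 1, 0.5, 1, 1.5, 0, 0, 0.5), "out of bounds")
  expect_error(orl_params(0.5, -0.1, 1, 0, 0), "out of bounds")
  expect_error(session_loglik("orl", orl_params(0.5, 0.5, 1, 0, 0),
                              list(trials = data.frame(trial = 1, deck = "Q",
                                                       net = 0))),
               "outside A-D")
})
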