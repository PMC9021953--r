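# Independent scalar-loop reference implementations of the four models'
# trial-by-trial choice log-likelihoods, written directly from the model
# equations. These deliberately share no code with the package internals.

oracle_softmax_logp <- function(V, sens, chosen) {
  z <- sens * V
  z <- z - max(z)
  z[chosen] - log(sum(exp(z)))
}

oracle_pvl_loglik <- function(rule, alpha, lam, A, cc, choices, nets, scale = 100) {
  E <- rep(0, 4)
  sens <- 3^cc - 1
  out <- numeric(length(choices))
  for (t in seq_along(choices)) {
    ch <- choices[t]
    out[t] <- oracle_softmax_logp(E, sens, ch)
    x <- nets[t] / scale
    u <- if (x >= 0) x^alpha else -lam * (-x)^alpha
    if (rule == "delta") {
      E[ch] <- E[ch] + A * (u - E[ch])
    } else {
      E <- A * E
      E[ch] <- E[ch] + u
    }
  }
  out
}

oracle_vpp_loglik <- function(alpha, lam, A, cc, K, ep_p, ep_n, w,
                              choices, nets, scale = 100) {
  E <- rep(0, 4)
  P <- rep(0, 4)
  sens <- 3^cc - 1
  out <- numeric(length(choices))
  for (t in seq_along(choices)) {
    ch <- choices[t]
    V <- w * E + (1 - w) * P
    out[t] <- oracle_softmax_logp(V, sens, ch)
    x <- nets[t] / scale
    u <- if (x >= 0) x^alpha else -lam * (-x)^alpha
    E[ch] <- E[ch] + A * (u - E[ch])
    P <- K * P
    P[ch] <- P[ch] + if (x >= 0) ep_p else ep_n
  }
  out
}

oracle_orl_loglik <- function(A_rew, A_pun, K_prime, beta_F, beta_P,
                              choices, nets, scale = 100) {
  EV <- EF <- PS <- rep(0, 4)
  K <- 3^K_prime - 1
  out <- numeric(length(choices))
  for (t in seq_along(choices)) {
    ch <- choices[t]
    V <- EV + beta_F * EF + beta_P * PS
    out[t] <- oracle_softmax_logp(V, 1, ch)
    x <- nets[t] / scale
    sg <- sign(x)
    A_ch <- if (x >= 0) A_rew else A_pun
    A_fic <- if (x >= 0) A_pun else A_rew
    EV[ch] <- EV[ch] + A_ch * (x - EV[ch])
    ef_ch <- EF[ch] + A_ch * (sg - EF[ch])
    for (j in setdiff(1:4, ch)) EF[j] <- EF[j] + A_fic * (-sg / 3 - EF[j])
    EF[ch] <- ef_ch
    PS <- PS / (1 + K)
    PS[ch] <- 1 / (1 + K)
  }
  out
}

oracle_loglik <- function(model, pars, session, scale = 100) {
  choices <- match(session$trials$deck, c("A", "B", "C", "D"))
  nets <- session$trials$net
  switch(model,
    pvl_delta = oracle_pvl_loglik("delta", pars[["alpha"]], pars[["lam"]],
                                  pars[["A"]], pars[["c"]], choices, nets, scale),
    pvl_decay = oracle_pvl_loglik("decay", pars[["alpha"]], pars[["lam"]],
                                  pars[["A"]], pars[["c"]], choices, nets, scale),
    vpp = oracle_vpp_loglik(pars[["alpha"]], pars[["lam"]], pars[["A"]],
                            pars[["c"]], pars[["K"]], pars[["ep_p"]],
                            pars[["ep_n"]], pars[["w"]], choices, nets, scale),
    orl = oracle_orl_loglik(pars[["A_rew"]], pars[["A_pun"]], pars[["K_prime"]],
                            pars[["beta_F"]], pars[["beta_P"]], choices, nets,
                            scale)
  )
}

# a session with an arbitrary fixed choice sequence played against the
# standard payoff schedule
make_fixed_session <- function(decks, seed = 1, subject_id = "fx1",
                               group = "healthy") {
  policy <- function(state) decks[state$t]
  run_session(policy, n_trials = length(decks), seed = seed,
              subject_id = subject_id, group = group)
}

random_params <- function(model) {
  switch(model,
    pvl_delta = pvl_params(runif(1, 0.1, 0.9), runif(1, 0.2, 5),
                           runif(1, 0, 1), runif(1, 0, 2), rule = "delta"),
    pvl_decay = pvl_params(runif(1, 0.1, 0.9), runif(1, 0.2, 5),
                           runif(1, 0, 1), runif(1, 0, 2), rule = "decay"),
    vpp = vpp_params(runif(1, 0.1, 0.9), runif(1, 0.2, 5), runif(1, 0, 1),
                     runif(1, 0, 2), runif(1, 0, 1), rnorm(1), rnorm(1),
                     runif(1, 0.05, 0.95)),
    orl = orl_params(runif(1, 0.05, 0.95), runif(1, 0.05, 0.95),
                     runif(1, 0, 3), rnorm(1, 0, 2), rnorm(1, 0, 2))
  )
}

# quick small hierarchical cohort for fit-based unit tests
make_small_cohort <- function(n_subj = 8, n_trials = 80, model = "pvl_delta",
                              seed = 100) {
  set.seed(seed)
  seeds <- sample.int(1e6, n_subj)
  lapply(seq_len(n_subj), function(i) {
    p <- switch(model,
      pvl_delta = pvl_params(pnorm(rnorm(1, -0.3, 0.4)),
                             10 * pnorm(rnorm(1, -1.2, 0.3)),
                             pnorm(rnorm(1, -1, 0.5)),
                             5 * pnorm(rnorm(1, -1, 0.3))),
      orl = orl_params(pnorm(rnorm(1, -1, 0.5)),
                       pnorm(rnorm(1, -1.2, 0.5)),
                       5 * pnorm(rnorm(1, -1, 0.4)),
                       rnorm(1, 1.5, 0.8), rnorm(1, 0.8, 0.8))
    )
    simulate_agent(model, p, n_trials = n_trials, seed = seeds[i],
                   subject_id = sprintf("u%02d", i))
  })
}
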