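#' Prospect utility of a net outcome
#'
#' `u(x) = x^alpha` for gains and `-lam * |x|^alpha` for losses: diminishing
#' sensitivity to magnitude, asymmetric weighting of losses versus gains.
#'
#' @param x Scaled net outcome (gain minus loss).
#' @param alpha Outcome sensitivity in (0,1).
#' @param lam Loss aversion in (0,10).
#' @return Subjective utility, same length as `x`.
#' @export
prospect_utility <- function(x, alpha, lam) {
  ifelse(x >= 0, x^alpha, -lam * abs(x)^alpha)
}

#' Delta-rule expectancy update
#'
#' Only the chosen deck moves, by `A` of the prediction error; the other decks
#' are untouched.
#'
#' @param E Length-4 expectancy vector.
#' @param chosen Chosen deck index (1..4).
#' @param u Utility of the experienced outcome.
#' @param A Learning rate in `[0,1]`.
#' @return Updated expectancy vector.
#' @export
delta_update <- function(E, chosen, u, A) {
  E[chosen] <- E[chosen] + A * (u - E[chosen])
  E
}

#' Decay-rule expectancy update
#'
#' Every deck's expectancy is discounted by `A`; the chosen deck additionally
#' absorbs the full current utility.
#'
#' @inheritParams delta_update
#' @param A Decay rate in `[0,1]`.
#' @return Updated expectancy vector.
#' @export
decay_update <- function(E, chosen, u, A) {
  E <- A * E
  E[chosen] <- E[chosen] + u
  E
}

#' Softmax choice probabilities over deck values
#'
#' Max-stabilised; a sensitivity of 0 gives the uniform distribution.
#'
#' @param V Finite numeric vector of deck values.
#' @param sensitivity Non-negative inverse temperature.
#' @return Probability vector summing to 1.
#' @export
softmax_probs <- function(V, sensitivity) {
  if (any(!is.finite(V))) stop("non-finite deck values")
  z <- sensitivity * V
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' VPP perseverance update
#'
#' All decks decay by `K`; the chosen deck is then incremented by the gain
#' impact `ep_p` if the net outcome was non-negative, else the loss impact
#' `ep_n`.
#'
#' @param P Length-4 perseverance vector.
#' @param chosen Chosen deck index.
#' @param net Net outcome of the trial (sign is what matters).
#' @param K Decay in `[0,1]`.
#' @param ep_p,ep_n Gain and loss impact parameters.
#' @return Updated perseverance vector.
#' @export
vpp_perseverance_update <- function(P, chosen, net, K, ep_p, ep_n) {
  P <- K * P
  P[chosen] <- P[chosen] + if (net >= 0) ep_p else ep_n
  P
}

#' VPP integrated deck value
#'
#' @param E Expectancy vector.
#' @param P Perseverance vector.
#' @param w Weight on expectancy in (0,1).
#' @return `w * E + (1 - w) * P`.
#' @export
vpp_value <- function(E, P, w) w * E + (1 - w) * P

#' One ORL learning step
#'
#' Updates the chosen deck's expected value and win frequency with the
#' valence-matched learning rate (`A_rew` for `x >= 0`, `A_pun` otherwise),
#' applies the fictive frequency update `-sgn(x)/3` to the unchosen decks
#' (by default with the opposite-valence rate), and refreshes the perseverance
#' trace with decay `K = 3^K_prime - 1`.
#'
#' @param state List with length-4 vectors `EV`, `EF`, `PS`.
#' @param chosen Chosen deck index.
#' @param x Scaled net outcome.
#' @param params An `orl_params()` vector.
#' @param fictive Either `"opposite"` (default) or `"same"`: which learning
#'   rate the unchosen decks' frequency update uses.
#' @return Updated state list.
#' @export
orl_update <- function(state, chosen, x, params, fictive = c("opposite", "same")) {
  fictive <- match.arg(fictive)
  A_ch <- if (x >= 0) params[["A_rew"]] else params[["A_pun"]]
  A_fic <- if (fictive == "same") A_ch else {
    if (x >= 0) params[["A_pun"]] else params[["A_rew"]]
  }
  sg <- sign(x)
  state$EV[chosen] <- state$EV[chosen] + A_ch * (x - state$EV[chosen])
  ef_ch <- state$EF[chosen] + A_ch * (sg - state$EF[chosen])
  state$EF <- state$EF + A_fic * (-sg / 3 - state$EF)
  state$EF[chosen] <- ef_ch
  K <- 3^params[["K_prime"]] - 1
  state$PS <- state$PS / (1 + K)
  state$PS[chosen] <- 1 / (1 + K)
  state
}

#' ORL integrated deck value
#'
#' @param EV,EF,PS Length-4 value, frequency and perseverance vectors.
#' @param beta_F,beta_P Frequency and perseverance weights.
#' @return `EV + beta_F * EF + beta_P * PS`; choice probabilities are the
#'   softmax of this value with sensitivity 1.
#' @export
orl_value <- function(EV, EF, PS, beta_F, beta_P) EV + beta_F * EF + beta_P * PS

#' Per-trial log-likelihood of a session under a cognitive model
#'
#' Computes, for each trial, the log probability of the observed choice given
#' the history of previous choices and outcomes, starting from the all-zero
#' latent state (so trial 1 is uniform at log 1/4). Net outcomes are divided
#' by `scale` before entering utility and learning.
#'
#' @param model Model id: `"pvl_delta"`, `"pvl_decay"`, `"vpp"` or `"orl"`.
#' @param params Parameters from the matching constructor (or a named vector).
#' @param session An `igt_session`.
#' @param scale Outcome divisor (default 100).
#' @param orl_fictive Fictive-rate convention for ORL; see [orl_update()].
#' @return Numeric vector of per-trial log-probabilities.
#' @export
session_loglik <- function(model, params, session, scale = 100,
                           orl_fictive = c("opposite", "same")) {
  model <- match.arg(model, names(MODEL_IDS))
  orl_fictive <- match.arg(orl_fictive)
  p <- validate_params(model, as.list(params))
  choices <- match(session$trials$deck, c("A", "B", "C", "D"))
  if (anyNA(choices)) {
    stop("session contains deck ids outside A-D: ",
         paste(unique(session$trials$deck[is.na(choices)]), collapse = ", "))
  }
  if (!length(choices)) stop("session has no trials")
  cpp_session_logp(MODEL_IDS[[model]], p, choices, session$trials$net / scale,
                   as.integer(orl_fictive == "same"))
}

#' Simulate a model-driven agent playing the IGT
#'
#' Choices are sampled trial by trial from the model's softmax probabilities;
#' outcomes come from a seeded payoff schedule. Uses the same compiled update
#' code as [session_loglik()].
#'
#' @inheritParams session_loglik
#' @param scheme An `igt_scheme`.
#' @param n_trials Session length.
#' @param seed Integer seed; same seed gives an identical session.
#' @param subject_id,group,endowment Session metadata.
#' @return An `igt_session`.
#' @export
simulate_agent <- function(model, params, scheme = build_payoff_scheme(),
                           n_trials = 100L, seed = 1L, subject_id = "sim1",
                           group = "healthy", endowment = 2000,
                           orl_fictive = c("opposite", "same")) {
  model <- match.arg(model, names(MODEL_IDS))
  orl_fictive <- match.arg(orl_fictive)
  p <- validate_params(model, as.list(params))
  set.seed(seed)
  sched <- payoff_schedule(scheme, n_trials)
  sim <- cpp_simulate_agent(MODEL_IDS[[model]], p, sched$rewards, sched$losses,
                            as.integer(n_trials), scheme$outcome_scale,
                            as.integer(orl_fictive == "same"))
  new_session(subject_id, group, endowment, data.frame(
    trial = seq_len(n_trials), deck = c("A", "B", "C", "D")[sim$deck],
    reward = sim$reward, loss = sim$loss, net = sim$reward + sim$loss,
    stringsAsFactors = FALSE
  ), seed = seed)
}
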