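MODEL_IDS <- c(pvl_delta = 0L, pvl_decay = 1L, vpp = 2L, orl = 3L)

#' Parameter metadata for a cognitive model
#'
#' Returns the parameter names, bounds and link specification of one of the
#' four IGT models. Bounded parameters use a probit link scaled to `[0, U]`
#' (`U` in the `link_U` column); unbounded parameters (`link_U = 0`) use the
#' identity link.
#'
#' @param model One of `"pvl_delta"`, `"pvl_decay"`, `"vpp"`, `"orl"`.
#' @return Data frame with columns `name`, `lower`, `upper`, `link_U`.
#' @export
param_info <- function(model) {
  model <- match.arg(model, names(MODEL_IDS))
  switch(model,
    pvl_delta = ,
    pvl_decay = data.frame(
      name = c("alpha", "lam", "A", "c"),
      lower = c(0, 0, 0, 0), upper = c(1, 10, 1, 5),
      link_U = c(1, 10, 1, 5)
    ),
    vpp = data.frame(
      name = c("alpha", "lam", "A", "c", "K", "ep_p", "ep_n", "w"),
      lower = c(0, 0, 0, 0, 0, -Inf, -Inf, 0),
      upper = c(1, 10, 1, 5, 1, Inf, Inf, 1),
      link_U = c(1, 10, 1, 5, 1, 0, 0, 1)
    ),
    orl = data.frame(
      name = c("A_rew", "A_pun", "K_prime", "beta_F", "beta_P"),
      lower = c(0, 0, 0, -Inf, -Inf), upper = c(1, 1, 5, Inf, Inf),
      link_U = c(1, 1, 5, 0, 0)
    )
  )
}

validate_params <- function(model, params) {
  info <- param_info(model)
  miss <- setdiff(info$name, names(params))
  if (length(miss)) {
    stop(model, " parameters missing: ", paste(miss, collapse = ", "))
  }
  v <- as.numeric(params[info$name])
  bad <- !is.finite(v) & info$link_U > 0
  bad <- bad | v < info$lower | v > info$upper
  if (any(bad)) {
    stop(model, " parameter(s) out of bounds: ",
         paste(info$name[bad], collapse = ", "))
  }
  stats::setNames(v, info$name)
}

#' Prospect Valence Learning parameters
#'
#' @param alpha Outcome sensitivity, in (0,1): curvature of the utility
#'   function.
#' @param lam Loss aversion, in (0,10): weight of losses relative to gains.
#' @param A Learning rate (delta rule) or decay rate (decay rule), in `[0,1]`.
#' @param c Response consistency, in `[0,5]`; softmax sensitivity is
#'   `3^c - 1`.
#' @param rule `"delta"` or `"decay"`.
#' @return Named numeric vector of class `igt_params` with a `model` attribute.
#' @export
pvl_params <- function(alpha, lam, A, c, rule = c("delta", "decay")) {
  rule <- match.arg(rule)
  model <- paste0("pvl_", rule)
  p <- validate_params(model, list(alpha = alpha, lam = lam, A = A, c = c))
  structure(p, model = model, class = "igt_params")
}

#' Values-Plus-Perseverance parameters
#'
#' PVL-Delta augmented with a decaying perseverance signal mixed into the
#' deck value by weight `w`.
#'
#' @inheritParams pvl_params
#' @param K Perseverance decay, in `[0,1]`.
#' @param ep_p Gain impact added to the chosen deck's perseverance after a
#'   non-negative net outcome (unbounded).
#' @param ep_n Loss impact after a negative net outcome (unbounded).
#' @param w Weight of expectancy relative to perseverance, in (0,1).
#' @return Named numeric vector of class `igt_params`.
#' @export
vpp_params <- function(alpha, lam, A, c, K, ep_p, ep_n, w) {
  p <- validate_params("vpp", list(alpha = alpha, lam = lam, A = A, c = c,
                                   K = K, ep_p = ep_p, ep_n = ep_n, w = w))
  structure(p, model = "vpp", class = "igt_params")
}

#' Outcome-Representation Learning parameters
#'
#' @param A_rew Reward learning rate, in (0,1): applied after non-negative net
#'   outcomes.
#' @param A_pun Punishment learning rate, in (0,1): applied after losses.
#' @param K_prime Decay parameter, in `[0,5]`; the effective perseverance decay
#'   is `K = 3^K_prime - 1`, in `[0, 242]`.
#' @param beta_F Outcome-frequency weight (unbounded); positive values favour
#'   decks with high win frequency.
#' @param beta_P Perseverance weight (unbounded); positive values favour
#'   repeating recent choices, negative values favour switching.
#' @return Named numeric vector of class `igt_params`.
#' @export
orl_params <- function(A_rew, A_pun, K_prime, beta_F, beta_P) {
  p <- validate_params("orl", list(A_rew = A_rew, A_pun = A_pun,
                                   K_prime = K_prime, beta_F = beta_F,
                                   beta_P = beta_P))
  structure(p, model = "orl", class = "igt_params")
}

#' Map unconstrained values to the natural parameter scale
#'
#' Bounded parameters use `U * pnorm(u)`; unbounded ones pass through.
#'
#' @param model Model id.
#' @param u Numeric vector (or matrix with one column per parameter) on the
#'   unconstrained scale, in `param_info(model)$name` order.
#' @return Values on the natural scale, same shape as `u`.
#' @export
link_to_natural <- function(model, u) {
  info <- param_info(model)
  f <- function(vec) {
    ifelse(info$link_U > 0, info$link_U * stats::pnorm(vec), vec)
  }
  if (is.matrix(u)) t(apply(u, 1, f)) else stats::setNames(f(u), info$name)
}

#' Map natural-scale parameters to the unconstrained scale
#'
#' Inverse of [link_to_natural()].
#'
#' @inheritParams link_to_natural
#' @param x Natural-scale values in `param_info(model)$name` order.
#' @export
link_to_unconstrained <- function(model, x) {
  info <- param_info(model)
  ifelse(info$link_U > 0, stats::qnorm(pmin(pmax(x / pmax(info$link_U, 1e-12),
                                                 1e-12), 1 - 1e-12)), x)
}
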