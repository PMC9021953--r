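#' Construct an Iowa Gambling Task payoff scheme
#'
#' The default scheme is the classic four-deck structure: decks A and B pay a
#' constant EUR 100 per pick but lose EUR 1250 over every 10-pick cycle (deck A
#' spreads the loss over 5 trials, deck B concentrates it in 1), while decks C
#' and D pay EUR 50 per pick and lose only EUR 250 per cycle (5 vs 1 loss
#' trials). Net outcome per cycle is therefore -250 for A/B and +250 for C/D,
#' making C and D the advantageous ("good") decks.
#'
#' @param overrides Named list of per-deck overrides. Each element is named
#'   `"A"`.."D"` and may supply `reward_per_trial`, `total_loss_per_cycle`,
#'   `n_loss_trials_per_cycle`, or `cycle_length`. Scheme-level entries
#'   `cycle_length` and `outcome_scale` are also accepted.
#' @return An object of class `igt_scheme`: a list with a `decks` data frame
#'   (one row per deck), `n_alternatives` (3) and `outcome_scale` (divisor
#'   applied to net outcomes before cognitive modeling; default 100).
#' @examples
#' sch <- build_payoff_scheme()
#' sch$decks
#' @export
build_payoff_scheme <- function(overrides = NULL) {
  decks <- data.frame(
    deck = c("A", "B", "C", "D"),
    reward_per_trial = c(100, 100, 50, 50),
    total_loss_per_cycle = c(-1250, -1250, -250, -250),
    n_loss_trials_per_cycle = c(5L, 1L, 5L, 1L),
    cycle_length = c(10L, 10L, 10L, 10L),
    stringsAsFactors = FALSE
  )
  outcome_scale <- 100
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides))
    if (!is.null(overrides$cycle_length)) {
      decks$cycle_length <- as.integer(overrides$cycle_length)
    }
    if (!is.null(overrides$outcome_scale)) {
      outcome_scale <- overrides$outcome_scale
    }
    for (d in intersect(names(overrides), decks$deck)) {
      ov <- overrides[[d]]
      i <- match(d, decks$deck)
      for (f in intersect(names(ov), names(decks))) decks[i, f] <- ov[[f]]
    }
  }
  bad <- decks$n_loss_trials_per_cycle > decks$cycle_length |
    decks$n_loss_trials_per_cycle < 0 | decks$cycle_length < 1 |
    decks$reward_per_trial < 0 | decks$total_loss_per_cycle > 0
  if (any(bad)) {
    stop("invalid payoff configuration for deck(s): ",
         paste(decks$deck[bad], collapse = ", "))
  }
  if (!is.numeric(outcome_scale) || outcome_scale <= 0) {
    stop("outcome_scale must be a positive number")
  }
  decks$net_per_cycle <- decks$cycle_length * decks$reward_per_trial +
    decks$total_loss_per_cycle
  structure(
    list(decks = decks, n_alternatives = 3L, outcome_scale = outcome_scale),
    class = "igt_scheme"
  )
}

#' Initialise per-deck draw state for outcome generation
#'
#' Loss positions within each deck's cycle are a uniformly random permutation
#' (drawn with the session RNG), with each loss trial carrying an equal share
#' `total_loss_per_cycle / n_loss_trials_per_cycle`. Decks never deplete:
#' a fresh cycle is shuffled whenever the previous one is exhausted.
#'
#' @param scheme An `igt_scheme`.
#' @return A `deck_state` list with one counter and loss-position set per deck.
#' @export
new_deck_state <- function(scheme) {
  st <- lapply(seq_len(nrow(scheme$decks)), function(i) {
    list(count = 0L, loss_pos = integer(0))
  })
  names(st) <- scheme$decks$deck
  structure(list(scheme = scheme, decks = st), class = "deck_state")
}

#' Draw one trial outcome from a deck
#'
#' @param state A `deck_state` from [new_deck_state()]. Uses R's RNG: seed the
#'   session with `set.seed()` for reproducibility.
#' @param deck Deck identifier, one of the scheme's deck labels.
#' @return List with `reward`, `loss`, `net` (all in EUR) and the updated
#'   `state`.
#' @export
draw_outcome <- function(state, deck) {
  stopifnot(inherits(state, "deck_state"))
  i <- match(deck, state$scheme$decks$deck)
  if (is.na(i)) stop("unknown deck id: ", deck)
  spec <- state$scheme$decks[i, ]
  ds <- state$decks[[deck]]
  pos_in_cycle <- ds$count %% spec$cycle_length
  if (pos_in_cycle == 0L) {
    ds$loss_pos <- sample.int(spec$cycle_length)[seq_len(spec$n_loss_trials_per_cycle)]
  }
  ds$count <- ds$count + 1L
  loss <- if ((pos_in_cycle + 1L) %in% ds$loss_pos) {
    spec$total_loss_per_cycle / spec$n_loss_trials_per_cycle
  } else 0
  state$decks[[deck]] <- ds
  list(reward = spec$reward_per_trial, loss = loss,
       net = spec$reward_per_trial + loss, state = state)
}

#' Precompute per-deck outcome schedules
#'
#' Generates, for each deck, the reward and loss of its k-th draw for
#' k = 1..n_draws, using the seeded-permutation loss placement. Used by the
#' session runner and the generative agents so both share one outcome stream.
#'
#' @param scheme An `igt_scheme`.
#' @param n_draws Maximum number of draws any one deck may receive.
#' @return List with `rewards` and `losses`, each an `n_draws x 4` matrix with
#'   columns in deck order.
#' @export
payoff_schedule <- function(scheme, n_draws) {
  nd <- nrow(scheme$decks)
  rewards <- matrix(0, n_draws, nd, dimnames = list(NULL, scheme$decks$deck))
  losses <- matrix(0, n_draws, nd, dimnames = list(NULL, scheme$decks$deck))
  for (i in seq_len(nd)) {
    spec <- scheme$decks[i, ]
    rewards[, i] <- spec$reward_per_trial
    n_cycles <- ceiling(n_draws / spec$cycle_length)
    loss_each <- if (spec$n_loss_trials_per_cycle > 0) {
      spec$total_loss_per_cycle / spec$n_loss_trials_per_cycle
    } else 0
    for (cy in seq_len(n_cycles)) {
      if (spec$n_loss_trials_per_cycle == 0L) next
      pos <- sample.int(spec$cycle_length)[seq_len(spec$n_loss_trials_per_cycle)]
      idx <- (cy - 1L) * spec$cycle_length + pos
      idx <- idx[idx <= n_draws]
      losses[idx, i] <- loss_each
    }
  }
  list(rewards = rewards, losses = losses)
}

#' Run one IGT session under an arbitrary choice policy
#'
#' @param policy Function `(state) -> deck label`, where `state` is a list with
#'   `t` (the 1-based trial about to be played) and vectors `deck`, `reward`,
#'   `loss`, `net` of the trials played so far.
#' @param scheme An `igt_scheme`; defaults to the classic four-deck scheme.
#' @param n_trials Session length (default 100; the task ends automatically).
#' @param seed Integer seed; identical `(policy, scheme, seed)` triples
#'   reproduce bit-identical sessions.
#' @param subject_id,group,endowment Session metadata; the endowment defaults
#'   to the EUR 2000 the task begins with.
#' @return An `igt_session`: list with the metadata and a `trials` data frame
#'   (`trial`, `deck`, `reward`, `loss`, `net`).
#' @export
run_session <- function(policy, scheme = build_payoff_scheme(), n_trials = 100L,
                        seed = 1L, subject_id = "s1", group = "healthy",
                        endowment = 2000) {
  stopifnot(is.function(policy), n_trials >= 1)
  set.seed(seed)
  sched <- payoff_schedule(scheme, n_trials)
  labels <- scheme$decks$deck
  deck <- character(n_trials)
  reward <- loss <- numeric(n_trials)
  count <- stats::setNames(integer(length(labels)), labels)
  for (t in seq_len(n_trials)) {
    sofar <- seq_len(t - 1L)
    ch <- policy(list(t = t, deck = deck[sofar], reward = reward[sofar],
                      loss = loss[sofar], net = reward[sofar] + loss[sofar]))
    if (length(ch) != 1L || !ch %in% labels) {
      stop("policy returned an invalid deck at trial ", t)
    }
    count[ch] <- count[ch] + 1L
    deck[t] <- ch
    reward[t] <- sched$rewards[count[ch], ch]
    loss[t] <- sched$losses[count[ch], ch]
  }
  new_session(subject_id, group, endowment, data.frame(
    trial = seq_len(n_trials), deck = deck, reward = reward, loss = loss,
    net = reward + loss, stringsAsFactors = FALSE
  ), seed = seed)
}

new_session <- function(subject_id, group, endowment, trials, seed = NA_integer_) {
  stopifnot(identical(trials$trial, seq_len(nrow(trials))))
  structure(
    list(subject_id = subject_id, group = group, endowment = endowment,
         trials = trials, rng_seed = seed),
    class = "igt_session"
  )
}

#' @export
print.igt_session <- function(x, ...) {
  cat(sprintf("IGT session: subject %s (%s), %d trials, total gain EUR %.0f\n",
              x$subject_id, x$group, nrow(x$trials), total_gain(x)))
  invisible(x)
}

#' Total gain at the end of a session
#'
#' @param session An `igt_session`.
#' @return Endowment plus the cumulative net outcome, in EUR.
#' @export
total_gain <- function(session) {
  session$endowment + sum(session$trials$net)
}
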