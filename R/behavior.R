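GOOD_DECKS <- c("C", "D")

#' Per-block behavioral summaries of an IGT session
#'
#' Splits the session into consecutive non-overlapping blocks and, for each,
#' counts good-deck (C, D) and bad-deck (A, B) picks, the learning score
#' (good minus bad), and the proportion of good picks.
#'
#' @param session An `igt_session`.
#' @param block_size Trials per block (default 20, giving 5 blocks of a
#'   100-trial session).
#' @return Data frame with one row per block: `block`, `n_good`, `n_bad`,
#'   `learning_score`, `prop_good`.
#' @export
block_scores <- function(session, block_size = 20L) {
  n <- nrow(session$trials)
  if (n %% block_size != 0L) {
    stop("session length ", n, " is not divisible by block size ", block_size)
  }
  blk <- rep(seq_len(n %/% block_size), each = block_size)
  good <- session$trials$deck %in% GOOD_DECKS
  n_good <- as.integer(tapply(good, blk, sum))
  data.frame(
    block = seq_len(n %/% block_size),
    n_good = n_good,
    n_bad = as.integer(block_size) - n_good,
    learning_score = 2L * n_good - as.integer(block_size),
    prop_good = n_good / block_size
  )
}

#' Behavioral summary table for a list of sessions
#'
#' One row per subject: total gain plus per-block learning scores and
#' good-deck proportions.
#'
#' @param sessions List of `igt_session` objects.
#' @param block_size Trials per block.
#' @return Data frame with columns `subject_id`, `group`, `total_gain`,
#'   `learning_b<k>` and `prop_good_b<k>` for each block `k`.
#' @export
behavioral_summary <- function(sessions, block_size = 20L) {
  rows <- lapply(sessions, function(s) {
    bs <- block_scores(s, block_size)
    out <- data.frame(subject_id = s$subject_id, group = s$group,
                      total_gain = total_gain(s), stringsAsFactors = FALSE)
    for (k in bs$block) {
      out[[paste0("learning_b", k)]] <- bs$learning_score[k]
      out[[paste0("prop_good_b", k)]] <- bs$prop_good[k]
    }
    out
  })
  do.call(rbind, rows)
}

#' Write sessions as a long trial-log CSV
#'
#' Columns: `subject_id`, `group`, `trial`, `deck`, `reward`, `loss`, `net`.
#'
#' @param sessions List of `igt_session` objects.
#' @param path Output CSV path.
#' @export
write_trial_logs <- function(sessions, path) {
  rows <- lapply(sessions, function(s) {
    cbind(data.frame(subject_id = s$subject_id, group = s$group,
                     stringsAsFactors = FALSE), s$trials)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial-log CSV back into sessions
#'
#' @param path CSV written by [write_trial_logs()] (or any file with the same
#'   columns).
#' @param endowment Starting endowment to attach to each session.
#' @return List of `igt_session` objects, in file order of first appearance.
#' @export
read_trial_logs <- function(path, endowment = 2000) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "trial", "deck", "reward", "loss", "net")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trial log missing column(s): ", paste(miss, collapse = ", "))
  ids <- unique(df$subject_id)
  lapply(ids, function(id) {
    sub <- df[df$subject_id == id, ]
    sub <- sub[order(sub$trial), ]
    new_session(id, sub$group[1], endowment,
                data.frame(trial = sub$trial, deck = sub$deck, reward = sub$reward,
                           loss = sub$loss, net = sub$net, stringsAsFactors = FALSE))
  })
}
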