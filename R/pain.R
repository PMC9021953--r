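BPISF_SEVERITY_ITEMS <- c("worst", "least", "average", "now")
BPISF_INTERFERENCE_ITEMS <- c("general_activity", "mood", "walking",
                              "normal_work", "relations", "sleep", "enjoyment")
BPISF_REM_ITEMS <- c("relations", "enjoyment", "mood")
BPISF_WASW_ITEMS <- c("walking", "general_activity", "sleep", "normal_work")

#' Score a Brief Pain Inventory-Short Form response
#'
#' Severity is the mean of the four intensity items (worst, least, average,
#' current); interference is the mean of the seven daily-functioning items and
#' splits into the affective subdimension REM (relations, enjoyment, mood) and
#' the activity subdimension WASW (walking, general activity, sleep, work),
#' so that `interference = (3*REM + 4*WASW) / 7`. All items are 0-10 integers;
#' missing or out-of-range items are an error (no imputation).
#'
#' @param responses Named list or one-row data frame with the severity items
#'   (`worst`, `least`, `average`, `now`) and interference items
#'   (`general_activity`, `mood`, `walking`, `normal_work`, `relations`,
#'   `sleep`, `enjoyment`).
#' @return List of class `pain_profile`: `severity`, `interference`, `REM`,
#'   `WASW`, all on the 0-10 scale.
#' @export
score_bpisf <- function(responses) {
  responses <- as.list(responses)
  items <- c(BPISF_SEVERITY_ITEMS, BPISF_INTERFERENCE_ITEMS)
  for (it in items) {
    v <- responses[[it]]
    if (is.null(v) || length(v) != 1 || is.na(v)) {
      stop("BPI-SF item missing: ", it)
    }
    if (!is.numeric(v) || v < 0 || v > 10) {
      stop("BPI-SF item out of range [0,10]: ", it)
    }
  }
  g <- function(nm) mean(vapply(responses[nm], as.numeric, numeric(1)))
  structure(list(
    severity = g(BPISF_SEVERITY_ITEMS),
    interference = g(BPISF_INTERFERENCE_ITEMS),
    REM = g(BPISF_REM_ITEMS),
    WASW = g(BPISF_WASW_ITEMS)
  ), class = "pain_profile")
}

#' Score a table of BPI-SF responses
#'
#' @param df Data frame with a `subject_id` column and one column per BPI-SF
#'   item.
#' @return Data frame with `subject_id`, `severity`, `interference`, `REM`,
#'   `WASW`.
#' @export
score_bpisf_table <- function(df) {
  rows <- lapply(seq_len(nrow(df)), function(i) {
    pr <- score_bpisf(df[i, , drop = FALSE])
    data.frame(subject_id = df$subject_id[i], severity = pr$severity,
               interference = pr$interference, REM = pr$REM, WASW = pr$WASW,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-sample group comparison (pooled-variance t test)
#'
#' Unpaired two-tailed t test with pooled variance, Cohen's d on the pooled
#' SD, and the 95% CI of the group difference.
#'
#' @param values Numeric per-subject measure.
#' @param groups Group labels (exactly 2 levels, >= 2 subjects each).
#' @return List with `t`, `df`, `p`, `d`, `ci` (length 2), `means` (per
#'   group), `n` (per group).
#' @export
compare_groups <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("need exactly 2 groups")
  ns <- table(groups)
  if (any(ns < 2)) stop("each group needs at least 2 subjects")
  a <- values[groups == levels(groups)[1]]
  b <- values[groups == levels(groups)[2]]
  tt <- stats::t.test(a, b, var.equal = TRUE)
  sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  d <- if (sp > 0) (mean(a) - mean(b)) / sp else 0
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = d, ci = as.numeric(tt$conf.int),
       means = stats::setNames(c(mean(a), mean(b)), levels(groups)),
       n = stats::setNames(as.integer(ns), levels(groups)))
}

#' Pearson correlation with Fisher-transform confidence interval
#'
#' @param x,y Numeric per-subject measures (n >= 4, finite, non-constant).
#' @return List of class `igt_cor`: `r`, `ci` (95%, Fisher z), `p` (two-sided),
#'   `n`, `df`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in input: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
  structure(list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
                 p = ct$p.value, n = length(x),
                 df = unname(ct$parameter)), class = "igt_cor")
}

#' @export
print.igt_cor <- function(x, ...) {
  cat(sprintf("r(%d) = %.3f, 95%% CI [%.3f, %.3f], p = %.4g\n",
              x$df, x$r, x$ci[1], x$ci[2], x$p))
  invisible(x)
}

#' Parameter-pain correlation report
#'
#' Correlates each individual-level posterior-mean parameter with each pain
#' measure (severity, interference, REM, WASW) over the pooled sample (both
#' groups together). No multiplicity adjustment by default, matching the
#' single-test convention; set `adjust = "BH"` for Benjamini-Hochberg.
#'
#' @param fits List of `igt_fit` objects (one per group, same model); their
#'   individual posterior means are pooled.
#' @param profiles Data frame from [score_bpisf_table()] (plus `subject_id`).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame with one row per parameter x pain measure: `param`,
#'   `measure`, `r`, `ci_lower`, `ci_upper`, `p`, `n` (and `p_adj` if
#'   adjusted). Attribute `"adjust"` records the setting; a `log_bf10` column
#'   is reserved (NA).
#' @export
parameter_pain_report <- function(fits, profiles, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (inherits(fits, "igt_fit")) fits <- list(fits)
  models <- unique(vapply(fits, `[[`, character(1), "model"))
  if (length(models) != 1) stop("fits must share one model")
  im <- do.call(rbind, lapply(fits, individual_means))
  missing_ids <- setdiff(im$subject_id, profiles$subject_id)
  if (length(missing_ids)) {
    stop("no pain profile for subject(s): ", paste(missing_ids, collapse = ", "))
  }
  prof <- profiles[match(im$subject_id, profiles$subject_id), ]
  params <- setdiff(names(im), "subject_id")
  measures <- c("severity", "interference", "REM", "WASW")
  measures <- intersect(measures, names(prof))
  rows <- list()
  for (p in params) {
    for (m in measures) {
      cr <- correlate(im[[p]], prof[[m]])
      rows[[length(rows) + 1]] <- data.frame(
        param = p, measure = m, r = cr$r, ci_lower = cr$ci[1],
        ci_upper = cr$ci[2], p = cr$p, n = cr$n, log_bf10 = NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  if (adjust == "BH") tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
  attr(tab, "adjust") <- adjust
  tab
}
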