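#' Remove trials with few fixations
#'
#' Keeps only trials with strictly more than `min_fixations` fixations
#' (the `> 0` / `> 3` / `> 5` trial-inclusion rule); trials at or below
#' the threshold are removed entirely.
#'
#' @param ts a [trialset()].
#' @param min_fixations non-negative integer; `0`, `3`, and `5` are the
#'   standard levels.
#' @return the filtered trial set.
#' @export
filter_trials <- function(ts, min_fixations) {
  stopifnot(min_fixations >= 0)
  fx <- ts$fixations
  if (!nrow(fx)) return(ts)
  keep_ids <- fx[, .N, by = trial_id][N > min_fixations, trial_id]
  out <- fx[trial_id %in% keep_ids]
  trialset(out, ts$items, ts$geometry, ia = ts$ia, validate = FALSE)
}

#' Extract single fixation durations
#'
#' For each trial, the first pass over the target word is the maximal run
#' of consecutive fixations inside the target interest area starting at
#' the first entry into it.  An observation is emitted iff that run has
#' length exactly one; its `sfd_ms` is that fixation's duration.  Skipped
#' targets and first-pass refixations yield no observation; later
#' rereading does not retroactively disqualify one.
#'
#' @param ts a [trialset()] whose item table carries `target_ia_index`.
#' @return a `data.table` of observations: `subject_id`, `item_id`,
#'   `condition`, `sfd_ms` (at most one row per trial).
#' @export
extract_sfd <- function(ts) {
  items <- as.data.table(ts$items)
  if (!"target_ia_index" %in% names(items))
    stop("item table has no target_ia_index; cannot locate target words")
  fx <- ts$fixations
  if (!nrow(fx))
    return(data.table(subject_id = integer(), item_id = integer(),
                      condition = character(), sfd_ms = numeric()))
  fx <- fx[order(subject_id, trial_id, fix_index)]
  tgt <- items$target_ia_index[match(fx$item_id, items$item_id)]
  if (anyNA(tgt)) stop("item(s) without target_ia_index")
  on_t <- !is.na(fx$ia_index) & fx$ia_index == tgt
  n <- nrow(fx)
  new_trial <- c(TRUE, fx$trial_id[-1] != fx$trial_id[-n])
  ## runs of consecutive on-target/off-target states within a trial
  state_change <- c(TRUE, on_t[-1] != on_t[-n]) | new_trial
  rid <- cumsum(state_change)
  d <- data.table(trial_id = fx$trial_id, subject_id = fx$subject_id,
                  item_id = fx$item_id, condition = fx$condition,
                  duration_ms = fx$duration_ms, on_target = on_t, rid = rid)
  runs <- d[, .(trial_id = trial_id[1], subject_id = subject_id[1],
                item_id = item_id[1], condition = condition[1],
                on_target = on_target[1], len = .N,
                dur1 = duration_ms[1]), by = rid]
  first_entry <- runs[on_target == TRUE, .SD[1], by = trial_id]
  obs <- first_entry[len == 1L,
                     .(subject_id, item_id, condition, sfd_ms = dur1)]
  obs[]
}

#' Outlier-trimming rule
#'
#' @param scope reference mean for the SD cutoff: `"none"` (no trimming),
#'   `"grand"` (all observations), `"subject"` (the subject's
#'   observations), or `"subject_condition"` (the subject-by-condition
#'   cell).
#' @param k_sd cutoff in standard deviations (2.5 and 3 are the standard
#'   levels); ignored when `scope = "none"`.
#' @return an object of class `outlier_rule`.
#' @export
outlier_rule <- function(scope = c("none", "grand", "subject", "subject_condition"),
                         k_sd = 2.5) {
  scope <- match.arg(scope)
  stopifnot(k_sd > 0)
  structure(list(scope = scope, k_sd = if (scope == "none") NA_real_ else k_sd),
            class = "outlier_rule")
}

#' Remove outlying observations
#'
#' One-shot (non-iterative) trimming: an observation is removed iff
#' `|sfd - m| > k_sd * s`, where `m` and `s` are the mean and sample SD
#' (n - 1 denominator) of the reference cell implied by the rule's scope,
#' computed once on the untrimmed data.  Cells with fewer than two
#' observations or zero SD pass through untrimmed; `scope = "none"` is the
#' identity.
#'
#' @param obs observation table from [extract_sfd()].
#' @param rule an [outlier_rule()].
#' @return the trimmed observation table.
#' @export
remove_outliers <- function(obs, rule) {
  stopifnot(inherits(rule, "outlier_rule"))
  if (rule$scope == "none" || !nrow(obs)) return(obs)
  obs <- as.data.table(obs)
  by_cols <- switch(rule$scope,
                    grand = character(0),
                    subject = "subject_id",
                    subject_condition = c("subject_id", "condition"))
  k <- rule$k_sd
  cell_keep <- function(x) {
    if (length(x) < 2L) return(rep(TRUE, length(x)))
    s <- sd(x)
    if (s == 0) return(rep(TRUE, length(x)))
    abs(x - mean(x)) <= k * s
  }
  if (!length(by_cols)) {
    obs[cell_keep(sfd_ms)]
  } else {
    obs[, keep := cell_keep(sfd_ms), by = by_cols][keep == TRUE][, keep := NULL][]
  }
}
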