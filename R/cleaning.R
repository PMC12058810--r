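#' Cleaning-function configuration
#'
#' One parameterization of the four-stage fixation cleaning function plus
#' the optional deletion of fixations outside all interest areas:
#' \describe{
#'   \item{stage 1}{merge fixations shorter than `max_dur_ms` (default 80)
#'     into a strictly longer temporally adjacent fixation within
#'     `max_dist_deg` (default 0.5 degrees).}
#'   \item{stage 2}{same engine, defaults 40 ms / 1.25 degrees.}
#'   \item{stage 3}{merge every maximal run of three or more consecutive
#'     fixations, each shorter than `max_dur_ms` (default 140) and all in
#'     the same interest area, into one fixation.}
#'   \item{stage 4}{remove fixations shorter than `min_dur_ms` (default
#'     140) or longer than `max_dur_ms` (default 800); boundary values are
#'     kept (strict inequalities).}
#'   \item{outside-IA deletion}{remove fixations not inside any interest
#'     area; off by default.}
#' }
#'
#' @param config_id label for the configuration.
#' @param stage1,stage2,stage3,stage4 lists overriding the stage defaults
#'   (`enabled`, `max_dur_ms`, `max_dist_deg`, `min_dur_ms` as relevant).
#' @param delete_outside_ia flag, default off.
#' @return an object of class `cleaning_config`.
#' @export
cleaning_config <- function(config_id,
                            stage1 = list(), stage2 = list(),
                            stage3 = list(), stage4 = list(),
                            delete_outside_ia = FALSE) {
  s1 <- utils::modifyList(list(enabled = TRUE, max_dur_ms = 80, max_dist_deg = 0.5), stage1)
  s2 <- utils::modifyList(list(enabled = TRUE, max_dur_ms = 40, max_dist_deg = 1.25), stage2)
  s3 <- utils::modifyList(list(enabled = TRUE, max_dur_ms = 140), stage3)
  s4 <- utils::modifyList(list(enabled = TRUE, min_dur_ms = 140, max_dur_ms = 800), stage4)
  stopifnot(s1$max_dur_ms > 0, s2$max_dur_ms > 0, s3$max_dur_ms > 0,
            s1$max_dist_deg > 0, s2$max_dist_deg > 0,
            s4$min_dur_ms > 0, s4$min_dur_ms < s4$max_dur_ms)
  structure(list(config_id = config_id, stage1 = s1, stage2 = s2,
                 stage3 = s3, stage4 = s4,
                 delete_outside_ia = isTRUE(delete_outside_ia)),
            class = "cleaning_config")
}

#' The 14-configuration cleaning catalog
#'
#' A catalog of 14 cleaning-function settings spanning the standard
#' configuration, each stage disabled in turn, no cleaning at all,
#' threshold variants of each stage, and the outside-interest-area
#' deletion.  The published table of settings is not reproduced verbatim
#' (only the standard values and a few variant names are documented in
#' prose), so this catalog is a reconstruction covering the same kind of
#' reasonable variation.
#'
#' @return a named list of 14 [cleaning_config()] objects.
#' @export
cleaning_catalog <- function() {
  off <- list(enabled = FALSE)
  cfgs <- list(
    cleaning_config("standard"),
    cleaning_config("no_cleaning", stage1 = off, stage2 = off,
                    stage3 = off, stage4 = off),
    cleaning_config("stage1_off", stage1 = off),
    cleaning_config("stage2_off", stage2 = off),
    cleaning_config("stage3_off", stage3 = off),
    cleaning_config("stage4_off", stage4 = off),
    cleaning_config("stage1_max40", stage1 = list(max_dur_ms = 40)),
    cleaning_config("stage1_max100", stage1 = list(max_dur_ms = 100)),
    cleaning_config("stage2_dist0.5", stage2 = list(max_dist_deg = 0.5)),
    cleaning_config("stage3_max100", stage3 = list(max_dur_ms = 100)),
    cleaning_config("stage4_min80_max800", stage4 = list(min_dur_ms = 80)),
    cleaning_config("stage4_min100_max600",
                    stage4 = list(min_dur_ms = 100, max_dur_ms = 600)),
    cleaning_config("stage4_min140_max1000", stage4 = list(max_dur_ms = 1000)),
    cleaning_config("delete_outside_ia", delete_outside_ia = TRUE)
  )
  setNames(cfgs, vapply(cfgs, `[[`, "", "config_id"))
}

## ---------------------------------------------------------------------------
## per-trial cores (operate on parallel vectors, return list + tally)

## Stages 1-2.  Deterministic fixed point: repeatedly take the earliest
## fixation shorter than the threshold that has a strictly longer
## temporally adjacent neighbor within max_dist_px, absorb it into that
## neighbor (nearer neighbor wins; if equidistant the longer; if still
## tied the preceding one), and restart the scan.  The host keeps its
## position and interest area and gains the absorbed duration.
merge_pass_core <- function(x, y, dur, ia, max_dur, max_dist_px) {
  merges <- 0L
  repeat {
    n <- length(dur)
    if (n < 2L) break
    done <- TRUE
    for (i in which(dur < max_dur)) {
      best <- 0L; best_d <- Inf
      for (j in c(i - 1L, i + 1L)) {
        if (j < 1L || j > n) next
        if (dur[j] <= dur[i]) next
        d <- sqrt((x[j] - x[i])^2 + (y[j] - y[i])^2)
        if (d > max_dist_px) next
        pick <- if (best == 0L) TRUE
        else if (d != best_d) d < best_d
        else if (dur[j] != dur[best]) dur[j] > dur[best]
        else j < best
        if (pick) { best <- j; best_d <- d }
      }
      if (best > 0L) {
        dur[best] <- dur[best] + dur[i]
        x <- x[-i]; y <- y[-i]; dur <- dur[-i]; ia <- ia[-i]
        merges <- merges + 1L
        done <- FALSE
        break
      }
    }
    if (done) break
  }
  list(x = x, y = y, dur = dur, ia = ia, merges = merges)
}

## Stage 3.  Replace every maximal run of >= 3 consecutive fixations, each
## shorter than max_dur and all sharing one non-missing interest area, by
## a single fixation with summed duration and duration-weighted position,
## placed at the run's first slot.
merge_ia_runs_core <- function(x, y, dur, ia, max_dur) {
  n <- length(dur)
  if (n < 3L) return(list(x = x, y = y, dur = dur, ia = ia, merges = 0L))
  short <- dur < max_dur & !is.na(ia)
  ## run id increments whenever eligibility breaks or the ia changes
  brk <- c(TRUE, !short[-1] | !short[-n] | ia[-1] != ia[-n])
  brk[is.na(brk)] <- TRUE
  rid <- cumsum(brk)
  keep_x <- x; keep_y <- y; keep_dur <- dur; keep_ia <- ia
  drop <- logical(n)
  merges <- 0L
  for (r in unique(rid[short])) {
    idx <- which(rid == r & short)
    if (length(idx) < 3L) next
    first <- idx[1]
    w <- dur[idx]
    keep_x[first] <- sum(x[idx] * w) / sum(w)
    keep_y[first] <- sum(y[idx] * w) / sum(w)
    keep_dur[first] <- sum(w)
    keep_ia[first] <- ia[first]
    drop[idx[-1]] <- TRUE
    merges <- merges + length(idx) - 1L
  }
  list(x = keep_x[!drop], y = keep_y[!drop], dur = keep_dur[!drop],
       ia = keep_ia[!drop], merges = merges)
}

## ---------------------------------------------------------------------------
## public per-trial operations (data.table in, data.table out)

trial_to_vec <- function(trial) {
  list(x = trial$x_px, y = trial$y_px, dur = trial$duration_ms,
       ia = trial$ia_index)
}

vec_to_trial <- function(trial, v) {
  n <- length(v$dur)
  data.table(subject_id = rep(trial$subject_id[1], n),
             trial_id = rep(trial$trial_id[1], n),
             item_id = rep(trial$item_id[1], n),
             condition = rep(trial$condition[1], n),
             fix_index = seq_len(n),
             x_px = v$x, y_px = v$y, duration_ms = v$dur,
             ia_index = v$ia)
}

#' Merge short fixations into adjacent longer neighbors (stages 1 and 2)
#'
#' The shared engine behind cleaning stages 1 and 2; see
#' [cleaning_config()] for the rule and `merge_pass_core` tie-breaking:
#' nearer neighbor first, then longer, then preceding.  Short fixations
#' with no eligible neighbor are left in place (their removal is stage 4's
#' job).
#'
#' @param trial one trial's fixation records, ordered by `fix_index`.
#' @param max_dur_ms merge threshold: only fixations strictly shorter are
#'   candidates.
#' @param max_dist_deg maximum Euclidean distance to the host, in degrees.
#' @param geometry list with `pixels_per_degree`.
#' @return the merged trial, indices renumbered.
#' @export
merge_pass <- function(trial, max_dur_ms, max_dist_deg, geometry) {
  if (!nrow(trial)) return(trial)
  v <- trial_to_vec(trial)
  r <- merge_pass_core(v$x, v$y, v$dur, v$ia, max_dur_ms,
                       max_dist_deg * geometry$pixels_per_degree)
  vec_to_trial(trial, r)
}

#' Merge runs of short same-word fixations (stage 3)
#'
#' Replaces every maximal run of three or more consecutive fixations, each
#' shorter than `max_dur_ms` and all within the same interest area, by a
#' single fixation with summed duration and duration-weighted mean
#' position at the run's first slot.
#'
#' @inheritParams merge_pass
#' @return the merged trial, indices renumbered.
#' @export
merge_ia_runs <- function(trial, max_dur_ms) {
  if (!nrow(trial)) return(trial)
  v <- trial_to_vec(trial)
  r <- merge_ia_runs_core(v$x, v$y, v$dur, v$ia, max_dur_ms)
  vec_to_trial(trial, r)
}

#' Remove implausibly short and long fixations (stage 4)
#'
#' Fixations strictly shorter than `min_dur_ms` or strictly longer than
#' `max_dur_ms` are removed; boundary values are retained.
#'
#' @inheritParams merge_pass
#' @param min_dur_ms,max_dur_ms retention bounds in ms.
#' @return the filtered trial, indices renumbered.
#' @export
temporal_filter <- function(trial, min_dur_ms, max_dur_ms) {
  if (!nrow(trial)) return(trial)
  keep <- trial$duration_ms >= min_dur_ms & trial$duration_ms <= max_dur_ms
  out <- trial[keep]
  out[, fix_index := seq_len(.N)]
  out
}

#' Delete fixations outside all interest areas
#'
#' @inheritParams merge_pass
#' @return the filtered trial, indices renumbered.
#' @export
delete_outside_ia <- function(trial) {
  if (!nrow(trial)) return(trial)
  out <- trial[!is.na(ia_index)]
  out[, fix_index := seq_len(.N)]
  out
}

## ---------------------------------------------------------------------------
## dataset-level driver

## apply a per-trial core to the flagged trials of a fixation table
apply_core_by_trial <- function(fx, flagged, core, ...) {
  if (!length(flagged)) return(list(fx = fx, removed = 0L))
  sub <- fx[trial_id %in% flagged]
  rest <- fx[!trial_id %in% flagged]
  before <- nrow(sub)
  res <- sub[, {
    r <- core(x_px, y_px, duration_ms, ia_index, ...)
    list(subject_id = rep(subject_id[1], length(r$dur)),
         item_id = rep(item_id[1], length(r$dur)),
         condition = rep(condition[1], length(r$dur)),
         fix_index = seq_along(r$dur),
         x_px = r$x, y_px = r$y, duration_ms = r$dur, ia_index = r$ia)
  }, by = trial_id]
  setcolorder(res, names(fx))
  out <- rbind(rest, res)
  setorder(out, subject_id, trial_id, fix_index)
  list(fx = out, removed = before - nrow(res))
}

#' Apply a cleaning configuration to a trial set
#'
#' Runs the enabled stages in fixed order (1, 2, 3, 4, then the optional
#' outside-interest-area deletion) over every trial and tallies per-stage
#' merge/removal counts.  With every stage disabled the output equals the
#' input (the "No Cleaning" dataset).  Stages 1--3 conserve total fixation
#' duration per trial; only stage 4 and the outside-IA deletion discard
#' duration mass.
#'
#' @param ts a [trialset()] with `ia_index` assigned.
#' @param config a [cleaning_config()].
#' @return a list with elements `trialset` (cleaned) and `stats` (class
#'   `cleaning_stats`).
#' @export
apply_cleaning <- function(ts, config) {
  stopifnot(inherits(ts, "trialset"), inherits(config, "cleaning_config"))
  fx <- copy(ts$fixations)
  ppd <- ts$geometry$pixels_per_degree
  n_before <- nrow(fx)
  stats <- list(stage1_merged = 0L, stage2_merged = 0L, stage3_merged = 0L,
                stage4_removed = 0L, outside_removed = 0L)

  for (sname in c("stage1", "stage2")) {
    st <- config[[sname]]
    if (!st$enabled || !nrow(fx)) next
    flagged <- fx[duration_ms < st$max_dur_ms, unique(trial_id)]
    r <- apply_core_by_trial(fx, flagged, merge_pass_core,
                             st$max_dur_ms, st$max_dist_deg * ppd)
    fx <- r$fx
    stats[[paste0(sname, "_merged")]] <- r$removed
  }

  if (config$stage3$enabled && nrow(fx)) {
    thr <- config$stage3$max_dur_ms
    sh <- fx$duration_ms < thr & !is.na(fx$ia_index)
    same_trial1 <- c(fx$trial_id[-1] == fx$trial_id[-nrow(fx)], FALSE)
    same_trial2 <- c(fx$trial_id[-(1:2)] == fx$trial_id[seq_len(nrow(fx) - 2)], FALSE, FALSE)
    same_ia1 <- c(fx$ia_index[-1] == fx$ia_index[-nrow(fx)], FALSE)
    same_ia2 <- c(fx$ia_index[-(1:2)] == fx$ia_index[seq_len(nrow(fx) - 2)], FALSE, FALSE)
    triple <- sh & c(sh[-1], FALSE) & c(sh[-(1:2)], FALSE, FALSE) &
      same_trial1 & same_trial2 &
      !is.na(same_ia1) & same_ia1 & !is.na(same_ia2) & same_ia2
    flagged <- unique(fx$trial_id[which(triple)])
    r <- apply_core_by_trial(fx, flagged, merge_ia_runs_core, thr)
    fx <- r$fx
    stats$stage3_merged <- r$removed
  }

  if (config$stage4$enabled && nrow(fx)) {
    keep <- fx$duration_ms >= config$stage4$min_dur_ms &
      fx$duration_ms <= config$stage4$max_dur_ms
    stats$stage4_removed <- sum(!keep)
    fx <- fx[keep]
    fx[, fix_index := seq_len(.N), by = trial_id]
  }

  if (config$delete_outside_ia && nrow(fx)) {
    keep <- !is.na(fx$ia_index)
    stats$outside_removed <- sum(!keep)
    fx <- fx[keep]
    fx[, fix_index := seq_len(.N), by = trial_id]
  }

  stats$n_fixations_before <- n_before
  stats$n_fixations_after <- nrow(fx)
  stats$config_id <- config$config_id
  out_ts <- trialset(fx, ts$items, ts$geometry, ia = ts$ia, validate = FALSE)
  list(trialset = out_ts, stats = structure(stats, class = "cleaning_stats"))
}

#' @export
print.cleaning_stats <- function(x, ...) {
  cat(sprintf(paste0("<cleaning_stats> %s: %d -> %d fixations ",
                     "(s1 %d, s2 %d, s3 %d merged; s4 %d, outside %d removed)\n"),
              x$config_id, x$n_fixations_before, x$n_fixations_after,
              x$stage1_merged, x$stage2_merged, x$stage3_merged,
              x$stage4_removed, x$outside_removed))
  invisible(x)
}

#' Compare two cleaned trial sets for identity
#'
#' True iff both trial sets contain the same trials and every trial has
#' the same fixation sequence (position, duration, interest area).
#'
#' @param a,b [trialset()] objects over the same subjects/items.
#' @return logical flag.
#' @export
datasets_identical <- function(a, b) {
  fa <- a$fixations[order(subject_id, trial_id, fix_index)]
  fb <- b$fixations[order(subject_id, trial_id, fix_index)]
  if (nrow(fa) != nrow(fb)) return(FALSE)
  if (!nrow(fa)) return(TRUE)
  all(fa$trial_id == fb$trial_id) &&
    all(fa$x_px == fb$x_px) && all(fa$y_px == fb$y_px) &&
    all(fa$duration_ms == fb$duration_ms) &&
    all(fa$ia_index == fb$ia_index | (is.na(fa$ia_index) & is.na(fb$ia_index)),
        na.rm = FALSE) %in% TRUE
}
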