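## Independent brute-force reference implementations used as oracles.
## These deliberately share no code with the package: they re-state the
## cleaning rules in the most naive way possible.

suppressPackageStartupMessages(library(data.table))

## build a one-trial data.table from parallel vectors
make_trial <- function(dur, x, y = rep(300, length(dur)),
                       ia = rep(NA_integer_, length(dur)),
                       subject = 1L, item = 1L, condition = "high") {
  data.table(subject_id = subject, trial_id = subject * 100000L + item,
             item_id = item, condition = condition,
             fix_index = seq_along(dur), x_px = x, y_px = y,
             duration_ms = dur, ia_index = as.integer(ia))
}

## random trial of up to max_n fixations with durations and interest areas
## spanning every cleaning threshold regime
random_trial <- function(max_n = 10L) {
  n <- sample.int(max_n, 1L)
  dur <- sample(c(runif(n, 21, 79), runif(n, 80, 139), runif(n, 140, 900),
                  runif(n, 900, 2000)), n)
  x <- cumsum(runif(n, -30, 60)) + 200
  y <- 300 + runif(n, -15, 15)
  ia <- sample(c(1:4, NA_integer_), n, replace = TRUE)
  make_trial(dur, x, y, ia)
}

## --- oracle for stages 1-2 -------------------------------------------------
## literal restatement: while some fixation shorter than the threshold has a
## strictly longer adjacent neighbor within reach, take the earliest such
## fixation, resolve the neighbor by (nearer, then longer, then preceding),
## absorb, renumber, and start over from scratch.
oracle_merge_pass <- function(trial, max_dur_ms, max_dist_deg, ppd) {
  tr <- copy(trial)
  max_px <- max_dist_deg * ppd
  repeat {
    n <- nrow(tr)
    cand <- NULL
    for (i in seq_len(n)) {
      if (tr$duration_ms[i] >= max_dur_ms) next
      opts <- data.table(j = integer(), d = numeric(), dur = numeric())
      for (j in c(i - 1L, i + 1L)) {
        if (j >= 1L && j <= n && tr$duration_ms[j] > tr$duration_ms[i]) {
          d <- sqrt((tr$x_px[j] - tr$x_px[i])^2 + (tr$y_px[j] - tr$y_px[i])^2)
          if (d <= max_px) opts <- rbind(opts, data.table(j = j, d = d,
                                                          dur = tr$duration_ms[j]))
        }
      }
      if (nrow(opts)) {
        setorder(opts, d, -dur, j)
        cand <- list(i = i, j = opts$j[1])
        break
      }
    }
    if (is.null(cand)) break
    tr$duration_ms[cand$j] <- tr$duration_ms[cand$j] + tr$duration_ms[cand$i]
    tr <- tr[-cand$i]
    tr$fix_index <- seq_len(nrow(tr))
  }
  tr
}

## --- oracle for stage 3 ----------------------------------------------------
## literal scan for maximal runs of >= 3 consecutive short same-area
## fixations; each run collapses to one fixation with summed duration and
## duration-weighted centroid at the run's first slot.
oracle_merge_ia_runs <- function(trial, max_dur_ms) {
  n <- nrow(trial)
  eligible <- trial$duration_ms < max_dur_ms & !is.na(trial$ia_index)
  runs <- list(); start <- NA_integer_
  for (i in seq_len(n + 1L)) {
    extends <- i <= n && eligible[i] &&
      (!is.na(start) && trial$ia_index[i] == trial$ia_index[start])
    if (is.na(start) && i <= n && eligible[i]) { start <- i; next }
    if (extends) next
    if (!is.na(start) && (i - start) >= 3L)
      runs[[length(runs) + 1L]] <- start:(i - 1L)
    start <- if (i <= n && eligible[i]) i else NA_integer_
  }
  tr <- copy(trial)
  drop <- integer(0)
  for (r in runs) {
    w <- trial$duration_ms[r]
    tr$duration_ms[r[1]] <- sum(w)
    tr$x_px[r[1]] <- sum(trial$x_px[r] * w) / sum(w)
    tr$y_px[r[1]] <- sum(trial$y_px[r] * w) / sum(w)
    drop <- c(drop, r[-1])
  }
  if (length(drop)) tr <- tr[-drop]
  tr$fix_index <- seq_len(nrow(tr))
  tr
}

## --- oracle for stage 4 ----------------------------------------------------
oracle_temporal_filter <- function(trial, min_dur_ms, max_dur_ms) {
  keep <- logical(nrow(trial))
  for (i in seq_len(nrow(trial)))
    keep[i] <- !(trial$duration_ms[i] < min_dur_ms ||
                   trial$duration_ms[i] > max_dur_ms)
  tr <- trial[keep]
  tr$fix_index <- seq_len(nrow(tr))
  tr
}

## --- brute-force point-in-box interest-area lookup -------------------------
oracle_assign_ia <- function(x, y, boxes) {
  out <- rep(NA_integer_, length(x))
  for (i in seq_along(x)) {
    for (b in seq_len(nrow(boxes))) {
      if (x[i] >= boxes$x_min_px[b] && x[i] < boxes$x_max_px[b] &&
          y[i] >= boxes$y_min_px[b] && y[i] < boxes$y_max_px[b]) {
        out[i] <- boxes$ia_index[b]
        break
      }
    }
  }
  out
}

## trial equality on the fields the cleaning contracts speak about
expect_same_trial <- function(a, b) {
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$duration_ms, b$duration_ms, tolerance = 1e-12)
  expect_equal(a$x_px, b$x_px, tolerance = 1e-12)
  expect_equal(a$y_px, b$y_px, tolerance = 1e-12)
  expect_equal(a$ia_index, b$ia_index)
}

## small, fast synthetic dataset for integration-style tests
small_dataset <- function(seed = 1L, n_subjects = 8L, n_items = 12L, ...) {
  generate_dataset(synthetic_config(n_subjects = n_subjects,
                                    n_items = n_items, seed = seed, ...))
}
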