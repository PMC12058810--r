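#' Configuration for the synthetic reading-data generator
#'
#' Bundles every tunable of the generator: design size, the ex-Gaussian
#' baseline duration distribution, the frequency effect (split between the
#' Gaussian mean and the exponential tail), crossed random-intercept SDs,
#' stimulus calibration statistics, artifact rates, and display geometry.
#'
#' Durations are simulated as
#' `exGauss(mu + b_subject + b_item + effect_mu * low_target, sigma,
#'          tau + effect_tau * low_target)`
#' floored at `min_duration_floor_ms`, where `low_target` indicates a
#' fixation on the target word of a low-frequency item.  The effect loads
#' on both the mean and the tail because word frequency is known to shift
#' both the location and the skew of fixation-duration distributions; the
#' population mean effect is `effect_mu_ms + effect_tau_ms`.
#'
#' @param n_subjects,n_items design size; `n_items` must be even (the
#'   high/low frequency conditions are counterbalanced half/half).
#' @param exgauss_mu_ms,exgauss_sigma_ms,exgauss_tau_ms baseline
#'   ex-Gaussian parameters in ms.
#' @param effect_mu_ms,effect_tau_ms frequency effect added to the
#'   low-frequency targets' `mu` and `tau` (ms).
#' @param sd_subject_ms,sd_item_ms SDs of the subject and item random
#'   intercepts (ms).
#' @param p_skip_base word-skipping probability for a 4-letter word;
#'   skipping decreases exponentially with word length.
#' @param artifact_short_rate per-trial probability of inserting one very
#'   short (20--79 ms) fixation next to a host fixation.
#' @param artifact_long_rate per-trial probability of inflating one
#'   fixation to 801--2000 ms.
#' @param sparse_trial_rate per-trial probability of truncating the trial
#'   to 1--3 fixations (simulating an aborted recording).
#' @param min_duration_floor_ms physical floor for generated durations.
#' @param pixels_per_degree,char_width_px display geometry; all cleaning
#'   distances are configured in degrees and converted via
#'   `pixels_per_degree`.
#' @param zipf_mean,zipf_sd named numeric vectors (`high`, `low`): target
#'   Zipf-frequency calibration per condition.
#' @param len_mean,len_sd,len_range target word length calibration
#'   (letters); lengths are integers within `len_range`.
#' @param seed integer master seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 100L,
                             n_items = 78L,
                             exgauss_mu_ms = 180,
                             exgauss_sigma_ms = 35,
                             exgauss_tau_ms = 60,
                             effect_mu_ms = 10,
                             effect_tau_ms = 5,
                             sd_subject_ms = 30,
                             sd_item_ms = 15,
                             p_skip_base = 0.25,
                             artifact_short_rate = 0.05,
                             artifact_long_rate = 0.02,
                             sparse_trial_rate = 0.003,
                             min_duration_floor_ms = 21,
                             pixels_per_degree = 40,
                             char_width_px = 12,
                             zipf_mean = c(high = 5.28, low = 3.22),
                             zipf_sd = c(high = 0.36, low = 0.43),
                             len_mean = 5.4,
                             len_sd = 0.87,
                             len_range = c(4L, 9L),
                             seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_items = as.integer(n_items),
    exgauss_mu_ms = exgauss_mu_ms, exgauss_sigma_ms = exgauss_sigma_ms,
    exgauss_tau_ms = exgauss_tau_ms,
    effect_mu_ms = effect_mu_ms, effect_tau_ms = effect_tau_ms,
    sd_subject_ms = sd_subject_ms, sd_item_ms = sd_item_ms,
    p_skip_base = p_skip_base,
    artifact_short_rate = artifact_short_rate,
    artifact_long_rate = artifact_long_rate,
    sparse_trial_rate = sparse_trial_rate,
    min_duration_floor_ms = min_duration_floor_ms,
    pixels_per_degree = pixels_per_degree,
    char_width_px = char_width_px,
    zipf_mean = zipf_mean, zipf_sd = zipf_sd,
    len_mean = len_mean, len_sd = len_sd,
    len_range = as.integer(len_range),
    seed = as.integer(seed),
    ## reading-model constants (invented generative model, fixed)
    p_refix = 0.15, p_regress = 0.08,
    n_words_range = c(8L, 12L), other_len_range = c(2L, 10L),
    x_start_px = 50, line_y_px = 300, line_band_px = c(280, 320)
  )
  stopifnot(
    cfg$n_subjects >= 1, cfg$n_items >= 2,
    cfg$exgauss_sigma_ms > 0, cfg$exgauss_tau_ms >= 0,
    cfg$sd_subject_ms >= 0, cfg$sd_item_ms >= 0,
    cfg$p_skip_base >= 0, cfg$p_skip_base <= 1,
    cfg$artifact_short_rate >= 0, cfg$artifact_short_rate <= 1,
    cfg$artifact_long_rate >= 0, cfg$artifact_long_rate <= 1,
    cfg$sparse_trial_rate >= 0, cfg$sparse_trial_rate <= 1,
    cfg$min_duration_floor_ms >= 0, cfg$pixels_per_degree > 0,
    cfg$char_width_px > 0,
    all(c("high", "low") %in% names(cfg$zipf_mean)),
    all(cfg$zipf_sd > 0), cfg$len_sd > 0,
    cfg$len_range[1] >= 1, cfg$len_range[2] >= cfg$len_range[1]
  )
  structure(cfg, class = "synthetic_config")
}

## ---------------------------------------------------------------------------
## Stimulus generation

## Adjust an integer vector (values in [lo, hi]) so that its sample mean and
## SD round to the configured targets.  Works on the integer lattice: first
## the sum is moved to a feasible value, then mean-preserving pair transfers
## steer the sum of squares into the window implied by the SD rounding.
repair_int_stats <- function(x, lo, hi, mean_target, sd_target,
                             mean_digits = 1, sd_digits = 2) {
  n <- length(x)
  stopifnot(n >= 2)
  half_m <- 0.5 * 10^(-mean_digits)
  half_s <- 0.5 * 10^(-sd_digits)

  ## candidate sums whose mean rounds to mean_target, nearest first
  s_lo <- ceiling(n * (mean_target - half_m))
  s_hi <- floor(n * (mean_target + half_m - 1e-12))
  sums <- seq(max(s_lo, n * lo), min(s_hi, n * hi))
  if (!length(sums)) stop("no feasible sum for the requested mean")
  sums <- sums[order(abs(sums - n * mean_target))]

  ## pick the first sum for which an S2 of matching parity exists in the
  ## window implied by round(sd, sd_digits) == sd_target
  pick <- NULL
  for (S in sums) {
    v_lo <- (sd_target - half_s)^2
    v_hi <- (sd_target + half_s)^2
    lo2 <- v_lo * (n - 1) + S^2 / n
    hi2 <- v_hi * (n - 1) + S^2 / n
    cand <- seq(ceiling(lo2), floor(hi2 - 1e-9))
    cand <- cand[cand %% 2 == S %% 2]  # S2 parity is pinned to S parity
    if (length(cand)) { pick <- list(S = S, S2 = cand[1]); break }
  }
  if (is.null(pick)) stop("no feasible integer solution for the requested mean/SD")

  ## step 1: move the sum (unit steps on extreme eligible elements)
  guard <- 0L
  while (sum(x) != pick$S) {
    if (sum(x) < pick$S) {
      i <- which(x < hi); i <- i[which.min(x[i])]; x[i] <- x[i] + 1L
    } else {
      i <- which(x > lo); i <- i[which.max(x[i])]; x[i] <- x[i] - 1L
    }
    guard <- guard + 1L
    if (guard > 100L * n) stop("sum repair did not converge")
  }

  ## step 2: mean-preserving transfers; moving mass outward raises S2 by
  ## 2(x_i - x_j) + 2, moving inward lowers it by 2(x_i - x_j) - 2
  s2 <- sum(as.double(x)^2)
  guard <- 0L
  while (s2 != pick$S2) {
    need <- pick$S2 - s2
    if (need > 0) {
      i <- which(x < hi); j <- which(x > lo)
      ## largest step not overshooting, else the smallest available
      best <- NULL
      oi <- i[order(-x[i])]; oj <- j[order(x[j])]
      for (a in oi) { for (b in oj) {
        if (a == b) next
        d <- 2L * (x[a] - x[b]) + 2L
        if (d <= 0) next
        if (d <= need) { best <- c(a, b); break }
        if (is.null(best)) best <- c(a, b)  # smallest overshoot fallback
      }; if (!is.null(best) && (2L * (x[best[1]] - x[best[2]]) + 2L) <= need) break }
      if (is.null(best)) stop("S2 repair infeasible (increase)")
      x[best[1]] <- x[best[1]] + 1L; x[best[2]] <- x[best[2]] - 1L
    } else {
      i <- which(x > lo); j <- which(x < hi)
      best <- NULL
      oi <- i[order(-x[i])]; oj <- j[order(x[j])]
      for (a in oi) { for (b in oj) {
        if (a == b) next
        d <- -(2L * (x[a] - x[b]) - 2L)   # change in S2 (negative when x_a - x_b >= 2)
        if (d >= 0) next
        if (d >= need) { best <- c(a, b); break }
        if (is.null(best)) best <- c(a, b)
      }; if (!is.null(best) && -(2L * (x[best[1]] - x[best[2]]) - 2L) >= need) break }
      if (is.null(best)) stop("S2 repair infeasible (decrease)")
      x[best[1]] <- x[best[1]] - 1L; x[best[2]] <- x[best[2]] + 1L
    }
    s2 <- sum(as.double(x)^2)
    guard <- guard + 1L
    if (guard > 200L * n) stop("S2 repair did not converge")
  }
  x
}

#' Generate a calibrated stimulus set
#'
#' Creates `n_items` single-line sentences, half with a high-frequency and
#' half with a low-frequency target word.  Target word lengths are integers
#' within `len_range` whose sample mean and SD round to the configured
#' values; Zipf frequencies are drawn normally per condition and affinely
#' recentered so each condition's sample mean and SD equal the configured
#' values exactly.
#'
#' @param config a [synthetic_config()].
#' @return a `data.table` with one row per item: `item_id`, `condition`,
#'   `n_words`, `target_ia_index`, `target_len`, `zipf_target`, and a
#'   `word_lengths` list column (letters per word).
#' @export
generate_stimuli <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_items %% 2L != 0L)
    stop("n_items must be even: conditions are counterbalanced half/half")
  with_subseed(config$seed, 1L, {
    n <- config$n_items
    condition <- sample(rep(c("high", "low"), each = n / 2L))
    n_words <- sample(seq(config$n_words_range[1], config$n_words_range[2]),
                      n, replace = TRUE)
    target_ia_index <- vapply(n_words, function(w) sample(3:(w - 2L), 1L), 1L)

    lo <- config$len_range[1]; hi <- config$len_range[2]
    raw <- pmin(hi, pmax(lo, as.integer(round(rnorm(n, config$len_mean, config$len_sd)))))
    target_len <- repair_int_stats(raw, lo, hi, config$len_mean, config$len_sd)

    zipf <- numeric(n)
    for (cond in c("high", "low")) {
      idx <- which(condition == cond)
      z <- rnorm(length(idx))
      zipf[idx] <- config$zipf_mean[[cond]] +
        (z - mean(z)) / sd(z) * config$zipf_sd[[cond]]
    }

    word_lengths <- vector("list", n)
    for (i in seq_len(n)) {
      wl <- sample(seq(config$other_len_range[1], config$other_len_range[2]),
                   n_words[i], replace = TRUE)
      wl[target_ia_index[i]] <- target_len[i]
      word_lengths[[i]] <- as.integer(wl)
    }

    data.table(item_id = seq_len(n), condition = condition,
               n_words = n_words, target_ia_index = target_ia_index,
               target_len = target_len, zipf_target = zipf,
               word_lengths = word_lengths)
  })
}

#' Build the interest-area table for a stimulus set
#'
#' One rectangular box per word, laid out left to right on a single text
#' line; each box spans the word plus its trailing space.  Bounds are
#' half-open `[min, max)` pixels, origin top-left.
#'
#' @param items output of [generate_stimuli()].
#' @param config the [synthetic_config()] that produced `items`.
#' @return a `data.table`: `item_id`, `ia_index`, `x_min_px`, `x_max_px`,
#'   `y_min_px`, `y_max_px`.
#' @export
build_ia_table <- function(items, config) {
  cw <- config$char_width_px
  out <- lapply(seq_len(nrow(items)), function(i) {
    wl <- items$word_lengths[[i]]
    widths <- (wl + 1) * cw
    x0 <- config$x_start_px + c(0, cumsum(widths))[seq_along(wl)]
    data.table(item_id = items$item_id[i], ia_index = seq_along(wl),
               x_min_px = x0, x_max_px = x0 + widths,
               y_min_px = config$line_band_px[1],
               y_max_px = config$line_band_px[2])
  })
  rbindlist(out)
}

## word-skipping probability, decreasing in word length
p_skip_len <- function(len, config) {
  pmin(0.95, pmax(0.01, config$p_skip_base * exp(-0.15 * (len - 4))))
}

## word-level layout of a set of items as parallel vectors (fast path)
word_layout <- function(items, config) {
  ia <- build_ia_table(items, config)
  ia[, `:=`(len = unlist(items$word_lengths),
            is_target = ia_index == rep(items$target_ia_index, lengths(items$word_lengths)),
            low = rep(items$condition == "low", lengths(items$word_lengths)))]
  list(item = ia$item_id, word = ia$ia_index, len = ia$len,
       x_min = ia$x_min_px, x_max = ia$x_max_px,
       is_target = ia$is_target,
       low_target = ia$is_target & ia$low,
       first_word_at = match(unique(ia$item_id), ia$item_id),
       item_ids = unique(ia$item_id))
}

## Simulate all trials of one subject over the given word layout, using the
## current RNG state.  Returns parallel vectors; `ord` orders fixations
## within a trial.  The reading model: left-to-right with length-dependent
## skipping, occasional immediate refixations, and occasional one-word
## regressions that briefly revisit the previous word.
gen_subject_block <- function(lay, subj_int, item_ints, config) {
  nW <- length(lay$item)
  p_skip <- p_skip_len(lay$len, config)
  skip <- runif(nW) < p_skip
  ## a trial must contain at least one fixation outside the sparse-artifact
  ## path: un-skip the first word of fully skipped trials
  fixated_per_item <- rowsum((!skip) * 1L, lay$item)
  empty <- rownames(fixated_per_item)[fixated_per_item[, 1] == 0L]
  if (length(empty))
    skip[lay$first_word_at[match(as.integer(empty), lay$item_ids)]] <- FALSE

  refix <- !skip & runif(nW) < config$p_refix
  regress <- !skip & lay$word > 1L & runif(nW) < config$p_regress

  idx_base <- which(!skip)
  idx_refix <- which(refix)
  idx_reg_origin <- which(regress)

  ## row = one fixation; `land` is the layout index of the fixated word,
  ## `key` orders fixations within the trial (regressions land after the
  ## originating word's fixations, on the previous word)
  land <- c(idx_base, idx_refix, idx_reg_origin - 1L)
  key <- c(lay$word[idx_base] * 10L,
           lay$word[idx_refix] * 10L + 1L,
           lay$word[idx_reg_origin] * 10L + 5L)
  item <- c(lay$item[idx_base], lay$item[idx_refix], lay$item[idx_reg_origin])

  o <- order(item, key)
  land <- land[o]; item <- item[o]
  n <- length(land)

  cx <- (lay$x_min[land] + lay$x_max[land]) / 2
  x <- pmin(lay$x_max[land] - 1, pmax(lay$x_min[land] + 1,
                                      cx + rnorm(n, 0, config$char_width_px)))
  y <- pmin(config$line_band_px[2] - 1, pmax(config$line_band_px[1] + 1,
                                             config$line_y_px + rnorm(n, 0, 5)))
  lt <- lay$low_target[land]
  mu <- config$exgauss_mu_ms + subj_int + item_ints[item] +
    config$effect_mu_ms * lt
  tau <- config$exgauss_tau_ms + config$effect_tau_ms * lt
  dur <- pmax(config$min_duration_floor_ms,
              rexgauss(n, mu, config$exgauss_sigma_ms, tau))

  list(item = item, ord = seq_len(n), x = x, y = y, dur = dur,
       ia = lay$word[land])
}

## ---------------------------------------------------------------------------
## Artifact injection (shared helpers operate on per-trial vectors)

## insert one very short fixation adjacent in time to a host fixation
insert_short_artifact <- function(tr, config) {
  n <- length(tr$dur)
  hosts <- which(tr$dur >= 100)
  h <- if (length(hosts)) hosts[sample.int(length(hosts), 1L)] else which.max(tr$dur)
  near <- runif(1) < 0.5
  radius_deg <- if (near) runif(1, 0, 0.5) else runif(1, 0.6, 3)
  ang <- runif(1, 0, 2 * pi)
  dx <- cos(ang) * radius_deg * config$pixels_per_degree
  dy <- sin(ang) * radius_deg * config$pixels_per_degree
  dur <- runif(1, 20, 79)
  list(item = c(tr$item, tr$item[1]),
       ord = c(tr$ord, tr$ord[h] + 0.5),
       x = c(tr$x, tr$x[h] + dx), y = c(tr$y, tr$y[h] + dy),
       dur = c(tr$dur, dur),
       ia = c(tr$ia, NA_integer_))
}

## inflate one fixation's duration into the implausible range
inflate_long_artifact <- function(tr) {
  i <- sample.int(length(tr$dur), 1L)
  tr$dur[i] <- runif(1, 801, 2000)
  tr
}

## truncate the trial to its first 1--3 fixations
truncate_sparse_artifact <- function(tr) {
  k <- sample.int(3L, 1L)
  if (length(tr$dur) <= k) return(tr)
  lapply(tr, function(v) v[seq_len(k)])
}

## re-resolve the interest area of rows flagged NA after artifact insertion
resolve_artifact_ia <- function(tr, boxes) {
  na_idx <- which(is.na(tr$ia))
  for (i in na_idx) {
    hit <- which(tr$x[i] >= boxes$x_min & tr$x[i] < boxes$x_max &
                   tr$y[i] >= boxes$y_min & tr$y[i] < boxes$y_max)
    if (length(hit) == 1L) tr$ia[i] <- boxes$ia[hit]
  }
  tr
}

#' Inject artifact fixations into one trial
#'
#' With probability `artifact_short_rate`, inserts a 20--79 ms fixation
#' adjacent in time to a host fixation, within 0.5 degrees of the host half
#' the time and 0.6--3 degrees away otherwise; with `artifact_long_rate`,
#' inflates one fixation's duration to 801--2000 ms; with
#' `sparse_trial_rate`, truncates the trial to 1--3 fixations.  Order
#' indices are renumbered.  Randomness uses the caller's RNG state.
#'
#' @param trial a `data.table` of one trial's fixation records (columns
#'   `x_px`, `y_px`, `duration_ms`, `ia_index`, plus identifiers).
#' @param config a [synthetic_config()] supplying the rates and geometry.
#' @param ia optional interest-area table for the trial's item, used to
#'   resolve the interest area of inserted fixations; inserted fixations
#'   get a missing `ia_index` when no table is supplied or no box contains
#'   them.
#' @return the modified trial, `fix_index` renumbered from 1.
#' @export
inject_artifacts <- function(trial, config, ia = NULL) {
  stopifnot(nrow(trial) >= 1)
  tr <- list(item = rep(trial$item_id[1], nrow(trial)),
             ord = as.numeric(seq_len(nrow(trial))),
             x = trial$x_px, y = trial$y_px, dur = trial$duration_ms,
             ia = trial$ia_index)
  n0 <- length(tr$dur)
  if (runif(1) < config$artifact_short_rate) {
    tr <- insert_short_artifact(tr, config)
    if (!is.null(ia)) {
      boxes <- list(x_min = ia$x_min_px, x_max = ia$x_max_px,
                    y_min = ia$y_min_px, y_max = ia$y_max_px, ia = ia$ia_index)
      tr <- resolve_artifact_ia(tr, boxes)
    }
  }
  if (runif(1) < config$artifact_long_rate) tr <- inflate_long_artifact(tr)
  if (runif(1) < config$sparse_trial_rate) tr <- truncate_sparse_artifact(tr)
  o <- order(tr$ord)
  out <- data.table(subject_id = trial$subject_id[1],
                    trial_id = trial$trial_id[1],
                    item_id = trial$item_id[1],
                    condition = trial$condition[1],
                    fix_index = seq_along(o),
                    x_px = tr$x[o], y_px = tr$y[o],
                    duration_ms = tr$dur[o], ia_index = tr$ia[o])
  out
}

#' Simulate one reading trial
#'
#' Fixations proceed left to right with length-dependent word skipping,
#' occasional immediate refixations, and occasional one-word regressions.
#' Durations follow the configured ex-Gaussian with subject/item intercepts
#' and the frequency effect on low-frequency targets, floored at
#' `min_duration_floor_ms`.  The caller owns the RNG state; no artifacts
#' are injected here (see [inject_artifacts()]).
#'
#' @param subject_id integer subject identifier.
#' @param item one row of a [generate_stimuli()] table.
#' @param effects list with `subject_intercept` and `item_intercept` (ms).
#' @param config a [synthetic_config()].
#' @return a `data.table` of fixation records ordered by `fix_index`.
#' @export
generate_trial <- function(subject_id, item, effects, config) {
  lay <- word_layout(item, config)
  item_ints <- numeric(max(lay$item))
  item_ints[item$item_id[1]] <- effects$item_intercept
  bl <- gen_subject_block(lay, effects$subject_intercept, item_ints, config)
  data.table(subject_id = as.integer(subject_id),
             trial_id = as.integer(subject_id) * 100000L + item$item_id[1],
             item_id = item$item_id[1], condition = item$condition[1],
             fix_index = seq_along(bl$ord),
             x_px = bl$x, y_px = bl$y, duration_ms = bl$dur, ia_index = bl$ia)
}

#' Generate a full synthetic fixation dataset
#'
#' Simulates `n_subjects x n_items` reading trials.  Random state is split
#' hierarchically from `config$seed` (stimuli / subject intercepts / item
#' intercepts / one stream per subject), so changing `n_subjects` does not
#' reshuffle the stimulus set and equal configurations reproduce the
#' dataset exactly.
#'
#' @param config a [synthetic_config()].
#' @return a [trialset()]: fixation table, stimulus table, interest-area
#'   table and geometry.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  items <- generate_stimuli(config)
  lay <- word_layout(items, config)
  ia_tab <- build_ia_table(items, config)
  subj_int <- with_subseed(config$seed, 2L, rnorm(config$n_subjects, 0, config$sd_subject_ms))
  item_int <- with_subseed(config$seed, 3L, rnorm(config$n_items, 0, config$sd_item_ms))

  per_item_boxes <- split(
    data.frame(x_min = ia_tab$x_min_px, x_max = ia_tab$x_max_px,
               y_min = ia_tab$y_min_px, y_max = ia_tab$y_max_px,
               ia = ia_tab$ia_index),
    ia_tab$item_id)

  blocks <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    blocks[[s]] <- with_subseed(config$seed, 1000L + s, {
      bl <- gen_subject_block(lay, subj_int[s], item_int, config)
      ## per-trial artifact decisions, drawn in item order
      u_short <- runif(config$n_items)
      u_long <- runif(config$n_items)
      u_sparse <- runif(config$n_items)
      fire <- which(u_short < config$artifact_short_rate |
                      u_long < config$artifact_long_rate |
                      u_sparse < config$sparse_trial_rate)
      if (length(fire)) {
        keep_chunks <- list(); drop <- logical(length(bl$item))
        for (it in fire) {
          rows <- which(bl$item == it)
          tr <- lapply(bl[c("item", "ord", "x", "y", "dur", "ia")],
                       function(v) v[rows])
          if (u_short[it] < config$artifact_short_rate) {
            tr <- insert_short_artifact(tr, config)
            tr <- resolve_artifact_ia(tr, per_item_boxes[[as.character(it)]])
          }
          if (u_long[it] < config$artifact_long_rate) tr <- inflate_long_artifact(tr)
          if (u_sparse[it] < config$sparse_trial_rate) tr <- truncate_sparse_artifact(tr)
          drop[rows] <- TRUE
          keep_chunks[[length(keep_chunks) + 1L]] <- tr
        }
        base <- lapply(bl, function(v) v[!drop])
        merged <- list(
          item = c(base$item, unlist(lapply(keep_chunks, `[[`, "item"))),
          ord = c(base$ord, unlist(lapply(keep_chunks, `[[`, "ord"))),
          x = c(base$x, unlist(lapply(keep_chunks, `[[`, "x"))),
          y = c(base$y, unlist(lapply(keep_chunks, `[[`, "y"))),
          dur = c(base$dur, unlist(lapply(keep_chunks, `[[`, "dur"))),
          ia = c(base$ia, unlist(lapply(keep_chunks, `[[`, "ia"))))
        o <- order(merged$item, merged$ord)
        bl <- lapply(merged, function(v) v[o])
      }
      n <- length(bl$item)
      data.table(subject_id = s,
                 trial_id = s * 100000L + bl$item,
                 item_id = bl$item,
                 fix_index = 0L,  # renumbered below
                 x_px = bl$x, y_px = bl$y, duration_ms = bl$dur,
                 ia_index = as.integer(bl$ia))
    })
  }
  fx <- rbindlist(blocks)
  fx[, fix_index := seq_len(.N), by = trial_id]
  fx[, condition := items$condition[item_id]]
  setcolorder(fx, c("subject_id", "trial_id", "item_id", "condition",
                    "fix_index", "x_px", "y_px", "duration_ms", "ia_index"))
  trialset(fixations = fx, items = items,
           geometry = list(pixels_per_degree = config$pixels_per_degree,
                           char_width_px = config$char_width_px),
           ia = ia_tab)
}
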