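test_that("generate_stimuli: counterbalance, calibration, determinism", {
  cfg <- synthetic_config()
  st <- generate_stimuli(cfg)
  expect_equal(nrow(st), 78L)
  expect_equal(unname(table(st$condition)["high"]), 39L)
  expect_equal(unname(table(st$condition)["low"]), 39L)

  ## printed calibration is met exactly (Zipf) / after rounding (lengths)
  for (cond in c("high", "low")) {
    z <- st$zipf_target[st$condition == cond]
    expect_equal(mean(z), cfg$zipf_mean[[cond]], tolerance = 1e-10)
    expect_equal(sd(z), cfg$zipf_sd[[cond]], tolerance = 1e-10)
  }
  expect_true(all(st$target_len >= 4L & st$target_len <= 9L))
  expect_equal(round(mean(st$target_len), 1), 5.4)
  expect_equal(round(sd(st$target_len), 2), 0.87)
  expect_true(all(st$target_ia_index <= st$n_words))

  ## smallest counterbalanced set and the odd-n error
  st2 <- generate_stimuli(synthetic_config(n_items = 2))
  expect_setequal(st2$condition, c("high", "low"))
  expect_error(generate_stimuli(synthetic_config(n_items = 3)),
               "counterbalanced")

  ## determinism contract
  expect_identical(generate_stimuli(cfg), generate_stimuli(cfg))
})

test_that("stimulus calibration repair works across seeds and targets", {
  for (s in 1:15) {
    st <- generate_stimuli(synthetic_config(seed = s))
    expect_equal(round(mean(st$target_len), 1), 5.4)
    expect_equal(round(sd(st$target_len), 2), 0.87)
    expect_true(all(st$target_len >= 4L & st$target_len <= 9L))
  }
  ## a different stated calibration is honored too
  st <- generate_stimuli(synthetic_config(n_items = 40, len_mean = 6.1,
                                          len_sd = 1.2, len_range = c(4, 10)))
  expect_equal(round(mean(st$target_len), 1), 6.1)
  expect_equal(round(sd(st$target_len), 2), 1.2)
})

test_that("duration floor contract holds when artifacts are off", {
  ts <- small_dataset(seed = 3, artifact_short_rate = 0,
                      artifact_long_rate = 0, sparse_trial_rate = 0,
                      min_duration_floor_ms = 80)
  expect_true(all(ts$fixations$duration_ms >= 80))
})

test_that("ex-Gaussian calibration: mean near mu + tau, positive skew", {
  ts <- generate_dataset(synthetic_config(
    n_subjects = 20, n_items = 40, seed = 7,
    sd_subject_ms = 0, sd_item_ms = 0, effect_mu_ms = 0, effect_tau_ms = 0,
    artifact_short_rate = 0, artifact_long_rate = 0, sparse_trial_rate = 0,
    min_duration_floor_ms = 0))
  d <- ts$fixations$duration_ms
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - (180 + 60)), 3 * se)
  skew <- mean((d - mean(d))^3) / sd(d)^3
  expect_gt(skew, 0)
})

test_that("null effect yields no condition difference on target SFDs", {
  ## ~10,000 trials under effect 0: condition difference within 2 SE
  ts <- generate_dataset(synthetic_config(
    n_subjects = 125, n_items = 80, seed = 11,
    effect_mu_ms = 0, effect_tau_ms = 0,
    artifact_short_rate = 0, artifact_long_rate = 0, sparse_trial_rate = 0))
  obs <- extract_sfd(ts)
  hi <- obs$sfd_ms[obs$condition == "high"]
  lo <- obs$sfd_ms[obs$condition == "low"]
  se <- sqrt(var(hi) / length(hi) + var(lo) / length(lo))
  expect_lt(abs(mean(lo) - mean(hi)), 2 * se)
})

test_that("configured effect is recovered: ex-Gaussian mean is mu + tau", {
  ## effect 10 on mu + 5 on tau => population mean difference 15 ms
  ts <- generate_dataset(synthetic_config(
    n_subjects = 125, n_items = 80, seed = 13,
    effect_mu_ms = 10, effect_tau_ms = 5,
    artifact_short_rate = 0, artifact_long_rate = 0, sparse_trial_rate = 0))
  obs <- extract_sfd(ts)
  hi <- obs$sfd_ms[obs$condition == "high"]
  lo <- obs$sfd_ms[obs$condition == "low"]
  se <- sqrt(var(hi) / length(hi) + var(lo) / length(lo))
  expect_lt(abs((mean(lo) - mean(hi)) - 15), 2 * se)
})

test_that("tail-loaded effect shrinks under trimming (effect placement)", {
  ts <- generate_dataset(synthetic_config(
    n_subjects = 60, n_items = 60, seed = 17,
    effect_mu_ms = 10, effect_tau_ms = 15,
    artifact_short_rate = 0, artifact_long_rate = 0, sparse_trial_rate = 0))
  obs <- extract_sfd(ts)
  hi <- obs$sfd_ms[obs$condition == "high"]
  lo <- obs$sfd_ms[obs$condition == "low"]
  full_diff <- mean(lo) - mean(hi)
  lo_trim <- lo[lo <= quantile(lo, 0.95)]
  expect_lt(mean(lo_trim) - mean(hi), full_diff)
})

test_that("inject_artifacts honors its rates and construction", {
  cfg0 <- synthetic_config(artifact_short_rate = 0, artifact_long_rate = 0,
                           sparse_trial_rate = 0)
  trial <- make_trial(dur = c(200, 250, 300), x = c(100, 160, 220),
                      ia = c(1L, 2L, 3L))
  set.seed(1)
  expect_identical(inject_artifacts(trial, cfg0), trial)

  ## short rate 1: exactly one sub-80 ms fixation appears adjacent to a
  ## host; near branch lands within 0.5 deg, far branch within 0.6-3 deg
  cfg_s <- synthetic_config(artifact_short_rate = 1, artifact_long_rate = 0,
                            sparse_trial_rate = 0)
  set.seed(42)
  dists <- replicate(200, {
    out <- inject_artifacts(trial, cfg_s)
    stopifnot(nrow(out) == 4L, sum(out$duration_ms < 80) == 1L)
    i <- which(out$duration_ms < 80)
    host <- i - 1L  # the artifact is inserted immediately after its host
    stopifnot(host >= 1L, out$duration_ms[host] > out$duration_ms[i])
    sqrt((out$x_px[i] - out$x_px[host])^2 +
           (out$y_px[i] - out$y_px[host])^2) / cfg_s$pixels_per_degree
  })
  expect_true(any(dists <= 0.5))
  expect_true(any(dists >= 0.6))
  expect_true(all(dists <= 0.5 | (dists >= 0.6 - 1e-9 & dists <= 3 + 1e-9)))

  ## long rate 1: one duration inflated into (800, 2000]
  cfg_l <- synthetic_config(artifact_short_rate = 0, artifact_long_rate = 1,
                            sparse_trial_rate = 0)
  set.seed(7)
  out <- inject_artifacts(trial, cfg_l)
  expect_equal(sum(out$duration_ms > 800), 1L)

  ## sparse rate 1: trials truncated to <= 3 fixations
  cfg_sp <- synthetic_config(artifact_short_rate = 0, artifact_long_rate = 0,
                             sparse_trial_rate = 1)
  long_trial <- make_trial(dur = rep(200, 8), x = seq(100, 800, by = 100),
                           ia = 1:8)
  set.seed(5)
  for (i in 1:20) expect_lte(nrow(inject_artifacts(long_trial, cfg_sp)), 3L)
})

test_that("generate_dataset: size, determinism, seed sensitivity", {
  cfg <- synthetic_config(n_subjects = 6, n_items = 10, seed = 23)
  ts <- generate_dataset(cfg)
  expect_equal(data.table::uniqueN(ts$fixations$trial_id), 60L)
  expect_true(all(ts$fixations$fix_index >= 1L))

  ## same seed: byte-identical reports after writing
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile()
  write_fixation_report(ts, f1)
  write_fixation_report(generate_dataset(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  ## different seed: different durations
  cfg2 <- synthetic_config(n_subjects = 6, n_items = 10, seed = 24)
  write_fixation_report(generate_dataset(cfg2), f3)
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f3, "raw", file.size(f3))))
  unlink(c(f1, f2, f3))
})

test_that("adding subjects does not reshuffle items or earlier subjects", {
  a <- generate_dataset(synthetic_config(n_subjects = 4, n_items = 10, seed = 31))
  b <- generate_dataset(synthetic_config(n_subjects = 6, n_items = 10, seed = 31))
  expect_identical(a$items, b$items)
  expect_identical(a$fixations, b$fixations[subject_id <= 4])
})

test_that("target is fixated exactly once in first pass more often than not", {
  ts <- generate_dataset(synthetic_config(n_subjects = 30, n_items = 40,
                                          seed = 37, artifact_short_rate = 0,
                                          artifact_long_rate = 0,
                                          sparse_trial_rate = 0))
  obs <- extract_sfd(ts)
  expect_gte(nrow(obs) / (30 * 40), 0.5)
})
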