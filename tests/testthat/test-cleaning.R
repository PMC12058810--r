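geom40 <- list(pixels_per_degree = 40)

test_that("merge_pass follows the stated rule on hand-worked cases", {
  ## short fixation 12 px (0.3 deg) from a longer one: absorbed by it
  t1 <- make_trial(dur = c(200, 70), x = c(100, 112), ia = c(1L, 1L))
  out <- merge_pass(t1, 80, 0.5, geom40)
  expect_equal(nrow(out), 1L)
  expect_equal(out$duration_ms, 270)
  expect_equal(out$x_px, 100)  # host keeps its position

  ## 60 px (1.5 deg) away: out of reach, unchanged
  t2 <- make_trial(dur = c(200, 70), x = c(100, 160), ia = c(1L, 2L))
  out2 <- merge_pass(t2, 80, 0.5, geom40)
  expect_equal(nrow(out2), 2L)
  expect_equal(out2$duration_ms, c(200, 70))

  ## no candidates below the threshold: identity
  t3 <- make_trial(dur = c(200, 150, 300), x = c(100, 120, 140))
  expect_same_trial(merge_pass(t3, 80, 0.5, geom40), t3)

  ## equidistant neighbors: the longer one wins
  t4 <- make_trial(dur = c(300, 50, 200), x = c(100, 110, 120))
  out4 <- merge_pass(t4, 80, 0.5, geom40)
  expect_equal(out4$duration_ms, c(350, 200))

  ## 40 < 50: the 40 ms one is absorbed into the (strictly longer) 50 ms
  ## one, leaving a single 90 ms fixation
  t5 <- make_trial(dur = c(50, 40), x = c(100, 105))
  expect_equal(merge_pass(t5, 80, 0.5, geom40)$duration_ms, 90)
  ## equal durations: no strictly longer host, both left in place
  ## (removal of unmergeable shorts is stage 4's job)
  t6 <- make_trial(dur = c(50, 50), x = c(100, 105))
  expect_equal(merge_pass(t6, 80, 0.5, geom40)$duration_ms, c(50, 50))
})

test_that("merge_ia_runs follows the stated rule on hand-worked cases", {
  ## three consecutive 100 ms fixations in one area merge into 300 ms
  t1 <- make_trial(dur = c(100, 100, 100), x = c(100, 110, 120),
                   ia = c(5L, 5L, 5L))
  out <- merge_ia_runs(t1, 140)
  expect_equal(nrow(out), 1L)
  expect_equal(out$duration_ms, 300)
  expect_equal(out$ia_index, 5L)
  expect_equal(out$x_px, weighted.mean(c(100, 110, 120), c(100, 100, 100)))

  ## two consecutive short fixations: below run length, unchanged
  t2 <- make_trial(dur = c(100, 100), x = c(100, 110), ia = c(5L, 5L))
  expect_same_trial(merge_ia_runs(t2, 140), t2)

  ## areas 5,5,6: no single-area run of three, unchanged
  t3 <- make_trial(dur = c(100, 100, 100), x = c(100, 110, 200),
                   ia = c(5L, 5L, 6L))
  expect_same_trial(merge_ia_runs(t3, 140), t3)

  ## missing interest area breaks a run
  t4 <- make_trial(dur = c(100, 100, 100), x = c(100, 110, 120),
                   ia = c(5L, NA, 5L))
  expect_same_trial(merge_ia_runs(t4, 140), t4)
})

test_that("temporal_filter removes strictly outside the bounds", {
  t1 <- make_trial(dur = c(100, 200, 900), x = c(100, 150, 200))
  expect_equal(temporal_filter(t1, 140, 800)$duration_ms, 200)
  ## boundary values are retained
  t2 <- make_trial(dur = c(140, 800), x = c(100, 150))
  expect_equal(temporal_filter(t2, 140, 800)$duration_ms, c(140, 800))
  ## degenerate bounds: identity
  expect_same_trial(temporal_filter(t1, 0, Inf), t1)
})

test_that("delete_outside_ia equals the brute-force point-in-box filter", {
  ts <- small_dataset(seed = 9, n_subjects = 3, n_items = 6)
  fx <- data.table::copy(ts$fixations)
  set.seed(2)
  off <- sample(nrow(fx), 20)
  fx$y_px[off] <- fx$y_px[off] + 300
  scattered <- assign_interest_areas(
    trialset(fx, ts$items, ts$geometry, ia = ts$ia, validate = FALSE))
  one_trial <- scattered$fixations[trial_id == fx$trial_id[off[1]]]
  out <- delete_outside_ia(one_trial)
  boxes <- ts$ia[ts$ia$item_id == one_trial$item_id[1]]
  keep <- !is.na(oracle_assign_ia(one_trial$x_px, one_trial$y_px, boxes))
  expect_equal(nrow(out), sum(keep))
  expect_equal(out$duration_ms, one_trial$duration_ms[keep])
})

test_that("random trials: engine output equals brute-force oracles", {
  set.seed(123)
  for (rep in 1:300) {
    tr <- random_trial()
    thr <- sample(c(40, 80, 100, 140), 1)
    dist <- sample(c(0.5, 1.25), 1)
    eng <- merge_pass(tr, thr, dist, geom40)
    ora <- oracle_merge_pass(tr, thr, dist, 40)
    expect_same_trial(eng, ora)
    ## mass conservation and idempotence
    expect_equal(sum(eng$duration_ms), sum(tr$duration_ms), tolerance = 1e-9)
    expect_same_trial(merge_pass(eng, thr, dist, geom40), eng)

    eng3 <- merge_ia_runs(tr, 140)
    expect_same_trial(eng3, oracle_merge_ia_runs(tr, 140))
    expect_equal(sum(eng3$duration_ms), sum(tr$duration_ms), tolerance = 1e-9)
    expect_same_trial(merge_ia_runs(eng3, 140), eng3)

    eng4 <- temporal_filter(tr, 140, 800)
    expect_same_trial(eng4, oracle_temporal_filter(tr, 140, 800))
    expect_same_trial(temporal_filter(eng4, 140, 800), eng4)
  }
})

test_that("cleaning catalog replicates the 14 configurations", {
  cat14 <- cleaning_catalog()
  expect_length(cat14, 14L)
  expect_true(all(vapply(cat14, inherits, TRUE, "cleaning_config")))
  expect_true("standard" %in% names(cat14))
  expect_true("no_cleaning" %in% names(cat14))
  std <- cat14$standard
  expect_equal(std$stage1$max_dur_ms, 80)
  expect_equal(std$stage1$max_dist_deg, 0.5)
  expect_equal(std$stage2$max_dur_ms, 40)
  expect_equal(std$stage2$max_dist_deg, 1.25)
  expect_equal(std$stage3$max_dur_ms, 140)
  expect_equal(std$stage4$min_dur_ms, 140)
  expect_equal(std$stage4$max_dur_ms, 800)
  expect_false(std$delete_outside_ia)
  nc <- cat14$no_cleaning
  expect_false(any(nc$stage1$enabled, nc$stage2$enabled,
                   nc$stage3$enabled, nc$stage4$enabled))
})

test_that("apply_cleaning: no-cleaning identity, artifact removal, stats", {
  ts <- small_dataset(seed = 10, artifact_short_rate = 0.3,
                      artifact_long_rate = 0.1)
  r0 <- apply_cleaning(ts, cleaning_catalog()$no_cleaning)
  expect_true(datasets_identical(r0$trialset, ts))
  expect_equal(r0$stats$n_fixations_before, r0$stats$n_fixations_after)
  expect_equal(r0$stats$stage1_merged + r0$stats$stage2_merged +
                 r0$stats$stage3_merged + r0$stats$stage4_removed, 0L)

  r1 <- apply_cleaning(ts, cleaning_catalog()$standard)
  expect_lt(r1$stats$n_fixations_after, r1$stats$n_fixations_before)
  expect_equal(r1$stats$n_fixations_before - r1$stats$n_fixations_after,
               r1$stats$stage1_merged + r1$stats$stage2_merged +
                 r1$stats$stage3_merged + r1$stats$stage4_removed +
                 r1$stats$outside_removed)
  ## idempotence on generator data
  r2 <- apply_cleaning(r1$trialset, cleaning_catalog()$standard)
  expect_true(datasets_identical(r2$trialset, r1$trialset))
})

test_that("stages 1-3 conserve duration mass; enabling stages is monotone", {
  ts <- small_dataset(seed = 12, artifact_short_rate = 0.3)
  merge_only <- cleaning_config("merge_only", stage4 = list(enabled = FALSE))
  r <- apply_cleaning(ts, merge_only)
  tot_in <- sum(ts$fixations$duration_ms)
  expect_equal(sum(r$trialset$fixations$duration_ms), tot_in, tolerance = 1e-9)

  ## progressively enabling stages never increases the fixation count
  off <- list(enabled = FALSE)
  configs <- list(
    cleaning_config("c0", stage1 = off, stage2 = off, stage3 = off, stage4 = off),
    cleaning_config("c1", stage2 = off, stage3 = off, stage4 = off),
    cleaning_config("c2", stage3 = off, stage4 = off),
    cleaning_config("c3", stage4 = off),
    cleaning_config("c4"))
  counts <- vapply(configs, function(cc)
    apply_cleaning(ts, cc)$stats$n_fixations_after, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("datasets_identical discriminates exactly as specified", {
  ts <- small_dataset(seed = 14, artifact_short_rate = 0.4)
  expect_true(datasets_identical(ts, ts))

  ## artifact-free data with all durations inside the stage-4 bounds:
  ## stage-4-only cleaning is a no-op, so the datasets compare identical
  calm <- generate_dataset(synthetic_config(
    n_subjects = 4, n_items = 6, seed = 15,
    exgauss_mu_ms = 300, exgauss_sigma_ms = 20, exgauss_tau_ms = 0,
    sd_subject_ms = 5, sd_item_ms = 5,
    artifact_short_rate = 0, artifact_long_rate = 0, sparse_trial_rate = 0))
  expect_true(all(calm$fixations$duration_ms > 140 &
                    calm$fixations$duration_ms < 800))
  off <- list(enabled = FALSE)
  stage4_only <- cleaning_config("s4only", stage1 = off, stage2 = off, stage3 = off)
  nc <- apply_cleaning(calm, cleaning_catalog()$no_cleaning)$trialset
  s4 <- apply_cleaning(calm, stage4_only)$trialset
  expect_true(datasets_identical(nc, s4))

  ## artifact-laden data: standard cleaning changes the dataset
  std <- apply_cleaning(ts, cleaning_catalog()$standard)$trialset
  expect_false(datasets_identical(ts, std))
})
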