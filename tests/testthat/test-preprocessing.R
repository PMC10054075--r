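# RR cleaning chain and segment quality control.

test_that("range filter flags outside 300-2000 ms inclusively", {
  rr <- filter_rr_range(rr_series(c(250, 800, 2100, 300, 2000)))
  expect_identical(rr$flags,
                   c("range_outlier", "ok", "range_outlier", "ok", "ok"))
  expect_identical(rr$rr_ms, c(250, 800, 2100, 300, 2000))  # values untouched
  clean <- filter_rr_range(rr_series(rep(800, 10)))
  expect_true(all(clean$flags == "ok"))
  expect_error(filter_rr_range(rr_series(800), 2000, 300),
               class = "vo2hrv_config_error")
})

test_that("Karlsson rule flags >20% deviation from adjacent-interval mean, strictly", {
  rr <- detect_ectopic_karlsson(rr_series(c(800, 800, 1200, 800, 800)))
  expect_identical(which(rr$flags == "ectopic"), 3L)
  expect_true(all(detect_ectopic_karlsson(rr_series(rep(800, 20)))$flags == "ok"))
  # |960 - 800| = 160 = 0.2 * 800 exactly: boundary is not flagged
  rr <- detect_ectopic_karlsson(rr_series(c(800, 960, 800)))
  expect_true(all(rr$flags == "ok"))
  expect_error(detect_ectopic_karlsson(rr_series(c(800, 810))),
               class = "vo2hrv_too_short_error")
})

test_that("Karlsson skips range-flagged neighbours", {
  rr <- filter_rr_range(rr_series(c(800, 2500, 820, 810)))
  rr <- detect_ectopic_karlsson(rr)
  # beat 3's reference is the mean of beats 1 and 4, not the spike
  expect_identical(rr$flags[3], "ok")
  expect_identical(rr$flags[2], "range_outlier")
})

test_that("interpolation is linear over beat index with edge fill", {
  rr <- rr_series(c(800, 850, 900), flags = c("ok", "ectopic", "ok"))
  expect_equal(interpolate_flagged(rr)$rr_ms, c(800, 850, 900))
  rr <- rr_series(c(800, 700, 700, 920),
                  flags = c("ok", "ectopic", "range_outlier", "ok"))
  out <- interpolate_flagged(rr)
  expect_equal(out$rr_ms, c(800, 840, 880, 920))
  expect_identical(out$flags, c("ok", "interpolated", "interpolated", "ok"))
  # leading flagged run takes the nearest unflagged value
  rr <- rr_series(c(2500, 800, 900), flags = c("range_outlier", "ok", "ok"))
  expect_equal(interpolate_flagged(rr)$rr_ms, c(800, 800, 900))
  # identity when nothing is flagged
  rr <- rr_series(c(800, 810))
  expect_identical(interpolate_flagged(rr)$rr_ms, rr$rr_ms)
  expect_error(interpolate_flagged(
    rr_series(c(100, 100, 800), flags = c("ectopic", "ectopic", "ectopic"))),
    class = "vo2hrv_integrity_error")
})

test_that("cleaning preserves beat count and restores in-range values", {
  co <- .tiny_cohort(n = 4, seed = 7, ectopic_rate = 0.01, spike_rate = 0.01)
  cfg <- pipeline_config()
  for (s in co$sessions) {
    cl <- clean_rr(s$rr, cfg)
    expect_identical(length(cl$rr_ms), length(s$rr$rr_ms))
    expect_true(all(cl$rr_ms >= cfg$rr_min_ms & cl$rr_ms <= cfg$rr_max_ms))
  }
})

test_that("the cleaning chain is idempotent", {
  co <- .tiny_cohort(n = 5, seed = 11, ectopic_rate = 0.005,
                     spike_rate = 0.005)
  for (s in co$sessions) {
    once <- clean_rr(s$rr)
    twice <- clean_rr(once)
    expect_equal(twice$rr_ms, once$rr_ms, tolerance = 1e-12)
  }
})

test_that("each QC rule fires on a violating session and not on a clean one", {
  cfg <- pipeline_config()
  s <- preprocess_session(.tiny_cohort(n = 2, seed = 3, ectopic_rate = 0,
                                       spike_rate = 0)$sessions[[1]], cfg)
  expect_true(qc_segment(s, "exercise", cfg)$kept)
  expect_true(qc_segment(s, "recovery", cfg)$kept)

  jump <- s
  jump$trace$hr[100] <- jump$trace$hr[99] + 35  # 120 -> 155-style step
  expect_true("hr_jump" %in% qc_segment(jump, "exercise", cfg)$reasons)

  short <- s
  cut <- 240
  short$trace <- short$trace[short$trace$time <= cut + 180, ]
  short$exercise_end_time <- cut
  short$recovery_end_time <- cut + 180
  expect_true("too_short" %in% qc_segment(short, "exercise", cfg)$reasons)
  # recovery is exempt from the duration rule (fixed 3-min design length)
  expect_false("too_short" %in% qc_segment(short, "recovery", cfg)$reasons)

  gap <- s
  gap$trace$vo2[50] <- NA
  expect_true("missing_values" %in% qc_segment(gap, "exercise", cfg)$reasons)

  inv <- s
  ex_idx <- inv$trace$time <= inv$exercise_end_time
  inv$trace$vo2[ex_idx] <- rev(inv$trace$vo2[ex_idx])  # HR up, VO2 down
  expect_true("out_of_phase" %in% qc_segment(inv, "exercise", cfg)$reasons)

  expect_error(qc_segment(s, "cooldown", cfg), class = "vo2hrv_config_error")
})

test_that("kept is true exactly when no reason is recorded", {
  co <- .tiny_cohort(n = 6, seed = 5)
  rep <- qc_cohort(co$sessions)
  expect_identical(rep$kept, rep$reasons == "")
  expect_identical(nrow(rep), 12L)
})
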