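# Synthetic GET cohort generator: determinism, cohort-level laws, trace
# physiology and artifact injection.

test_that("cohorts are deterministic under a fixed seed", {
  a <- generate_cohort(sim_config(n_subjects = 4, seed = 9))
  b <- generate_cohort(sim_config(n_subjects = 4, seed = 9))
  expect_identical(a$truth, b$truth)
  expect_identical(a$sessions[[2]]$trace, b$sessions[[2]]$trace)
  expect_identical(a$sessions[[2]]$rr$rr_ms, b$sessions[[2]]$rr$rr_ms)
  # the traces = FALSE shortcut must not perturb the physiology draw
  # (artifact indices exist only when traces are simulated)
  c <- generate_cohort(sim_config(n_subjects = 4, seed = 9), traces = FALSE)
  keep <- setdiff(names(a$truth), "artifact_beats")
  expect_identical(a$truth[keep], c$truth[keep])
})

test_that("deviant count follows the rounding rule exactly", {
  tr <- generate_cohort(sim_config(n_subjects = 200, seed = 1,
                                   deviant_fraction = 0.05),
                        traces = FALSE)$truth
  expect_identical(sum(tr$is_deviant), 10L)
  tr0 <- generate_cohort(sim_config(n_subjects = 50, seed = 1,
                                    deviant_fraction = 0),
                         traces = FALSE)$truth
  expect_identical(sum(tr0$is_deviant), 0L)
})

test_that("fitness and maximal speed are strongly rank-correlated without deviants", {
  tr <- generate_cohort(sim_config(n_subjects = 500, seed = 1,
                                   deviant_fraction = 0),
                        traces = FALSE)$truth
  rho <- cor(tr$vo2max_true, tr$max_speed_true, method = "spearman")
  expect_gte(rho, 0.8)
  expect_true(all(tr$vo2max_true >= 25 & tr$vo2max_true <= 75))
})

test_that("cohort validation rejects degenerate configurations", {
  expect_error(sim_config(n_subjects = 1), class = "vo2hrv_config_error")
  expect_error(sim_config(deviant_fraction = 1.2),
               class = "vo2hrv_config_error")
  expect_error(simulate_trace(list(subject_id = "x", age = 30,
                                   gender = "male", height = 180, weight = 75,
                                   vo2max_true = 40, max_speed_true = 4.5,
                                   hr_max = 185, hr_rest = 60), "step"),
               class = "vo2hrv_degenerate_error")
})

test_that("fitter subjects recover faster at matched exercise profile", {
  base <- list(subject_id = "x", age = 30, gender = "male", height = 180,
               weight = 75, max_speed_true = 15, hr_max = 190, hr_rest = 60)
  fit <- simulate_trace(c(base, vo2max_true = 60), "step", seed = 1)
  unfit <- simulate_trace(c(base, vo2max_true = 30), "step", seed = 1)
  at <- function(s, t) s$trace$hr[s$trace$time == s$exercise_end_time + t]
  expect_lt(at(fit, 60), at(unfit, 60))
})

test_that("every clean subject shows HR-VO2 coherence and recovery decay", {
  co <- .tiny_cohort(n = 8, seed = 21, ectopic_rate = 0, spike_rate = 0)
  for (s in co$sessions) {
    ex <- s$trace[s$trace$time <= s$exercise_end_time, ]
    expect_gt(cor(ex$hr, ex$vo2, method = "spearman"), 0.9)
    hr_end <- s$trace$hr[s$trace$time == s$exercise_end_time]
    hr_60 <- s$trace$hr[s$trace$time == s$exercise_end_time + 60]
    expect_lt(hr_60, hr_end)
  }
})

test_that("exercise RR variability shrinks from first to last minute", {
  base <- list(subject_id = "x", age = 28, gender = "female", height = 165,
               weight = 60, vo2max_true = 48, max_speed_true = 14,
               hr_max = 188, hr_rest = 62)
  hits <- 0L
  for (seed in 1:50) {
    s <- simulate_trace(base, "step", seed = seed)
    first <- rr_series(s$rr$rr_ms[s$rr$beat_time_s <= 60])
    last <- rr_series(s$rr$rr_ms[s$rr$beat_time_s > s$exercise_end_time - 60 &
                                   s$rr$beat_time_s <= s$exercise_end_time])
    rm1 <- time_domain_features(first)["RMSSD"]
    rm2 <- time_domain_features(last)["RMSSD"]
    if (rm1 > rm2) hits <- hits + 1L
  }
  expect_gte(hits, 45L)  # >= 90% of runs
})

test_that("ectopic events split a beat and lengthen its successor", {
  out <- inject_artifacts(rr_series(c(800, 800)), ectopic_rate = 1,
                          spike_rate = 0, seed = 4)
  expect_equal(out$rr$rr_ms, c(400, 1200))
  expect_identical(out$ectopic_beats, c(1L, 2L))
  # total time is preserved
  expect_equal(sum(out$rr$rr_ms), 1600)
})

test_that("zero artifact rates leave the series unchanged", {
  rr <- random_rr(100, seed = 6)
  out <- inject_artifacts(rr, 0, 0, seed = 1)
  expect_identical(out$rr$rr_ms, rr$rr_ms)
  expect_identical(out$injected_beats, integer())
})

test_that("spike events land outside the physiological range", {
  rr <- random_rr(500, seed = 8)
  out <- inject_artifacts(rr, ectopic_rate = 0, spike_rate = 0.05, seed = 2)
  expect_gt(length(out$spike_beats), 0L)
  spikes <- out$rr$rr_ms[out$spike_beats]
  expect_true(all(spikes < 300 | spikes > 2000))
})
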