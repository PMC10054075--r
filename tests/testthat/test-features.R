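# HRV and session-level feature extraction.

test_that("time-domain features match hand-computed values", {
  f <- time_domain_features(c(800, 810, 790, 805))
  expect_equal(unname(f["RMSSD"]), sqrt((100 + 400 + 225) / 3))
  expect_equal(unname(f["Mean NNI"]), 801.25)
  expect_equal(unname(f["Range NNI"]), 20)
  f2 <- time_domain_features(c(800, 825, 810, 840))
  expect_equal(unname(f2["NNI 20"]), 2)
  expect_equal(unname(f2["PNNI 20"]), 200 / 3)
  fc <- time_domain_features(rep(850, 30))
  expect_equal(unname(fc[c("RMSSD", "PNNI 50", "Range NNI", "SDNN")]),
               c(0, 0, 0, 0))
  expect_error(time_domain_features(800), class = "vo2hrv_too_short_error")
})

test_that("Poincare axes follow the successive-difference identities", {
  f <- nonlinear_features(c(800, 810, 790, 805))
  sdsd <- sd(diff(c(800, 810, 790, 805)))
  expect_equal(unname(f["SD1"]), sdsd / sqrt(2))
  expect_equal(unname(f["CSI"]), unname(f["SD2/SD1"]))
  fc <- nonlinear_features(rep(800, 30))
  expect_equal(unname(fc["SD1"]), 0)
  expect_true(is.na(fc["CSI"]))  # 0/0 ratio is reported missing
})

test_that("DFA distinguishes white noise from integrated noise and rejects constants", {
  # box-counting DFA over integer scales 4..16 carries a known finite-size
  # bias on uncorrelated input (expected slope 0.583, from
  # E[F^2(n)] = sigma^2 (n^2 - 4) / (15 n)); the discriminative contrast
  # with integrated noise is what matters here
  a_white <- withr::with_seed(1, dfa_alpha(rnorm(5000, 800, 30), 4, 16))
  expect_lt(abs(a_white - 0.583), 0.08)
  a_walk <- withr::with_seed(1, dfa_alpha(1e4 + cumsum(rnorm(5000)), 4, 16))
  expect_lt(abs(a_walk - 1.5), 0.15)
  expect_gt(a_walk - a_white, 0.5)
  expect_error(dfa_alpha(rep(800, 200)), class = "vo2hrv_degenerate_error")
  expect_error(dfa_alpha(rnorm(10, 800, 10), 4, 16),
               class = "vo2hrv_too_short_error")
})

test_that("a single 0.1 Hz modulation concentrates power in the LF band", {
  mk_rr <- function(amp, seed = 3) {
    withr::with_seed(seed, {
      rr <- numeric(500); t <- 0
      for (i in seq_len(500)) {
        rr[i] <- 800 + amp * sin(2 * pi * 0.1 * t) + rnorm(1, 0, 1)
        t <- t + rr[i] / 1000
      }
    })
    rr_series(rr)
  }
  f <- frequency_domain_features(mk_rr(50))
  expect_gte(unname(f["LF"] / f["Total Power"]), 0.8)
  expect_equal(unname(f["VLF"] + f["LF"] + f["HF"]),
               unname(f["Total Power"]), tolerance = 1e-12)
  # power scales with amplitude squared
  f2 <- frequency_domain_features(mk_rr(25))
  expect_equal(unname(f["LF"] / f2["LF"]), 4, tolerance = 0.05)
})

test_that("short segments yield missing spectral values, not errors", {
  f <- frequency_domain_features(random_rr(60, seed = 2))  # ~48 s of beats
  expect_true(all(is.na(f)))
  expect_named(f, c("VLF", "LF", "HF", "Total Power"))
})

test_that("feature scaling behaves as documented", {
  x <- random_rr(300, seed = 5)$rr_ms
  c_ <- 1.7
  f1 <- time_domain_features(x); f2 <- time_domain_features(c_ * x)
  for (nm in c("RMSSD", "SDNN", "SDSD", "Range NNI"))
    expect_equal(unname(f2[nm]), c_ * unname(f1[nm]), tolerance = 1e-12)
  expect_equal(unname(f2["CVNNI"]), unname(f1["CVNNI"]), tolerance = 1e-12)
  n1 <- nonlinear_features(x); n2 <- nonlinear_features(c_ * x)
  expect_equal(unname(n2["SD1"]), c_ * unname(n1["SD1"]), tolerance = 1e-12)
  expect_equal(unname(n2["SD2"]), c_ * unname(n1["SD2"]), tolerance = 1e-12)
  expect_equal(unname(n2["DFA Alpha 1"]), unname(n1["DFA Alpha 1"]),
               tolerance = 1e-9)
})

test_that("sliding-window slopes recover exact linear trends", {
  rr <- random_rr(600, mean = 500, sd = 1, seed = 9)  # ~300 s of beats
  const <- function(w) c(f = 5)
  expect_equal(unname(slope_features(rr, const)["f slope"]), 0)
  # an RR level drifting at 0.2 ms/s must surface as a Mean NNI slope of 0.2
  drift <- local({
    x <- numeric(700); t <- 0
    for (i in seq_along(x)) { x[i] <- 400 + 0.2 * t; t <- t + x[i] / 1000 }
    rr_series(x)
  })
  expect_equal(unname(slope_features(drift, time_domain_features)["Mean NNI slope"]),
               0.2, tolerance = 0.02)
  # too-short segment yields NA
  short <- random_rr(20, mean = 500, seed = 9)
  expect_true(all(is.na(slope_features(short, const))))
})

test_that("windowed DFA slopes reduce to the finite difference on two windows", {
  # span ~80 s: windows start at 0 and 15 only; both slope flavours must
  # equal the single finite-difference slope
  rr <- random_rr(110, mean = 730, sd = 25, seed = 13)
  out <- dfa_window_slopes(rr, horizons = 60)
  expect_true(is.finite(out["DFA Slope 60"]))
  expect_equal(unname(out["DFA Slope 60"]), unname(out["Ins DFA Slope 60"]))
})

test_that("speed/time landmarks match the ramp geometry", {
  tm <- 0:600
  trace <- data.frame(time = tm, speed = 12 * tm / 600,
                      hr = 60 + 0.2 * tm, vo2 = 10 + 0.05 * tm)
  s <- gxt_session("R1", age = 30, gender = "male", height = 180, weight = 75,
                   protocol_type = "incremental", trace = trace,
                   exercise_end_time = 600, recovery_end_time = 600,
                   vo2max_measured = 50)
  f <- session_speed_time_features(s)
  expect_equal(unname(f["TimeSp25"]), 150)  # first crossing of 3 km/h
  expect_equal(unname(f["RT25"]), 1)        # both exactly linear in time
  expect_equal(unname(f["SlopeT100"]), 0.2)
  expect_equal(unname(f["Max. Speed"]), 12)
  expect_equal(unname(f["HR Reserve"]), 120)
  # HR spends no time below 60% of max HR here except the built zones
  expect_equal(unname(f["DurationHR60"]),
               sum(trace$hr >= 0.5 * 180 & trace$hr < 0.6 * 180))
})

test_that("assembled vectors have the manifest's exact length and order", {
  co <- .tiny_cohort(n = 3, seed = 17)
  s <- preprocess_session(co$sessions[[1]])
  ex <- assemble_features(s, "exercise")
  expect_identical(names(ex), feature_manifest("exercise")$name)
  rec <- assemble_features(s, "recovery")
  expect_identical(names(rec), feature_manifest("recovery")$name)
  expect_error(
    assemble_features(s, "recovery",
                      manifest = rbind(feature_manifest("recovery"),
                                       data.frame(name = "VLF",
                                                  family = "frequency"))),
    class = "vo2hrv_integrity_error")
  bad <- rbind(feature_manifest("recovery"),
               data.frame(name = "No Such Feature", family = "time_domain"))
  expect_error(assemble_features(s, "recovery", manifest = bad),
               class = "vo2hrv_integrity_error")
})

test_that("published name variants resolve to manifest entries", {
  ex <- feature_manifest("exercise")
  exercise_vocab <- c("Max. speed", "TimeSp25", "TimeSp50", "TimeSp75",
                      "TimeSp100", "Ex. Duration", "Total Power", "VLF",
                      "LF", "HF", "Total Power slope", "SlopeSp25", "RT25",
                      "RSp25", "TimeHR25", "DurationHR60", "HR MAX 25",
                      "R TIME 75", "PNNI 20", "CVI", "CVNNI slope",
                      "Protocol Type", "BMI", "Gender", "Age", "SD1", "SD2",
                      "NNI 20", "NNI 50", "Range NNI", "Std. HR")
  res <- resolve_feature_name(exercise_vocab, ex)
  expect_false(anyNA(res))
  rec <- feature_manifest("recovery")
  recovery_vocab <- c("Age", "Height", "BMI", "Gender", "Protocol Type",
                      "Std. HR", "Min HR", "NNI 50", "PNNI 20",
                      "Ins DFA Slope 120", "Ins DFA Slope 180",
                      "DFA Slope 120", "DFA Slope 180", "Ex. Duration",
                      "SDSD", "NNI 20", "DFA Slope 60", "Max. Speed",
                      "Weight", "Median NNI", "PNNI 50", "Max. HR",
                      "Range NNI", "SDNN", "CVNNI")
  expect_false(anyNA(resolve_feature_name(recovery_vocab, rec)))
})

test_that("the shipped YAML manifests match the in-code defaults", {
  for (ph in c("exercise", "recovery", "base")) {
    p <- system.file("extdata", paste0(ph, "_manifest.yaml"),
                     package = "vo2hrv")
    expect_identical(read_feature_manifest(p), feature_manifest(ph))
  }
  # round trip through a fresh file
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_feature_manifest(feature_manifest("recovery"), tmp)
  expect_identical(read_feature_manifest(tmp), feature_manifest("recovery"))
})

test_that("cohort feature tables carry targets and drop QC failures", {
  co <- .tiny_cohort(n = 6, seed = 23)
  tab <- build_feature_table(co$sessions, "exercise")
  expect_s3_class(tab, "feature_table")
  expect_identical(ncol(tab$X), 101L)
  expect_equal(tab$y,
               co$truth$vo2max_true[match(tab$subject_ids,
                                          co$truth$subject_id)])
  qc <- attr(tab, "qc")
  expect_identical(sum(qc$kept), length(tab$subject_ids))
})
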