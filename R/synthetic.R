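# Synthetic graded-exercise-test (GET) cohort generator.
#
# The generator is first-class, tested code: it produces cohorts with the
# statistical structure the estimation pipeline assumes -- a noisy monotone
# link between true VO2max and maximal treadmill speed, first-order HR
# kinetics toward an individual maximum, RR variability that shrinks with
# intensity and recovers over the 3-min cool-down (faster in fitter
# subjects), injected spike/ectopic artifacts with recorded ground truth, and
# a configurable fraction of "deviant" subjects whose maximal speed is
# decoupled from their fitness.

# Physiological constants of the generator. They are plumbing, not estimates:
# chosen so the qualitative claims the analysis relies on (HR-VO2 linearity,
# vagal withdrawal with intensity, faster recovery with fitness) hold
# literally in simulation. Each is addressable by name.
gxt_constants <- function() {
  list(vo2_base_male = 55, vo2_base_female = 47,   # mL/kg/min at age <= 20
       vo2_age_slope = 0.25,                       # decline per year past 20
       speed_intercept = 4, speed_slope = 0.22,    # km/h per mL/kg/min
       hrmax_intercept = 208, hrmax_age_slope = 0.7,  # Tanaka-style law
       tau_hr = 30,                                # HR on-kinetics (s)
       hr_target_exponent = 0.9,
       tau_rec_intercept = 80, tau_rec_slope = 0.6, tau_rec_floor = 20,
       recovery_hr_offset = 20,                    # plateau above rest (bpm)
       sigma0_intercept = 2, sigma0_slope = 0.25,  # RR noise scale (ms)
       sigma_exercise_drop = 0.8,                  # 5:1 rest-to-max ratio
       start_speed = 5, step_s = 60,               # protocol shape
       vo2_rest = 3.5)
}

#' Generate a synthetic GET cohort
#'
#' Draws subject physiology, simulates every session trace, injects beat
#' artifacts, and returns the sessions together with the ground truth needed
#' for recovery tests. Deterministic given `cfg$seed`. Ages are uniform on
#' 10--63 years; true VO2max is a gender baseline (55 male / 47 female) minus
#' 0.25 per year beyond age 20 plus Gaussian noise, clamped to 25--75;
#' maximal speed is `4 + 0.22 * vo2max` km/h plus noise; maximal HR follows
#' `208 - 0.7 * age` plus noise. Deviant subjects have their maximal speed
#' redrawn uniformly over the cohort's speed range, decoupling it from
#' fitness.
#'
#' @param cfg a [sim_config()].
#' @param traces simulate the session traces (default). With `traces =
#'   FALSE` only the physiology draw is performed -- the returned truth
#'   table is identical (each trace consumes an independent child seed), and
#'   `sessions` is empty; useful for statistical checks of the cohort-level
#'   laws.
#' @return A list with `sessions` (list of `gxt_session`) and `truth`
#'   (a data frame: `subject_id`, `vo2max_true`, `max_speed_true`,
#'   `hr_max_true`, `is_deviant`, `artifact_beats` as semicolon-joined
#'   indices).
#' @export
generate_cohort <- function(cfg = sim_config(), traces = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  k <- gxt_constants()
  n <- cfg$n_subjects
  withr::with_seed(cfg$seed, {
    age <- stats::runif(n, 10, 63)
    gender <- ifelse(stats::runif(n) < cfg$female_fraction, "female", "male")
    height <- ifelse(gender == "male", stats::rnorm(n, 175, 8),
                     stats::rnorm(n, 163, 7))
    bmi <- pmin(pmax(stats::rnorm(n, 23.5, 2.5), 17), 35)
    weight <- bmi * (height / 100)^2
    base <- ifelse(gender == "male", k$vo2_base_male, k$vo2_base_female)
    vo2max <- base - k$vo2_age_slope * pmax(age - 20, 0) +
      stats::rnorm(n, 0, cfg$vo2max_sd)
    vo2max <- pmin(pmax(vo2max, 25), 75)
    max_speed <- k$speed_intercept + k$speed_slope * vo2max +
      stats::rnorm(n, 0, cfg$speed_link_sd)
    hr_max <- k$hrmax_intercept - k$hrmax_age_slope * age +
      stats::rnorm(n, 0, cfg$hr_sd)
    hr_rest <- pmin(pmax(stats::rnorm(n, cfg$hr_rest_mean, cfg$hr_rest_sd), 40),
                    hr_max - 40)
    protocol <- ifelse(stats::runif(n) < cfg$incremental_fraction,
                       "incremental", "step")
    n_dev <- round(cfg$deviant_fraction * n)
    deviant <- rep(FALSE, n)
    if (n_dev > 0) {
      idx <- sample.int(n, n_dev)
      deviant[idx] <- TRUE
      lo <- min(max_speed); hi <- max(max_speed)
      # a deviant's speed is redrawn uniformly over the cohort range, but
      # outside a 3-sigma margin of the speed its fitness would predict:
      # a deviant pair must actually lie off the primary cluster
      margin <- 3 * cfg$speed_link_sd
      expected <- k$speed_intercept + k$speed_slope * vo2max[idx]
      for (j in seq_along(idx)) {
        repeat {
          draw <- stats::runif(1, lo, hi)
          if (abs(draw - expected[j]) > margin) break
        }
        max_speed[idx[j]] <- draw
      }
    }
    ids <- sprintf("S%04d", seq_len(n))
    sessions <- vector("list", n)
    artifacts <- character(n)
    for (i in seq_len(if (traces) n else 0L)) {
      subj <- list(subject_id = ids[i], age = age[i], gender = gender[i],
                   height = height[i], weight = weight[i],
                   vo2max_true = vo2max[i], max_speed_true = max_speed[i],
                   hr_max = hr_max[i], hr_rest = hr_rest[i])
      s <- simulate_trace(subj, protocol[i], seed = child_seed(cfg$seed, i),
                          recovery_s = cfg$recovery_s,
                          vo2_noise_sd = cfg$vo2_noise_sd)
      inj <- inject_artifacts(s$rr, cfg$ectopic_rate, cfg$spike_rate,
                              seed = child_seed(cfg$seed, n + i))
      s$rr <- inj$rr
      # the monitor records the artifact-laden beat stream
      s$trace$hr <- stats::approx(inj$rr$beat_time_s, 60000 / inj$rr$rr_ms,
                                  xout = s$trace$time, rule = 2)$y
      sessions[[i]] <- s
      artifacts[i] <- paste(inj$injected_beats, collapse = ";")
    }
    truth <- data.frame(subject_id = ids, vo2max_true = vo2max,
                        max_speed_true = max_speed, hr_max_true = hr_max,
                        is_deviant = deviant, artifact_beats = artifacts,
                        stringsAsFactors = FALSE)
    list(sessions = sessions, truth = truth)
  })
}

#' Simulate one session's breath-by-breath trace and beat series
#'
#' Speed follows the chosen protocol (step: start 5 km/h, +1 km/h per 60 s,
#' final 60-s stage at the subject's maximal speed; incremental: linear ramp
#' over the same total duration). HR obeys first-order kinetics
#' `dHR/dt = (HRtarget - HR)/tau` with `tau = 30 s` and a target rising with
#' relative speed to the 0.9 power; over recovery (speed 0) HR decays
#' exponentially toward rest + 20 bpm with a time constant of
#' `80 - 0.6 * VO2max` s (floored at 20 s), so fitter subjects recover
#' faster. VO2 is an affine function of the HR reserve fraction plus noise.
#' Beats are generated by integrating RR = 60000/HR plus a variability term
#' whose scale shrinks by 80 percent from rest to maximal intensity and
#' re-expands linearly over recovery; the breath-by-breath HR column is the
#' instantaneous beat HR linearly resampled to the 1-s grid.
#'
#' @param subject list with `subject_id`, `age`, `gender`, `height`, `weight`,
#'   `vo2max_true`, `max_speed_true`, `hr_max`, `hr_rest`.
#' @param protocol `"step"` or `"incremental"`.
#' @param seed integer seed.
#' @param recovery_s recovery duration (s).
#' @param vo2_noise_sd breath-by-breath VO2 noise (mL/kg/min).
#' @return A `gxt_session` object.
#' @export
simulate_trace <- function(subject, protocol = c("step", "incremental"),
                           seed = 1, recovery_s = 180, vo2_noise_sd = 1) {
  protocol <- match.arg(protocol)
  k <- gxt_constants()
  vmax <- subject$max_speed_true
  if (vmax <= k$start_speed)
    degenerate_error("maximal speed at or below protocol start speed")
  hr_max <- subject$hr_max
  hr_rest <- subject$hr_rest
  vo2max <- subject$vo2max_true
  stages <- c(k$start_speed:floor(vmax), if (vmax > floor(vmax)) vmax)
  t_ex <- k$step_s * length(stages)
  t_tot <- t_ex + recovery_s
  tt <- 0:t_tot
  speed <- ifelse(tt < t_ex,
                  if (protocol == "step") {
                    pmin(k$start_speed + floor(tt / k$step_s), vmax)
                  } else {
                    k$start_speed + (vmax - k$start_speed) * tt / t_ex
                  }, 0)
  speed[tt >= t_ex] <- 0

  withr::with_seed(seed, {
    # first-order HR kinetics on the 1-s grid during exercise
    hr <- numeric(length(tt))
    hr[1] <- hr_rest
    n_ex <- sum(tt < t_ex)
    for (j in seq_len(n_ex)) {
      target <- hr_rest + (hr_max - hr_rest) *
        (speed[j] / vmax)^k$hr_target_exponent
      hr[j + 1] <- hr[j] + (target - hr[j]) / k$tau_hr
    }
    # analytic exponential recovery
    tau_rec <- max(k$tau_rec_floor,
                   k$tau_rec_intercept - k$tau_rec_slope * vo2max)
    plateau <- hr_rest + k$recovery_hr_offset
    hr_end <- hr[n_ex + 1]
    rec_idx <- which(tt >= t_ex)
    hr[rec_idx] <- plateau + (hr_end - plateau) * exp(-(tt[rec_idx] - t_ex) / tau_rec)

    vo2 <- k$vo2_rest + (vo2max - k$vo2_rest) *
      (hr - hr_rest) / (hr_max - hr_rest) +
      stats::rnorm(length(tt), 0, vo2_noise_sd)

    # beat-by-beat RR with intensity-dependent variability
    sigma0 <- k$sigma0_intercept + k$sigma0_slope * (vo2max - 25)
    phi1 <- stats::runif(1, 0, 2 * pi)
    phi2 <- stats::runif(1, 0, 2 * pi)
    n_guess <- ceiling(t_tot * 4) + 16L
    noise <- stats::rnorm(n_guess)
    rr_ms <- numeric(n_guess)
    n_grid <- length(tt)
    tb <- 0
    nb <- 0L
    while (TRUE) {
      # inline linear interpolation on the 1-s grid (hot loop)
      j <- min(floor(tb), n_grid - 2)
      hr_b <- hr[j + 1] + (tb - j) * (hr[j + 2] - hr[j + 1])
      if (tb < t_ex) {
        sp <- if (protocol == "step") min(k$start_speed + floor(tb / k$step_s), vmax)
              else k$start_speed + (vmax - k$start_speed) * tb / t_ex
        sig <- sigma0 * (1 - k$sigma_exercise_drop * sp / vmax)
      } else {
        sig <- sigma0 * (0.2 + 0.8 * min(tb - t_ex, recovery_s) / recovery_s)
      }
      v <- sig * (noise[nb + 1L] +
                    0.5 * sin(2 * pi * 0.1 * tb + phi1) +
                    0.5 * sin(2 * pi * 0.3 * tb + phi2))
      rr <- max(60000 / hr_b + v, 250)
      if (tb + rr / 1000 > t_tot) break
      nb <- nb + 1L
      rr_ms[nb] <- rr
      tb <- tb + rr / 1000
      if (nb >= n_guess) {  # HR above 4 Hz never happens, but stay safe
        noise <- c(noise, stats::rnorm(n_guess))
        rr_ms <- c(rr_ms, numeric(n_guess))
        n_guess <- length(rr_ms)
      }
    }
    rr <- rr_series(rr_ms[seq_len(nb)])
    trace <- data.frame(time = tt, speed = speed,
                        hr = stats::approx(rr$beat_time_s, 60000 / rr$rr_ms,
                                           xout = tt, rule = 2)$y,
                        vo2 = vo2)
    gxt_session(subject_id = subject$subject_id, age = subject$age,
                gender = subject$gender, height = subject$height,
                weight = subject$weight,
                protocol_type = protocol, trace = trace,
                exercise_end_time = t_ex, recovery_end_time = t_tot,
                vo2max_measured = vo2max, rr = rr)
  })
}

#' Inject spike and ectopic artifacts into an RR series
#'
#' Emulates the corruption the cleaning stage must undo, with recorded ground
#' truth. An ectopic event replaces the interval pair `(d, d')` at beats
#' `(i, i+1)` by `(0.5 d, d' + 0.5 d)` (a premature beat with compensatory
#' pause, preserving total time); a spike event sets one beat outside the
#' 300--2000 ms physiological range.
#'
#' @param rr an [rr_series()].
#' @param ectopic_rate,spike_rate per-beat event rates in `[0, 1]`.
#' @param seed integer seed.
#' @return A list: `rr` (corrupted series), `injected_beats` (sorted beat
#'   indices touched by any event), `ectopic_beats`, `spike_beats`.
#' @export
inject_artifacts <- function(rr, ectopic_rate = 0.001, spike_rate = 0.005,
                             seed = 1) {
  rr <- as_rr(rr)
  if (ectopic_rate < 0 || ectopic_rate > 1 || spike_rate < 0 || spike_rate > 1)
    config_error("artifact rates must lie in [0, 1]")
  n <- length(rr$rr_ms)
  if (n == 0L)
    return(list(rr = rr, injected_beats = integer(), ectopic_beats = integer(),
                spike_beats = integer()))
  withr::with_seed(seed, {
    x <- rr$rr_ms
    ect <- which(stats::runif(n) < ectopic_rate)
    ect <- ect[ect < n]
    ect <- ect[c(TRUE, diff(ect) > 1)]  # no overlapping pairs
    for (i in ect) {
      d <- x[i]
      x[i] <- 0.5 * d
      x[i + 1] <- x[i + 1] + 0.5 * d
    }
    spike_pool <- setdiff(which(stats::runif(n) < spike_rate),
                          c(ect, ect + 1L))
    for (i in spike_pool) {
      x[i] <- if (stats::runif(1) < 0.5) stats::runif(1, 100, 280)
              else stats::runif(1, 2100, 3200)
    }
    touched <- sort(unique(c(ect, ect + 1L, spike_pool)))
    list(rr = rr_series(x, t0_s = rr$beat_time_s[1] - rr$rr_ms[1] / 1000),
         injected_beats = touched,
         ectopic_beats = sort(unique(c(ect, ect + 1L))),
         spike_beats = sort(spike_pool))
  })
}
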