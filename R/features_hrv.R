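# Beat-level HRV features: time domain, Welch spectral band powers,
# Poincare / DFA nonlinear indices, and sliding-window slope variants.

time_domain_names <- c("Mean NNI", "Median NNI", "SDNN", "SDSD", "RMSSD",
                       "CVNNI", "CVSD", "NNI 20", "PNNI 20", "NNI 50",
                       "PNNI 50", "Range NNI")

#' Time-domain HRV features
#'
#' Standard descriptive statistics of the NN series: sample-SD conventions
#' (`n - 1` denominator) throughout, `NNI x` counts successive differences
#' with absolute value strictly above `x` ms, and `PNNI x` expresses that
#' count as a percentage of the `n - 1` successive differences. The
#' `NNI/PNNI` thresholds are absolute (ms), so they are intentionally not
#' scale-equivariant.
#'
#' @param rr an [rr_series()] or numeric RR vector (ms), length >= 2.
#' @return Named numeric vector: Mean NNI, Median NNI, SDNN, SDSD, RMSSD,
#'   CVNNI, CVSD, NNI 20, PNNI 20, NNI 50, PNNI 50, Range NNI.
#' @export
time_domain_features <- function(rr) {
  x <- as_rr(rr)$rr_ms
  n <- length(x)
  if (n < 2L) too_short_error("time-domain features need at least 2 beats")
  d <- diff(x)
  rmssd <- sqrt(mean(d^2))
  sdnn <- stats::sd(x)
  m <- mean(x)
  c("Mean NNI" = m, "Median NNI" = stats::median(x), SDNN = sdnn,
    SDSD = stats::sd(d), RMSSD = rmssd,
    CVNNI = sdnn / m, CVSD = rmssd / m,
    "NNI 20" = sum(abs(d) > 20), "PNNI 20" = 100 * sum(abs(d) > 20) / (n - 1),
    "NNI 50" = sum(abs(d) > 50), "PNNI 50" = 100 * sum(abs(d) > 50) / (n - 1),
    "Range NNI" = max(x) - min(x))
}

# Welch power spectral density: Hann-windowed, mean-removed segments with 50%
# overlap, one-sided density scaling. Returns freq (Hz) and psd (ms^2/Hz).
welch_psd <- function(x, fs, seg_len, overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1))
  scale <- fs * sum(w^2)
  nf <- floor(seg_len / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- abs(stats::fft(seg))^2 / scale
    p <- p[1:nf]
    if (seg_len %% 2 == 0) p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
    else p[2:nf] <- 2 * p[2:nf]
    acc <- acc + p
  }
  list(freq = (0:(nf - 1L)) * fs / seg_len, psd = acc / length(starts))
}

frequency_names <- c("VLF", "LF", "HF", "Total Power")

#' Frequency-domain HRV band powers
#'
#' The NN series is resampled to a uniform 4 Hz grid by cubic spline,
#' linearly detrended, and a Welch periodogram is computed (Hann window of
#' `min(256 s, segment length)`, 50 percent overlap). Band powers (ms^2) are
#' trapezoidal integrals of the density over VLF 0--0.04 Hz, LF
#' 0.04--0.15 Hz and HF 0.15--0.4 Hz; total power is their sum by
#' construction. Segments shorter than 120 s of beats yield all-NA values
#' (spectral estimates on shorter windows are unreliable, and the 3-min
#' recovery phase is excluded from spectral analysis altogether).
#'
#' @param rr an [rr_series()].
#' @param fs resampling rate (Hz).
#' @param min_duration_s minimal beat-span required for an estimate.
#' @return Named numeric vector: VLF, LF, HF, Total Power (ms^2).
#' @export
frequency_domain_features <- function(rr, fs = 4, min_duration_s = 120) {
  rr <- as_rr(rr)
  nas <- stats::setNames(rep(NA_real_, 4L), frequency_names)
  n <- length(rr$rr_ms)
  if (n < 8L) return(nas)
  tspan <- rr$beat_time_s[n] - rr$beat_time_s[1]
  if (tspan < min_duration_s) return(nas)
  grid <- seq(rr$beat_time_s[1], rr$beat_time_s[n], by = 1 / fs)
  nn <- stats::spline(rr$beat_time_s, rr$rr_ms, xout = grid)$y
  nn <- stats::resid(stats::lm.fit(cbind(1, grid), nn))
  ps <- welch_psd(nn, fs, seg_len = min(256 * fs, length(nn)))
  vlf <- trapz_band(ps$freq, ps$psd, 0, 0.04)
  lf <- trapz_band(ps$freq, ps$psd, 0.04, 0.15)
  hf <- trapz_band(ps$freq, ps$psd, 0.15, 0.4)
  c(VLF = vlf, LF = lf, HF = hf, "Total Power" = vlf + lf + hf)
}

nonlinear_names <- c("SD1", "SD2", "SD2/SD1", "CSI", "CVI",
                     "DFA Alpha 1", "DFA Alpha 2")

#' Nonlinear HRV features (Poincare and DFA)
#'
#' Poincare axes from the successive-difference identity
#' `SD1^2 = var(diff)/2`, `SD2^2 = 2 SDNN^2 - SD1^2`; CSI is the SD2/SD1
#' ratio and `CVI = log10(16 SD1 SD2)`. The short- and long-range detrended
#' fluctuation exponents use 4--16 and 16--64 beat box sizes and require at
#' least 20 and 70 beats respectively (NA otherwise). Degenerate input
#' (constant series, negative SD2^2) yields NA for the affected values
#' rather than an error, so missingness propagates to the feature table.
#'
#' @param rr an [rr_series()] or numeric RR vector (ms).
#' @param alpha2 compute the long-range exponent (skipped by the
#'   sliding-window slope path, where 60-s windows are too short for
#'   64-beat boxes to be meaningful).
#' @return Named numeric vector: SD1, SD2, SD2/SD1, CSI, CVI, DFA Alpha 1,
#'   DFA Alpha 2.
#' @export
nonlinear_features <- function(rr, alpha2 = TRUE) {
  x <- as_rr(rr)$rr_ms
  n <- length(x)
  if (n < 3L) too_short_error("nonlinear features need at least 3 beats")
  sd1 <- sqrt(stats::var(diff(x)) / 2)
  sd2sq <- 2 * stats::var(x) - sd1^2
  sd2 <- if (sd2sq >= 0) sqrt(sd2sq) else NA_real_
  # below 1e-6 ms SD1 is numerically zero (e.g. a window of linearly
  # interpolated beats); the ratio indices are then undefined, not huge
  ok1 <- sd1 > 1e-6
  ratio <- if (!is.na(sd2) && ok1) sd2 / sd1 else NA_real_
  cvi <- if (!is.na(sd2) && ok1 && sd2 > 1e-6) log10(16 * sd1 * sd2) else NA_real_
  a1 <- if (n >= 20L) try_dfa(x, 4L, 16L) else NA_real_
  a2 <- if (alpha2 && n >= 70L) try_dfa(x, 16L, 64L) else NA_real_
  c(SD1 = sd1, SD2 = sd2, "SD2/SD1" = ratio, CSI = ratio, CVI = cvi,
    "DFA Alpha 1" = a1, "DFA Alpha 2" = a2)
}

# short-exponent-only variant used on sliding windows
nonlinear_short <- function(w) nonlinear_features(w, alpha2 = FALSE)

try_dfa <- function(x, lo, hi) {
  tryCatch(dfa_alpha(x, lo, hi), vo2hrv_error = function(e) NA_real_)
}

#' Detrended fluctuation analysis scaling exponent
#'
#' Integrates the mean-centred series, partitions the profile into
#' non-overlapping boxes of every integer size in `scale_lo:scale_hi`,
#' removes a least-squares line from each box, and regresses the log RMS
#' fluctuation on log box size. White noise gives an exponent near 0.5,
#' Brownian (integrated) noise near 1.5.
#'
#' @param rr an [rr_series()] or numeric RR vector.
#' @param scale_lo,scale_hi box-size range in beats (4--16 for the short
#'   exponent, 16--64 for the long one).
#' @return The scaling exponent (slope of log F vs log n).
#' @export
dfa_alpha <- function(rr, scale_lo = 4, scale_hi = 16) {
  x <- as_rr(rr)$rr_ms
  n <- length(x)
  if (scale_lo < 2 || scale_lo >= scale_hi)
    config_error("need 2 <= scale_lo < scale_hi")
  if (n < scale_hi) too_short_error("series shorter than the largest DFA box")
  y <- cumsum(x - mean(x))
  scales <- seq.int(scale_lo, scale_hi)
  fn <- vapply(scales, function(s) {
    m <- n %/% s
    ymat <- matrix(y[seq_len(s * m)], nrow = s)
    t <- seq_len(s)
    # residual of a per-box least-squares line, all boxes at once
    tc <- t - mean(t)
    beta <- colSums(ymat * tc) / sum(tc^2)
    resid <- ymat - outer(tc, beta) - rep(colMeans(ymat), each = s)
    sqrt(mean(resid^2))
  }, numeric(1))
  if (any(fn == 0))
    degenerate_error("zero fluctuation at some scale; exponent undefined")
  ls_slope(log(scales), log(fn))
}

#' Sliding-window slope of beat-level features
#'
#' Evaluates a feature function on consecutive windows of the beat series
#' (default 60 s windows stepping 30 s) and returns, for every feature the
#' function emits, the least-squares slope of its value against the window
#' midpoint time. Windows where the function fails (too few beats) are
#' dropped; fewer than two valid windows yields NA.
#'
#' @param rr an [rr_series()].
#' @param feature_fn function mapping an `rr_series` to a named numeric
#'   vector, e.g. [time_domain_features()].
#' @param window_s,step_s window length and step (s).
#' @param suffix appended to the base feature names (default `" slope"`).
#' @return Named numeric vector of slopes (feature unit per second).
#' @export
slope_features <- function(rr, feature_fn = time_domain_features,
                           window_s = 60, step_s = 30, suffix = " slope") {
  rr <- as_rr(rr)
  t0 <- rr$beat_time_s[1] - rr$rr_ms[1] / 1000
  tend <- rr$beat_time_s[length(rr$rr_ms)]
  if (!length(rr$rr_ms) || tend - t0 < window_s)
    return(stats::setNames(NA_real_, paste0("window", suffix)))
  starts <- seq(t0, tend - window_s, by = step_s)
  vals <- lapply(starts, function(s) {
    w <- rr_window(rr, s, s + window_s)
    tryCatch(feature_fn(w), error = function(e) NULL)
  })
  ok <- !vapply(vals, is.null, logical(1))
  if (!any(ok)) return(stats::setNames(NA_real_, paste0("window", suffix)))
  vm <- do.call(rbind, vals[ok])
  mids <- starts[ok] + window_s / 2
  slopes <- apply(vm, 2L, function(col) ls_slope(mids, col))
  stats::setNames(slopes, paste0(colnames(vm), suffix))
}

#' Windowed DFA slope features
#'
#' The short-range DFA exponent is computed on 60-s windows stepping 15 s;
#' for each horizon `h` the windows whose midpoints fall within `[0, h]`
#' contribute. `DFA Slope h` is the least-squares slope of the exponent
#' against the window midpoint; `Ins DFA Slope h` is the mean of the
#' successive finite-difference slopes (the two coincide when the exponent
#' trajectory is exactly linear).
#'
#' @param rr an [rr_series()].
#' @param horizons horizons in seconds (default 60, 120, 180).
#' @param window_s,step_s exponent window length and step (s).
#' @return Named vector `DFA Slope h` and `Ins DFA Slope h` for each horizon.
#' @export
dfa_window_slopes <- function(rr, horizons = c(60, 120, 180),
                              window_s = 60, step_s = 15) {
  rr <- as_rr(rr)
  t0 <- rr$beat_time_s[1] - rr$rr_ms[1] / 1000
  tend <- rr$beat_time_s[length(rr$rr_ms)]
  out <- stats::setNames(rep(NA_real_, 2L * length(horizons)),
                         c(paste("DFA Slope", horizons),
                           paste("Ins DFA Slope", horizons)))
  if (tend - t0 < window_s) return(out)
  starts <- seq(t0, tend - window_s, by = step_s)
  mids <- starts + window_s / 2 - t0
  keep <- mids <= max(horizons)  # windows past every horizon are never used
  starts <- starts[keep]; mids <- mids[keep]
  if (!length(starts)) return(out)
  a1 <- vapply(starts, function(s) {
    w <- rr_window(rr, s, s + window_s)
    if (length(w$rr_ms) < 20L) return(NA_real_)
    try_dfa(w$rr_ms, 4L, 16L)
  }, numeric(1))
  for (h in horizons) {
    # the horizon must be reachable by a window midpoint (a 180-s segment
    # covers the 180-s horizon even though its beat span is a beat short)
    if (tend - t0 < h - window_s / 2) next
    sel <- mids <= h & is.finite(a1)
    if (sum(sel) < 2L) next
    v <- a1[sel]; m <- mids[sel]
    out[paste("DFA Slope", h)] <- ls_slope(m, v)
    out[paste("Ins DFA Slope", h)] <- mean(diff(v) / diff(m))
  }
  out
}
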