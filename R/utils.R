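# Internal helpers shared across modules.

# Classed error constructors: every user-facing failure carries one of these
# classes so callers (and tests) can distinguish format, integrity, config and
# too-short conditions without matching message text.
abort_vo2 <- function(class, msg, ...) {
  stop(errorCondition(msg, class = c(class, "vo2hrv_error", "error"), ...))
}
format_error    <- function(msg, ...) abort_vo2("vo2hrv_format_error", msg, ...)
integrity_error <- function(msg, ...) abort_vo2("vo2hrv_integrity_error", msg, ...)
config_error    <- function(msg, ...) abort_vo2("vo2hrv_config_error", msg, ...)
too_short_error <- function(msg, ...) abort_vo2("vo2hrv_too_short_error", msg, ...)
degenerate_error <- function(msg, ...) abort_vo2("vo2hrv_degenerate_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Least-squares slope of y on x, NA when fewer than 2 finite pairs or x constant.
ls_slope <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  vx <- stats::var(x)
  if (!is.finite(vx) || vx == 0) return(NA_real_)
  stats::cov(x, y) / vx
}

# Spearman rank correlation tolerant of constant input (returns NA instead of
# warning-laden cor()).
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

# Trapezoidal integral of y(x) over [lo, hi] with linear interpolation at the
# band edges, so adjacent bands tile an interval exactly.
trapz_band <- function(x, y, lo, hi) {
  if (hi <= x[1] || lo >= x[length(x)]) return(0)
  lo <- max(lo, x[1]); hi <- min(hi, x[length(x)])
  inner <- x > lo & x < hi
  xs <- c(lo, x[inner], hi)
  ys <- c(stats::approx(x, y, xout = lo)$y, y[inner], stats::approx(x, y, xout = hi)$y)
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

# Derive a child seed that stays within 32-bit integer range.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000 + i) %% .Machine$integer.max)
}
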