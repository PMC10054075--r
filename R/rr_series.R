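#' RR-interval series
#'
#' A beat-by-beat series of RR intervals with per-beat quality flags. Beat
#' times are the cumulative sums of the intervals, so the series is fully
#' determined by `rr_ms`; flags record the cleaning history of each beat
#' (`"ok"`, `"range_outlier"`, `"ectopic"`, `"interpolated"`).
#'
#' @param rr_ms positive RR intervals in milliseconds.
#' @param flags optional per-beat flag vector (defaults to all `"ok"`).
#' @param t0_s time of the first beat's onset (s); beat times are
#'   `t0_s + cumsum(rr_ms)/1000`.
#'
#' @return An object of class `rr_series`: a list with `rr_ms`, `beat_time_s`
#'   and `flags`.
#' @export
rr_series <- function(rr_ms, flags = NULL, t0_s = 0) {
  rr_ms <- as.numeric(rr_ms)
  if (length(rr_ms) && any(!is.finite(rr_ms) | rr_ms <= 0))
    integrity_error("RR intervals must be positive and finite")
  flags <- flags %||% rep("ok", length(rr_ms))
  if (length(flags) != length(rr_ms))
    integrity_error("flags must have one entry per beat")
  bad <- setdiff(unique(flags), c("ok", "range_outlier", "ectopic", "interpolated"))
  if (length(bad)) integrity_error(paste("unknown beat flag:", bad[1]))
  structure(list(rr_ms = rr_ms,
                 beat_time_s = t0_s + cumsum(rr_ms) / 1000,
                 flags = flags),
            class = "rr_series")
}

#' @export
length.rr_series <- function(x) length(x$rr_ms)

#' @export
print.rr_series <- function(x, ...) {
  n <- length(x$rr_ms)
  cat(sprintf("<rr_series> %d beats, %.1f s, flags: %s\n", n,
              if (n) x$beat_time_s[n] - x$beat_time_s[1] + x$rr_ms[1] / 1000 else 0,
              paste(names(table(x$flags)), table(x$flags), sep = "=", collapse = " ")))
  invisible(x)
}

as_rr <- function(x) {
  if (inherits(x, "rr_series")) x else rr_series(x)
}

# Subset an rr_series by beat time window (lo, hi], re-zeroing time.
rr_window <- function(rr, lo_s, hi_s) {
  keep <- rr$beat_time_s > lo_s & rr$beat_time_s <= hi_s
  rr_series(rr$rr_ms[keep], flags = rr$flags[keep])
}
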