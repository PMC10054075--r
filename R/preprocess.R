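# RR cleaning and segment quality control.
#
# Cleaning chain: (1) physiological range filter, (2) Karlsson ectopic
# detection against the mean of adjacent intervals, (3) linear interpolation
# of every flagged beat. The chain never changes the number of beats and is
# idempotent on its own output.

#' Flag RR intervals outside the physiological range
#'
#' Beats strictly below `lo_ms` or strictly above `hi_ms` are flagged
#' `"range_outlier"`; the bounds themselves are accepted. Values are never
#' modified here.
#'
#' @param rr an [rr_series()] (or a bare numeric RR vector).
#' @param lo_ms,hi_ms inclusive physiological bounds, default 300 and 2000 ms.
#' @return The series with updated flags.
#' @export
filter_rr_range <- function(rr, lo_ms = 300, hi_ms = 2000) {
  rr <- as_rr(rr)
  if (!length(rr$rr_ms)) return(rr)
  if (lo_ms >= hi_ms) config_error("lo_ms must be smaller than hi_ms")
  out <- rr$rr_ms < lo_ms | rr$rr_ms > hi_ms
  rr$flags[out] <- "range_outlier"
  rr
}

#' Karlsson ectopic-beat detection
#'
#' An interior beat is called ectopic when its interval deviates from the mean
#' of its adjacent intervals by strictly more than `rel_threshold` times that
#' mean; the first and last beats are compared to their single neighbour.
#' Neighbours already flagged as range outliers are skipped: the nearest
#' unflagged beat on each side serves as reference.
#'
#' @param rr an [rr_series()], length at least 3.
#' @param rel_threshold relative deviation threshold (default 0.2 = 20%).
#' @return The series with `"ectopic"` flags added.
#' @export
detect_ectopic_karlsson <- function(rr, rel_threshold = 0.2) {
  rr <- as_rr(rr)
  n <- length(rr$rr_ms)
  if (n < 3L) too_short_error("Karlsson detection needs at least 3 beats")
  usable <- rr$flags != "range_outlier"
  if (sum(usable) < 2L) return(rr)
  x <- rr$rr_ms
  # nearest usable beat strictly before / after each position (0 and n+1 are
  # "none" sentinels), computed with cumulative extrema to stay O(n)
  p <- ifelse(usable, seq_len(n), 0L)
  prev_ok <- c(0L, cummax(p)[-n])
  q <- ifelse(usable, seq_len(n), n + 1L)
  nxt_ok <- c(rev(cummin(rev(q)))[-1L], n + 1L)
  left_val  <- ifelse(prev_ok > 0L, x[pmax(prev_ok, 1L)], NA_real_)
  right_val <- ifelse(nxt_ok <= n, x[pmin(nxt_ok, n)], NA_real_)
  m <- rowMeans(cbind(left_val, right_val), na.rm = TRUE)
  hit <- usable & is.finite(m) & abs(x - m) > rel_threshold * m
  rr$flags[hit] <- "ectopic"
  rr
}

#' Replace flagged beats by linear interpolation
#'
#' Every beat flagged `"range_outlier"` or `"ectopic"` is replaced by linear
#' interpolation of the RR value over beat index between the nearest unflagged
#' neighbours; leading/trailing flagged runs take the nearest unflagged value.
#' Replaced beats are re-flagged `"interpolated"` and beat times are rebuilt
#' from the corrected intervals.
#'
#' @param rr an [rr_series()] with at least two unflagged beats.
#' @return The corrected series.
#' @export
interpolate_flagged <- function(rr) {
  rr <- as_rr(rr)
  bad <- rr$flags %in% c("range_outlier", "ectopic")
  if (!any(bad)) return(rr)
  good <- which(!bad)
  if (length(good) < 2L)
    integrity_error("fewer than 2 unflagged beats; series unrecoverable")
  x <- rr$rr_ms
  x[bad] <- stats::approx(good, x[good], xout = which(bad), rule = 2)$y
  flags <- rr$flags
  flags[bad] <- "interpolated"
  rr_series(x, flags = flags, t0_s = rr$beat_time_s[1] - rr$rr_ms[1] / 1000)
}

#' Full RR cleaning chain
#'
#' Range filter, Karlsson detection and interpolation in sequence, using the
#' thresholds in `cfg`. Beat count is preserved and the chain is idempotent.
#'
#' @param rr an [rr_series()].
#' @param cfg a [pipeline_config()].
#' @return The cleaned series.
#' @export
clean_rr <- function(rr, cfg = pipeline_config()) {
  rr <- filter_rr_range(rr, cfg$rr_min_ms, cfg$rr_max_ms)
  if (length(rr$rr_ms) >= 3L)
    rr <- detect_ectopic_karlsson(rr, cfg$karlsson_threshold)
  interpolate_flagged(rr)
}

#' Clean a session's beat series and rebuild its HR trace
#'
#' Applies [clean_rr()] to the session's RR series and re-derives the
#' breath-by-breath HR column by linear interpolation of the instantaneous
#' beat HR (60000/RR) onto the 1-s trace grid, so that downstream quality
#' control sees the artifact-corrected heart rate.
#'
#' @param session a `gxt_session`.
#' @param cfg a [pipeline_config()].
#' @return The session with cleaned `rr` and updated trace HR.
#' @export
preprocess_session <- function(session, cfg = pipeline_config()) {
  stopifnot(inherits(session, "gxt_session"))
  rr <- clean_rr(session$rr, cfg)
  session$rr <- rr
  inst_hr <- 60000 / rr$rr_ms
  hr <- stats::approx(rr$beat_time_s, inst_hr, xout = session$trace$time,
                      rule = 2)$y
  keep_na <- is.na(session$trace$hr)  # preserve recorded gaps
  session$trace$hr <- hr
  session$trace$hr[keep_na] <- NA_real_
  session
}

#' Segment quality control
#'
#' Applies the four segment rules to one phase of a (preprocessed) session:
#' \describe{
#'   \item{out_of_phase}{HR and VO2 trends disagree: Spearman correlation of
#'     HR and VO2 over the exercise phase below `cfg$phase_rho_threshold`.}
#'   \item{hr_jump}{some consecutive HR samples differ by more than
#'     `cfg$hr_jump_bpm` after cleaning.}
#'   \item{too_short}{exercise phase shorter than `cfg$min_segment_s`
#'     (recovery has its fixed 3-min design length and is exempt).}
#'   \item{missing_values}{missing HR or VO2 samples in the phase.}
#' }
#'
#' @param session a `gxt_session`, ideally after [preprocess_session()].
#' @param phase `"exercise"` or `"recovery"`.
#' @param cfg a [pipeline_config()].
#' @return A list with `subject_id`, `phase`, `kept` and `reasons`
#'   (`kept` is `TRUE` exactly when `reasons` is empty).
#' @export
qc_segment <- function(session, phase = c("exercise", "recovery"),
                       cfg = pipeline_config()) {
  stopifnot(inherits(session, "gxt_session"))
  if (!is.character(phase) || !phase[1] %in% c("exercise", "recovery"))
    config_error(paste("unknown phase label:", phase[1]))
  phase <- phase[1]
  tr <- session$trace
  seg <- if (phase == "exercise") {
    tr[tr$time <= session$exercise_end_time, , drop = FALSE]
  } else {
    tr[tr$time > session$exercise_end_time &
         tr$time <= session$recovery_end_time, , drop = FALSE]
  }
  ex <- tr[tr$time <= session$exercise_end_time, , drop = FALSE]
  reasons <- character()
  if (anyNA(seg$hr) || anyNA(seg$vo2)) reasons <- c(reasons, "missing_values")
  if (any(abs(diff(seg$hr)) > cfg$hr_jump_bpm, na.rm = TRUE))
    reasons <- c(reasons, "hr_jump")
  if (phase == "exercise" &&
      (nrow(seg) < 2L || diff(range(seg$time)) < cfg$min_segment_s))
    reasons <- c(reasons, "too_short")
  rho <- spearman(ex$hr, ex$vo2)
  if (!is.na(rho) && rho < cfg$phase_rho_threshold)
    reasons <- c(reasons, "out_of_phase")
  list(subject_id = session$subject_id, phase = phase,
       kept = length(reasons) == 0L, reasons = reasons)
}

#' Cohort-level quality control report
#'
#' Runs [preprocess_session()] and [qc_segment()] for both phases of every
#' session and assembles the results in one data frame (one row per session
#' and phase; reasons are comma-joined).
#'
#' @param sessions list of `gxt_session` objects.
#' @param cfg a [pipeline_config()].
#' @return A data frame with columns `subject_id`, `phase`, `kept`, `reasons`.
#' @export
qc_cohort <- function(sessions, cfg = pipeline_config()) {
  rows <- lapply(sessions, function(s) {
    ps <- preprocess_session(s, cfg)
    do.call(rbind, lapply(c("exercise", "recovery"), function(ph) {
      q <- qc_segment(ps, ph, cfg)
      data.frame(subject_id = q$subject_id, phase = q$phase, kept = q$kept,
                 reasons = paste(q$reasons, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
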