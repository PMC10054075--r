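#' Graded-exercise-test session record
#'
#' One subject's metadata, breath-by-breath trace, phase boundaries, beat
#' series and measured VO2max. The constructor validates the structural
#' invariants: strictly increasing trace times, ordered phase boundaries, and
#' BMI consistent with height and weight.
#'
#' @param subject_id opaque subject identifier.
#' @param age years.
#' @param gender `"male"` or `"female"`.
#' @param height cm.
#' @param weight kg.
#' @param protocol_type `"step"` or `"incremental"`.
#' @param trace data frame with columns `time` (s), `speed` (km/h), `hr`
#'   (bpm) and `vo2` (mL/kg/min).
#' @param exercise_end_time,recovery_end_time phase boundaries (s).
#' @param vo2max_measured criterion VO2max (mL/kg/min).
#' @param rr optional [rr_series()] of beat intervals.
#' @param bmi kg/m^2; derived from height and weight when omitted.
#'
#' @return An object of class `gxt_session`.
#' @export
gxt_session <- function(subject_id, age, gender, height, weight,
                        protocol_type, trace, exercise_end_time,
                        recovery_end_time, vo2max_measured, rr = NULL,
                        bmi = NULL) {
  required <- c("time", "speed", "hr", "vo2")
  missing_cols <- setdiff(required, names(trace))
  if (length(missing_cols))
    format_error(paste("trace is missing column:", missing_cols[1]),
                 column = missing_cols[1])
  if (!gender %in% c("male", "female"))
    format_error("gender must be 'male' or 'female'")
  if (!protocol_type %in% c("step", "incremental"))
    format_error("protocol_type must be 'step' or 'incremental'")
  tm <- trace$time
  if (anyNA(tm) || any(diff(tm) <= 0))
    integrity_error("trace times must be strictly increasing")
  if (!(exercise_end_time <= recovery_end_time &&
        recovery_end_time <= tm[length(tm)] + 1e-9))
    integrity_error("phase boundaries must satisfy exercise_end <= recovery_end <= last time")
  derived_bmi <- weight / (height / 100)^2
  if (is.null(bmi)) bmi <- derived_bmi
  if (abs(bmi - derived_bmi) > 1e-6)
    integrity_error("bmi inconsistent with height and weight")
  structure(list(subject_id = as.character(subject_id), age = age,
                 gender = gender, height = height, weight = weight, bmi = bmi,
                 protocol_type = protocol_type,
                 trace = trace[required],
                 exercise_end_time = exercise_end_time,
                 recovery_end_time = recovery_end_time,
                 vo2max_measured = vo2max_measured, rr = rr),
            class = "gxt_session")
}

#' @export
print.gxt_session <- function(x, ...) {
  cat(sprintf("<gxt_session> %s: %s, age %.0f, %s protocol, %.0f s exercise + %.0f s recovery, VO2max %.1f\n",
              x$subject_id, x$gender, x$age, x$protocol_type,
              x$exercise_end_time, x$recovery_end_time - x$exercise_end_time,
              x$vo2max_measured))
  invisible(x)
}
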