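# Session-level speed/time/HR landmark features and the feature manifests
# that fix the composition and order of the exercise (101) and recovery (30)
# feature vectors.

#' Speed, time and HR landmark features of the exercise phase
#'
#' For each quartile Q in 25/50/75/100 percent:
#' \describe{
#'   \item{TimeSpQ}{first time treadmill speed reaches Q percent of maximal
#'     speed (s).}
#'   \item{SlopeSpQ / RSpQ}{least-squares slope of HR vs time, and Pearson
#'     correlation of speed and HR, over `[0, TimeSpQ]`.}
#'   \item{SlopeTQ / RTQ}{the same two quantities over the first Q percent of
#'     total exercise time.}
#'   \item{TimeHRQ}{first time HR reaches Q percent of maximal HR (s).}
#'   \item{HR MAX Q}{maximal HR within the first Q percent of exercise time.}
#' }
#' `DurationHRz` is the time (s) spent with HR in `[z-10, z)` percent of
#' maximal HR for z in 60..100; `DurationSpz` the time with speed in
#' `[z-20, z)` percent of maximal speed for z in 20..100. Summaries
#' (`Max. Speed`, `Ex. Duration`, `Max. HR`, `Min HR`, `Mean HR`, `Std. HR`,
#' `HR Reserve`) complete the set. Landmark spans with fewer than 3 samples
#' yield NA for their slope/correlation features.
#'
#' @param session a `gxt_session`.
#' @return Named numeric vector of the 43 landmark and summary features.
#' @export
session_speed_time_features <- function(session) {
  stopifnot(inherits(session, "gxt_session"))
  tr <- session$trace
  ex <- tr[tr$time <= session$exercise_end_time, , drop = FALSE]
  t <- ex$time; hr <- ex$hr; sp <- ex$speed
  t_ex <- session$exercise_end_time
  max_sp <- max(sp, na.rm = TRUE)
  max_hr <- max(tr$hr, na.rm = TRUE)
  out <- c("Max. Speed" = max_sp, "Ex. Duration" = t_ex,
           "Max. HR" = max_hr, "Min HR" = min(hr, na.rm = TRUE),
           "Mean HR" = mean(hr, na.rm = TRUE),
           "Std. HR" = stats::sd(hr, na.rm = TRUE),
           "HR Reserve" = max_hr - min(hr, na.rm = TRUE))
  span_stats <- function(idx) {
    if (sum(idx, na.rm = TRUE) < 3L) return(c(NA_real_, NA_real_))
    c(ls_slope(t[idx], hr[idx]),
      tryCatch(stats::cor(sp[idx], hr[idx], use = "complete.obs"),
               error = function(e) NA_real_))
  }
  for (q in c(25, 50, 75, 100)) {
    hit <- which(sp >= q / 100 * max_sp)
    tq <- if (length(hit)) t[hit[1]] else NA_real_
    out[paste0("TimeSp", q)] <- tq
    ss <- span_stats(!is.na(tq) & t <= tq)
    out[paste0("SlopeSp", q)] <- ss[1]
    out[paste0("RSp", q)] <- ss[2]
    st <- span_stats(t <= q / 100 * t_ex)
    out[paste0("SlopeT", q)] <- st[1]
    out[paste0("RT", q)] <- st[2]
    hh <- which(hr >= q / 100 * max_hr)
    out[paste0("TimeHR", q)] <- if (length(hh)) t[hh[1]] else NA_real_
    out[paste0("HR MAX ", q)] <- max(hr[t <= q / 100 * t_ex], na.rm = TRUE)
  }
  dt <- c(diff(t), 0)  # per-sample dwell time
  for (z in seq(60, 100, by = 10)) {
    inz <- hr >= (z - 10) / 100 * max_hr & hr < z / 100 * max_hr
    out[paste0("DurationHR", z)] <- sum(dt[inz], na.rm = TRUE)
  }
  for (z in seq(20, 100, by = 20)) {
    inz <- sp >= (z - 20) / 100 * max_sp & sp < z / 100 * max_sp
    out[paste0("DurationSp", z)] <- sum(dt[inz], na.rm = TRUE)
  }
  out
}

#' Feature manifests
#'
#' The manifest fixes the names, families and order of the feature vector a
#' phase produces: 101 features for exercise, 30 for recovery, and a 9-entry
#' "base" manifest (metadata plus maximal speed, exercise duration and
#' maximal HR) matching the reference-model feature set. Frequency-domain
#' families never appear in the recovery manifest because the 3-min recovery
#' window is too short for spectral estimation.
#'
#' @param phase `"exercise"`, `"recovery"` or `"base"`.
#' @return A data frame with columns `name` and `family`.
#' @export
feature_manifest <- function(phase = c("exercise", "recovery", "base")) {
  phase <- match.arg(phase)
  block <- function(names, family)
    data.frame(name = names, family = family, stringsAsFactors = FALSE)
  meta <- block(c("Age", "Gender", "Height", "Weight", "BMI", "Protocol Type"),
                "metadata")
  if (phase == "base") {
    return(rbind(meta,
                 block(c("Max. Speed", "Ex. Duration", "Max. HR"), "session")))
  }
  session6 <- block(c("Max. Speed", "Ex. Duration", "Max. HR", "Min HR",
                      "Mean HR", "Std. HR"), "session")
  if (phase == "recovery") {
    td11 <- setdiff(time_domain_names, "CVSD")
    return(rbind(meta, session6,
                 block(td11, "time_domain"),
                 block(c("SD1", "SD2"), "nonlinear"),
                 block(c("DFA Slope 60", "DFA Slope 120", "DFA Slope 180",
                         "Ins DFA Slope 120", "Ins DFA Slope 180"),
                       "dfa_window")))
  }
  nl6 <- c("SD1", "SD2", "SD2/SD1", "CSI", "CVI", "DFA Alpha 1")
  rbind(meta, session6,
        block(time_domain_names, "time_domain"),
        block(paste(time_domain_names, "slope"), "time_domain_slope"),
        block(frequency_names, "frequency"),
        block(paste(frequency_names, "slope"), "frequency_slope"),
        block(nl6, "nonlinear"),
        block(paste(nl6, "slope"), "nonlinear_slope"),
        block(c("DFA Slope 60", "DFA Slope 120", "DFA Slope 180",
                "Ins DFA Slope 60", "Ins DFA Slope 120", "Ins DFA Slope 180"),
              "dfa_window"),
        block(c(paste0("SlopeSp", c(25, 50, 75, 100)),
                paste0("RSp", c(25, 50, 75, 100)),
                paste0("TimeSp", c(25, 50, 75, 100))), "speed_quartile"),
        block(c(paste0("RT", c(25, 50, 75, 100)),
                paste0("SlopeT", c(25, 50, 75, 100))), "time_quartile"),
        block(c(paste0("TimeHR", c(25, 50, 75, 100)),
                paste0("HR MAX ", c(25, 50, 75, 100))), "hr_quartile"),
        block(paste0("DurationHR", seq(60, 100, 10)), "hr_zone"),
        block(paste0("DurationSp", seq(20, 100, 20)), "speed_zone"),
        block("HR Reserve", "session"))
}

#' Read / write a feature manifest as YAML
#'
#' The canonical manifests ship with the package under
#' `system.file("extdata", ...)`; a manifest edited on disk can be passed to
#' [assemble_features()] and [build_feature_table()] to change the feature
#' composition without touching code.
#'
#' @param manifest a manifest data frame.
#' @param path YAML file path.
#' @return `write_feature_manifest()` returns `path` invisibly;
#'   `read_feature_manifest()` returns the manifest data frame.
#' @export
write_feature_manifest <- function(manifest, path) {
  yaml::write_yaml(list(features = lapply(seq_len(nrow(manifest)), function(i)
    list(name = manifest$name[i], family = manifest$family[i]))), path)
  invisible(path)
}

#' @rdname write_feature_manifest
#' @export
read_feature_manifest <- function(path) {
  if (!file.exists(path)) format_error(paste("no such manifest:", path))
  raw <- yaml::read_yaml(path)$features
  data.frame(name = vapply(raw, `[[`, "", "name"),
             family = vapply(raw, `[[`, "", "family"),
             stringsAsFactors = FALSE)
}

#' Resolve a published feature-name variant to its manifest entry
#'
#' Feature names circulate in several spellings (`"Max. speed"`,
#' `"R TIME 75"` for `RT75`, `"HR MAX 25"`). Matching is case-insensitive,
#' ignores punctuation and whitespace, and applies a small alias table.
#'
#' @param name character vector of names to resolve.
#' @param manifest a manifest from [feature_manifest()].
#' @return The canonical manifest names; NA where no entry matches.
#' @export
resolve_feature_name <- function(name, manifest = feature_manifest("exercise")) {
  norm <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  key <- norm(name)
  key <- sub("^rtime([0-9]+)$", "rt\\1", key)
  key <- sub("^dfaslopeestimatealpha1$", "dfaalpha1", key)
  key <- sub("^alpha([0-9])$", "dfaalpha\\1", key)
  manifest$name[match(key, norm(manifest$name))]
}

#' Assemble a session's feature vector
#'
#' Computes exactly the features the manifest requests, in manifest order.
#' The session should already have passed quality control; its RR series is
#' (idempotently) re-cleaned here before beat-level features are computed.
#' Requesting frequency-domain families for the recovery phase is an
#' integrity error.
#'
#' @param session a `gxt_session` with an attached RR series.
#' @param phase `"exercise"` or `"recovery"`.
#' @param manifest a manifest data frame; defaults to the phase's standard
#'   manifest ([feature_manifest()]).
#' @param cfg a [pipeline_config()].
#' @return Named numeric vector with one entry per manifest row. Gender is
#'   encoded male = 1 / female = 0 and protocol incremental = 1 / step = 0.
#' @export
assemble_features <- function(session, phase = c("exercise", "recovery"),
                              manifest = NULL, cfg = pipeline_config()) {
  phase <- match.arg(phase)
  manifest <- manifest %||% feature_manifest(phase)
  fams <- unique(manifest$family)
  if (phase == "recovery" && any(grepl("^frequency", fams)))
    integrity_error("frequency-domain features are not defined for recovery")
  vals <- c()
  if ("metadata" %in% fams) {
    vals <- c(vals,
              Age = session$age,
              Gender = as.numeric(session$gender == "male"),
              Height = session$height, Weight = session$weight,
              BMI = session$bmi,
              "Protocol Type" = as.numeric(session$protocol_type == "incremental"))
  }
  needs_session <- any(c("session", "speed_quartile", "time_quartile",
                         "hr_quartile", "hr_zone", "speed_zone") %in% fams)
  if (needs_session) {
    sv <- session_speed_time_features(session)
    if (phase == "recovery") {
      # HR summaries describe the phase the features are drawn from
      rec <- session$trace[session$trace$time > session$exercise_end_time &
                             session$trace$time <= session$recovery_end_time, ]
      sv["Min HR"] <- min(rec$hr, na.rm = TRUE)
      sv["Mean HR"] <- mean(rec$hr, na.rm = TRUE)
      sv["Std. HR"] <- stats::sd(rec$hr, na.rm = TRUE)
    }
    vals <- c(vals, sv)
  }
  beat_fams <- c("time_domain", "time_domain_slope", "frequency",
                 "frequency_slope", "nonlinear", "nonlinear_slope",
                 "dfa_window")
  if (any(beat_fams %in% fams)) {
    if (is.null(session$rr))
      integrity_error("session has no beat series; beat-level features unavailable")
    rr_all <- clean_rr(session$rr, cfg)
    rr <- if (phase == "exercise") {
      rr_window(rr_all, -Inf, session$exercise_end_time)
    } else {
      rr_window(rr_all, session$exercise_end_time, session$recovery_end_time)
    }
    if ("time_domain" %in% fams) vals <- c(vals, time_domain_features(rr))
    if ("time_domain_slope" %in% fams)
      vals <- c(vals, slope_features(rr, time_domain_features))
    if ("frequency" %in% fams) vals <- c(vals, frequency_domain_features(rr))
    if ("frequency_slope" %in% fams)
      vals <- c(vals, slope_features(rr, frequency_domain_features,
                                     window_s = 150, step_s = 30))
    if ("nonlinear" %in% fams || "nonlinear_slope" %in% fams) {
      if ("nonlinear" %in% fams) vals <- c(vals, nonlinear_features(rr))
      if ("nonlinear_slope" %in% fams)
        vals <- c(vals, slope_features(rr, nonlinear_short))
    }
    if ("dfa_window" %in% fams) vals <- c(vals, dfa_window_slopes(rr))
  }
  miss <- setdiff(manifest$name, names(vals))
  if (length(miss))
    integrity_error(paste("feature not produced for this manifest:", miss[1]))
  out <- vals[manifest$name]
  names(out) <- manifest$name
  out
}

#' Build a cohort feature table
#'
#' Preprocesses every session, applies segment quality control for the
#' requested phase, and assembles the feature vectors of the kept sessions
#' into a [feature_table()] with the measured VO2max as target.
#'
#' @param sessions list of `gxt_session` objects.
#' @param phase `"exercise"` or `"recovery"`.
#' @param manifest optional manifest (defaults to the phase manifest; pass
#'   `feature_manifest("base")` for the reference base-feature set).
#' @param cfg a [pipeline_config()].
#' @param qc apply quality control (default TRUE); sessions failing QC are
#'   dropped.
#' @return A `feature_table`; the QC report is attached as attribute `"qc"`.
#' @export
build_feature_table <- function(sessions, phase = c("exercise", "recovery"),
                                manifest = NULL, cfg = pipeline_config(),
                                qc = TRUE) {
  phase <- match.arg(phase)
  manifest <- manifest %||% feature_manifest(phase)
  pre <- lapply(sessions, preprocess_session, cfg = cfg)
  qcs <- lapply(pre, qc_segment, phase = phase, cfg = cfg)
  kept <- if (qc) vapply(qcs, `[[`, logical(1), "kept") else rep(TRUE, length(pre))
  if (!any(kept)) integrity_error("no session passed quality control")
  rows <- lapply(pre[kept], assemble_features, phase = phase,
                 manifest = manifest, cfg = cfg)
  X <- do.call(rbind, rows)
  tab <- feature_table(vapply(pre[kept], `[[`, character(1), "subject_id"),
                       X,
                       vapply(pre[kept], `[[`, numeric(1), "vo2max_measured"),
                       manifest, phase)
  attr(tab, "qc") <- do.call(rbind, lapply(qcs, function(q) {
    data.frame(subject_id = q$subject_id, phase = q$phase, kept = q$kept,
               reasons = paste(q$reasons, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  tab
}
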