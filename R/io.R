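# Readers and writers for session data, feature tables and reports.
#
# Native on-disk cohort layout: one `<id>_trace.csv` per subject (columns
# time,speed,hr,vo2), an optional `<id>_beats.csv` (beat_time_s,rr_ms,flag),
# and a single `metadata.csv` keyed by subject_id. Missing values are empty
# cells and surface as NA. A best-effort adapter for the public treadmill
# repository layout (free-form column names) is isolated here.

metadata_cols <- c("subject_id", "age", "gender", "height", "weight", "bmi",
                   "protocol_type", "exercise_end_time", "recovery_end_time",
                   "vo2max_measured")

#' Write one session to a directory
#'
#' Emits `<id>_trace.csv` and, when a beat series is attached,
#' `<id>_beats.csv`. Metadata is written by [write_cohort()].
#'
#' @param session a `gxt_session`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the trace file path.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "gxt_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tp <- file.path(dir, paste0(session$subject_id, "_trace.csv"))
  utils::write.csv(session$trace, tp, row.names = FALSE, na = "")
  if (!is.null(session$rr)) {
    bp <- file.path(dir, paste0(session$subject_id, "_beats.csv"))
    utils::write.csv(data.frame(beat_time_s = session$rr$beat_time_s,
                                rr_ms = session$rr$rr_ms,
                                flag = session$rr$flags),
                     bp, row.names = FALSE, na = "")
  }
  invisible(tp)
}

#' Read one session
#'
#' @param path path to the subject's trace CSV.
#' @param layout `"native_csv"` (the package layout above) or
#'   `"physionet_treadmill"` (best-effort column matching for the deposited
#'   treadmill-test layout; metadata must then be supplied via `metadata`).
#' @param metadata optional one-row data frame with the metadata columns; by
#'   default the native layout looks it up in `metadata.csv` next to the
#'   trace file.
#' @return A validated `gxt_session`.
#' @export
read_session <- function(path, layout = c("native_csv", "physionet_treadmill"),
                         metadata = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) format_error(paste("no such file:", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (layout == "native_csv") {
    required <- c("time", "speed", "hr", "vo2")
    miss <- setdiff(required, names(raw))
    if (length(miss))
      format_error(paste("trace file missing column:", miss[1]), column = miss[1])
    trace <- raw[required]
    sid <- sub("_trace\\.csv$", "", basename(path))
  } else {
    # free-form headers: match by name fragments, case-insensitively
    pick <- function(patterns) {
      for (p in patterns) {
        hit <- grep(p, names(raw), ignore.case = TRUE)
        if (length(hit)) return(names(raw)[hit[1]])
      }
      NULL
    }
    cols <- list(time = pick(c("^time", "^t$", "sec")),
                 speed = pick(c("speed", "velocity")),
                 hr = pick(c("^hr", "heart")),
                 vo2 = pick(c("vo2", "oxygen")))
    miss <- names(cols)[vapply(cols, is.null, logical(1))]
    if (length(miss))
      format_error(paste("could not locate column:", miss[1]), column = miss[1])
    trace <- stats::setNames(raw[unlist(cols)], names(cols))
    sid <- sub("\\.csv$", "", basename(path))
  }
  if (anyNA(trace$time) || any(duplicated(trace$time)))
    integrity_error("trace contains missing or duplicated timestamps")
  if (is.null(metadata)) {
    mp <- file.path(dirname(path), "metadata.csv")
    if (!file.exists(mp))
      format_error("no metadata supplied and no metadata.csv sidecar found")
    md <- utils::read.csv(mp, stringsAsFactors = FALSE)
    metadata <- md[md$subject_id == sid, , drop = FALSE]
    if (nrow(metadata) != 1L)
      integrity_error(paste("metadata.csv has", nrow(metadata),
                            "rows for subject", sid))
  }
  miss <- setdiff(setdiff(metadata_cols, "bmi"), names(metadata))
  if (length(miss))
    format_error(paste("metadata missing column:", miss[1]), column = miss[1])
  rr <- NULL
  bp <- file.path(dirname(path), paste0(sid, "_beats.csv"))
  if (file.exists(bp)) {
    beats <- utils::read.csv(bp, stringsAsFactors = FALSE)
    rr <- rr_series(beats$rr_ms, flags = beats$flag,
                    t0_s = beats$beat_time_s[1] - beats$rr_ms[1] / 1000)
  }
  gxt_session(subject_id = sid, age = metadata$age, gender = metadata$gender,
              height = metadata$height, weight = metadata$weight,
              protocol_type = metadata$protocol_type, trace = trace,
              exercise_end_time = metadata$exercise_end_time,
              recovery_end_time = metadata$recovery_end_time,
              vo2max_measured = metadata$vo2max_measured, rr = rr)
}

#' Write / read a whole cohort
#'
#' @param cohort a list with `sessions` and optionally `truth` (as returned
#'   by [generate_cohort()]), or a bare list of sessions.
#' @param dir cohort directory.
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   a list with `sessions` and (if present on disk) `truth`.
#' @export
write_cohort <- function(cohort, dir) {
  sessions <- if (!is.null(cohort$sessions)) cohort$sessions else cohort
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  md <- do.call(rbind, lapply(sessions, function(s) {
    data.frame(subject_id = s$subject_id, age = s$age, gender = s$gender,
               height = s$height, weight = s$weight, bmi = s$bmi,
               protocol_type = s$protocol_type,
               exercise_end_time = s$exercise_end_time,
               recovery_end_time = s$recovery_end_time,
               vo2max_measured = s$vo2max_measured, stringsAsFactors = FALSE)
  }))
  utils::write.csv(md, file.path(dir, "metadata.csv"), row.names = FALSE, na = "")
  for (s in sessions) write_session(s, dir)
  if (!is.null(cohort$truth))
    utils::write.csv(cohort$truth, file.path(dir, "cohort_truth.csv"),
                     row.names = FALSE, na = "")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  mp <- file.path(dir, "metadata.csv")
  if (!file.exists(mp)) format_error(paste("no metadata.csv in", dir))
  md <- utils::read.csv(mp, stringsAsFactors = FALSE)
  sessions <- lapply(seq_len(nrow(md)), function(i) {
    read_session(file.path(dir, paste0(md$subject_id[i], "_trace.csv")),
                 metadata = md[i, , drop = FALSE])
  })
  tp <- file.path(dir, "cohort_truth.csv")
  truth <- if (file.exists(tp)) utils::read.csv(tp, stringsAsFactors = FALSE)
  list(sessions = sessions, truth = truth)
}

#' Feature table
#'
#' Subjects-by-features value matrix plus the target vector and the manifest
#' the columns were drawn from.
#'
#' @param subject_ids character vector, no duplicates.
#' @param X numeric matrix (subjects x features), columns named exactly as in
#'   `manifest$name`.
#' @param y target VO2max per subject.
#' @param manifest a feature manifest data frame (`name`, `family`).
#' @param phase `"exercise"`, `"recovery"` or `"base"`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(subject_ids, X, y, manifest, phase = "exercise") {
  if (length(subject_ids) == 0L) integrity_error("feature table is empty")
  if (anyDuplicated(subject_ids)) integrity_error("duplicate subject ids")
  if (anyDuplicated(manifest$name)) integrity_error("duplicate feature names")
  X <- as.matrix(X)
  if (!identical(colnames(X), manifest$name))
    integrity_error("feature columns must match the manifest order")
  if (nrow(X) != length(subject_ids) || length(y) != length(subject_ids))
    integrity_error("subjects, rows and targets must align")
  structure(list(subject_ids = as.character(subject_ids), X = X,
                 y = as.numeric(y), manifest = manifest, phase = phase),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d features (%s phase)\n",
              nrow(x$X), ncol(x$X), x$phase))
  invisible(x)
}

subset_feature_table <- function(table, keep) {
  feature_table(table$subject_ids[keep], table$X[keep, , drop = FALSE],
                table$y[keep], table$manifest, table$phase)
}

#' Write / read a feature table
#'
#' The CSV stores `subject_id`, `vo2max_measured`, then one column per
#' feature in manifest order; a JSON sidecar (`<stem>_manifest.json`) stores
#' the manifest and phase so that the round trip is lossless field-for-field.
#' Missing cells are written as empty strings and read back as NA.
#'
#' @param table a [feature_table()].
#' @param path CSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(subject_id = table$subject_ids,
                   vo2max_measured = table$y,
                   table$X, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  side <- sidecar_path(path)
  jsonlite::write_json(list(phase = table$phase, manifest = table$manifest),
                       side, dataframe = "columns", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) format_error(paste("no such file:", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  side <- sidecar_path(path)
  if (!file.exists(side))
    format_error(paste("missing manifest sidecar:", side))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  manifest <- as.data.frame(meta$manifest, stringsAsFactors = FALSE)
  X <- as.matrix(df[, manifest$name, drop = FALSE])
  rownames(X) <- NULL
  feature_table(df$subject_id, X, df$vo2max_measured, manifest, meta$phase)
}

sidecar_path <- function(path) {
  paste0(sub("\\.csv$", "", path), "_manifest.json")
}

#' Write an evaluation report as JSON
#'
#' @param report an `eval_report` from [run_experiment()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  x <- unclass(report)
  x$pooled <- as.list(x$pooled)          # keep metric names in the JSON
  x$fold_mean <- as.list(x$fold_mean)
  x$folds <- as.list(x$folds)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}
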