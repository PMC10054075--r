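# Deviant-point analysis: kNN aggregate-distance scores in the
# (maximal speed, measured VO2max) plane, Tukey-fence flagging, and the two
# re-evaluation protocols (removal everywhere vs removal from training only).

#' kNN aggregate-distance outlier scores
#'
#' Each subject's score is the mean Euclidean distance to its k nearest
#' neighbours (self excluded). Axes are z-scored first by default because
#' speed (km/h) and VO2max (mL/kg/min) are on incomparable scales.
#'
#' @param points numeric matrix or data frame, one row per subject (the
#'   deviant analysis uses the two columns maximal speed and measured
#'   VO2max, but any dimension works).
#' @param k neighbour count (default 5); requires `nrow(points) > k`.
#' @param standardize z-score the axes before computing distances.
#' @return Numeric score vector (named by row names when present).
#' @export
knn_scores <- function(points, k = 5, standardize = TRUE) {
  P <- as.matrix(points)
  n <- nrow(P)
  if (n <= k) config_error("need more points than neighbours")
  if (standardize) {
    sdv <- apply(P, 2L, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    P <- sweep(sweep(P, 2L, colMeans(P)), 2L, sdv, "/")
  }
  D <- as.matrix(stats::dist(P))
  diag(D) <- Inf
  scores <- apply(D, 1L, function(r) mean(sort(r)[seq_len(k)]))
  stats::setNames(scores, rownames(points))
}

#' Flag deviant points from their scores
#'
#' Default rule: a point is deviant when its score exceeds the upper Tukey
#' fence Q3 + 1.5 IQR of the score distribution (strictly), which is
#' scale-free and flags nothing when all scores are equal.
#'
#' @param scores numeric scores from [knn_scores()], all finite.
#' @param rule `"tukey"` (only rule implemented).
#' @param fence IQR multiplier of the fence (default 1.5).
#' @return An `outlier_result`: `scores`, logical `flag`, `threshold`,
#'   `rule`, `n_flagged`.
#' @export
flag_deviant <- function(scores, rule = "tukey", fence = 1.5) {
  if (any(!is.finite(scores))) integrity_error("scores must be finite")
  if (!identical(rule, "tukey"))
    config_error(paste("unknown threshold rule:", rule))
  q <- stats::quantile(scores, c(0.25, 0.75), names = FALSE)
  thr <- q[2] + fence * (q[2] - q[1])
  flag <- scores > thr
  structure(list(scores = scores, flag = flag, threshold = thr, rule = rule,
                 n_flagged = sum(flag)),
            class = "outlier_result")
}

#' @export
print.outlier_result <- function(x, ...) {
  cat(sprintf("<outlier_result> %d / %d flagged (%s fence at %.3f)\n",
              x$n_flagged, length(x$flag), x$rule, x$threshold))
  invisible(x)
}

#' Re-evaluate a model under the deviant-point protocols
#'
#' `"baseline"` is the standard person-independent experiment. `"case1"`
#' removes the globally flagged subjects from the whole dataset and reruns
#' the experiment, emulating a cleaned benchmark. `"case2"` mimics
#' deployment: test folds are stratified on the global flag so they retain
#' the cohort's reliable-to-deviant ratio, and within each fold deviants are
#' removed from the training portion only -- using flags recomputed from the
#' training points alone, since identifying deviants needs the ground-truth
#' VO2max, which is only available for training subjects.
#'
#' @param table a [feature_table()]; its `Max. Speed` column and target form
#'   the detection plane.
#' @param case `"baseline"`, `"case1"` or `"case2"`.
#' @param selector,spec,cfg,seed forwarded to [run_experiment()].
#' @param k,fence kNN neighbour count and Tukey fence multiplier.
#' @return The `eval_report`, with the global `outlier_result` attached as
#'   `$outliers`.
#' @export
case_evaluate <- function(table, case = c("baseline", "case1", "case2"),
                          selector = "none", spec = model_spec("mlr"),
                          cfg = pipeline_config(), seed = 1,
                          k = cfg$knn_k, fence = 1.5) {
  case <- match.arg(case)
  pts <- deviant_plane(table)
  flags <- flag_deviant(knn_scores(pts, k = k), fence = fence)
  if (all(flags$flag)) integrity_error("every subject flagged as deviant")
  report <- switch(case,
    baseline = run_experiment(table, selector, spec, cfg, seed),
    case1 = {
      keep <- !flags$flag
      run_experiment(subset_feature_table(table, keep), selector, spec, cfg,
                     seed)
    },
    case2 = {
      folds <- stratified_folds(table$subject_ids, flags$flag, cfg$cv_folds,
                                seed)
      ids <- table$subject_ids
      filt <- function(tr_ids) {
        tr_idx <- match(tr_ids, ids)
        tr_flags <- flag_deviant(knn_scores(pts[tr_idx, , drop = FALSE],
                                            k = k), fence = fence)
        # a training subject is dropped only when the training data alone
        # identify it AND it belongs to the deviant population; fold-shaped
        # gaps in the point cloud cannot evict reliable subjects
        drop <- tr_flags$flag & flags$flag[tr_idx]
        tr_ids[!drop]
      }
      run_experiment(table, selector, spec, cfg, seed, folds = folds,
                     train_filter = filt)
    })
  report$case <- case
  report$outliers <- flags
  report
}

deviant_plane <- function(table) {
  if (!"Max. Speed" %in% colnames(table$X))
    integrity_error("feature table lacks a 'Max. Speed' column")
  cbind(max_speed = table$X[, "Max. Speed"], vo2max = table$y)
}

# Per-stratum fold assignment that reduces to person_independent_folds()
# when one stratum is empty, so a zero-flag case2 equals the baseline.
stratified_folds <- function(ids, flag, k, seed) {
  if (!any(flag)) return(person_independent_folds(ids, k, seed))
  fr <- person_independent_folds(ids[!flag], k, seed)
  fd <- person_independent_folds(ids[flag], min(k, sum(flag)),
                                 seed = child_seed(seed, 1))
  assign <- integer(length(ids))
  names(assign) <- ids
  assign[names(fr)] <- fr
  # spread deviants over the k folds even when fewer deviants than folds
  assign[names(fd)] <- ((fd - 1L + seed) %% k) + 1L
  assign
}
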