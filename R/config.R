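#' Pipeline configuration
#'
#' Bundles every tunable constant of the estimation pipeline. Defaults follow
#' the analysis protocol: RR intervals accepted in 300--2000 ms, consecutive
#' heart-rate jumps above 30 bpm invalidate a segment, exercise segments
#' shorter than 300 s are discarded, collinearity pruning uses a 0.7 Spearman
#' threshold, and evaluation uses 10 outer / 5 inner cross-validation folds.
#'
#' @param rr_min_ms,rr_max_ms inclusive physiological RR range (ms).
#' @param karlsson_threshold relative deviation from the neighbour mean above
#'   which a beat is called ectopic (0.2 = 20 percent).
#' @param hr_jump_bpm maximal plausible beat-to-beat HR step (bpm).
#' @param min_segment_s minimal exercise-segment duration (s).
#' @param phase_rho_threshold a session is "out of phase" when the Spearman
#'   correlation of HR and VO2 over exercise falls below this value.
#' @param collinearity_threshold absolute Spearman correlation above which two
#'   features are treated as collinear during pruning.
#' @param mi_k neighbour count of the kNN mutual-information estimator.
#' @param knn_k neighbour count for deviant-point scores.
#' @param knn_threshold_rule outlier threshold rule; only `"tukey"`
#'   (Q3 + 1.5 IQR) is currently implemented.
#' @param cv_folds,inner_cv_folds outer and inner cross-validation folds.
#' @param greedy_tol minimal RMSE improvement counted as progress by the
#'   greedy selector.
#' @param rng_seed default seed used when an operation is not given one.
#' @param svr_grid,rf_grid named lists of hyperparameter candidates for the
#'   support-vector and random-forest grid searches.
#' @param feature_manifest name of the manifest in use (documentation only).
#'
#' @return An object of class `pipeline_config` (a validated named list).
#' @seealso [write_pipeline_config()], [read_pipeline_config()]
#' @export
pipeline_config <- function(rr_min_ms = 300,
                            rr_max_ms = 2000,
                            karlsson_threshold = 0.2,
                            hr_jump_bpm = 30,
                            min_segment_s = 300,
                            phase_rho_threshold = 0,
                            collinearity_threshold = 0.7,
                            mi_k = 3,
                            knn_k = 5,
                            knn_threshold_rule = "tukey",
                            cv_folds = 10,
                            inner_cv_folds = 5,
                            greedy_tol = 1e-6,
                            rng_seed = 1,
                            svr_grid = list(cost = c(0.1, 1, 10, 100),
                                            gamma = c(0.001, 0.01, 0.1, 1),
                                            epsilon = c(0.1, 0.5, 1)),
                            rf_grid = list(num_trees = c(100, 300),
                                           max_depth = c(3, 5, 10, 0),
                                           min_node_size = c(2, 5, 10)),
                            feature_manifest = "default") {
  cfg <- list(rr_min_ms = rr_min_ms, rr_max_ms = rr_max_ms,
              karlsson_threshold = karlsson_threshold,
              hr_jump_bpm = hr_jump_bpm, min_segment_s = min_segment_s,
              phase_rho_threshold = phase_rho_threshold,
              collinearity_threshold = collinearity_threshold,
              mi_k = mi_k, knn_k = knn_k,
              knn_threshold_rule = knn_threshold_rule,
              cv_folds = cv_folds, inner_cv_folds = inner_cv_folds,
              greedy_tol = greedy_tol, rng_seed = rng_seed,
              svr_grid = svr_grid, rf_grid = rf_grid,
              feature_manifest = feature_manifest)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  pos <- c("rr_min_ms", "rr_max_ms", "karlsson_threshold", "hr_jump_bpm",
           "min_segment_s", "collinearity_threshold", "mi_k", "knn_k",
           "greedy_tol")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      config_error(sprintf("config field '%s' must be a positive scalar", f))
  }
  if (cfg$rr_min_ms >= cfg$rr_max_ms)
    config_error("rr_min_ms must be smaller than rr_max_ms")
  if (cfg$cv_folds < 2 || cfg$inner_cv_folds < 2)
    config_error("cv_folds and inner_cv_folds must be at least 2")
  if (cfg$collinearity_threshold > 1)
    config_error("collinearity_threshold must lie in (0, 1]")
  invisible(cfg)
}

#' Write / read a pipeline configuration as YAML
#'
#' The round trip is lossless: `read_pipeline_config(write_pipeline_config(cfg))`
#' reproduces `cfg` exactly.
#'
#' @param cfg a [pipeline_config()] object.
#' @param path file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) format_error(paste("no such config file:", path))
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Synthetic cohort configuration
#'
#' Parameters of the synthetic graded-exercise-test generator. The defaults
#' define the study conditions used throughout the test-suite: a 3-min
#' recovery, a 5 percent deviant fraction, per-beat spike/ectopic artifact
#' rates of 0.005/0.001, and the noise scales of the fitness-speed link.
#'
#' @param n_subjects cohort size (at least 2).
#' @param seed integer seed; the whole cohort is a deterministic function of it.
#' @param deviant_fraction fraction of subjects whose maximal speed is redrawn
#'   independently of their true VO2max.
#' @param ectopic_rate,spike_rate per-beat artifact rates in `[0, 1]`.
#' @param vo2max_sd population VO2max spread (mL/kg/min).
#' @param speed_link_sd noise of the VO2max-to-maximal-speed link (km/h).
#' @param hr_sd spread of the maximal-HR law (bpm).
#' @param vo2_noise_sd breath-by-breath VO2 noise (mL/kg/min).
#' @param hr_rest_mean,hr_rest_sd resting heart-rate distribution (bpm).
#' @param incremental_fraction share of subjects on the ramp (vs step) protocol.
#' @param female_fraction share of female subjects.
#' @param recovery_s recovery length in seconds (monitor switched off after
#'   3 min, hence the 180 s default).
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 200,
                       seed = 1,
                       deviant_fraction = 0.05,
                       ectopic_rate = 0.001,
                       spike_rate = 0.005,
                       vo2max_sd = 6,
                       speed_link_sd = 0.8,
                       hr_sd = 5,
                       vo2_noise_sd = 1,
                       hr_rest_mean = 60,
                       hr_rest_sd = 5,
                       incremental_fraction = 0.5,
                       female_fraction = 0.5,
                       recovery_s = 180) {
  if (!is.numeric(n_subjects) || n_subjects < 2)
    config_error("n_subjects must be at least 2")
  rates <- c(deviant_fraction = deviant_fraction, ectopic_rate = ectopic_rate,
             spike_rate = spike_rate, incremental_fraction = incremental_fraction,
             female_fraction = female_fraction)
  if (any(rates < 0 | rates > 1))
    config_error("fractions and per-beat rates must lie in [0, 1]")
  if (recovery_s <= 0) config_error("recovery_s must be positive")
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 deviant_fraction = deviant_fraction,
                 ectopic_rate = ectopic_rate, spike_rate = spike_rate,
                 vo2max_sd = vo2max_sd, speed_link_sd = speed_link_sd,
                 hr_sd = hr_sd, vo2_noise_sd = vo2_noise_sd,
                 hr_rest_mean = hr_rest_mean, hr_rest_sd = hr_rest_sd,
                 incremental_fraction = incremental_fraction,
                 female_fraction = female_fraction,
                 recovery_s = recovery_s),
            class = "sim_config")
}
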