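# Hybrid feature selection: filter rankings (Spearman, kNN mutual
# information) with top-down collinearity pruning, and a greedy
# forward-backward wrapper scored by inner-cross-validated RMSE.

#' Median-impute missing feature cells
#'
#' Column medians are computed on `stats_from` (the training rows) and used
#' to fill NA cells; an all-missing column is filled with 0.
#'
#' @param X numeric matrix.
#' @param stats_from matrix to compute the medians from (default `X`).
#' @return The imputed matrix.
#' @export
impute_median <- function(X, stats_from = X) {
  med <- apply(stats_from, 2L, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(X))) {
    na <- is.na(X[, j])
    if (any(na)) X[na, j] <- med[j]
  }
  X
}

#' Rank features by association with the target
#'
#' Spearman scoring uses the absolute rank correlation with the target;
#' mutual-information scoring uses a Kraskov-style k-nearest-neighbour
#' estimator (k = 3 by default, in nats), with the discrete-continuous
#' variant for features taking few distinct values (Gender, Protocol Type).
#' Constant features score 0. Ties are broken by column order, so the
#' ranking is deterministic.
#'
#' @param X numeric matrix (subjects x features), NA cells allowed (median
#'   imputed before scoring).
#' @param y target vector.
#' @param score `"spearman"` or `"mutual_information"`.
#' @param k neighbour count of the MI estimator.
#' @param seed seed for the tie-breaking jitter of the MI estimator.
#' @return A data frame `name`, `score` sorted by decreasing score.
#' @export
rank_features <- function(X, y, score = c("spearman", "mutual_information"),
                          k = 3, seed = 1) {
  score <- match.arg(score)
  if (nrow(X) < 10L) too_short_error("ranking needs at least 10 subjects")
  X <- impute_median(X)
  sc <- if (score == "spearman") {
    s <- abs(suppressWarnings(stats::cor(X, y, method = "spearman")))[, 1]
    s[!is.finite(s)] <- 0
    s
  } else {
    vapply(seq_len(ncol(X)), function(j)
      mi_knn(X[, j], y, k = k, seed = child_seed(seed, j)), numeric(1))
  }
  ord <- order(-sc)  # stable: ties keep column order
  data.frame(name = colnames(X)[ord], score = unname(sc[ord]),
             stringsAsFactors = FALSE)
}

#' kNN mutual-information estimate
#'
#' Kraskov-Stoegbauer-Grassberger estimator (algorithm 1) for two continuous
#' variables, and the Ross discrete-continuous variant when `x` takes at
#' most 5 distinct values. Values are standardized and continuous inputs
#' receive a microscopic seeded jitter to break ties. Estimates are clipped
#' at 0 (MI is non-negative).
#'
#' @param x,y numeric vectors of equal length.
#' @param k neighbour count (default 3).
#' @param seed jitter seed.
#' @return Estimated mutual information in nats.
#' @export
mi_knn <- function(x, y, k = 3, seed = 1) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n <= k + 1) too_short_error("too few observations for the MI estimator")
  if (stats::sd(x) == 0) return(0)
  discrete <- length(unique(x)) <= 5L
  withr::with_seed(seed, {
    ys <- as.numeric(scale(y)) + stats::rnorm(n, 0, 1e-10)
    if (discrete) {
      dy <- abs(outer(ys, ys, "-"))
      diag(dy) <- Inf
      psi_nx <- numeric(n); psi_m <- numeric(n); ki <- numeric(n)
      for (lev in unique(x)) {
        idx <- which(x == lev)
        nl <- length(idx)
        kk <- min(k, nl - 1L)
        if (kk < 1L) { psi_nx[idx] <- NA; next }
        dsub <- dy[idx, idx, drop = FALSE]
        dk <- apply(dsub, 1L, function(r) sort(r)[kk])
        m <- rowSums(dy[idx, , drop = FALSE] <= dk) # neighbours in full sample
        psi_nx[idx] <- digamma(nl)
        psi_m[idx] <- digamma(pmax(m, 1))
        ki[idx] <- digamma(kk)
      }
      ok <- !is.na(psi_nx)
      mi <- digamma(n) - mean(psi_nx[ok]) + mean(ki[ok]) - mean(psi_m[ok])
    } else {
      xs <- as.numeric(scale(x)) + stats::rnorm(n, 0, 1e-10)
      dx <- abs(outer(xs, xs, "-"))
      dy <- abs(outer(ys, ys, "-"))
      dz <- pmax(dx, dy)
      diag(dz) <- Inf
      eps <- apply(dz, 1L, function(r) sort(r)[k])
      nx <- rowSums(dx < eps) - 1L  # exclude self
      ny <- rowSums(dy < eps) - 1L
      mi <- digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
    }
    max(mi, 0)
  })
}

#' Prune collinear features from a ranking
#'
#' Walks the ranking from the top; a feature is kept only when its absolute
#' Spearman correlation with every already-kept feature stays at or below
#' the threshold. Removed features record which kept feature displaced them.
#'
#' @param ranking data frame from [rank_features()] (or a character vector of
#'   names in rank order).
#' @param X the feature matrix the ranking refers to.
#' @param threshold collinearity threshold in (0, 1], default 0.7.
#' @return A list: `kept` (names, rank order), `removed` (data frame `name`,
#'   `displaced_by`).
#' @export
prune_collinear <- function(ranking, X, threshold = 0.7) {
  if (threshold <= 0 || threshold > 1)
    config_error("collinearity threshold must lie in (0, 1]")
  names_ranked <- if (is.data.frame(ranking)) ranking$name else ranking
  if (!all(names_ranked %in% colnames(X)))
    integrity_error("ranking refers to features absent from the matrix")
  Xr <- apply(impute_median(X[, names_ranked, drop = FALSE]), 2L, rank)
  C <- suppressWarnings(abs(stats::cor(Xr)))
  C[!is.finite(C)] <- 0
  kept <- character()
  removed <- data.frame(name = character(), displaced_by = character(),
                        stringsAsFactors = FALSE)
  for (f in names_ranked) {
    if (length(kept)) {
      r <- C[f, kept]
      if (any(r > threshold)) {
        removed <- rbind(removed,
                         data.frame(name = f,
                                    displaced_by = kept[which.max(r)],
                                    stringsAsFactors = FALSE))
        next
      }
    }
    kept <- c(kept, f)
  }
  list(kept = kept, removed = removed)
}

#' Greedy forward-backward feature selection
#'
#' Forward phase: repeatedly add the feature whose addition minimizes the
#' inner-cross-validated RMSE of the model, stopping when no candidate
#' improves the metric by more than `tol`. Backward phase: repeatedly remove
#' the feature whose removal most decreases the metric. The two phases
#' alternate until a full cycle changes nothing. The metric is computed on
#' the supplied (training) data only, with a fold assignment fixed once from
#' `seed`, so the procedure is deterministic and leakage-free. Candidates
#' with a non-finite metric are skipped with a warning.
#'
#' @param X numeric matrix (NA cells median-imputed once, up front).
#' @param y target vector.
#' @param model_spec a [model_spec()]; an efficient closed-form path is used
#'   for `"mlr"`.
#' @param folds number of inner CV folds (default 5).
#' @param tol minimal RMSE improvement counted as progress.
#' @param seed fold-assignment seed.
#' @param max_cycles safety bound on forward/backward alternations.
#' @return A `selection_result` list: `method`, `selected` (in addition
#'   order), `metric` (final CV RMSE), `trajectory` (data frame `action`,
#'   `name`, `metric`).
#' @export
greedy_forward_backward <- function(X, y, model_spec = NULL, folds = 5,
                                    tol = 1e-6, seed = 1, max_cycles = 25) {
  model_spec <- model_spec %||% vo2hrv::model_spec("mlr")
  p <- ncol(X)
  if (p < 2L) config_error("greedy selection needs at least 2 features")
  if (nrow(X) < 20L) too_short_error("greedy selection needs at least 20 subjects")
  X <- impute_median(X)
  assign <- person_independent_folds(seq_len(nrow(X)), k = folds, seed = seed)
  metric <- cv_metric_fn(X, y, model_spec, assign)
  current <- metric(integer())
  sel <- integer()
  traj <- data.frame(action = "start", name = "", metric = current,
                     stringsAsFactors = FALSE)
  eval_candidate <- function(idx) {
    m <- tryCatch(metric(idx), error = function(e) NA_real_)
    if (!is.finite(m)) {
      warning("candidate produced a non-finite metric; skipped",
              call. = FALSE)
      return(Inf)
    }
    m
  }
  for (cycle in seq_len(max_cycles)) {
    changed <- FALSE
    repeat {  # forward
      cand <- setdiff(seq_len(p), sel)
      if (!length(cand)) break
      scores <- vapply(cand, function(j) eval_candidate(c(sel, j)), numeric(1))
      best <- which.min(scores)
      if (scores[best] < current - tol) {
        sel <- c(sel, cand[best])
        current <- scores[best]
        traj <- rbind(traj, data.frame(action = "add",
                                       name = colnames(X)[cand[best]],
                                       metric = current))
        changed <- TRUE
      } else break
    }
    repeat {  # backward
      if (length(sel) < 2L) break
      scores <- vapply(seq_along(sel),
                       function(i) eval_candidate(sel[-i]), numeric(1))
      best <- which.min(scores)
      if (scores[best] < current - tol) {
        traj <- rbind(traj, data.frame(action = "remove",
                                       name = colnames(X)[sel[best]],
                                       metric = scores[best]))
        sel <- sel[-best]
        current <- scores[best]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  structure(list(method = "greedy", selected = colnames(X)[sel],
                 metric = current, trajectory = traj),
            class = "selection_result")
}

# Inner-CV RMSE closure over a fixed fold assignment. The empty feature set
# is scored by the training-mean predictor.
cv_metric_fn <- function(X, y, spec, assign) {
  if (spec$kind == "mlr") {
    function(idx) {
      sse <- 0
      for (f in unique(assign)) {
        te <- assign == f
        Xtr <- cbind(1, X[!te, idx, drop = FALSE])
        fit <- stats::lm.fit(Xtr, y[!te])
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        pred <- cbind(1, X[te, idx, drop = FALSE]) %*% beta
        sse <- sse + sum((y[te] - pred)^2)
      }
      sqrt(sse / length(y))
    }
  } else {
    function(idx) {
      sse <- 0
      for (f in unique(assign)) {
        te <- assign == f
        if (!length(idx)) {
          pred <- rep(mean(y[!te]), sum(te))
        } else {
          fit <- fit_model(spec, X[!te, idx, drop = FALSE], y[!te])
          pred <- stats::predict(fit, X[te, idx, drop = FALSE])
        }
        sse <- sse + sum((y[te] - pred)^2)
      }
      sqrt(sse / length(y))
    }
  }
}

#' One-call feature selection
#'
#' Dispatches to the three selectors: `"corr"` (Spearman ranking + pruning),
#' `"mi"` (mutual-information ranking + Spearman pruning), `"greedy"`
#' (forward-backward wrapper), or `"none"`.
#'
#' @param X feature matrix.
#' @param y target.
#' @param method selector name.
#' @param model_spec model used by the greedy wrapper.
#' @param cfg a [pipeline_config()] supplying thresholds and inner folds.
#' @param seed selector seed.
#' @return A `selection_result` with at least `method` and `selected`.
#' @export
select_features <- function(X, y, method = c("none", "corr", "mi", "greedy"),
                            model_spec = NULL, cfg = pipeline_config(),
                            seed = 1) {
  method <- match.arg(method)
  if (method == "none") {
    return(structure(list(method = "none", selected = colnames(X)),
                     class = "selection_result"))
  }
  if (method == "greedy") {
    return(greedy_forward_backward(X, y,
                                   model_spec %||% vo2hrv::model_spec("mlr"),
                                   folds = cfg$inner_cv_folds,
                                   tol = cfg$greedy_tol, seed = seed))
  }
  score <- if (method == "corr") "spearman" else "mutual_information"
  ranking <- rank_features(X, y, score, k = cfg$mi_k, seed = seed)
  pruned <- prune_collinear(ranking, X, cfg$collinearity_threshold)
  structure(list(method = method, ranking = ranking,
                 selected = pruned$kept, removed = pruned$removed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d features selected\n",
              x$method, length(x$selected)))
  invisible(x)
}
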