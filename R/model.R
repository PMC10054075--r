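# Regression models (multiple linear regression, random forest, RBF support
# vector regression), nested hyperparameter grid search, person-independent
# folds and evaluation metrics.

#' Model specification
#'
#' @param kind `"mlr"`, `"rf"` or `"svr"`.
#' @param params fixed hyperparameters used when fitting directly (svr:
#'   `cost`, `gamma`, `epsilon`; rf: `num_trees`, `max_depth` (0 =
#'   unbounded), `min_node_size`).
#' @param grid named list of candidate values for [grid_search()]; `NULL`
#'   disables the search.
#' @param standardize z-score features with training statistics before
#'   fitting (default TRUE for mlr and svr, FALSE for rf whose splits are
#'   scale-invariant).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kind = c("mlr", "rf", "svr"), params = list(),
                       grid = NULL, standardize = NULL) {
  kind <- match.arg(kind)
  if (!is.null(grid) && !length(grid)) config_error("grid must be non-empty")
  standardize <- standardize %||% (kind != "rf")
  structure(list(kind = kind, params = params, grid = grid,
                 standardize = standardize),
            class = "model_spec")
}

default_grid <- function(kind, cfg) {
  switch(kind, svr = cfg$svr_grid, rf = cfg$rf_grid, NULL)
}

#' Fit a regression model
#'
#' MLR is solved in closed form by QR least squares: for a full-rank design
#' this is the exact minimizer of the mean-squared-error objective that
#' gradient descent converges to. Rank-deficient designs fall back to the
#' minimum-norm solution (with a warning). Random forests grow trees whose
#' splits minimize the sum of squared residuals; support vector regression
#' solves the epsilon-insensitive dual with a Gaussian RBF kernel
#' (delegated to a validated quadratic-programming solver).
#'
#' @param spec a [model_spec()].
#' @param X numeric feature matrix (no NA).
#' @param y numeric target.
#' @return A `vo2_model` with a [predict][predict.vo2_model] method.
#' @export
fit_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) integrity_error("fit_model requires complete data")
  std <- NULL
  Xs <- X
  if (spec$standardize) {
    mu <- colMeans(X)
    sdv <- apply(X, 2L, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
    std <- list(mu = mu, sd = sdv)
  }
  p <- spec$params
  fit <- switch(spec$kind,
    mlr = {
      D <- cbind(`(Intercept)` = 1, Xs)
      qrD <- qr(D)
      if (qrD$rank < ncol(D)) {
        if (nrow(D) > ncol(D)) {
          # overdetermined but aliased (duplicated or constant columns):
          # pivoted QR drops the aliased coefficients, as lm() would
          warning("rank-deficient design; aliased coefficients set to zero",
                  call. = FALSE)
          beta <- qr.coef(qrD, y)
          beta[is.na(beta)] <- 0
        } else {
          warning("fewer observations than coefficients; minimum-norm solution",
                  call. = FALSE)
          sv <- svd(D)
          keep <- sv$d > max(dim(D)) * .Machine$double.eps * sv$d[1]
          beta <- sv$v[, keep, drop = FALSE] %*%
            ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep])
          beta <- drop(beta)
        }
      } else {
        beta <- qr.coef(qrD, y)
      }
      names(beta) <- colnames(D)
      list(coef = beta)
    },
    rf = {
      df <- data.frame(.y = y, Xs, check.names = TRUE)
      ranger::ranger(dependent.variable.name = ".y", data = df,
                     num.trees = p$num_trees %||% 300,
                     max.depth = p$max_depth %||% 0,
                     min.node.size = p$min_node_size %||% 5,
                     replace = p$replace %||% TRUE,
                     sample.fraction = p$sample_fraction %||% 1,
                     seed = p$seed %||% 1, num.threads = 1)
    },
    svr = {
      if (stats::sd(y) == 0) {
        # degenerate problem: the eps-tube around a constant has no support
        # vectors, so the fit reduces to that constant
        list(constant = y[1])
      } else
      e1071::svm(x = Xs, y = y, type = "eps-regression", kernel = "radial",
                 cost = p$cost %||% 1,
                 gamma = p$gamma %||% (1 / ncol(Xs)),
                 epsilon = p$epsilon %||% 0.1,
                 tolerance = p$tolerance %||% 0.001, scale = FALSE)
    })
  structure(list(kind = spec$kind, fit = fit, std = std,
                 features = colnames(X), params = p),
            class = "vo2_model")
}

#' Predict from a fitted model
#'
#' @param object a `vo2_model`.
#' @param newdata matrix with the training feature columns.
#' @param ... unused.
#' @return Numeric predictions.
#' @export
predict.vo2_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$features, drop = FALSE]
  if (!is.null(object$std))
    X <- sweep(sweep(X, 2L, object$std$mu), 2L, object$std$sd, "/")
  switch(object$kind,
    mlr = drop(cbind(1, X) %*% object$fit$coef),
    rf = {
      df <- data.frame(X, check.names = TRUE)
      stats::predict(object$fit, data = df, num.threads = 1)$predictions
    },
    svr = {
      if (!is.null(object$fit$constant)) rep(object$fit$constant, nrow(X))
      else as.numeric(stats::predict(object$fit, X))
    })
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates every grid point by k-fold cross-validated RMSE on the supplied
#' (training) data, with a fold assignment fixed once from `seed`. Ties are
#' broken by grid order, so duplicated points return their first occurrence.
#'
#' @param spec a [model_spec()] whose `grid` is searched.
#' @param X,y training data.
#' @param folds inner folds (default 5).
#' @param seed fold seed.
#' @return List: `params` (best combination), `cv_rmse`, and the full
#'   evaluation `table`.
#' @export
grid_search <- function(spec, X, y, folds = 5, seed = 1) {
  grid <- spec$grid %||% config_error("model_spec carries no grid")
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  assign <- person_independent_folds(seq_len(nrow(X)), k = folds, seed = seed)
  rmse <- vapply(seq_len(nrow(combos)), function(i) {
    pars <- as.list(combos[i, , drop = FALSE])
    sp <- model_spec(spec$kind, params = pars, standardize = spec$standardize)
    sse <- 0
    for (f in unique(assign)) {
      te <- assign == f
      fit <- tryCatch(fit_model(sp, X[!te, , drop = FALSE], y[!te]),
                      error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      pred <- stats::predict(fit, X[te, , drop = FALSE])
      sse <- sse + sum((y[te] - pred)^2)
    }
    sqrt(sse / length(y))
  }, numeric(1))
  if (all(!is.finite(rmse))) degenerate_error("every grid point failed")
  best <- which.min(rmse)  # first minimum wins ties
  list(params = as.list(combos[best, , drop = FALSE]),
       cv_rmse = rmse[best],
       table = cbind(combos, cv_rmse = rmse))
}

#' Person-independent fold assignment
#'
#' A random permutation of the subjects partitioned into `k` near-equal
#' folds: every subject appears in exactly one test fold, so no subject
#' contributes to both the training and testing side of any split.
#'
#' @param subject_ids vector of unique ids.
#' @param k folds.
#' @param seed permutation seed.
#' @return Integer fold labels in 1..k named by subject id.
#' @export
person_independent_folds <- function(subject_ids, k = 10, seed = 1) {
  n <- length(subject_ids)
  if (k > n) config_error("more folds than subjects")
  if (anyDuplicated(subject_ids)) integrity_error("duplicate subject ids")
  withr::with_seed(seed, {
    perm <- sample.int(n)
    fold <- integer(n)
    fold[perm] <- rep_len(seq_len(k), n)
    stats::setNames(fold, subject_ids)
  })
}

#' Regression evaluation metrics
#'
#' Pearson correlation R, root-mean-squared error, mean absolute error and
#' mean absolute percentage error (in percent). R is NA when the truth is
#' constant.
#'
#' @param y_true,y_pred equal-length numeric vectors (length >= 2).
#' @return Named vector `R`, `RMSE`, `MAE`, `MAPE`.
#' @export
eval_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2L)
    config_error("need equal-length vectors of at least 2 values")
  err <- y_true - y_pred
  r <- if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) NA_real_
       else stats::cor(y_true, y_pred)
  c(R = r, RMSE = sqrt(mean(err^2)), MAE = mean(abs(err)),
    MAPE = 100 * mean(abs(err / y_true)))
}

#' Person-independent cross-validated experiment
#'
#' For each outer fold: impute and (per model) standardize with training
#' statistics only, run the feature selector on the training rows only,
#' grid-search hyperparameters on the training rows (5-fold inner CV), fit,
#' and predict the held-out subjects. Aggregate metrics are computed on the
#' pooled out-of-fold predictions (primary) and as per-fold means (also
#' reported).
#'
#' @param table a [feature_table()].
#' @param selector `"none"`, `"corr"`, `"mi"` or `"greedy"`.
#' @param spec a [model_spec()]; when its `grid` is `NULL` the config's
#'   default grid for that model kind is used (pass `grid = list()` inside a
#'   fixed `params` spec to skip searching).
#' @param cfg a [pipeline_config()].
#' @param seed outer-fold seed.
#' @param folds optional precomputed fold assignment (named integer vector).
#' @param train_filter optional function mapping the training subject ids of
#'   a fold to the subset to actually train on (used by the deviant-point
#'   protocols).
#' @return An `eval_report`: `pooled` and `fold_mean` metrics, `per_fold`
#'   data frame, `predictions`, fold assignment, selected features and
#'   chosen hyperparameters per fold, plus the configuration fingerprint.
#' @export
run_experiment <- function(table, selector = "none",
                           spec = model_spec("mlr"), cfg = pipeline_config(),
                           seed = 1, folds = NULL, train_filter = NULL) {
  stopifnot(inherits(table, "feature_table"))
  ids <- table$subject_ids
  assign <- folds %||% person_independent_folds(ids, cfg$cv_folds, seed)
  use_grid <- spec$kind != "mlr"
  grid <- spec$grid %||% default_grid(spec$kind, cfg)
  oof <- rep(NA_real_, length(ids))
  per_fold <- list(); sel_by_fold <- list(); par_by_fold <- list()
  for (f in sort(unique(assign))) {
    te <- assign == f
    tr_ids <- ids[!te]
    if (!is.null(train_filter)) tr_ids <- train_filter(tr_ids)
    tr <- ids %in% tr_ids
    Xtr_raw <- table$X[tr, , drop = FALSE]
    Xtr <- impute_median(Xtr_raw)
    Xte <- impute_median(table$X[te, , drop = FALSE], stats_from = Xtr_raw)
    ytr <- table$y[tr]
    # features constant on the training rows carry no information and would
    # only alias the intercept
    nz <- apply(Xtr, 2L, stats::sd) > 0
    if (!any(nz)) integrity_error("every feature is constant on this fold")
    Xtr <- Xtr[, nz, drop = FALSE]
    Xte <- Xte[, nz, drop = FALSE]
    sel <- select_features(Xtr, ytr, selector, model_spec = spec, cfg = cfg,
                           seed = child_seed(seed, f))
    feats <- sel$selected
    if (!length(feats)) integrity_error("selector emptied the feature set")
    pars <- spec$params
    if (use_grid && !is.null(grid) && length(grid)) {
      if (prod(lengths(grid)) == 1L) {
        pars <- lapply(grid, `[[`, 1L)
      } else {
        gs <- grid_search(model_spec(spec$kind, grid = grid,
                                     standardize = spec$standardize),
                          Xtr[, feats, drop = FALSE], ytr,
                          folds = cfg$inner_cv_folds,
                          seed = child_seed(seed, f))
        pars <- gs$params
      }
    }
    fit <- fit_model(model_spec(spec$kind, params = pars,
                                standardize = spec$standardize),
                     Xtr[, feats, drop = FALSE], ytr)
    pred <- stats::predict(fit, Xte[, feats, drop = FALSE])
    oof[te] <- pred
    per_fold[[as.character(f)]] <- eval_metrics(table$y[te], pred)
    sel_by_fold[[as.character(f)]] <- feats
    par_by_fold[[as.character(f)]] <- pars
  }
  pf <- as.data.frame(do.call(rbind, per_fold))
  pf$fold <- as.integer(names(per_fold))
  structure(list(pooled = eval_metrics(table$y, oof),
                 fold_mean = colMeans(pf[c("R", "RMSE", "MAE", "MAPE")],
                                      na.rm = TRUE),
                 per_fold = pf,
                 predictions = data.frame(subject_id = ids, y_true = table$y,
                                          y_pred = oof, fold = unname(assign),
                                          stringsAsFactors = FALSE),
                 folds = assign,
                 selector = selector, model = spec$kind,
                 selected_by_fold = sel_by_fold,
                 params_by_fold = par_by_fold,
                 config = list(cv_folds = cfg$cv_folds,
                               inner_cv_folds = cfg$inner_cv_folds,
                               seed = seed, phase = table$phase)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s + %s (%s phase): pooled R = %.3f, RMSE = %.3f (n = %d)\n",
              x$selector, x$model, x$config$phase,
              x$pooled["R"], x$pooled["RMSE"], nrow(x$predictions)))
  invisible(x)
}
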