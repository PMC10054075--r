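# Regression models, grid search, person-independent folds and metrics.

test_that("closed-form MLR recovers exact linear relationships", {
  x <- matrix(seq(0, 10, length.out = 50), dimnames = list(NULL, "x"))
  y <- 2 * drop(x) + 1
  fit <- fit_model(model_spec("mlr", standardize = FALSE), x, y)
  expect_equal(unname(fit$fit$coef), c(1, 2), tolerance = 1e-9)
  expect_equal(unname(predict(fit, x)), y, tolerance = 1e-9)
})

test_that("closed-form MLR equals a gradient-descent MSE minimizer", {
  withr::with_seed(12, {
    X <- matrix(rnorm(200 * 3), 200, dimnames = list(NULL, c("a", "b", "c")))
    y <- 1.5 - 2 * X[, 1] + 0.5 * X[, 3] + rnorm(200, 0, 0.2)
  })
  fit <- fit_model(model_spec("mlr", standardize = FALSE), X, y)
  # plain batch gradient descent on MSE, run to tight convergence
  D <- cbind(1, X)
  beta <- rep(0, 4)
  lr <- 0.1 / nrow(D)
  for (i in 1:20000) {
    g <- -2 * crossprod(D, y - D %*% beta)
    beta <- beta - lr * g
  }
  expect_equal(unname(fit$fit$coef), unname(drop(beta)), tolerance = 1e-6)
})

test_that("rank-deficient designs degrade gracefully with a warning", {
  withr::with_seed(31, {
    X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
    y <- X[, 1] + rnorm(20, 0, 0.1)
  })
  # overdetermined with a duplicated column: aliased coefficient dropped
  Xd <- cbind(X, dup = X[, 1])
  expect_warning(fit <- fit_model(model_spec("mlr", standardize = FALSE),
                                  Xd, y),
                 "aliased")
  expect_equal(unname(predict(fit, Xd)), unname(predict(
    fit_model(model_spec("mlr", standardize = FALSE), X, y), X)),
    tolerance = 1e-9)
  # underdetermined: minimum-norm solution still yields finite predictions
  Xw <- matrix(rnorm(5 * 8), 5, dimnames = list(NULL, paste0("f", 1:8)))
  expect_warning(fit2 <- fit_model(model_spec("mlr", standardize = FALSE),
                                   Xw, rnorm(5)),
                 "minimum-norm")
  expect_true(all(is.finite(predict(fit2, Xw))))
})

test_that("constant targets are reproduced by forest and SVR", {
  withr::with_seed(2, X <- matrix(rnorm(60), 30,
                                  dimnames = list(NULL, c("a", "b"))))
  y <- rep(42, 30)
  rf <- fit_model(model_spec("rf"), X, y)
  expect_equal(unname(predict(rf, X)), y, tolerance = 1e-9)
  sv <- fit_model(model_spec("svr"), X, y)
  expect_equal(unname(predict(sv, X)), y, tolerance = 0.11)  # epsilon tube
})

test_that("SVR honours the epsilon-insensitive tube at large cost", {
  x <- matrix(seq(-2, 2, length.out = 60), dimnames = list(NULL, "x"))
  y <- drop(x)
  fit <- fit_model(model_spec("svr",
                              params = list(cost = 1000, gamma = 1,
                                            epsilon = 0.05,
                                            tolerance = 1e-7),
                              standardize = FALSE), x, y)
  rmse <- sqrt(mean((y - predict(fit, x))^2))
  expect_lte(rmse, 0.05 + 1e-6)
})

test_that("a single forest tree splits at the brute-force SSR minimizer", {
  withr::with_seed(3, {
    x <- sort(runif(25, 0, 10))
    y <- ifelse(x > 6.2, 10, 0) + rnorm(25, 0, 0.1)
  })
  X <- matrix(x, dimnames = list(NULL, "x"))
  fit <- fit_model(model_spec("rf", params = list(num_trees = 1, max_depth = 1,
                                                  min_node_size = 2,
                                                  replace = FALSE,
                                                  sample_fraction = 1)),
                   X, y)
  split <- ranger::treeInfo(fit$fit, 1)$splitval[1]
  # exhaustive scan over candidate thresholds
  cand <- (x[-1] + x[-length(x)]) / 2
  ssr <- vapply(cand, function(c_) {
    l <- y[x <= c_]; r <- y[x > c_]
    sum((l - mean(l))^2) + sum((r - mean(r))^2)
  }, numeric(1))
  best <- cand[which.min(ssr)]
  expect_equal(split, best, tolerance = 1e-9)
})

test_that("grid search is exhaustive, deterministic and tie-stable", {
  withr::with_seed(4, {
    X <- matrix(rnorm(80 * 2), 80, dimnames = list(NULL, c("a", "b")))
    y <- X[, 1] + rnorm(80, 0, 0.3)
  })
  one <- grid_search(model_spec("svr", grid = list(cost = 1, gamma = 0.5,
                                                   epsilon = 0.1)),
                     X, y, seed = 1)
  expect_equal(one$params, list(cost = 1, gamma = 0.5, epsilon = 0.1))
  dup <- grid_search(model_spec("svr", grid = list(cost = c(1, 1),
                                                   gamma = 0.5,
                                                   epsilon = 0.1)),
                     X, y, seed = 1)
  expect_identical(which(dup$table$cv_rmse == dup$cv_rmse)[1], 1L)
  gs <- grid_search(model_spec("svr", grid = list(cost = c(0.1, 1, 10),
                                                  gamma = c(0.1, 1),
                                                  epsilon = 0.1)),
                    X, y, seed = 1)
  expect_equal(gs$cv_rmse, min(gs$table$cv_rmse))  # chosen = exhaustive argmin
})

test_that("person-independent folds partition the subjects", {
  ids <- paste0("s", 1:10)
  f <- person_independent_folds(ids, k = 10, seed = 1)
  expect_identical(sort(unname(f)), 1:10)  # one test subject per fold
  f2 <- person_independent_folds(paste0("s", 1:97), k = 10, seed = 5)
  expect_identical(length(f2), 97L)
  expect_true(all(table(f2) %in% c(9, 10)))
  expect_false(identical(person_independent_folds(paste0("s", 1:100), 10, 1),
                         person_independent_folds(paste0("s", 1:100), 10, 2)))
  expect_error(person_independent_folds(ids, k = 11),
               class = "vo2hrv_config_error")
})

test_that("metrics follow their standard definitions", {
  m <- eval_metrics(c(40, 50, 60), c(40, 50, 60))
  expect_equal(unname(m), c(1, 0, 0, 0))
  m2 <- eval_metrics(c(100, 200), c(110, 220))
  expect_equal(unname(m2["MAPE"]), 10)
  m3 <- eval_metrics(c(1, 2, 3, 4), 2 * c(1, 2, 3, 4) + 1)
  expect_equal(unname(m3["R"]), 1)
  expect_gt(unname(m3["RMSE"]), 0)
  expect_true(is.na(eval_metrics(c(5, 5, 5), c(4, 5, 6))["R"]))
})

test_that("experiments are leakage-free and reproducible", {
  withr::with_seed(6, {
    X <- matrix(rnorm(120 * 5), 120, dimnames = list(NULL, paste0("f", 1:5)))
    y <- 50 + 3 * X[, 2] + rnorm(120)
  })
  man <- data.frame(name = colnames(X), family = "x", stringsAsFactors = FALSE)
  tab <- feature_table(paste0("s", 1:120), X, y, man)
  cfg <- pipeline_config(cv_folds = 5)
  a <- run_experiment(tab, "corr", model_spec("mlr"), cfg, seed = 3)
  b <- run_experiment(tab, "corr", model_spec("mlr"), cfg, seed = 3)
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$selected_by_fold, b$selected_by_fold)
  # folds partition, and every prediction is out-of-fold
  expect_identical(sort(unique(unname(a$folds))), 1:5)
  expect_false(anyNA(a$predictions$y_pred))
  expect_gt(unname(a$pooled["R"]), 0.9)
})

test_that("a shuffled target yields no spurious pooled correlation", {
  withr::with_seed(7, {
    X <- matrix(rnorm(800 * 6), 800, dimnames = list(NULL, paste0("f", 1:6)))
    y <- sample(rnorm(800, 50, 7))
  })
  man <- data.frame(name = colnames(X), family = "x", stringsAsFactors = FALSE)
  tab <- feature_table(paste0("s", 1:800), X, y, man)
  rep <- run_experiment(tab, "none", model_spec("mlr"),
                        pipeline_config(), seed = 1)
  expect_lte(abs(unname(rep$pooled["R"])), 0.1)
})
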