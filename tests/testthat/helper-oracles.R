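# Independent reference implementations used as oracles. These deliberately
# take different computational routes than the package (rotated Poincare
# cloud instead of difference-variance identities, direct definition sums
# instead of vectorized shortcuts) so that agreement is informative.

oracle_time_domain <- function(x) {
  n <- length(x)
  d <- x[-1] - x[-n]
  c("Mean NNI" = sum(x) / n,
    "Median NNI" = stats::median(x),
    SDNN = sqrt(sum((x - mean(x))^2) / (n - 1)),
    SDSD = sqrt(sum((d - mean(d))^2) / (n - 2)),
    RMSSD = sqrt(sum(d^2) / (n - 1)),
    CVNNI = sqrt(sum((x - mean(x))^2) / (n - 1)) / (sum(x) / n),
    CVSD = sqrt(sum(d^2) / (n - 1)) / (sum(x) / n),
    "NNI 20" = length(which(abs(d) > 20)),
    "PNNI 20" = 100 * length(which(abs(d) > 20)) / (n - 1),
    "NNI 50" = length(which(abs(d) > 50)),
    "PNNI 50" = 100 * length(which(abs(d) > 50)) / (n - 1),
    "Range NNI" = max(x) - min(x))
}

# Poincare axes by rotating the lag-1 scatter 45 degrees and taking the
# sample SD along each rotated axis (the geometric definition).
oracle_poincare <- function(x) {
  n <- length(x)
  a <- x[-n]; b <- x[-1]
  u <- (b - a) / sqrt(2)
  c(SD1 = stats::sd(u))
}

# Brute-force kNN outlier scores from the raw distance formula.
oracle_knn_scores <- function(P, k) {
  n <- nrow(P)
  sapply(seq_len(n), function(i) {
    d <- sapply(seq_len(n), function(j)
      sqrt(sum((P[i, ] - P[j, ])^2)))
    mean(sort(d[-i])[seq_len(k)])
  })
}

# Exhaustive best-subset search under the same inner-CV RMSE metric the
# greedy wrapper optimizes (mean-predictor for the empty set).
oracle_best_subset_rmse <- function(X, y, assign) {
  p <- ncol(X)
  cv <- function(idx) {
    sse <- 0
    for (f in unique(assign)) {
      te <- assign == f
      if (!length(idx)) {
        pred <- rep(mean(y[!te]), sum(te))
      } else {
        D <- cbind(1, X[!te, idx, drop = FALSE])
        beta <- qr.coef(qr(D), y[!te])
        beta[is.na(beta)] <- 0
        pred <- cbind(1, X[te, idx, drop = FALSE]) %*% beta
      }
      sse <- sse + sum((y[te] - pred)^2)
    }
    sqrt(sse / length(y))
  }
  best <- cv(integer())
  for (m in seq_len(p)) {
    combs <- utils::combn(p, m)
    for (cc in seq_len(ncol(combs))) best <- min(best, cv(combs[, cc]))
  }
  best
}

# Small clean cohort shared by feature/model tests (memoised per session).
.tiny_cohort <- local({
  cache <- list()
  function(n = 12, seed = 42, deviant_fraction = 0, ...) {
    key <- paste(n, seed, deviant_fraction, ...)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- generate_cohort(sim_config(
        n_subjects = n, seed = seed, deviant_fraction = deviant_fraction, ...))
    }
    cache[[key]]
  }
})

random_rr <- function(n, mean = 800, sd = 50, seed = 1) {
  withr::with_seed(seed, rr_series(stats::rnorm(n, mean, sd)))
}
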