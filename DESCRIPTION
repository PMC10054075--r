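Package: vo2hrv
Title: Maximal Oxygen Uptake Estimation from Exercise and Recovery Heart
    Rate Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating cardiorespiratory fitness (VO2max, mL/kg/min)
    from heart-rate variability recorded during graded exercise tests and the
    three-minute recovery that follows. Provides RR-interval cleaning (range
    filter, Karlsson ectopic detection, linear interpolation, four segment
    quality-control rules), extraction of a 101-feature exercise vector and a
    30-feature recovery vector (time-domain, Welch spectral, Poincare,
    detrended fluctuation analysis, sliding-window slopes, speed/time/HR
    landmark features), three hybrid feature selectors (Spearman and mutual
    information ranking with collinearity pruning, and a greedy
    forward-backward wrapper), person-independent 10-fold evaluation of linear,
    random-forest and support-vector regressors with nested grid search, and
    kNN distance-based detection of deviant (maximal speed, VO2max) pairs.
    A synthetic graded-exercise-test cohort generator with ground truth
    supports end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    ranger,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
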