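test_that("bootstrap validation is deterministic and selects real signal", {
  set.seed(60)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n); junk <- rnorm(n)
  y <- ifelse(runif(n) < plogis(1.2 * x1 + 1.2 * x2), "pos", "neg")
  d <- data.frame(y = y, x1 = x1, x2 = x2, junk = junk)
  v1 <- bootstrap_validate(d, "y", c("x1", "x2", "junk"), n_boot = 100,
                           seed = 123, positive = "pos")
  v2 <- bootstrap_validate(d, "y", c("x1", "x2", "junk"), n_boot = 100,
                           seed = 123, positive = "pos")
  expect_identical(v1$aucs, v2$aucs)
  expect_identical(v1$selection_frequency, v2$selection_frequency)
  # strong predictors retained in almost every resample, noise rarely
  expect_gt(v1$selection_frequency[["x1"]], 0.95)
  expect_gt(v1$selection_frequency[["x2"]], 0.95)
  expect_lt(v1$selection_frequency[["junk"]],
            v1$selection_frequency[["x1"]])
  expect_true(v1$auc_ci[1] <= v1$auc_mean && v1$auc_mean <= v1$auc_ci[2])
})

test_that("bootstrap AUC shows the optimism direction on average", {
  set.seed(61)
  diffs <- sapply(1:8, function(i) {
    n <- 120
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- ifelse(runif(n) < plogis(0.6 * x1 + 0.4 * x2), "pos", "neg")
    if (length(unique(y)) < 2) return(NA_real_)
    d <- data.frame(y = y, x1 = x1, x2 = x2)
    v <- bootstrap_validate(d, "y", c("x1", "x2"), n_boot = 60,
                            seed = 100 + i, positive = "pos")
    v$auc_mean - v$apparent_auc
  })
  expect_lte(mean(diffs, na.rm = TRUE), 0)
})

test_that("calibration recovers identity for well-specified predictions", {
  set.seed(62)
  n <- 10000
  lp <- rnorm(n, sd = 1.2)
  y <- as.integer(runif(n) < plogis(lp))
  p <- plogis(lp)
  cal <- calibration_curve(p, y, n_bins = 10)
  expect_equal(cal$slope, 1, tolerance = 0.08)
  expect_equal(cal$intercept, 0, tolerance = 0.08)
  expect_equal(nrow(cal$bins), 10)
  expect_equal(sum(cal$bins$n), n)

  # doubling the logits halves the recalibration slope
  cal2 <- calibration_curve(plogis(2 * lp), y)
  expect_equal(cal2$slope, 0.5, tolerance = 0.05)

  # constant prediction at prevalence: single effective bin
  const <- calibration_curve(rep(mean(y), n), y)
  expect_equal(nrow(const$bins), 1)
  expect_equal(const$bins$pred_mean, mean(y))

  expect_error(calibration_curve(c(0, 0.5), c(0, 1)), "strictly")
})

test_that("net benefit matches confusion-matrix arithmetic everywhere", {
  set.seed(63)
  n <- 200
  p <- runif(n)
  y <- as.integer(runif(n) < p)
  thr <- seq(0.05, 0.95, by = 0.05)
  dca <- decision_curve(p, y, thresholds = thr)
  for (i in seq_along(thr)) {
    pt <- thr[i]
    tp <- sum(p >= pt & y == 1); fp <- sum(p >= pt & y == 0)
    expect_equal(dca$nb_model[i], tp / n - fp / n * pt / (1 - pt),
                 tolerance = 1e-12)
  }
  expect_true(all(dca$nb_none == 0))
  # treat-all closed form; at prevalence 0.5 and pt 0.5 it crosses zero
  prev <- mean(y)
  expect_equal(dca$nb_all,
               prev - (1 - prev) * thr / (1 - thr), tolerance = 1e-12)
  even <- decision_curve(rep(0.6, 4), c(1, 1, 0, 0), thresholds = 0.5)
  expect_equal(even$nb_all, 0)

  # perfect predictor: NB = prevalence below every case's probability
  perf <- decision_curve(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0),
                         thresholds = c(0.2, 0.5, 0.8))
  expect_true(all(perf$nb_model == 0.5))

  expect_error(decision_curve(p, y, thresholds = c(0, 0.5)), "strictly")
})

test_that("the full analysis report covers every published-table analog", {
  tb <- small_cohort(seed = 123)
  rep <- run_full_analysis(tb, n_boot = 50, seed = 123)

  params <- c("D", "Dstar", "f", "Ktrans", "Ve", "Kep")
  # agreement: one ICC per parameter, inside [-1, 1] with ordered CI
  expect_setequal(names(rep$agreement), params)
  for (a in rep$agreement) {
    expect_true(a$ci_low <= a$icc && a$icc <= a$ci_high)
  }
  # group-difference analogs for both stratifications
  expect_setequal(names(rep$group_tests), c("risk", "tp53"))
  expect_setequal(names(rep$group_tests$risk), params)
  expect_setequal(names(rep$risk_anova), params)
  # per-outcome model, ROC (each parameter + combined), validation,
  # calibration and decision curves
  for (oc in c("risk", "tp53")) {
    expect_setequal(names(rep$roc[[oc]]), c(params, "combined"))
    expect_true(all(rep$models[[oc]]$selected %in% params))
    expect_s3_class(rep$dca[[oc]], "dca_curve")
    expect_true(is.finite(rep$validation[[oc]]$auc_mean))
    expect_setequal(names(rep$delong[[oc]]), rep$models[[oc]]$selected)
  }

  # determinism of the whole report
  rep2 <- run_full_analysis(small_cohort(seed = 123), n_boot = 50,
                            seed = 123)
  expect_equal(rep$validation$risk$aucs, rep2$validation$risk$aucs)
  expect_equal(rep$roc$risk$combined$auc, rep2$roc$risk$combined$auc)
})

test_that("degenerate outcomes fail with a stage label", {
  tb <- small_cohort(seed = 5)
  tb$tp53 <- "mutant"
  expect_error(run_full_analysis(tb, n_boot = 10), "tp53")
})
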