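#' Bootstrap internal validation with backward elimination
#'
#' For each of `n_boot` resamples (with replacement, stratified by outcome
#' so both classes are always present): refit the logistic model on the
#' resample, backward-eliminate the largest-p predictor while any p-value
#' is at or above `bound`, then score the *original* table with the
#' resample's model and record its AUC. Reports the mean bootstrap AUC with
#' a percentile 95% CI and each predictor's selection frequency.
#'
#' @param table data frame.
#' @param outcome binary outcome column.
#' @param candidates character vector of candidate predictors (the
#'   starting model of every resample).
#' @param n_boot number of resamples (default 1000).
#' @param seed RNG seed (default 123).
#' @param bound backward-elimination retention bound on p (default 0.1).
#' @param positive outcome event level.
#' @return A `validation_report`: list with `n_boot`, `seed`, `bound`,
#'   `auc_mean`, `auc_ci` (percentile 2.5/97.5%), `apparent_auc` (full
#'   model on original data), `selection_frequency`, `aucs`.
#' @export
bootstrap_validate <- function(table, outcome, candidates, n_boot = 1000,
                               seed = 123, bound = 0.1, positive = NULL) {
  bo <- .binary_outcome(table[[outcome]], positive)
  keep <- bo$keep
  for (p in candidates) keep <- keep & is.finite(table[[p]])
  dat <- table[keep, c(outcome, candidates)]
  y <- as.integer(as.character(dat[[outcome]]) == bo$positive)
  idx_pos <- which(y == 1); idx_neg <- which(y == 0)
  assert_that(length(idx_pos) >= 2 && length(idx_neg) >= 2,
              "outcome is degenerate")
  x_orig <- as.matrix(dat[candidates])

  apparent <- .backward_fit(x_orig, y, candidates, bound)
  apparent_auc <- compute_roc(.lp(x_orig, apparent), y, positive = 1)$auc

  aucs <- numeric(n_boot)
  sel_count <- stats::setNames(numeric(length(candidates)), candidates)
  with_seed(seed, {
    for (i in seq_len(n_boot)) {
      bs <- c(sample(idx_pos, length(idx_pos), replace = TRUE),
              sample(idx_neg, length(idx_neg), replace = TRUE))
      mod <- .backward_fit(x_orig[bs, , drop = FALSE], y[bs], candidates,
                           bound)
      sel_count[mod$selected] <- sel_count[mod$selected] + 1
      aucs[i] <- compute_roc(.lp(x_orig, mod), y, positive = 1)$auc
    }
  })
  structure(list(n_boot = n_boot, seed = seed, bound = bound,
                 auc_mean = mean(aucs),
                 auc_ci = stats::quantile(aucs, c(0.025, 0.975),
                                          names = FALSE),
                 apparent_auc = apparent_auc,
                 selection_frequency = sel_count / n_boot,
                 aucs = aucs),
            class = "validation_report")
}

# Backward elimination on z-scored predictors: drop the largest-p term
# while any p >= bound (the intercept is never dropped); at least one
# predictor is always retained.
.backward_fit <- function(x, y, candidates, bound) {
  mu <- colMeans(x); sdev <- apply(x, 2, stats::sd)
  sdev[sdev == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sdev, "/")
  sel <- candidates
  repeat {
    xdes <- cbind(1, z[, sel, drop = FALSE])
    fit <- suppressWarnings(stats::glm.fit(xdes, y,
                                           family = stats::binomial()))
    sm <- .glm_wald(fit, xdes)
    pv <- sm$p[-1]
    if (length(sel) <= 1 || max(pv) < bound) break
    sel <- sel[-which.max(pv)]
  }
  list(selected = sel, coef = fit$coefficients, mu = mu[sel],
       sdev = sdev[sel])
}

.glm_wald <- function(fit, xmat) {
  # Wald z-tests from the IRLS weights of a glm.fit object
  w <- fit$weights
  xtwx <- crossprod(xmat * sqrt(w))
  cov <- tryCatch(solve(xtwx), error = function(e)
    matrix(Inf, ncol(xmat), ncol(xmat)))
  se <- sqrt(pmax(diag(cov), 0))
  zv <- fit$coefficients / se
  list(se = se, p = 2 * stats::pnorm(-abs(zv)))
}

.lp <- function(x, mod) {
  z <- sweep(sweep(x[, mod$selected, drop = FALSE], 2, mod$mu), 2,
             mod$sdev, "/")
  drop(mod$coef[1] + z %*% mod$coef[-1])
}

#' Calibration curve with logistic recalibration
#'
#' Bins predictions into equal-frequency groups and compares the mean
#' predicted probability with the observed event rate per bin; bins whose
#' predictions have zero spread are merged with their neighbor. Also
#' reports the logistic recalibration line: observed outcome regressed on
#' the logit of the predictions (slope 1 / intercept 0 indicate perfect
#' calibration) and the calibration-in-the-large intercept (offset model).
#'
#' @param predicted predicted probabilities in (0, 1).
#' @param observed binary outcomes (0/1 or logical).
#' @param n_bins number of equal-frequency bins (default 10).
#' @return list with `bins` (data frame `n`, `pred_mean`, `obs_rate`),
#'   `intercept`, `slope`, `citl`.
#' @export
calibration_curve <- function(predicted, observed, n_bins = 10) {
  observed <- as.integer(observed)
  assert_that(all(predicted > 0 & predicted < 1),
              "predictions must lie strictly in (0, 1)")
  assert_that(length(predicted) == length(observed),
              "predicted and observed lengths differ")
  lg <- stats::qlogis(predicted)
  if (stats::sd(lg) < 1e-12) {
    # constant prediction: a single effective bin; recalibration slope
    # is unidentified
    bins <- data.frame(n = length(predicted), pred_mean = mean(predicted),
                       obs_rate = mean(observed))
    return(list(bins = bins, intercept = NA_real_, slope = NA_real_,
                citl = stats::qlogis(mean(observed)) - mean(lg)))
  }
  qs <- unique(stats::quantile(predicted, probs = seq(0, 1,
                                                      length.out = n_bins + 1)))
  grp <- cut(predicted, qs, include.lowest = TRUE)
  bins <- do.call(rbind, lapply(split(seq_along(predicted), grp), function(i) {
    if (!length(i)) return(NULL)
    data.frame(n = length(i), pred_mean = mean(predicted[i]),
               obs_rate = mean(observed[i]))
  }))
  rownames(bins) <- NULL
  fit <- stats::glm(observed ~ lg, family = stats::binomial())
  citl <- stats::glm(observed ~ 1 + offset(lg),
                     family = stats::binomial())$coefficients[[1]]
  list(bins = bins, intercept = unname(fit$coefficients[1]),
       slope = unname(fit$coefficients[2]), citl = citl)
}

#' Decision curve analysis
#'
#' Net benefit of treating according to the model at each threshold
#' probability pt: NB(pt) = TP/n - FP/n * pt/(1-pt), where a subject is
#' "treated" when its predicted probability is >= pt. Also returns the
#' treat-all curve (everyone positive) and the treat-none reference (0).
#'
#' @param predicted predicted probabilities.
#' @param observed binary outcomes.
#' @param thresholds threshold grid strictly inside (0, 1); default
#'   0.01 to 0.99 by 0.01.
#' @return A `dca_curve` data frame with columns `threshold`, `nb_model`,
#'   `nb_all`, `nb_none`.
#' @export
decision_curve <- function(predicted, observed,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  observed <- as.integer(observed)
  assert_that(all(thresholds > 0 & thresholds < 1),
              "thresholds must lie strictly in (0, 1)")
  n <- length(observed)
  prev <- mean(observed)
  out <- lapply(thresholds, function(pt) {
    treat <- predicted >= pt
    tp <- sum(treat & observed == 1) / n
    fp <- sum(treat & observed == 0) / n
    w <- pt / (1 - pt)
    data.frame(threshold = pt,
               nb_model = tp - fp * w,
               nb_all = prev - (1 - prev) * w,
               nb_none = 0)
  })
  structure(do.call(rbind, out), class = c("dca_curve", "data.frame"))
}
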