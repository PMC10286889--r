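#' Empirical ROC curve with AUC, DeLong CI and Youden cutoff
#'
#' Builds the empirical ROC over all distinct score thresholds with the
#' convention "score >= threshold is called positive". The AUC is the
#' trapezoidal area, identical to the normalized Mann-Whitney statistic
#' with ties counted 1/2. The 95% CI uses the DeLong placement-value
#' variance. The reported cutoff maximizes Youden's J; ties are broken
#' toward higher specificity.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels binary labels; `positive` names the event level.
#' @param positive event level (default: `1` for 0/1 input, otherwise the
#'   alphabetically later level).
#' @return A `roc_result`: list with `points` (data frame `threshold`,
#'   `fpr`, `tpr`), `auc`, `ci_low`, `ci_high`, `se`, `cutoff`,
#'   `sensitivity`, `specificity`, `n_pos`, `n_neg`, plus the score/label
#'   vectors used (needed by [delong_test()]).
#' @export
compute_roc <- function(scores, labels, positive = NULL) {
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  bo <- .binary_outcome(labels, positive)
  y <- bo$y01
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  assert_that(n_pos > 0 && n_neg > 0, "both classes must be present")

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pos_scores <- scores[y == 1]; neg_scores <- scores[y == 0]
  tpr <- vapply(thr, function(t) mean(pos_scores >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg_scores >= t), numeric(1))
  points <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)

  # AUC via the rank (Mann-Whitney) formula, ties counted 1/2
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  se <- sqrt(.delong_var(scores, y))
  zc <- stats::qnorm(0.975)
  j <- tpr - fpr
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[which.min(fpr[best])]
  structure(list(points = points, auc = auc,
                 ci_low = max(0, auc - zc * se),
                 ci_high = min(1, auc + zc * se), se = se,
                 cutoff = thr[best], sensitivity = tpr[best],
                 specificity = 1 - fpr[best],
                 n_pos = n_pos, n_neg = n_neg,
                 scores = scores, y = y),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (95%% CI %.3f - %.3f), n = %d/%d\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  cat(sprintf("  Youden cutoff %.4g: sensitivity %.1f%%, specificity %.1f%%\n",
              x$cutoff, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

# DeLong placement values: for each case, the fraction of controls it beats
# (ties 1/2), and vice versa.
.placements <- function(scores, y) {
  xs <- scores[y == 1]; ys <- scores[y == 0]
  v10 <- vapply(xs, function(x) mean(ys < x) + 0.5 * mean(ys == x),
                numeric(1))
  v01 <- vapply(ys, function(x) mean(xs > x) + 0.5 * mean(xs == x),
                numeric(1))
  list(v10 = v10, v01 = v01)
}

.delong_var <- function(scores, y) {
  pl <- .placements(scores, y)
  stats::var(pl$v10) / length(pl$v10) + stats::var(pl$v01) / length(pl$v01)
}

#' DeLong test for two ROC curves
#'
#' Compares two AUCs using the DeLong placement-value covariance. For
#' paired designs (both scores on the same subjects, identical labels) the
#' covariance between the curves is included; for unpaired designs the
#' variances simply add.
#'
#' @param roc_a,roc_b `roc_result` objects from [compute_roc()].
#' @param paired logical; paired designs require identical label vectors.
#' @return list with `z`, `p` (two-sided), `auc_diff`, `se`.
#' @export
delong_test <- function(roc_a, roc_b, paired = TRUE) {
  stopifnot(inherits(roc_a, "roc_result"), inherits(roc_b, "roc_result"))
  if (paired) {
    assert_that(length(roc_a$y) == length(roc_b$y) &&
                  all(roc_a$y == roc_b$y),
                "paired comparison requires identical label vectors")
    pa <- .placements(roc_a$scores, roc_a$y)
    pb <- .placements(roc_b$scores, roc_b$y)
    m <- length(pa$v10); n <- length(pa$v01)
    s10 <- stats::cov(cbind(pa$v10, pb$v10))
    s01 <- stats::cov(cbind(pa$v01, pb$v01))
    var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
      (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  } else {
    var_diff <- roc_a$se^2 + roc_b$se^2
  }
  auc_diff <- roc_a$auc - roc_b$auc
  if (var_diff <= .Machine$double.eps) {
    # self-comparison: identical curves differ by exactly zero
    if (abs(auc_diff) <= .Machine$double.eps) {
      return(list(z = 0, p = 1, auc_diff = 0, se = 0))
    }
    stop_invalid("zero variance of the AUC difference (degenerate curves)")
  }
  z <- auc_diff / sqrt(var_diff)
  list(z = z, p = 2 * stats::pnorm(-abs(z)),
       auc_diff = auc_diff, se = sqrt(var_diff))
}
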