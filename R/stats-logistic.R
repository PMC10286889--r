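# Shared: binary outcome as 0/1 with explicit positive level.
.binary_outcome <- function(y, positive = NULL) {
  keep <- !is.na(y)
  lv <- unique(y[keep])
  assert_that(length(lv) == 2, "outcome must have exactly 2 levels")
  if (is.null(positive)) positive <- sort(as.character(lv))[2]
  assert_that(positive %in% as.character(lv),
              "positive level not found in outcome")
  list(y01 = as.integer(as.character(y) == positive), keep = keep,
       positive = positive)
}

#' Univariate logistic regression with per-1-SD odds ratio
#'
#' Maximum-likelihood logistic fit of a binary outcome on a single z-scored
#' predictor. The odds ratio is therefore per one standard deviation of the
#' predictor, with a Wald 95% confidence interval. Complete-case analysis:
#' rows with a missing outcome are dropped.
#'
#' @param table data frame.
#' @param outcome binary outcome column name.
#' @param predictor numeric predictor column name.
#' @param positive outcome level treated as the event (default: the
#'   alphabetically later level).
#' @return A `logistic_model`: list with `outcome`, `positive`,
#'   `predictors` (data frame with `or`, `ci_low`, `ci_high`, `p`,
#'   `coefficient`, `mean`, `sd`, `separation`), `intercept`,
#'   `linear_predictor` (per retained subject), `rows` (indices used),
#'   `converged`.
#' @export
fit_univariate_logistic <- function(table, outcome, predictor,
                                    positive = NULL) {
  fit_multivariate_logistic(table, outcome, predictor, entry_p = Inf,
                            positive = positive)
}

#' Multivariate logistic model with univariate entry rule
#'
#' Candidates first pass a univariate screen: only predictors whose
#' univariate per-1-SD logistic p-value is below `entry_p` enter the joint
#' fit. All predictors are z-scored, so joint odds ratios are also per
#' 1 SD. The subject-level linear predictor of the joint fit is retained as
#' the combined score for ROC analysis. Near-collinear candidate sets are
#' rejected.
#'
#' @param table data frame.
#' @param outcome binary outcome column name.
#' @param candidates character vector of numeric candidate columns.
#' @param entry_p univariate entry threshold (default 0.1); `Inf` admits
#'   every candidate (used for plain joint fits).
#' @param positive outcome level treated as the event.
#' @param max_condition condition-number threshold on the candidate
#'   correlation matrix (default 1e6).
#' @return A `logistic_model` (see [fit_univariate_logistic()]); the
#'   `predictors` table additionally carries `univariate_p` and `entered`.
#' @export
fit_multivariate_logistic <- function(table, outcome, candidates,
                                      entry_p = 0.1, positive = NULL,
                                      max_condition = 1e6) {
  assert_that(all(candidates %in% names(table)),
              "unknown candidate column(s)")
  bo <- .binary_outcome(table[[outcome]], positive)
  keep <- bo$keep
  for (p in candidates) keep <- keep & is.finite(table[[p]])
  rows <- which(keep)
  y <- as.integer(as.character(table[[outcome]][rows]) == bo$positive)
  assert_that(length(unique(y)) == 2, "outcome is degenerate after NA drop")

  # univariate screen (always reported)
  uni <- lapply(candidates, function(p) {
    x <- table[[p]][rows]
    z <- (x - mean(x)) / stats::sd(x)
    fit <- suppressWarnings(stats::glm(y ~ z, family = stats::binomial()))
    sm <- summary(fit)$coefficients
    list(p = p, coef = sm[2, 1], se = sm[2, 2], pval = sm[2, 4],
         separated = !fit$converged || sm[2, 2] > 10)
  })
  uni_p <- vapply(uni, `[[`, numeric(1), "pval")
  entered <- if (is.infinite(entry_p)) rep(TRUE, length(candidates)) else
    uni_p < entry_p
  assert_that(any(entered), "no candidate passes the univariate entry rule")
  sel <- candidates[entered]

  zmat <- vapply(sel, function(p) {
    x <- table[[p]][rows]
    (x - mean(x)) / stats::sd(x)
  }, numeric(length(rows)))
  zmat <- matrix(zmat, nrow = length(rows),
                 dimnames = list(NULL, sel))
  if (length(sel) > 1) {
    cn <- kappa(stats::cor(zmat), exact = TRUE)
    if (cn > max_condition) {
      cc <- stats::cor(zmat); diag(cc) <- 0
      worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
      stop_invalid("near-collinear candidates: ", sel[worst[1]], " and ",
                   sel[worst[2]])
    }
  }
  df <- data.frame(y = y, zmat, check.names = FALSE)
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  zcrit <- stats::qnorm(0.975)
  coefs <- sm[-1, , drop = FALSE]
  sep <- !fit$converged | coefs[, 2] > 10
  pred_tab <- data.frame(
    predictor = candidates,
    univariate_or = exp(vapply(uni, `[[`, numeric(1), "coef")),
    univariate_p = uni_p,
    entered = entered,
    coefficient = NA_real_, or = NA_real_, ci_low = NA_real_,
    ci_high = NA_real_, p = NA_real_,
    mean = vapply(candidates, function(p) mean(table[[p]][rows]),
                  numeric(1)),
    sd = vapply(candidates, function(p) stats::sd(table[[p]][rows]),
                numeric(1)),
    separation = FALSE)
  m <- match(sel, pred_tab$predictor)
  pred_tab$coefficient[m] <- coefs[, 1]
  pred_tab$or[m] <- exp(coefs[, 1])
  pred_tab$ci_low[m] <- exp(coefs[, 1] - zcrit * coefs[, 2])
  pred_tab$ci_high[m] <- exp(coefs[, 1] + zcrit * coefs[, 2])
  pred_tab$p[m] <- coefs[, 4]
  pred_tab$separation[m] <- sep
  structure(list(outcome = outcome, positive = bo$positive,
                 predictors = pred_tab,
                 intercept = unname(sm[1, 1]),
                 linear_predictor = unname(fit$linear.predictors),
                 fitted = unname(fit$fitted.values),
                 rows = rows, converged = fit$converged,
                 entry_p = entry_p, selected = sel),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("Logistic model: %s (event = %s), n = %d\n", x$outcome,
              x$positive, length(x$rows)))
  tab <- x$predictors[x$predictors$entered, ]
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %s: OR/1SD = %.3f (%.3f - %.3f), p = %.4g%s\n",
                tab$predictor[i], tab$or[i], tab$ci_low[i], tab$ci_high[i],
                tab$p[i],
                if (tab$separation[i]) " [unstable: separation]" else ""))
  }
  invisible(x)
}
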