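#' Full biomarker analysis of a two-reader cohort
#'
#' Runs the complete inferential pipeline on a cohort table:
#' two-reader agreement (ICC per parameter), reader averaging, three-level
#' risk ANOVA with pairwise follow-ups, normality-gated two-group
#' comparisons for both stratifications (low vs non-low risk; TP53 mutant
#' vs wild, complete-case), univariate and entry-rule multivariate logistic
#' models, single-parameter and combined-score ROC analysis with DeLong
#' comparisons, bootstrap internal validation with backward elimination,
#' calibration and decision curves. Single-parameter ROC scores are
#' oriented by the sign of the univariate logistic coefficient so that
#' higher score means higher event probability; the orientation is
#' recorded.
#'
#' @param cohort a `cohort_table` (two rows per patient).
#' @param parameters imaging parameters to analyze.
#' @param entry_p univariate entry threshold for the multivariate models
#'   (default 0.1).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed bootstrap seed (default 123).
#' @param dca_thresholds decision-curve threshold grid.
#' @return An `analysis_report` (nested list): `agreement`, `averaged`
#'   (per-patient table), `group_tests`, `risk_anova`, `models`, `roc`,
#'   `delong`, `validation`, `calibration`, `dca` — each keyed by outcome
#'   (`risk`, `tp53`) where applicable.
#' @export
run_full_analysis <- function(cohort,
                              parameters = c("D", "Dstar", "f", "Ktrans",
                                             "Ve", "Kep"),
                              entry_p = 0.1, n_boot = 1000, seed = 123,
                              dca_thresholds = seq(0.01, 0.99, by = 0.01)) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_invalid("stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  report <- list()
  report$agreement <- stage("agreement", cohort_agreement(cohort, parameters))
  avg <- stage("average_readers", average_readers(cohort))
  avg$risk_binary <- ifelse(avg$risk == "low", "low", "non_low")
  report$averaged <- avg

  outcomes <- list(
    risk = list(col = "risk_binary", positive = "non_low"),
    tp53 = list(col = "tp53", positive = "mutant"))

  report$risk_anova <- stage("risk_anova", {
    res <- lapply(parameters, function(p) {
      compare_three_groups(avg, p, "risk",
                           levels = c("low", "intermediate", "high"))
    })
    names(res) <- parameters
    res
  })

  report$group_tests <- list()
  report$models <- list(); report$roc <- list(); report$delong <- list()
  report$validation <- list(); report$calibration <- list()
  report$dca <- list()

  for (oc in names(outcomes)) {
    col <- outcomes[[oc]]$col; positive <- outcomes[[oc]]$positive
    lv <- unique(stats::na.omit(avg[[col]]))
    if (length(lv) != 2) {
      stop_invalid("stage 'group_tests:", oc,
                   "' failed: outcome has ", length(lv), " level(s)")
    }
    report$group_tests[[oc]] <- stage(paste0("group_tests:", oc), {
      res <- lapply(parameters, function(p) {
        compare_groups(avg, p, col, levels = c(setdiff(lv, positive),
                                               positive))
      })
      names(res) <- parameters
      res
    })
    model <- stage(paste0("logistic:", oc),
                   fit_multivariate_logistic(avg, col, parameters,
                                             entry_p = entry_p,
                                             positive = positive))
    report$models[[oc]] <- model

    rows <- model$rows
    y <- as.character(avg[[col]][rows])
    rocs <- stage(paste0("roc:", oc), {
      single <- lapply(parameters, function(p) {
        dir <- sign(log(model$predictors$univariate_or[
          model$predictors$predictor == p]))
        if (dir == 0) dir <- 1
        r <- compute_roc(dir * avg[[p]][rows], y, positive = positive)
        r$orientation <- if (dir >= 0) "higher" else "lower"
        r
      })
      names(single) <- parameters
      combined <- compute_roc(model$linear_predictor, y,
                              positive = positive)
      combined$orientation <- "higher"
      c(single, list(combined = combined))
    })
    report$roc[[oc]] <- rocs
    report$delong[[oc]] <- stage(paste0("delong:", oc), {
      res <- lapply(model$selected, function(p) {
        delong_test(rocs$combined, rocs[[p]], paired = TRUE)
      })
      names(res) <- model$selected
      res
    })
    report$validation[[oc]] <- stage(paste0("validation:", oc),
                                     bootstrap_validate(avg, col,
                                                        model$selected,
                                                        n_boot = n_boot,
                                                        seed = seed,
                                                        bound = entry_p,
                                                        positive = positive))
    report$calibration[[oc]] <- stage(paste0("calibration:", oc),
                                      calibration_curve(model$fitted,
                                                        as.integer(y == positive)))
    report$dca[[oc]] <- stage(paste0("dca:", oc),
                              decision_curve(model$fitted,
                                             as.integer(y == positive),
                                             thresholds = dca_thresholds))
  }
  class(report) <- "analysis_report"
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Quantitative-MRI biomarker analysis report\n")
  cat(sprintf("  %d patients, parameters: %s\n",
              nrow(x$averaged), paste(names(x$agreement), collapse = ", ")))
  for (oc in names(x$models)) {
    m <- x$models[[oc]]
    cat(sprintf("  [%s] combined model (%s): AUC = %.3f; bootstrap AUC = %.3f (%.3f - %.3f)\n",
                oc, paste(m$selected, collapse = " + "),
                x$roc[[oc]]$combined$auc,
                x$validation[[oc]]$auc_mean,
                x$validation[[oc]]$auc_ci[1], x$validation[[oc]]$auc_ci[2]))
  }
  invisible(x)
}
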