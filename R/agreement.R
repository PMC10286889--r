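#' Volume-of-interest mean of a parameter map
#'
#' Unweighted mean over all in-ROI, non-missing voxels. The ROI may be a
#' single 3-D mask or a list of per-slice 2-D masks (stacked along the
#' third axis), mirroring slice-by-slice tumor delineation.
#'
#' @param map 3-D numeric parameter map (missing voxels `NaN`/`NA`).
#' @param roi logical 3-D array, or list of logical 2-D slice masks.
#' @return The VOI mean (scalar).
#' @export
aggregate_voi <- function(map, roi) {
  if (is.list(roi)) roi <- simplify2array(roi)
  assert_that(identical(dim(map), dim(roi)),
              "map and ROI dimensions disagree")
  vals <- map[roi & !is.na(map)]
  assert_that(length(vals) > 0, "VOI is empty (no in-ROI, non-missing voxel)")
  mean(vals)
}

#' Two-way random-effects intraclass correlation (absolute agreement)
#'
#' Single-measure ICC for interchangeable raters, ICC(A,1) in the
#' McGraw-Wong taxonomy, computed from the two-way ANOVA mean squares
#' (subjects crossed with raters):
#' ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n).
#' The 95% confidence interval uses the F-distribution method, which yields
#' the asymmetric intervals typical of agreement reporting.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns
#'   (>= 5 subjects, >= 2 raters, no missing cells).
#' @param conf_level confidence level (default 0.95).
#' @return An `icc_result`: list with `icc`, `ci_low`, `ci_high`,
#'   `category` (see [classify_icc()]), `n_subjects`, `n_raters`, and the
#'   mean squares `msr`, `msc`, `mse`.
#' @export
icc_two_way <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  assert_that(n >= 5, "need at least 5 subjects")
  assert_that(k >= 2, "need at least 2 raters")
  assert_that(!anyNA(ratings), "missing cells are not supported")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_total <- sum((ratings - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  assert_that(ss_total > 0, "zero total variance: ICC undefined")
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # F-based CI for ICC(A,1) (McGraw & Wong)
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_star <- stats::qf(1 - alpha / 2, n - 1, v)
  ci_low <- (n * (msr - f_star * mse)) /
    (f_star * (k * msc + (k * n - k - n) * mse) + n * msr)
  f_star2 <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_high <- (n * (f_star2 * msr - mse)) /
    (k * msc + (k * n - k - n) * mse + n * f_star2 * msr)
  # perfect agreement degenerates the F bounds; the interval collapses
  if (!is.finite(ci_low)) ci_low <- icc
  if (!is.finite(ci_high)) ci_high <- icc
  ci_low <- max(min(ci_low, icc), -1)
  ci_high <- min(max(ci_high, icc), 1)
  structure(list(icc = icc, ci_low = ci_low, ci_high = ci_high,
                 category = classify_icc(icc), n_subjects = n, n_raters = k,
                 msr = msr, msc = msc, mse = mse),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f (95%% CI %.3f - %.3f), %s agreement (n = %d, k = %d)\n",
              x$icc, x$ci_low, x$ci_high, x$category, x$n_subjects,
              x$n_raters))
  invisible(x)
}

#' Classify an intraclass correlation coefficient
#'
#' Four-band agreement classification: poor (< 0.40),
#' fair (0.40 to < 0.60), good (0.60 to < 0.75), excellent (>= 0.75).
#'
#' @param icc a finite ICC value.
#' @return `"poor"`, `"fair"`, `"good"` or `"excellent"`.
#' @export
classify_icc <- function(icc) {
  assert_that(is_number(icc), "icc must be a finite number")
  if (icc < 0.40) "poor"
  else if (icc < 0.60) "fair"
  else if (icc < 0.75) "good"
  else "excellent"
}

#' Average the two readers of a cohort table
#'
#' Produces one row per patient whose parameter values are the arithmetic
#' mean of the two readers; labels and demographics are carried through.
#'
#' @param table a `cohort_table` with exactly two reader rows per patient.
#' @return A data frame with one row per patient (`reader_id` dropped).
#' @export
average_readers <- function(table) {
  counts <- base::table(table$patient_id)
  bad <- names(counts)[counts != 2]
  assert_that(length(bad) == 0,
              paste0("patients without exactly 2 reader rows: ",
                     paste(utils::head(bad, 5), collapse = ", ")))
  ord <- order(table$patient_id, table$reader_id)
  tb <- table[ord, ]
  num_cols <- intersect(c("D", "Dstar", "f", "Ktrans", "Ve", "Kep",
                          "age", "diameter"), names(tb))
  first <- tb[seq(1, nrow(tb), by = 2), ]
  second <- tb[seq(2, nrow(tb), by = 2), ]
  out <- first
  for (col in num_cols) out[[col]] <- (first[[col]] + second[[col]]) / 2
  out$reader_id <- NULL
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Per-parameter two-reader agreement of a cohort table
#'
#' @param table a `cohort_table`.
#' @param parameters parameter columns to assess.
#' @return named list of [icc_two_way()] results.
#' @export
cohort_agreement <- function(table,
                             parameters = c("D", "Dstar", "f", "Ktrans",
                                            "Ve", "Kep")) {
  ord <- order(table$patient_id, table$reader_id)
  tb <- table[ord, ]
  r1 <- tb[tb$reader_id == unique(tb$reader_id)[1], ]
  r2 <- tb[tb$reader_id == unique(tb$reader_id)[2], ]
  out <- lapply(parameters, function(p) {
    icc_two_way(cbind(r1[[p]], r2[[p]]))
  })
  names(out) <- parameters
  out
}
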