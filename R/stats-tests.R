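#' Shapiro-Wilk normality test
#'
#' @param x numeric sample of 3 to 5000 non-constant values.
#' @return list with `statistic` (W) and `p`.
#' @export
test_normality <- function(x) {
  x <- x[is.finite(x)]
  assert_that(length(x) >= 3 && length(x) <= 5000,
              "Shapiro-Wilk requires 3 <= n <= 5000")
  assert_that(stats::sd(x) > 0, "constant sample: normality test undefined")
  sw <- stats::shapiro.test(x)
  list(statistic = unname(sw$statistic), p = sw$p.value)
}

.summ_normal <- function(x) {
  sprintf("%.3g ± %.3g", mean(x), stats::sd(x))
}
.summ_skew <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  sprintf("%.3g (%.3g, %.3g)", q[2], q[1], q[3])
}

#' Normality-gated two-group comparison
#'
#' Tests a parameter between two groups: if both groups pass the
#' Shapiro-Wilk normality check (p > `alpha_normality`) an independent
#' samples t-test is used (Welch by default) and groups are summarized as
#' mean +/- SD; otherwise a Mann-Whitney U test with normal approximation
#' and tie correction (exact enumeration when min(n1, n2) <= 8 and no ties)
#' is used and groups are summarized as median (q1, q3).
#'
#' @param table data frame with the parameter and grouping columns.
#' @param parameter name of the numeric column to compare.
#' @param grouping name of the grouping column (exactly 2 levels used).
#' @param levels optional character vector of the two group levels.
#' @param alpha_normality gate for the normality check (default 0.05).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return A `group_comparison`: list with `parameter`, `groups`, `test`
#'   ("t" or "mann_whitney"), `statistic`, `p_value`, `normal` (gate
#'   outcome), and per-group `summaries`.
#' @export
compare_groups <- function(table, parameter, grouping, levels = NULL,
                           alpha_normality = 0.05, var_equal = FALSE) {
  assert_that(parameter %in% names(table), "unknown parameter column")
  assert_that(grouping %in% names(table), "unknown grouping column")
  g <- table[[grouping]]
  if (is.null(levels)) levels <- unique(stats::na.omit(g))
  assert_that(all(levels %in% g), "grouping level not present in data")
  assert_that(length(levels) == 2, "compare_groups needs exactly 2 levels")
  x1 <- table[[parameter]][!is.na(g) & g == levels[1]]
  x2 <- table[[parameter]][!is.na(g) & g == levels[2]]
  assert_that(length(x1) >= 3 && length(x2) >= 3,
              "need at least 3 observations per group")
  normal <- test_normality(x1)$p > alpha_normality &&
    test_normality(x2)$p > alpha_normality
  if (normal) {
    tt <- stats::t.test(x1, x2, var.equal = var_equal)
    res <- list(test = "t", statistic = unname(tt$statistic),
                p_value = tt$p.value,
                summaries = stats::setNames(c(.summ_normal(x1),
                                              .summ_normal(x2)), levels))
  } else {
    exact <- min(length(x1), length(x2)) <= 8 &&
      !any(duplicated(c(x1, x2)))
    wt <- stats::wilcox.test(x1, x2, exact = exact, correct = TRUE)
    res <- list(test = "mann_whitney", statistic = unname(wt$statistic),
                p_value = wt$p.value,
                summaries = stats::setNames(c(.summ_skew(x1),
                                              .summ_skew(x2)), levels))
  }
  structure(c(list(parameter = parameter, groups = levels, normal = normal),
              res),
            class = "group_comparison")
}

#' Three-group comparison with pairwise follow-ups
#'
#' One-way analysis of variance of a parameter across three (or more)
#' group levels, with each pairwise contrast routed through
#' [compare_groups()] (hence normality-gated). Levels with no observations
#' are dropped with a message.
#'
#' @param table data frame.
#' @param parameter numeric column name.
#' @param grouping grouping column name (e.g. the three risk levels).
#' @param levels optional explicit level order.
#' @return list with `anova` (`statistic` F, `df`, `p_value`), the levels
#'   used, and `pairwise` (list of `group_comparison` objects).
#' @export
compare_three_groups <- function(table, parameter, grouping, levels = NULL) {
  g <- table[[grouping]]
  if (is.null(levels)) levels <- unique(stats::na.omit(g))
  present <- levels[vapply(levels,
                           function(l) sum(g == l, na.rm = TRUE) >= 3,
                           logical(1))]
  if (length(present) < length(levels)) {
    message("dropping empty/small group level(s): ",
            paste(setdiff(levels, present), collapse = ", "))
  }
  assert_that(length(present) >= 2, "need at least 2 usable levels")
  sub <- table[!is.na(g) & g %in% present, ]
  fit <- stats::aov(sub[[parameter]] ~ factor(sub[[grouping]]))
  an <- summary(fit)[[1]]
  pairs <- utils::combn(present, 2, simplify = FALSE)
  pw <- lapply(pairs, function(pr) {
    compare_groups(sub, parameter, grouping, levels = pr)
  })
  names(pw) <- vapply(pairs, paste, character(1), collapse = " vs ")
  list(parameter = parameter,
       anova = list(statistic = an[["F value"]][1],
                    df = c(an[["Df"]][1], an[["Df"]][2]),
                    p_value = an[["Pr(>F)"]][1]),
       levels = present, pairwise = pw)
}
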