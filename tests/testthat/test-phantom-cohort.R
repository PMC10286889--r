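test_that("skewed cells match their quantile targets exactly", {
  cell <- skew_cell(0.61, 0.43, 1.14)   # strongly log-asymmetric
  expect_equal(cell$qfun(0.25), 0.43, tolerance = 1e-12)
  expect_equal(cell$qfun(0.50), 0.61, tolerance = 1e-12)
  expect_equal(cell$qfun(0.75), 1.14, tolerance = 1e-12)
  expect_true(all(cell$qfun(seq(0.001, 0.999, by = 0.001)) > 0))
  expect_error(skew_cell(0.5, 0.6, 0.9), "q1 < median")
})

test_that("truncated-normal cells hit their target moments", {
  # truncation at zero matters here: target mean is only 2.3 sd above 0
  cell <- norm_cell(0.72, 0.31, lower = 0)
  u <- (seq_len(2e5) - 0.5) / 2e5
  x <- cell$qfun(u)
  expect_true(all(x >= 0))
  expect_equal(mean(x), 0.72, tolerance = 0.002)
  expect_equal(stats::sd(x), 0.31, tolerance = 0.005)
})

test_that("cohort generator is reproducible with two consistent readers", {
  tb1 <- small_cohort(seed = 3)
  tb2 <- small_cohort(seed = 3)
  expect_identical(tb1, tb2)
  expect_equal(nrow(tb1), 2 * 74)
  expect_true(all(base::table(tb1$patient_id) == 2))
  # row-wise ratio identity for every reader row
  expect_lt(max(abs(tb1$Kep - tb1$Ktrans / tb1$Ve) /
                  pmax(tb1$Kep, 1e-12)), 1e-12)
  # label structure: 44/20/10 risk, 21/25/28 TP53
  avg <- average_readers(tb1)
  expect_equal(as.integer(base::table(avg$risk)[c("low", "intermediate",
                                                  "high")]),
               c(44L, 20L, 10L))
  expect_equal(sum(avg$tp53 == "mutant", na.rm = TRUE), 21)
  expect_equal(sum(avg$tp53 == "wild", na.rm = TRUE), 25)
  expect_equal(sum(is.na(avg$tp53)), 28)
})

test_that("zero reader noise gives identical readers and perfect ICC", {
  tb <- small_cohort(seed = 9, reader_sd = 0)
  r1 <- tb[tb$reader_id == "R1", ]
  r2 <- tb[tb$reader_id == "R2", ]
  expect_equal(r1$Ktrans, r2$Ktrans)
  agr <- cohort_agreement(tb, parameters = "Ktrans")
  expect_equal(agr$Ktrans$icc, 1)
})

test_that("identity copula yields uncorrelated parameters", {
  spec <- default_cohort_spec("risk", correlation = "independent")
  spec$groups <- spec$groups[1]
  spec$groups[[1]]$n <- 4000L
  spec$tp53_overlay <- FALSE
  tb <- generate_cohort(spec, reader_sd = 0, seed = 11)
  avg <- average_readers(tb)
  cm <- stats::cor(avg[, c("D", "Dstar", "f", "Ktrans", "Ve")])
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.05)
})

test_that("family copula induces the requested correlation", {
  spec <- default_cohort_spec("risk", correlation = "family")
  spec$groups <- spec$groups[1]
  spec$groups[[1]]$n <- 4000L
  spec$tp53_overlay <- FALSE
  tb <- generate_cohort(spec, reader_sd = 0, seed = 12)
  avg <- average_readers(tb)
  # rank correlation of a Gaussian copula: 6/pi asin(rho/2)
  expected <- 6 / pi * asin(0.3 / 2)
  expect_equal(stats::cor(avg$Ktrans, avg$Ve, method = "spearman"),
               expected, tolerance = 0.15)
})

test_that("infeasible specs are rejected", {
  expect_error(norm_cell(0.3, -1), "sd")
  bad_corr <- matrix(c(1, 2, 2, 1), 2,
                     dimnames = list(c("D", "f"), c("D", "f")))
  g <- cohort_group("g", 5, list(risk = "low"),
                    list(D = skew_cell(1, 0.5, 2),
                         f = norm_cell(2, 1)))
  expect_error(cohort_spec(list(g), correlation = bad_corr),
               "semi-definite")
})

test_that("enrollment roster assigns exclusions exactly and filters them", {
  counts <- c(non_ec_diagnosis = 7, figo_ii_or_higher = 16,
              prior_treatment = 4, incomplete_sequences = 3,
              inadequate_quality = 6, treated_elsewhere = 4)
  roster <- generate_enrollment_roster(counts, n_total = 114, seed = 1)
  flt <- apply_eligibility_filter(roster)
  expect_equal(flt$n_enrolled, 114 - sum(counts))
  expect_equal(flt$n_excluded, sum(counts))
  expect_equal(unname(flt$excluded_by_reason), unname(counts))

  # no exclusions at all
  none <- generate_enrollment_roster(counts * 0, n_total = 10, seed = 1)
  expect_equal(apply_eligibility_filter(none)$n_enrolled, 10)

  # permuting the reasons leaves the enrolled count unchanged
  perm <- generate_enrollment_roster(rev(counts), n_total = 114, seed = 1)
  expect_equal(apply_eligibility_filter(perm)$n_enrolled, flt$n_enrolled)

  expect_error(generate_enrollment_roster(c(a = 200), n_total = 114),
               "exceeds")
})

test_that("overlapping exclusion flags count once, matching a row scan", {
  roster <- data.frame(candidate_id = sprintf("C%02d", 1:8),
                       reason_a = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE,
                                    FALSE, FALSE),
                       reason_b = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
                                    FALSE, TRUE))
  flt <- apply_eligibility_filter(roster)
  # brute-force scan oracle
  brute <- 0
  for (i in seq_len(nrow(roster))) {
    if (!roster$reason_a[i] && !roster$reason_b[i]) brute <- brute + 1
  }
  expect_equal(flt$n_enrolled, brute)
  expect_equal(flt$n_excluded, 8 - brute)
})
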