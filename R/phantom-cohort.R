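#' Marginal distribution cells for cohort generation
#'
#' Per-parameter, per-group targets come in two reporting families.
#' `skew_cell()` targets a median with quartiles and is realized as a
#' two-piece log-normal: the quantile function is
#' Q(p) = m exp(sigma_L z_p) for p < 0.5 and m exp(sigma_R z_p) for p >= 0.5,
#' with the two log-scale spreads chosen so that q1, median and q3 are
#' matched exactly at population level while the variable stays positive and
#' may be skewed either way. `norm_cell()` targets a mean and standard
#' deviation and is realized as a normal truncated to physical bounds whose
#' underlying location/scale are solved numerically so that the *truncated*
#' moments equal the targets.
#'
#' @param median,q1,q3 target median and quartiles (q1 < median < q3, all
#'   > 0).
#' @param mean,sd target mean and standard deviation of the truncated draw.
#' @param lower,upper truncation bounds for `norm_cell`.
#' @return A cell object with a `qfun(p)` quantile function.
#' @name cohort-cells
NULL

#' @rdname cohort-cells
#' @export
skew_cell <- function(median, q1, q3) {
  assert_that(is_number(q1) && is_number(median) && is_number(q3),
              "median, q1, q3 must be numbers")
  assert_that(q1 > 0 && q1 < median && median < q3,
              "need 0 < q1 < median < q3")
  z75 <- stats::qnorm(0.75)
  sig_l <- log(median / q1) / z75
  sig_r <- log(q3 / median) / z75
  structure(list(kind = "skew", median = median, q1 = q1, q3 = q3,
                 qfun = function(p) {
                   # winsorize the extreme tails so heavy log-scale spreads
                   # cannot produce physically absurd draws; quartile
                   # targets are untouched
                   z <- stats::qnorm(pmin(pmax(p, 0.005), 0.995))
                   median * exp(ifelse(z < 0, sig_l, sig_r) * z)
                 }),
            class = "cohort_cell")
}

# mean/sd of a normal(mu, sig) truncated to [lo, hi]
trunc_moments <- function(mu, sig, lo, hi) {
  a <- (lo - mu) / sig; b <- (hi - mu) / sig
  z <- stats::pnorm(b) - stats::pnorm(a)
  pa <- stats::dnorm(a); pb <- stats::dnorm(b)
  m <- mu + sig * (pa - pb) / z
  v <- sig^2 * (1 + (a * pa - ifelse(is.finite(b), b * pb, 0)) / z -
                  ((pa - pb) / z)^2)
  c(mean = m, sd = sqrt(v))
}

#' @rdname cohort-cells
#' @export
norm_cell <- function(mean, sd, lower = 0, upper = Inf) {
  assert_that(is_number(mean) && is_number(sd) && sd > 0,
              "mean and sd must be numbers, sd > 0")
  assert_that(lower < mean && mean < upper,
              "target mean must lie inside the truncation bounds")
  # solve underlying (mu, sigma) so the truncated moments hit the target
  obj <- function(par) {
    mm <- trunc_moments(par[1], exp(par[2]), lower, upper)
    (mm[1] - mean)^2 / sd^2 + (mm[2] - sd)^2 / sd^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  mu <- fit$par[1]; sig <- exp(fit$par[2])
  plo <- stats::pnorm((lower - mu) / sig)
  phi <- stats::pnorm((upper - mu) / sig)
  structure(list(kind = "normal", mean = mean, sd = sd,
                 lower = lower, upper = upper, mu = mu, sigma = sig,
                 qfun = function(p) {
                   mu + sig * stats::qnorm(plo + p * (phi - plo))
                 }),
            class = "cohort_cell")
}

#' Define one cohort group
#'
#' @param name group name.
#' @param n group size (>= 2).
#' @param labels named list of label-column values carried by every patient
#'   of this group (e.g. `list(risk = "low")`).
#' @param cells named list of [skew_cell()]/[norm_cell()] objects, one per
#'   generated parameter.
#' @return A `cohort_group` object.
#' @export
cohort_group <- function(name, n, labels, cells) {
  assert_that(is_number(n) && n >= 2, "group size must be >= 2")
  assert_that(all(vapply(cells, inherits, logical(1), "cohort_cell")),
              "cells must be cohort_cell objects")
  structure(list(name = name, n = as.integer(n), labels = labels,
                 cells = cells),
            class = "cohort_group")
}

#' Define a cohort specification
#'
#' @param groups list of [cohort_group()] objects drawing the same parameter
#'   set.
#' @param correlation correlation matrix of the Gaussian copula over the
#'   generated imaging parameters (default identity). Must be symmetric
#'   positive semi-definite with unit diagonal.
#' @param tp53_overlay if `TRUE`, TP53 status is not drawn from its own
#'   groups but assigned afterwards from a covariate-linked sampler (see
#'   [generate_cohort()]); used by the risk-stratified default spec.
#' @param tp53_counts integer vector `c(mutant, wild)` used by the overlay.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(groups, correlation = NULL, tp53_overlay = FALSE,
                        tp53_counts = c(mutant = 21, wild = 25)) {
  assert_that(length(groups) >= 1, "need at least one group")
  par_names <- names(groups[[1]]$cells)
  for (g in groups) {
    assert_that(identical(names(g$cells), par_names),
                "all groups must define the same parameter cells")
  }
  img <- intersect(c("D", "Dstar", "f", "Ktrans", "Ve"), par_names)
  if (is.null(correlation)) {
    correlation <- diag(length(img))
    dimnames(correlation) <- list(img, img)
  }
  assert_that(isTRUE(all.equal(correlation, t(correlation))) &&
                all(abs(diag(correlation) - 1) < 1e-12),
              "correlation must be symmetric with unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  assert_that(min(ev) > -1e-8, "correlation must be positive semi-definite")
  structure(list(groups = groups, parameters = par_names,
                 imaging_parameters = img, correlation = correlation,
                 tp53_overlay = tp53_overlay, tp53_counts = tp53_counts),
            class = "cohort_spec")
}

# Table-3 / Table-2 distribution targets, display units
# (D, D* in 1e-3 mm^2/s; f in %; Ktrans, Kep in 1/min; Ve fraction).
.risk_targets <- function() list(
  low = list(n = 44,
             D = skew_cell(0.86, 0.64, 1.16),
             Dstar = skew_cell(44.35, 21.93, 95.33),
             f = norm_cell(2.43, 1.08),
             Ktrans = skew_cell(0.61, 0.43, 1.14),
             Ve = norm_cell(0.58, 0.25, upper = 1)),
  intermediate = list(n = 20,
                      D = skew_cell(0.55, 0.40, 0.81),
                      Dstar = skew_cell(52.00, 26.88, 74.33),
                      f = norm_cell(1.74, 0.96),
                      Ktrans = skew_cell(0.37, 0.29, 0.47),
                      Ve = norm_cell(0.33, 0.14, upper = 1)),
  high = list(n = 10,
              D = skew_cell(0.63, 0.40, 0.73),
              Dstar = skew_cell(58.40, 40.10, 88.73),
              f = norm_cell(1.64, 0.60),
              Ktrans = skew_cell(0.35, 0.15, 0.43),
              Ve = norm_cell(0.30, 0.07, upper = 1)))

.tp53_targets <- function() list(
  mutant = list(n = 21,
                D = norm_cell(0.72, 0.31),
                Dstar = skew_cell(43.70, 16.30, 90.75),
                f = norm_cell(2.30, 1.09),
                Ktrans = skew_cell(0.67, 0.41, 1.14),
                Ve = skew_cell(0.32, 0.25, 0.91)),
  wild = list(n = 25,
              D = norm_cell(0.91, 0.29),
              Dstar = skew_cell(50.60, 26.90, 82.75),
              f = norm_cell(2.20, 1.02),
              Ktrans = skew_cell(0.43, 0.37, 0.49),
              Ve = skew_cell(0.49, 0.36, 0.76)))

.demographic_cells <- function() {
  list(age = norm_cell(54.00, 7.91, lower = 18, upper = 90),
       diameter = skew_cell(25.10, 13.76, 42.58))
}

#' Stock cohort specifications matching the published group summaries
#'
#' `default_cohort_spec("risk")` defines the 74-patient early-stage cohort
#' stratified by ESMO risk (44 low / 20 intermediate / 10 high) with TP53
#' labels assigned by the covariate-linked overlay (21 mutant / 25 wild /
#' 28 untyped). `default_cohort_spec("tp53")` defines the 46 typed patients
#' drawn directly from the TP53-group distributions, with risk labels
#' assigned independently at the observed frequencies.
#'
#' @param stratification `"risk"` or `"tp53"`.
#' @param correlation `"independent"` (identity copula, the default) or
#'   `"family"` (0.3 between same-family perfusion parameter pairs
#'   D*--f and Ktrans--Ve), or a user correlation matrix.
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(stratification = c("risk", "tp53"),
                                correlation = c("independent", "family")) {
  stratification <- match.arg(stratification)
  img <- c("D", "Dstar", "f", "Ktrans", "Ve")
  if (is.character(correlation)) {
    correlation <- match.arg(correlation)
    cm <- diag(5); dimnames(cm) <- list(img, img)
    if (correlation == "family") {
      cm["Dstar", "f"] <- cm["f", "Dstar"] <- 0.3
      cm["Ktrans", "Ve"] <- cm["Ve", "Ktrans"] <- 0.3
    }
    correlation <- cm
  }
  targets <- if (stratification == "risk") .risk_targets() else .tp53_targets()
  label_col <- if (stratification == "risk") "risk" else "tp53"
  groups <- lapply(names(targets), function(gname) {
    tg <- targets[[gname]]
    cohort_group(gname, tg$n,
                 labels = stats::setNames(list(gname), label_col),
                 cells = c(tg[img], .demographic_cells()))
  })
  cohort_spec(groups, correlation = correlation,
              tp53_overlay = (stratification == "risk"))
}

# display units -> internal SI units
.to_si <- c(D = 1e-3, Dstar = 1e-3, f = 1e-2, Ktrans = 1, Ve = 1, Kep = 1,
            age = 1, diameter = 1)

#' Generate a synthetic two-reader patient cohort
#'
#' Draws per-patient latent imaging parameters group by group: a common
#' multivariate Gaussian is transformed through each parameter's marginal
#' quantile function (Gaussian copula), so marginal summaries match the
#' group targets while cross-parameter correlation follows the spec's
#' copula matrix. `Kep` is then derived as `Ktrans / Ve` patient-wise.
#' Each patient appears twice, once per reader; a reader's value is the
#' latent value plus independent Gaussian measurement noise (floored at
#' zero), and the reader's `Kep` is recomputed from that reader's `Ktrans`
#' and `Ve` so the ratio identity holds row-wise.
#'
#' When the spec requests a TP53 overlay, the typed subset is chosen at
#' random and mutant status is sampled without replacement with weights
#' increasing in standardized `Ktrans + Kep - D`, reproducing the reported
#' direction of the TP53 contrast without fixing its magnitude.
#'
#' @param spec a [cohort_spec()].
#' @param reader_sd either a single non-negative number interpreted as a
#'   fraction of each parameter's cohort standard deviation (default 0.42,
#'   which targets a two-reader intraclass correlation of about 0.85), a
#'   named vector of absolute per-parameter noise standard deviations in
#'   internal units, or 0 for identical readers.
#' @param seed integer seed.
#' @return A `cohort_table` data frame, one row per patient per reader, with
#'   columns `patient_id`, `reader_id`, `D`, `Dstar`, `f`, `Ktrans`, `Ve`,
#'   `Kep`, `risk`, `tp53`, `age`, `diameter`. Imaging parameters are in
#'   internal units: D and D* in mm^2/s, f and Ve as fractions, Ktrans and
#'   Kep in 1/min.
#' @export
generate_cohort <- function(spec, reader_sd = 0.42, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    lat <- .draw_latent(spec)
    lab <- lat$labels
    latent <- lat$values   # matrix patients x parameters, internal units

    if (isTRUE(spec$tp53_overlay)) {
      lab$tp53 <- .overlay_tp53(latent, spec$tp53_counts)
    }
    if (is.null(lab$risk)) {
      lab$risk <- sample(rep(c("low", "intermediate", "high"),
                             times = round(nrow(latent) *
                                             c(44, 20, 10) / 74))[
                                               seq_len(nrow(latent))])
    }
    if (is.null(lab$tp53)) lab$tp53 <- rep(NA_character_, nrow(latent))

    n <- nrow(latent)
    img <- spec$imaging_parameters
    noise_sd <- .reader_noise_sd(latent, reader_sd, spec$parameters)
    rows <- vector("list", 2L)
    for (r in 1:2) {
      vals <- latent
      for (p in colnames(latent)) {
        if (noise_sd[[p]] > 0) {
          vals[, p] <- latent[, p] + stats::rnorm(n, 0, noise_sd[[p]])
        }
      }
      # physical clamps after measurement noise
      for (p in intersect(c("D", "Dstar", "f", "Ktrans"), colnames(vals))) {
        vals[, p] <- pmax(vals[, p], 0)
      }
      if ("f" %in% colnames(vals)) vals[, "f"] <- pmin(vals[, "f"], 1)
      if ("Ve" %in% colnames(vals)) {
        vals[, "Ve"] <- pmin(pmax(vals[, "Ve"], 0.01), 1)
      }
      kep <- vals[, "Ktrans"] / vals[, "Ve"]
      rows[[r]] <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                              reader_id = paste0("R", r),
                              D = vals[, "D"], Dstar = vals[, "Dstar"],
                              f = vals[, "f"], Ktrans = vals[, "Ktrans"],
                              Ve = vals[, "Ve"], Kep = kep,
                              risk = lab$risk, tp53 = lab$tp53,
                              age = vals[, "age"],
                              diameter = vals[, "diameter"])
    }
    out <- rbind(rows[[1]], rows[[2]])
    out <- out[order(out$patient_id, out$reader_id), ]
    rownames(out) <- NULL
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

# Draw latent per-patient values (internal units) for every group.
.draw_latent <- function(spec) {
  img <- spec$imaging_parameters
  other <- setdiff(spec$parameters, img)
  chol_r <- chol(spec$correlation[img, img, drop = FALSE] +
                   diag(1e-12, length(img)))
  all_vals <- list(); all_labels <- list()
  for (g in spec$groups) {
    z <- matrix(stats::rnorm(g$n * length(img)), g$n) %*% chol_r
    u <- stats::pnorm(z)
    vals <- matrix(NA_real_, g$n, length(spec$parameters),
                   dimnames = list(NULL, spec$parameters))
    for (j in seq_along(img)) {
      p <- img[j]
      vals[, p] <- g$cells[[p]]$qfun(u[, j]) * .to_si[[p]]
    }
    for (p in other) {
      vals[, p] <- g$cells[[p]]$qfun(stats::runif(g$n)) * .to_si[[p]]
    }
    all_vals[[g$name]] <- vals
    all_labels[[g$name]] <- as.data.frame(g$labels)[rep(1, g$n), ,
                                                    drop = FALSE]
  }
  labels <- do.call(rbind, all_labels)
  rownames(labels) <- NULL
  list(values = do.call(rbind, all_vals), labels = labels)
}

.reader_noise_sd <- function(latent, reader_sd, parameters) {
  if (length(reader_sd) == 1 && is.null(names(reader_sd))) {
    assert_that(reader_sd >= 0, "reader_sd must be >= 0")
    # robust between-patient spread (IQR-based) so heavy upper tails of the
    # skewed parameters do not inflate the measurement-noise scale
    sds <- apply(latent, 2, function(x) stats::IQR(x) / 1.349)
    out <- as.list(sds * reader_sd)
  } else {
    out <- as.list(stats::setNames(rep(0, length(parameters)), parameters))
    for (p in names(reader_sd)) out[[p]] <- reader_sd[[p]]
  }
  # demographics are patient facts, not measurements: never noised
  out[["age"]] <- 0; out[["diameter"]] <- 0
  out
}

# Assign TP53 labels: typed subset at random, mutants sampled without
# replacement with weights exp(score), score = z(Ktrans) + z(Kep) - z(D).
.overlay_tp53 <- function(latent, counts) {
  n <- nrow(latent)
  n_typed <- sum(counts)
  assert_that(n_typed <= n, "tp53 counts exceed cohort size")
  typed <- sample.int(n, n_typed)
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  kep <- latent[, "Ktrans"] / latent[, "Ve"]
  score <- zs(latent[typed, "Ktrans"]) + zs(kep[typed]) - zs(latent[typed, "D"])
  mut_idx <- typed[sample.int(n_typed, counts[["mutant"]],
                              prob = exp(score))]
  lab <- rep(NA_character_, n)
  lab[typed] <- "wild"
  lab[mut_idx] <- "mutant"
  lab
}

#' Per-group summaries of a cohort table in display units
#'
#' Computes, for each group level and imaging parameter, the mean, sd,
#' median and quartiles after converting to display units (D, D* in
#' 1e-3 mm^2/s, f in percent). Used to compare generated cohorts against
#' their distribution targets.
#'
#' @param table a `cohort_table` (reader-averaged tables are accepted).
#' @param group_col grouping column, `"risk"` or `"tp53"`.
#' @return A data frame with one row per (group, parameter).
#' @export
cohort_summary <- function(table, group_col = "risk") {
  assert_that(group_col %in% names(table), "unknown grouping column")
  params <- c("D", "Dstar", "f", "Ktrans", "Ve", "Kep")
  lv <- unique(stats::na.omit(table[[group_col]]))
  out <- list()
  for (g in lv) {
    sub <- table[!is.na(table[[group_col]]) & table[[group_col]] == g, ]
    for (p in params) {
      x <- sub[[p]] / .to_si[[p]]
      qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      out[[length(out) + 1]] <- data.frame(
        group = g, parameter = p, n = length(x),
        mean = mean(x), sd = stats::sd(x),
        q1 = qs[1], median = qs[2], q3 = qs[3])
    }
  }
  do.call(rbind, out)
}
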