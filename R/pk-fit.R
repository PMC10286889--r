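.tofts_bounds <- list(Ktrans = c(0, 5), Ve = c(1e-3, 1))

#' Convert a dynamic SPGR signal to contrast-agent concentration
#'
#' Inverts the steady-state spoiled-gradient-echo signal equation frame by
#' frame. The mean of the baseline (pre-contrast) frames fixes the
#' equilibrium scale M0 sin(a) through the known T10; each frame's T1 is
#' then solved in closed form and converted to concentration via
#' C = (1/T1 - 1/T10) / r1.
#'
#' @param signal a `dce_signal` (columns `time`, `signal`).
#' @param protocol an [acquisition_protocol()].
#' @param t10 pre-contrast T1 in ms.
#' @param r1 relaxivity in 1/(s mM), default 4.5.
#' @return A `conc_curve` with attribute `clamped` (indices of frames whose
#'   signal exceeded the SPGR-attainable range and were clamped).
#' @export
signal_to_concentration <- function(signal, protocol, t10, r1 = 4.5) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  assert_that(is_number(t10) && t10 > 0, "t10 must be > 0")
  assert_that(is_number(r1) && r1 > 0, "r1 must be > 0")
  a <- protocol$flip_angle * pi / 180
  ca <- cos(a)
  nb <- protocol$n_baseline
  s <- signal$signal
  assert_that(length(s) >= nb, "fewer frames than n_baseline")
  e10 <- exp(-(protocol$tr / 1000) * (1000 / t10))
  s_base <- mean(s[seq_len(nb)])
  m0sin <- s_base * (1 - ca * e10) / (1 - e10)   # M0 sin(a)
  srel <- s / m0sin
  # S/M0sin = (1-E1)/(1-ca E1)  =>  E1 = (1 - srel) / (1 - ca*srel)
  attainable <- srel < 1
  clamped <- which(!attainable)
  if (length(clamped)) {
    warning(sprintf("%d frame(s) exceed the SPGR-attainable range; clamped",
                    length(clamped)))
    srel[!attainable] <- 1 - 1e-9
  }
  e1 <- (1 - srel) / (1 - ca * srel)
  e1 <- pmin(pmax(e1, 1e-15), 1 - 1e-15)
  r1_t <- -log(e1) / (protocol$tr / 1000)       # 1/s
  conc <- (r1_t - 1000 / t10) / r1
  out <- structure(data.frame(time = signal$time, conc = conc),
                   class = c("conc_curve", "data.frame"))
  attr(out, "clamped") <- clamped
  out
}

#' Extract an arterial input function from an artery signal
#'
#' Converts the artery's dynamic signal to blood concentration with the
#' blood T10, then divides by (1 - hematocrit) to obtain the plasma
#' concentration that drives the Tofts model.
#'
#' @param artery_signal a `dce_signal` measured in the artery.
#' @param protocol an [acquisition_protocol()].
#' @param t10_blood blood pre-contrast T1 in ms (default 1440).
#' @param r1 relaxivity in 1/(s mM).
#' @param hematocrit hematocrit fraction in [0, 1).
#' @return An `aif` object (negative conversion noise floored at zero).
#' @export
extract_aif <- function(artery_signal, protocol, t10_blood = 1440, r1 = 4.5,
                        hematocrit = 0.42) {
  assert_that(is_number(hematocrit) && hematocrit >= 0 && hematocrit < 1,
              "hematocrit must lie in [0, 1)")
  cb <- signal_to_concentration(artery_signal, protocol, t10_blood, r1)
  cp <- pmax(cb$conc, 0) / (1 - hematocrit)
  new_aif(cb$time, cp, hematocrit)
}

#' Fit the standard Tofts model to a tissue concentration curve
#'
#' Bound-constrained least squares over (Ktrans, Ve) minimizing
#' || Ct - Ktrans (Cp (*) exp(-Kep t)) ||^2 with Kep = Ktrans/Ve, using the
#' exact piecewise-linear exponential convolution. Kep is always emitted as
#' the fitted Ktrans/Ve.
#'
#' @param ct a `conc_curve` of tissue concentration.
#' @param aif an `aif` on the same time grid.
#' @param init starting [pk_params()] (default Ktrans 0.2, Ve 0.3).
#' @return A `dce_fit`: list with `pk` ([pk_params()] fields Ktrans, Ve,
#'   Kep), `rss`, `converged`.
#' @export
fit_tofts <- function(ct, aif, init = pk_params(0.2, 0.3)) {
  stopifnot(inherits(aif, "aif"), inherits(init, "pk_params"))
  assert_that(length(ct$time) == length(aif$times) &&
                max(abs(ct$time - aif$times)) < 1e-9,
              "concentration and AIF time grids are mismatched")
  y <- ct$conc
  if (all(abs(y) < .Machine$double.eps)) {
    return(structure(list(pk = structure(list(Ktrans = 0, Ve = 1, Kep = 0),
                                         class = "pk_params"),
                          rss = 0, converged = TRUE),
                     class = "dce_fit"))
  }
  lower <- c(.tofts_bounds$Ktrans[1], .tofts_bounds$Ve[1])
  upper <- c(.tofts_bounds$Ktrans[2], .tofts_bounds$Ve[2])
  start <- pmin(pmax(c(init$Ktrans, init$Ve), lower), upper)
  resid_fn <- function(p) {
    y - tofts_conv(p[1], p[1] / p[2], aif$cp, aif$times)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-15, ptol = 1e-15, maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    p <- start; converged <- FALSE
  } else {
    p <- fit$par; converged <- fit$info %in% 1:4
  }
  pk <- if (p[1] > 0) pk_params(p[1], p[2]) else
    structure(list(Ktrans = 0, Ve = p[2], Kep = 0), class = "pk_params")
  structure(list(pk = pk, rss = sum(resid_fn(p)^2), converged = converged),
            class = "dce_fit")
}

#' @export
print.dce_fit <- function(x, ...) {
  cat(sprintf("Tofts fit (%s), rss = %.3g\n",
              if (x$converged) "converged" else "NOT converged", x$rss))
  print(x$pk)
  invisible(x)
}

#' Voxelwise Tofts parameter maps
#'
#' Converts every masked voxel's dynamic signal to concentration and fits
#' the standard Tofts model. Out-of-mask voxels are `NaN`.
#'
#' @param stack 4-D DCE array (x, y, z, t).
#' @param mask logical 3-D array.
#' @param aif an `aif` object.
#' @param protocol an [acquisition_protocol()].
#' @param t10 tissue pre-contrast T1 in ms (scalar or 3-D map).
#' @param r1 relaxivity in 1/(s mM).
#' @return list of 3-D maps `Ktrans`, `Ve`, `Kep` plus logical `quality`.
#' @export
fit_tofts_map <- function(stack, mask, aif, protocol, t10 = 1400, r1 = 4.5) {
  assert_that(length(dim(stack)) == 4, "stack must be 4-D")
  assert_that(identical(dim(stack)[1:3], dim(mask)[1:3]),
              "stack and mask shapes disagree")
  assert_that(dim(stack)[4] == protocol$n_phases,
              "4th dimension must equal n_phases")
  assert_that(any(mask), "mask is empty")
  dims <- dim(stack)[1:3]
  t10_map <- if (length(t10) == 1) array(t10, dims) else t10
  maps <- list(Ktrans = array(NaN, dims), Ve = array(NaN, dims),
               Kep = array(NaN, dims), quality = array(FALSE, dims))
  times <- dce_times(protocol)
  voxmat <- matrix(stack, prod(dims), dim(stack)[4])
  for (i in which(mask)) {
    sig <- structure(data.frame(time = times, signal = voxmat[i, ]),
                     class = c("dce_signal", "data.frame"))
    conc <- suppressWarnings(
      signal_to_concentration(sig, protocol, t10_map[i], r1))
    fit <- fit_tofts(conc, aif)
    maps$Ktrans[i] <- fit$pk$Ktrans; maps$Ve[i] <- fit$pk$Ve
    maps$Kep[i] <- fit$pk$Kep
    maps$quality[i] <- isTRUE(fit$converged)
  }
  maps
}
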