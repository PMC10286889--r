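# Bounded parameter ranges for IVIM fits (mm^2/s where applicable).
# D* is kept above 3e-3 so the pseudo-diffusion component stays faster
# than any plausible tissue diffusion.
.ivim_bounds <- list(D = c(0, 3e-3), Dstar = c(3e-3, 0.5), f = c(0, 1))

#' High-b mono-exponential fit
#'
#' Ordinary least squares of log-signal on b restricted to b >= `b_min`;
#' the perfusion compartment is assumed fully attenuated there, so
#' D = -slope and the intercept extrapolates the diffusion-only signal to
#' b = 0.
#'
#' @param signal a `dwi_signal` (columns `b`, `signal`).
#' @param b_min lower b-value cutoff (s/mm^2), default 200.
#' @return list with `D` and `intercept` (signal units).
#' @export
fit_monoexponential <- function(signal, b_min = 200) {
  use <- signal$b >= b_min
  pos <- use & signal$signal > 0
  if (any(use & !pos)) {
    warning("nonpositive signals at high b excluded from log-linear fit")
  }
  assert_that(sum(pos) >= 2,
              "need at least 2 positive signals at b >= b_min")
  b <- signal$b[pos]; y <- log(signal$signal[pos])
  fit <- stats::lm.fit(cbind(1, b), y)
  list(D = -unname(fit$coefficients[2]),
       intercept = exp(unname(fit$coefficients[1])))
}

#' Segmented IVIM fit
#'
#' Classic two-step estimator of the bi-exponential IVIM model with a
#' fixed-point refinement. Step 1 fits D and the extrapolated intercept by
#' log-linear OLS on b >= `b_threshold`; step 2 takes
#' f = 1 - intercept/S0 and estimates D* by bounded one-dimensional least
#' squares on the full curve (linear signal scale) with D and f held fixed.
#' Because the perfusion compartment is not exactly zero at the threshold,
#' the two steps are then iterated: the current perfusion component
#' f S0 exp(-b D*) is subtracted from the high-b signals before refitting
#' D, which converges to the exact parameters on noiseless data.
#'
#' @param signal a `dwi_signal`.
#' @param protocol an [acquisition_protocol()] (used for validation of the
#'   b-schedule).
#' @param b_threshold perfusion/diffusion split (s/mm^2), default 200.
#' @param max_iter maximum fixed-point refinements (default 30).
#' @param tol relative parameter-change convergence tolerance.
#' @return An `ivim_fit` object: list with `params` ([ivim_params()]),
#'   `rss`, `converged`, `method`, `n_iter`.
#' @export
fit_ivim_segmented <- function(signal, protocol = NULL, b_threshold = 200,
                               max_iter = 30, tol = 1e-10) {
  if (!is.null(protocol)) {
    assert_that(length(signal$b) == length(protocol$b_values) &&
                  max(abs(signal$b - protocol$b_values)) < 1e-9,
                "signal b-values do not match the protocol schedule")
  }
  b <- signal$b; s <- signal$signal
  s0 <- s[b == 0][1]
  if (!is_number(s0) || s0 <= 0) {
    return(.ivim_failed("segmented"))
  }
  high <- b >= b_threshold

  est <- tryCatch(fit_monoexponential(signal, b_threshold),
                  error = function(e) NULL)
  if (is.null(est)) return(.ivim_failed("segmented"))
  D <- min(max(est$D, .ivim_bounds$D[1]), .ivim_bounds$D[2])
  f <- min(max(1 - est$intercept / s0, .ivim_bounds$f[1]), .ivim_bounds$f[2])
  Dstar <- max(10 * D, .ivim_bounds$Dstar[1])
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    Dstar <- .fit_dstar_1d(b, s, s0, D, f)
    if (f <= 0) { Dstar <- max(10 * D, .ivim_bounds$Dstar[1]) }
    # refine: remove the perfusion component, refit the diffusion step
    s_corr <- s - f * s0 * exp(-b * Dstar)
    pos <- high & s_corr > 0
    if (sum(pos) < 2) break
    co <- stats::lm.fit(cbind(1, b[pos]), log(s_corr[pos]))$coefficients
    D_new <- min(max(-unname(co[2]), .ivim_bounds$D[1]), .ivim_bounds$D[2])
    f_new <- min(max(1 - exp(unname(co[1])) / s0, .ivim_bounds$f[1]),
                 .ivim_bounds$f[2])
    delta <- max(abs(D_new - D) / max(D, 1e-12),
                 abs(f_new - f) / max(f, 1e-12))
    D <- D_new; f <- f_new
    if (delta < tol) break
  }
  Dstar <- max(Dstar, D)  # enforce D <= D*
  params <- ivim_params(D = D, Dstar = Dstar, f = f, S0 = s0)
  pred <- simulate_ivim_signal(params,
                               acquisition_protocol(b_values = b))$signal
  structure(list(params = params, rss = sum((s - pred)^2), converged = TRUE,
                 method = "segmented", n_iter = n_iter),
            class = "ivim_fit")
}

# 1-D bounded least squares for D* with (S0, D, f) fixed.
.fit_dstar_1d <- function(b, s, s0, D, f) {
  if (f <= 0) return(.ivim_bounds$Dstar[1])
  obj <- function(ds) {
    pred <- s0 * ((1 - f) * exp(-b * D) + f * exp(-b * ds))
    sum((s - pred)^2)
  }
  lo <- max(.ivim_bounds$Dstar[1], D)
  opt <- stats::optimize(obj, c(lo, .ivim_bounds$Dstar[2]), tol = 1e-14)
  # optimize() can miss a boundary optimum by its tolerance; polish locally
  cand <- c(opt$minimum, lo, .ivim_bounds$Dstar[2])
  cand[which.min(vapply(cand, obj, numeric(1)))]
}

.ivim_failed <- function(method) {
  structure(list(params = NULL, rss = NA_real_, converged = FALSE,
                 method = method, n_iter = 0L),
            class = "ivim_fit")
}

#' Full nonlinear least-squares IVIM fit
#'
#' Bound-constrained Levenberg-Marquardt fit of (S0, D, D*, f) on the
#' linear signal scale, initialized at the segmented estimate unless an
#' explicit `init` is given.
#'
#' @param signal a `dwi_signal`.
#' @param protocol optional [acquisition_protocol()] for schedule checking.
#' @param init optional [ivim_params()] starting point within bounds.
#' @return An `ivim_fit` with `method = "full"`. If the optimizer fails the
#'   best available iterate is returned with `converged = FALSE`.
#' @export
fit_ivim_full <- function(signal, protocol = NULL, init = NULL) {
  if (is.null(init)) {
    seg <- fit_ivim_segmented(signal, protocol)
    if (!seg$converged) return(.ivim_failed("full"))
    init <- seg$params
  }
  stopifnot(inherits(init, "ivim_params"))
  b <- signal$b; s <- signal$signal
  lower <- c(1e-9, .ivim_bounds$D[1], .ivim_bounds$Dstar[1],
             .ivim_bounds$f[1])
  upper <- c(Inf, .ivim_bounds$D[2], .ivim_bounds$Dstar[2],
             .ivim_bounds$f[2])
  start <- pmin(pmax(c(init$S0, init$D, init$Dstar, init$f), lower), upper)
  resid_fn <- function(p) {
    s - p[1] * ((1 - p[4]) * exp(-b * p[2]) + p[4] * exp(-b * p[3]))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-15, ptol = 1e-15, maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    p <- start; converged <- FALSE; n_iter <- 0L
  } else {
    p <- fit$par; converged <- fit$info %in% 1:4; n_iter <- fit$niter
  }
  p[3] <- max(p[3], p[2])
  params <- ivim_params(D = p[2], Dstar = p[3], f = p[4], S0 = p[1])
  structure(list(params = params, rss = sum(resid_fn(p)^2),
                 converged = converged, method = "full", n_iter = n_iter),
            class = "ivim_fit")
}

#' @export
print.ivim_fit <- function(x, ...) {
  cat(sprintf("IVIM %s fit (%s, %d iterations), rss = %.3g\n", x$method,
              if (x$converged) "converged" else "NOT converged", x$n_iter,
              x$rss))
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' Voxelwise IVIM parameter maps
#'
#' Fits every voxel inside the mask; voxels outside the mask are `NaN` in
#' all maps. Voxels whose fit does not converge are flagged in the quality
#' map but still carry their best-iterate parameters.
#'
#' @param stack 4-D DWI array (x, y, z, b).
#' @param mask logical 3-D array; must contain at least one voxel.
#' @param protocol an [acquisition_protocol()] matching the 4th dimension.
#' @param method `"segmented"` (default) or `"full"`.
#' @return list of 3-D maps `D`, `Dstar`, `f`, `S0` plus logical `quality`
#'   (TRUE = converged).
#' @export
fit_ivim_map <- function(stack, mask, protocol,
                         method = c("segmented", "full")) {
  method <- match.arg(method)
  assert_that(length(dim(stack)) == 4, "stack must be 4-D")
  assert_that(identical(dim(stack)[1:3], dim(mask)[1:3]),
              "stack and mask shapes disagree")
  assert_that(dim(stack)[4] == length(protocol$b_values),
              "4th dimension must match the b-value schedule")
  assert_that(any(mask), "mask is empty")
  dims <- dim(stack)[1:3]
  maps <- list(D = array(NaN, dims), Dstar = array(NaN, dims),
               f = array(NaN, dims), S0 = array(NaN, dims),
               quality = array(FALSE, dims))
  idx <- which(mask)
  voxmat <- matrix(stack, prod(dims), dim(stack)[4])
  for (i in idx) {
    sig <- structure(data.frame(b = protocol$b_values, signal = voxmat[i, ]),
                     class = c("dwi_signal", "data.frame"))
    fit <- if (method == "segmented") fit_ivim_segmented(sig, protocol)
    else fit_ivim_full(sig, protocol)
    if (!is.null(fit$params)) {
      maps$D[i] <- fit$params$D; maps$Dstar[i] <- fit$params$Dstar
      maps$f[i] <- fit$params$f; maps$S0[i] <- fit$params$S0
    }
    maps$quality[i] <- isTRUE(fit$converged)
  }
  maps
}
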