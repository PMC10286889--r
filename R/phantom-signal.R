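#' Simulate a noiseless IVIM diffusion signal
#'
#' Evaluates the bi-exponential IVIM model
#' S(b) = S0 * ((1 - f) exp(-b D) + f exp(-b D*))
#' at every b-value of the protocol.
#'
#' @param params an [ivim_params()] object.
#' @param protocol an [acquisition_protocol()] supplying the b-value schedule.
#' @return A `dwi_signal`: data frame with columns `b` (s/mm^2) and `signal`.
#' @export
simulate_ivim_signal <- function(params, protocol) {
  stopifnot(inherits(params, "ivim_params"),
            inherits(protocol, "acquisition_protocol"))
  b <- protocol$b_values
  s <- params$S0 * ((1 - params$f) * exp(-b * params$D) +
                      params$f * exp(-b * params$Dstar))
  structure(data.frame(b = b, signal = s),
            class = c("dwi_signal", "data.frame"))
}

#' Add Rician noise to a magnitude MR signal
#'
#' Magnitude MRI noise: each value s is replaced by
#' sqrt((s + n1)^2 + n2^2) with n1, n2 independent zero-mean Gaussians of
#' standard deviation `sigma = S0 / snr`, where S0 is the b = 0 (or supplied
#' reference) signal. SNR is therefore defined on the unweighted signal.
#'
#' @param signal a `dwi_signal` (or any data frame with a `signal` column).
#' @param snr signal-to-noise ratio S0/sigma, > 0.
#' @param seed integer seed for reproducibility (optional).
#' @param s_ref reference signal defining sigma; defaults to the first
#'   (b = 0) entry of `signal`.
#' @return The input with its `signal` column replaced by noisy magnitudes.
#' @export
add_rician_noise <- function(signal, snr, seed = NULL, s_ref = NULL) {
  assert_that(is_number(snr) && snr > 0, "snr must be > 0")
  s <- signal$signal
  assert_that(!is.null(s), "signal must have a 'signal' column")
  s_ref <- s_ref %||% s[1]
  sigma <- s_ref / snr
  with_seed(seed, {
    n1 <- stats::rnorm(length(s), 0, sigma)
    n2 <- stats::rnorm(length(s), 0, sigma)
    signal$signal <- sqrt((s + n1)^2 + n2^2)
  })
  signal
}

# Parker population AIF (plasma concentration, mM) at time t minutes after
# bolus arrival, for a 0.1 mmol/kg dose. Two Gaussians plus a
# sigmoid-modulated exponential washout.
parker_cp <- function(t_min) {
  A <- c(0.809, 0.330); T0 <- c(0.17046, 0.365); sg <- c(0.0563, 0.132)
  alpha <- 1.050; beta <- 0.1685; s <- 38.078; tau <- 0.483
  g <- A[1] / (sg[1] * sqrt(2 * pi)) * exp(-(t_min - T0[1])^2 / (2 * sg[1]^2)) +
    A[2] / (sg[2] * sqrt(2 * pi)) * exp(-(t_min - T0[2])^2 / (2 * sg[2]^2))
  g + alpha * exp(-beta * t_min) / (1 + exp(-s * (t_min - tau)))
}

# Weinmann bi-exponential plasma clearance (mM) for dose in mmol/kg.
weinmann_cp <- function(t_min, dose) {
  dose * (3.99 * exp(-0.144 * t_min) + 4.78 * exp(-0.0111 * t_min))
}

#' Simulate a population arterial input function
#'
#' Returns the plasma contrast-agent concentration sampled on the DCE frame
#' grid. The bolus arrives at the end of the baseline period; all baseline
#' frames have zero concentration. Two population models are available:
#' `"biexponential"` (Weinmann-type clearance, analytically convenient) and
#' `"parker"` (first-pass peaks plus washout, at its published coefficients
#' for a 0.1 mmol/kg dose, scaled linearly in dose).
#'
#' @param protocol an [acquisition_protocol()].
#' @param aif_model `"biexponential"` (default) or `"parker"`.
#' @param dose contrast dose in mmol/kg (default 0.1, i.e. 0.2 mL/kg of a
#'   0.5 mmol/mL gadolinium chelate).
#' @param hematocrit hematocrit fraction recorded on the object (used by
#'   blood/plasma conversions downstream); default 0.42.
#' @return An `aif` object: list with `times` (s), `cp` (mM), `hematocrit`.
#' @export
simulate_aif <- function(protocol, aif_model = c("biexponential", "parker"),
                         dose = 0.1, hematocrit = 0.42) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  aif_model <- match.arg(aif_model)
  assert_that(is_number(dose) && dose > 0, "dose must be > 0")
  times <- dce_times(protocol)
  onset <- protocol$n_baseline * protocol$dt
  t_min <- pmax(times - onset, 0) / 60
  cp <- switch(aif_model,
               biexponential = weinmann_cp(t_min, dose),
               parker = parker_cp(t_min) * dose / 0.1)
  cp[times < onset] <- 0
  # arrival exactly at the onset frame: Parker starts at ~0 there anyway;
  # the bi-exponential starts at its full mixing value
  new_aif(times, cp, hematocrit)
}

#' Construct an arterial input function object
#'
#' @param times frame times in seconds, strictly increasing, uniform spacing.
#' @param cp plasma concentration (mM), non-negative, same length as times.
#' @param hematocrit hematocrit fraction in [0, 1).
#' @return An `aif` object.
#' @export
new_aif <- function(times, cp, hematocrit = 0.42) {
  assert_that(length(times) == length(cp), "times and cp must match")
  assert_that(all(diff(times) > 0), "times must be strictly increasing")
  if (length(times) > 2) {
    dts <- diff(times)
    assert_that(max(abs(dts - dts[1])) < 1e-9 * dts[1] + 1e-12,
                "times must be uniformly spaced")
  }
  assert_that(all(cp >= 0), "cp must be non-negative")
  assert_that(is_number(hematocrit) && hematocrit >= 0 && hematocrit < 1,
              "hematocrit must lie in [0, 1)")
  structure(list(times = as.numeric(times), cp = as.numeric(cp),
                 hematocrit = hematocrit),
            class = "aif")
}

#' Tissue concentration under the standard Tofts model
#'
#' Computes Ct(t) = Ktrans * integral_0^t Cp(u) exp(-Kep (t - u)) du on the
#' AIF time grid, using an exact exponential recursion that treats Cp as
#' piecewise linear between frames (stable at coarse frame spacing).
#'
#' @param pk a [pk_params()] object.
#' @param aif an `aif` object.
#' @param times optional time grid; must equal the AIF grid if supplied.
#' @return A `conc_curve`: data frame with columns `time` (s) and `conc` (mM).
#' @export
simulate_tofts_concentration <- function(pk, aif, times = NULL) {
  stopifnot(inherits(pk, "pk_params"), inherits(aif, "aif"))
  if (!is.null(times)) {
    assert_that(length(times) == length(aif$times) &&
                  max(abs(times - aif$times)) < 1e-9,
                "times must align with the AIF time grid")
  }
  ct <- tofts_conv(pk$Ktrans, pk$Kep, aif$cp, aif$times)
  structure(data.frame(time = aif$times, conc = ct),
            class = c("conc_curve", "data.frame"))
}

# Exact convolution Ktrans * (Cp (*) exp(-kep t)) for piecewise-linear Cp
# sampled at uniform times (seconds); kep in 1/min.
tofts_conv <- function(ktrans, kep, cp, times) {
  n <- length(cp)
  if (n == 0) return(numeric(0))
  dt_min <- if (n > 1) (times[2] - times[1]) / 60 else 0
  k <- kep
  ct <- numeric(n)
  if (ktrans == 0 || n == 1) return(ct)
  x <- k * dt_min
  if (x > 1e-5) {
    E <- exp(-x)
    w0 <- (1 - E - x * E) / (k^2 * dt_min)   # weight of cp[i-1]
    w1 <- (x - 1 + E) / (k^2 * dt_min)       # weight of cp[i]
  } else {
    # series expansion, stable as kep -> 0 (weights -> trapezoid dt/2)
    E <- exp(-x)
    w0 <- dt_min * (1 / 2 - x / 3 + x^2 / 8)
    w1 <- dt_min * (1 / 2 - x / 6 + x^2 / 24)
  }
  acc <- 0
  for (i in 2:n) {
    acc <- acc * E + cp[i - 1] * w0 + cp[i] * w1
    ct[i] <- acc
  }
  ktrans * ct
}

#' Convert a concentration curve to a spoiled-gradient-echo signal
#'
#' Applies the fast-exchange relaxivity model 1/T1(t) = 1/T10 + r1 C(t) and
#' the steady-state SPGR signal equation
#' S = M0 sin(a) (1 - E1) / (1 - cos(a) E1), E1 = exp(-TR/T1).
#' At C = 0 the baseline signal is reproduced exactly.
#'
#' @param conc a `conc_curve` (columns `time`, `conc`).
#' @param truth a [tissue_truth()] supplying T10 (ms), or a single number
#'   interpreted as T10 in ms.
#' @param protocol an [acquisition_protocol()] (TR, flip angle).
#' @param r1 longitudinal relaxivity in 1/(s mM); default 4.5 (gadopentetate
#'   at 1.5 T).
#' @param m0 equilibrium magnetization scale (arbitrary units, default 1000).
#' @return A `dce_signal`: data frame with columns `time` and `signal`.
#' @export
concentration_to_spgr_signal <- function(conc, truth, protocol, r1 = 4.5,
                                         m0 = 1000) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  t10 <- if (inherits(truth, "tissue_truth")) truth$t10 else truth
  assert_that(is_number(t10) && t10 > 0, "t10 must be > 0")
  assert_that(is_number(r1) && r1 > 0, "r1 must be > 0")
  a <- protocol$flip_angle * pi / 180
  assert_that(sin(a) > 1e-12, "flip angle of 0 or 180 degrees is degenerate")
  r1_t <- 1000 / t10 + r1 * conc$conc       # 1/s; T10, TR in ms
  e1 <- exp(-(protocol$tr / 1000) * r1_t)
  s <- m0 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
  structure(data.frame(time = conc$time, signal = s),
            class = c("dce_signal", "data.frame"))
}
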