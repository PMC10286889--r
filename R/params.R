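#' IVIM parameter set
#'
#' Parameters of the bi-exponential intravoxel-incoherent-motion signal
#' model: S(b)/S0 = (1 - f) exp(-b D) + f exp(-b D*).
#'
#' @param D true diffusion coefficient (mm^2/s).
#' @param Dstar pseudo-diffusion coefficient (mm^2/s); must be >= D.
#' @param f microvascular volume fraction, stored as a fraction in [0, 1].
#' @param S0 unweighted (b = 0) signal, arbitrary units, > 0.
#' @return An object of class `ivim_params`.
#' @export
ivim_params <- function(D, Dstar, f, S0 = 1) {
  assert_that(is_number(D) && D >= 0, "D must be a finite number >= 0")
  assert_that(is_number(Dstar) && Dstar >= D,
              "Dstar must be a finite number >= D")
  assert_that(is_number(f) && f >= 0 && f <= 1, "f must lie in [0, 1]")
  assert_that(is_number(S0) && S0 > 0, "S0 must be > 0")
  structure(list(D = D, Dstar = Dstar, f = f, S0 = S0),
            class = "ivim_params")
}

#' Tofts pharmacokinetic parameter set
#'
#' Standard-Tofts parameters. `Kep` is always derived as `Ktrans / Ve`; it
#' cannot be supplied independently.
#'
#' @param Ktrans volume transfer constant (1/min), >= 0.
#' @param Ve extravascular extracellular volume fraction in (0, 1].
#' @return An object of class `pk_params` with fields `Ktrans`, `Ve`, `Kep`.
#' @export
pk_params <- function(Ktrans, Ve) {
  assert_that(is_number(Ktrans) && Ktrans >= 0, "Ktrans must be >= 0")
  assert_that(is_number(Ve) && Ve > 0 && Ve <= 1, "Ve must lie in (0, 1]")
  structure(list(Ktrans = Ktrans, Ve = Ve, Kep = Ktrans / Ve),
            class = "pk_params")
}

#' Ground-truth tissue description for phantom voxels
#'
#' @param ivim an [ivim_params()] object.
#' @param pk a [pk_params()] object.
#' @param t10 pre-contrast longitudinal relaxation time in ms (> 0);
#'   default 1400 ms, a typical pelvic soft-tissue value at 1.5 T.
#' @return An object of class `tissue_truth`.
#' @export
tissue_truth <- function(ivim, pk, t10 = 1400) {
  stopifnot(inherits(ivim, "ivim_params"), inherits(pk, "pk_params"))
  assert_that(is_number(t10) && t10 > 0, "t10 must be > 0")
  structure(list(ivim = ivim, pk = pk, t10 = t10), class = "tissue_truth")
}

#' @export
print.ivim_params <- function(x, ...) {
  cat(sprintf("IVIM params: D = %.4g mm^2/s, D* = %.4g mm^2/s, f = %.4g, S0 = %.4g\n",
              x$D, x$Dstar, x$f, x$S0))
  invisible(x)
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("Tofts params: Ktrans = %.4g /min, Ve = %.4g, Kep = %.4g /min\n",
              x$Ktrans, x$Ve, x$Kep))
  invisible(x)
}
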