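#' Acquisition protocol
#'
#' Bundles the acquisition settings that both simulation and fitting need:
#' the diffusion b-value schedule and the dynamic (DCE) frame timing plus
#' the spoiled-gradient-echo (SPGR) readout parameters used for
#' signal/concentration conversion.
#'
#' @param b_values numeric vector of diffusion weightings (s/mm^2), strictly
#'   increasing, first value 0. The default is the ten-b-value schedule
#'   0, 20, 40, 80, 160, 200, 400, 600, 800, 1000.
#' @param n_phases number of DCE frames (default 40).
#' @param dt DCE frame interval in seconds (default 9).
#' @param tr repetition time of the dynamic SPGR sequence in ms (default 3.5).
#' @param flip_angle flip angle in degrees (default 15).
#' @param n_baseline number of pre-contrast frames (default 3).
#' @return An object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(b_values = c(0, 20, 40, 80, 160, 200, 400,
                                              600, 800, 1000),
                                 n_phases = 40, dt = 9, tr = 3.5,
                                 flip_angle = 15, n_baseline = 3) {
  assert_that(is.numeric(b_values) && length(b_values) >= 2,
              "b_values must be a numeric vector of length >= 2")
  assert_that(b_values[1] == 0, "first b-value must be 0")
  assert_that(all(diff(b_values) > 0), "b_values must be strictly increasing")
  assert_that(is_number(n_phases) && n_phases >= 1,
              "n_phases must be a positive integer")
  assert_that(is_number(n_baseline) && n_baseline >= 1,
              "n_baseline must be >= 1")
  assert_that(n_phases >= n_baseline, "n_phases must be >= n_baseline")
  assert_that(is_number(dt) && dt > 0, "dt must be > 0")
  assert_that(is_number(tr) && tr > 0, "tr must be > 0")
  assert_that(is_number(flip_angle) && flip_angle > 0 && flip_angle < 180,
              "flip_angle must lie strictly between 0 and 180 degrees")
  structure(
    list(b_values = as.numeric(b_values),
         n_phases = as.integer(n_phases),
         dt = as.numeric(dt), tr = as.numeric(tr),
         flip_angle = as.numeric(flip_angle),
         n_baseline = as.integer(n_baseline)),
    class = "acquisition_protocol"
  )
}

#' DCE frame times of a protocol
#'
#' @param protocol an [acquisition_protocol()].
#' @return numeric vector of frame mid-times in seconds, starting at 0.
#' @export
dce_times <- function(protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  (seq_len(protocol$n_phases) - 1) * protocol$dt
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat("Acquisition protocol\n")
  cat("  b-values (s/mm^2):", paste(x$b_values, collapse = ", "), "\n")
  cat(sprintf("  DCE: %d phases, dt = %gs (%d baseline), TR = %g ms, FA = %g deg\n",
              x$n_phases, x$dt, x$n_baseline, x$tr, x$flip_angle))
  invisible(x)
}
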