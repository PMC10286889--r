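# Shared fixtures: everything is generated in code at test time.

default_protocol <- function() acquisition_protocol()

rel_error <- function(est, truth) abs(est - truth) / abs(truth)

# small two-region phantom layout
two_region_layout <- function(shape = c(4, 4, 2)) {
  layout <- array(1L, shape)
  layout[seq_len(shape[1] / 2), , ] <- 2L
  layout
}

example_truth <- function() {
  tissue_truth(ivim_params(D = 0.86e-3, Dstar = 44.35e-3, f = 0.0243,
                           S0 = 1000),
               pk_params(Ktrans = 0.61, Ve = 0.58), t10 = 1400)
}

# tiny cohort for structural tests
small_cohort <- function(seed = 1, reader_sd = 0.42) {
  generate_cohort(default_cohort_spec("risk"), reader_sd = reader_sd,
                  seed = seed)
}
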