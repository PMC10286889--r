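test_that("IVIM signal model reduces correctly at its limits", {
  proto <- default_protocol()
  p <- ivim_params(D = 1.2e-3, Dstar = 60e-3, f = 0.08, S0 = 250)
  sig <- simulate_ivim_signal(p, proto)
  expect_identical(sig$signal[1], 250)            # b = 0 gives S0 exactly
  expect_equal(nrow(sig), length(proto$b_values))

  # f = 0: pure mono-exponential
  mono <- simulate_ivim_signal(ivim_params(1.0e-3, 50e-3, 0, S0 = 1), proto)
  expect_equal(mono$signal[proto$b_values == 1000], exp(-1),
               tolerance = 1e-12)

  # scalar evaluation at typical low-risk tumor values, frozen from a
  # term-by-term hand computation of the bi-exponential model
  sig2 <- simulate_ivim_signal(ivim_params(0.86e-3, 44.35e-3, 0.0243,
                                           S0 = 1), proto)
  expect_equal(sig2$signal[proto$b_values == 200], 0.8215224944453858,
               tolerance = 1e-12)
})

test_that("invalid IVIM parameters are rejected by name", {
  expect_error(ivim_params(D = 2e-3, Dstar = 1e-3, f = 0.1), "Dstar")
  expect_error(ivim_params(D = 1e-3, Dstar = 50e-3, f = 1.2), "f must")
  expect_error(ivim_params(D = 1e-3, Dstar = 50e-3, f = 0.1, S0 = 0),
               "S0")
})

test_that("Rician noise has the right limits and moments", {
  proto <- default_protocol()
  sig <- simulate_ivim_signal(ivim_params(0.8e-3, 40e-3, 0.05, S0 = 100),
                              proto)
  # noiseless limit
  quiet <- add_rician_noise(sig, snr = 1e12, seed = 1)
  expect_lt(max(abs(quiet$signal - sig$signal) / sig$signal), 1e-9)

  # determinism
  n1 <- add_rician_noise(sig, snr = 10, seed = 42)
  n2 <- add_rician_noise(sig, snr = 10, seed = 42)
  expect_identical(n1$signal, n2$signal)

  # zero signal: magnitude noise is Rayleigh with mean sigma*sqrt(pi/2)
  zero <- data.frame(b = rep(0, 2e5), signal = rep(0, 2e5))
  sigma <- 1 / 10   # s_ref = 1 below
  noisy <- add_rician_noise(zero, snr = 10, seed = 7, s_ref = 1)
  expect_equal(mean(noisy$signal), sigma * sqrt(pi / 2), tolerance = 0.01)

  expect_error(add_rician_noise(sig, snr = 0), "snr")
})

test_that("population AIFs respect baseline, positivity and decay", {
  proto <- default_protocol()
  for (model in c("biexponential", "parker")) {
    aif <- simulate_aif(proto, model)
    onset <- proto$n_baseline * proto$dt
    expect_true(all(aif$cp[aif$times < onset] == 0))
    expect_true(all(aif$cp >= 0))
    expect_gt(which.max(aif$cp), proto$n_baseline)
  }
  # bi-exponential washout decays toward zero
  long <- acquisition_protocol(n_phases = 2000, dt = 9)
  aif <- simulate_aif(long, "biexponential")
  expect_lt(aif$cp[2000], 0.05 * max(aif$cp))

  # first-pass peak: coarse sampling is bounded by, and near, the dense
  # grid-search maximum
  dense <- simulate_aif(acquisition_protocol(n_phases = 40000, dt = 0.01,
                                             n_baseline = 1), "parker")
  fine <- simulate_aif(acquisition_protocol(n_phases = 4000, dt = 0.1,
                                            n_baseline = 1), "parker")
  expect_lte(max(fine$cp), max(dense$cp) * (1 + 1e-9))
  expect_equal(max(fine$cp), max(dense$cp), tolerance = 0.02)

  expect_error(simulate_aif(proto, "gamma"), "arg")
})

test_that("Tofts concentration matches closed forms", {
  # zero transfer
  aif <- simulate_aif(default_protocol())
  ct0 <- simulate_tofts_concentration(
    structure(list(Ktrans = 0, Ve = 0.3, Kep = 0), class = "pk_params"),
    aif)
  expect_true(all(ct0$conc == 0))

  # constant Cp: Ct(t) = (Ktrans c / Kep)(1 - exp(-Kep t))
  times <- seq(0, 999) * 0.6
  aifc <- new_aif(times, rep(2, 1000))
  pk <- pk_params(0.61, 0.58)
  ct <- simulate_tofts_concentration(pk, aifc)
  closed <- pk$Ktrans * 2 / pk$Kep * (1 - exp(-pk$Kep * times / 60))
  expect_lt(max(abs(ct$conc - closed) / pmax(closed, 1e-300)), 1e-6)

  # instantaneous washout: Kep -> infinity drives Ct -> 0
  fast <- simulate_tofts_concentration(pk_params(0.5, 1e-4 / 5), aifc)
  expect_lt(max(fast$conc), 1e-3)

  # mismatched grids rejected
  expect_error(simulate_tofts_concentration(pk, aifc, times = times + 1),
               "align")
})

test_that("SPGR conversion reproduces baseline and saturates", {
  proto <- default_protocol()
  tt <- example_truth()
  flat <- structure(data.frame(time = dce_times(proto),
                               conc = rep(0, proto$n_phases)),
                    class = c("conc_curve", "data.frame"))
  sig <- concentration_to_spgr_signal(flat, tt, proto, m0 = 1000)
  expect_equal(stats::sd(sig$signal), 0)

  # frozen scalar evaluation of the SPGR equation at T10 = 1400 ms,
  # TR = 3.5 ms, flip 15 deg, r1 = 4.5, C = 1 mM, m0 = 1000
  one <- flat; one$conc[5] <- 1
  s <- concentration_to_spgr_signal(one, tt, proto, r1 = 4.5, m0 = 1000)
  expect_equal(s$signal[5], 90.81074484550322, tolerance = 1e-12)

  # T1 -> 0 (huge concentration): full recovery limit m0 sin(a)
  sat <- flat; sat$conc[] <- 1e9
  s2 <- concentration_to_spgr_signal(sat, tt, proto, m0 = 1000)
  expect_equal(s2$signal[1], 1000 * sin(15 * pi / 180), tolerance = 1e-9)

  bad <- acquisition_protocol(flip_angle = 90)
  bad$flip_angle <- 0   # bypass constructor to hit the conversion guard
  expect_error(concentration_to_spgr_signal(flat, tt, bad), "degenerate")
})

test_that("voxel phantoms compose the scalar models and are reproducible", {
  proto <- default_protocol()
  layout <- two_region_layout()
  regions <- list("1" = example_truth(),
                  "2" = tissue_truth(ivim_params(0.58e-3, 55.25e-3, 0.0171,
                                                 S0 = 1000),
                                     pk_params(0.37, 0.32), t10 = 1400))
  ph <- generate_voxel_phantom(layout, regions, proto, snr = Inf)
  # noiseless composition: every voxel's DWI column equals the scalar model
  iv <- regions[["1"]]$ivim; iv$S0 <- 1000
  ref <- simulate_ivim_signal(iv, proto)$signal
  vox <- ph$dwi[4, 1, 1, ]
  expect_equal(vox, ref, tolerance = 1e-14)
  expect_true(all(ph$truth$D[layout == 2] == 0.58e-3))

  ph1 <- generate_voxel_phantom(layout, regions, proto, snr = 20, seed = 5)
  ph2 <- generate_voxel_phantom(layout, regions, proto, snr = 20, seed = 5)
  expect_identical(ph1$dwi, ph2$dwi)
  expect_identical(ph1$dce, ph2$dce)

  expect_error(generate_voxel_phantom(array(0L, c(2, 2, 1)), regions,
                                      proto), "at least one region")
})
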