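test_that("noiseless CEST simulation matches the line-shape formula", {
  cfg <- acq_config(grid_size = 8, noise_sigma = 0)
  ph <- make_phantom(cfg, truth_overrides = list(
    water_amplitude = 0, hydroxyl_amplitude = 0, amine_amplitude = 0,
    noe_mt_amplitude = 0, amide_amplitude = 0.05, amide_fwhm = 1.0,
    ramp_frac = 0, b0_amplitude = 0))
  zg <- normalize_zspectrum(simulate_cest_series(ph, cfg))
  i <- which(ph$mask, arr.ind = TRUE)[1, ]
  # independent single-point evaluation of the line-shape formula at the
  # grid offsets nearest the amide center and its half-width point
  for (target in c(3.5, 4.0)) {
    at <- which.min(abs(zg$offsets - target))
    f <- zg$offsets[at]
    expect_equal(zg$z[i[1], i[2], at],
                 1 - 0.05 / (1 + ((f - 3.5) / 0.5)^2), tolerance = 1e-12)
  }
  # exactly at the center the dip is the full amide amplitude
  expect_equal(min(zg$z[i[1], i[2], ]),
               1 - 0.05 / (1 + ((zg$offsets[which.min(zg$z[i[1], i[2], ])] - 3.5) / 0.5)^2),
               tolerance = 1e-12)
})

test_that("Rician noise keeps magnitudes non-negative and scales with sigma", {
  cfg <- acq_config(grid_size = 12, noise_sigma = 0.02, seed = 3)
  ph <- make_phantom(cfg, truth_overrides = list(ramp_frac = 0, b0_amplitude = 0))
  ser <- simulate_cest_series(ph, cfg)
  expect_true(all(ser$signal >= 0))
  expect_true(all(ser$reference >= 0))
  zg <- normalize_zspectrum(ser)
  # noise level sanity: sd of far-off-resonance samples ~ sigma
  far <- zg$z[, , 1][ph$mask]
  expect_lt(abs(sd(far) - 0.02) / 0.02, 0.6)
})

test_that("two-pool Bloch-McConnell reduces to the one-pool closed form", {
  off <- seq(-6, 6, by = 0.25)
  z <- simulate_two_pool_bm(off, exchange_rate = 50, pool_fraction = 0,
                            pool_offset = 3.5, b1 = 3)
  # closed-form CW saturation of a single pool
  gamma <- 267.522; w1 <- gamma * 3; ppm_to_rad <- 2 * pi * 400
  r1 <- 1 / 1.5; r2 <- 1 / 0.06
  d <- -off * ppm_to_rad
  closed <- r1 * (r2^2 + d^2) / (r1 * (r2^2 + d^2) + w1^2 * r2)
  expect_equal(z, closed, tolerance = 1e-10)
})

test_that("Bloch-McConnell saturation vanishes as B1 goes to zero", {
  off <- c(-3, 0.5, 3.5)
  z <- simulate_two_pool_bm(off, exchange_rate = 100, pool_fraction = 0.005,
                            pool_offset = 3.5, b1 = 1e-6)
  expect_true(all(abs(z - 1) < 1e-6))
  expect_error(simulate_two_pool_bm(off, -1, 0.005, 3.5), "positive")
  expect_error(simulate_two_pool_bm(off, 100, 0.5, 3.5), "0.1")
  expect_error(simulate_two_pool_bm(off, 100, 0.005, 3.5, t2_water = 0),
               "positive")
})

test_that("Lorentzian fit of a physical two-pool spectrum finds the solute peak", {
  off <- default_offsets()
  z <- simulate_two_pool_bm(off, exchange_rate = 100, pool_fraction = 0.005,
                            pool_offset = 3.5, b1 = 3)
  fit <- fit_pixel(z, off)
  expect_true(fit$converged)
  amide <- fit$peaks[fit$peaks$name == "amide", ]
  expect_lt(abs(amide$center - 3.5), 0.3)
  expect_gt(amide$amplitude, 0.01)
})

test_that("noiseless relaxometry simulations follow their forward models", {
  cfg <- acq_config(grid_size = 8, noise_sigma = 0,
                    b_values = c(150, 334, 518, 702, 886, 1070))
  ph <- make_phantom(cfg, truth_overrides = list(adc = 1e-3, t2 = 40,
                                                 t1 = 800, ramp_frac = 0))
  i <- which(ph$mask, arr.ind = TRUE)[1, ]

  dwi <- simulate_relaxometry(ph, cfg, "diffusion")
  s0 <- dwi$signal[i[1], i[2], 1] / exp(-150 * 1e-3)
  expect_equal(dwi$signal[i[1], i[2], ] / s0, exp(-cfg$b_values * 1e-3),
               tolerance = 1e-12)

  # log-signal vs TE is exactly linear with slope -1/T2
  t2s <- simulate_relaxometry(ph, cfg, "t2")
  fitlm <- lm(log(t2s$signal[i[1], i[2], ]) ~ cfg$echo_times)
  expect_equal(unname(coef(fitlm)[2]), -1 / 40, tolerance = 1e-10)

  # Look-Locker with B = 2A: apparent and corrected T1 coincide
  t1s <- simulate_relaxometry(ph, cfg, "t1", b_over_a = 2)
  t1map <- fit_t1_look_locker(t1s)
  expect_equal(t1map$values[i[1], i[2]], 800, tolerance = 1e-6)
})
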