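test_that("normalization divides by the reference and guards bad pixels", {
  n <- 4; noff <- 31
  off <- seq(-3, 3, length.out = noff)
  raw <- array(1, c(n, n, noff))
  ref <- matrix(2, n, n)
  zg <- normalize_zspectrum(raw, ref, off)
  expect_equal(unique(as.vector(zg$z)), 0.5)
  # S = S0 everywhere -> Z identically 1
  zg1 <- normalize_zspectrum(array(2, c(n, n, noff)), ref, off)
  expect_equal(unique(as.vector(zg1$z)), 1)
  # non-positive reference pixels are dropped from the mask
  ref2 <- ref; ref2[1, 1] <- 0
  expect_message(zg2 <- normalize_zspectrum(raw, ref2, off),
                 "non-positive reference")
  expect_false(zg2$mask[1, 1])
  expect_equal(zg2$n_nonpositive_ref, 1)
  # corrupt pixels (Z > 1.5) are flagged and dropped
  raw3 <- raw; raw3[2, 2, 5] <- 10
  expect_message(zg3 <- normalize_zspectrum(raw3, ref, off), "corrupt")
  expect_false(zg3$mask[2, 2])
  # all-zero reference aborts
  expect_error(normalize_zspectrum(raw, matrix(0, n, n), off),
               "non-positive at every masked pixel")
})

test_that("a flat unit spectrum fits with negligible non-water amplitudes", {
  off <- default_offsets()
  fit <- fit_pixel(rep(1, length(off)), off)
  expect_true(fit$converged)
  non_water <- fit$peaks$amplitude[fit$peaks$name != "water"]
  expect_true(all(non_water <= 1e-4))
})

test_that("noiseless five-pool spectra are recovered to fitting precision", {
  tr <- nominal_truth()
  off <- default_offsets()
  z <- model_zspectrum(off, tr$centers, tr$amplitudes, tr$fwhms, 0)
  fit <- fit_pixel(z, off)
  expect_true(fit$converged)
  expect_lt(max(rel_err(fit$peaks$amplitude, tr$amplitudes)), 1e-3)
  expect_lt(max(rel_err(fit$peaks$fwhm, tr$fwhms)), 1e-3)
  expect_lt(max(abs(fit$peaks$center - tr$centers)), 1e-3)
  expect_lt(abs(fit$b0_shift), 1e-3)
})

test_that("the fitted B0 shift tracks a simulated field offset", {
  tr <- nominal_truth()
  off <- default_offsets()
  z <- model_zspectrum(off, tr$centers, tr$amplitudes, tr$fwhms, b0_shift = 0.08)
  fit <- fit_pixel(z, off)
  expect_true(fit$converged)
  expect_lt(abs(fit$b0_shift - 0.08), 0.02)
  # centers are reported B0-corrected
  expect_lt(abs(fit$peaks$center[4] - 3.5), 0.02)
})

test_that("fit_pixel enforces its preconditions", {
  off <- default_offsets()
  expect_error(fit_pixel(rep(1, 10), off[1:10]), "at least 30")
  expect_error(fit_pixel(rep(1, 40), seq(0.1, 4, length.out = 40)),
               "both sides")
  # non-finite values are dropped, not fatal
  tr <- nominal_truth()
  z <- model_zspectrum(off, tr$centers, tr$amplitudes, tr$fwhms, 0)
  z[c(5, 50)] <- NA
  expect_true(fit_pixel(z, off)$converged)
})

test_that("fitted amide area scales linearly with the true amplitude", {
  tr <- nominal_truth()
  off <- default_offsets()
  base_area <- NULL
  for (k in c(1, 1.3, 2)) {
    a <- tr$amplitudes; a[4] <- a[4] * k
    z <- model_zspectrum(off, tr$centers, a, tr$fwhms, 0)
    fit <- fit_pixel(z, off)
    ar <- fit$peaks$area[fit$peaks$name == "amide"]
    if (k == 1) base_area <- ar
    expect_equal(ar / base_area, k, tolerance = 1e-3)
  }
})

test_that("random in-prior truths are recovered from noiseless spectra", {
  set.seed(31)
  off <- default_offsets()
  for (i in 1:25) {
    tr <- random_truth()
    z <- model_zspectrum(off, tr$centers, tr$amplitudes, tr$fwhms, tr$b0)
    fit <- fit_pixel(z, off)
    expect_true(fit$converged)
    err <- max(rel_err(fit$peaks$amplitude, tr$amplitudes),
               rel_err(fit$peaks$fwhm, tr$fwhms),
               rel_err(fit$peaks$center, tr$centers),
               abs(fit$b0_shift - tr$b0))
    expect_lt(err, 1e-2)
  }
})

test_that("amide and amine area estimates are unbiased under 1% Rician noise", {
  tr <- nominal_truth()
  off <- default_offsets()
  z0 <- model_zspectrum(off, tr$centers, tr$amplitudes, tr$fwhms, 0)
  true_area <- peak_area(tr$amplitudes, tr$fwhms)
  set.seed(41)
  n_rep <- 200
  est <- matrix(NA_real_, n_rep, 2)
  for (r in seq_len(n_rep)) {
    s0 <- 1
    z <- sqrt((z0 * s0 + rnorm(length(z0), 0, 0.01))^2 +
                rnorm(length(z0), 0, 0.01)^2) / s0
    fit <- fit_pixel(z, off)
    if (fit$converged)
      est[r, ] <- fit$peaks$area[fit$peaks$name %in% c("amine", "amide")]
  }
  bias_amine <- mean(est[, 1], na.rm = TRUE) / true_area[3] - 1
  bias_amide <- mean(est[, 2], na.rm = TRUE) / true_area[4] - 1
  expect_lt(abs(bias_amine), 0.05)
  expect_lt(abs(bias_amide), 0.05)
})

test_that("pixel-wise image fitting reproduces a spatially varying truth map", {
  cfg <- acq_config(grid_size = 10, noise_sigma = 0)
  ph <- make_phantom(cfg)
  zg <- normalize_zspectrum(simulate_cest_series(ph, cfg))
  maps <- fit_image(zg)
  expect_equal(attr(maps, "n_failed"), 0)
  truth_area <- peak_area(ph$pools$amide$amplitude, ph$pools$amide$fwhm)
  est <- maps$amide_area$values[ph$mask]
  expect_lt(max(abs(est / truth_area[ph$mask] - 1)), 1e-2)
  # recovered per-pixel B0 shift matches the simulated field map
  expect_lt(max(abs(maps$b0_shift$values[ph$mask] - ph$b0_shift_map[ph$mask])),
            0.01)
})

test_that("an empty mask yields empty maps with a warning", {
  cfg <- acq_config(grid_size = 6, noise_sigma = 0)
  ph <- make_phantom(cfg)
  zg <- normalize_zspectrum(simulate_cest_series(ph, cfg))
  zg$mask[] <- FALSE
  expect_warning(maps <- fit_image(zg), "empty mask")
  expect_equal(attr(maps, "n_fitted"), 0)
  expect_true(all(is.nan(maps$amide_area$values)))
})
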