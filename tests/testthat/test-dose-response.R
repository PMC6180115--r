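sw1222_like <- function() hill_params(V0 = 100, Smax = 30, EC50 = 3, hs = 1.5,
                                      Imax = 90, IC50 = 12.6, hi = 1.5)

test_that("biphasic Hill model has its defining limits", {
  p <- sw1222_like()
  expect_equal(hill_model(0, p), 100)
  # half-inhibition definition with no stimulation
  p2 <- hill_params(V0 = 100, Smax = 0, Imax = 80, IC50 = 20, hi = 2)
  expect_equal(hill_model(20, p2), 100 - 40)
  # hormetic shape: rises above baseline at low dose, falls below 50% high
  cc <- 10^seq(log10(0.1), log10(400), length.out = 200)
  v <- hill_model(cc, p)
  expect_gt(max(v), 100)
  expect_lt(v[length(v)], 50)
  # monotonicity in the single-term limits
  expect_true(all(diff(hill_model(cc, hill_params(Smax = 20, EC50 = 5))) >= 0))
  expect_true(all(diff(hill_model(cc, hill_params(Imax = 80, IC50 = 5))) <= 0))
  expect_error(hill_params(IC50 = -1), "positive")
  expect_error(hill_params(Imax = 300), "Imax")
})

test_that("simulated MTT plates follow the truth curve and the seed contract", {
  tr <- sw1222_like()
  # default ladder: 2-fold series, 9 points, 1.6-400 nM
  expect_equal(length(mtt_ladder()), 9)
  expect_equal(max(mtt_ladder()), 400)
  expect_equal(min(mtt_ladder()), 400 / 2^8)
  expect_equal(mtt_ladder()[-1] / mtt_ladder()[-9], rep(2, 8))

  p0 <- simulate_mtt_plate(tr, replicates = 2, noise_sigma = 0)
  expect_equal(p0$viability_pct, hill_model(p0$concentration_nM, tr))
  # stimulation pushes the noiseless curve above 100%
  expect_gt(max(p0$viability_pct), 100)
  # determinism
  expect_identical(simulate_mtt_plate(tr, replicates = 12, seed = 5),
                   simulate_mtt_plate(tr, replicates = 12, seed = 5))
  expect_error(simulate_mtt_plate(tr, concentrations = numeric(0)), "empty")
})

test_that("viability normalization divides by the control mean", {
  plate <- data.frame(concentration_nM = c(10, 10), replicate = 1:2,
                      absorbance = c(0.5, 1.0))
  v <- viability_from_absorbance(plate, control = c(0.8, 1.2))
  expect_equal(v$viability_pct, c(50, 100))
  expect_error(viability_from_absorbance(plate, control = c(0, 0)), "positive")
  expect_error(viability_from_absorbance(plate, control = numeric(0)),
               "control well")
})

test_that("noiseless biphasic truths are recovered within 1%", {
  set.seed(71)
  for (i in 1:8) {
    tr <- hill_params(V0 = 100, Smax = runif(1, 15, 40),
                      EC50 = runif(1, 1.5, 5), hs = runif(1, 1, 2.5),
                      Imax = runif(1, 70, 95), IC50 = runif(1, 8, 120),
                      hi = runif(1, 1, 2.5))
    plate <- simulate_mtt_plate(tr, replicates = 1, noise_sigma = 0, seed = i)
    fit <- fit_hill(plate)
    expect_true(fit$converged)
    expect_lt(abs(fit$params$IC50 / tr$IC50 - 1), 0.01)
    expect_lt(abs(fit$params$EC50 / tr$EC50 - 1), 0.01)
    expect_lt(abs(fit$params$V0 / tr$V0 - 1), 0.01)
  }
})

test_that("flat viability data yield negligible stimulation and inhibition", {
  flat <- data.frame(concentration_nM = rep(mtt_ladder(), 3),
                     viability_pct = 100)
  fit <- fit_hill(flat)
  net <- abs(hill_model(mtt_ladder(), fit$params) - 100)
  expect_lt(max(net), 0.5)
  expect_false(isTRUE(fit$biphasic_supported))
})

test_that("IC50 is recoverable from noisy plates with moderate error", {
  # median absolute IC50 error over random truths at assay-like noise
  set.seed(81)
  errs <- replicate(30, {
    tr <- hill_params(V0 = 100, Smax = runif(1, 10, 35),
                      EC50 = runif(1, 1.5, 5), hs = 1.5,
                      Imax = runif(1, 75, 95),
                      IC50 = 10^runif(1, log10(8), log10(150)), hi = 1.5)
    fit <- fit_hill(simulate_mtt_plate(tr, replicates = 12, noise_sigma = 5,
                                       seed = sample.int(1e6, 1)))
    abs(fit$params$IC50 / tr$IC50 - 1)
  })
  expect_lt(median(errs), 0.15)
})

test_that("unbound fraction follows single-site binding algebra", {
  expect_equal(unbound_fraction(0, Ki = 0.93), 100)
  expect_equal(unbound_fraction(0.93, Ki = 0.93), 50)
  # top of the assay ladder leaves under 0.25% of sites unbound
  expect_lt(unbound_fraction(400, Ki = 0.93), 0.25)
  cc <- seq(0, 100, by = 0.5)
  expect_true(all(diff(unbound_fraction(cc)) < 0))
  # unbound + occupied = 100
  occupied <- 100 - unbound_fraction(cc)
  expect_equal(unbound_fraction(cc) + occupied, rep(100, length(cc)))
  expect_error(unbound_fraction(-1), "non-negative")
  expect_error(unbound_fraction(1, Ki = 0), "positive")
})
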