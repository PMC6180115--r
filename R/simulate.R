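# Rician magnitude noise: |x + n1 + i n2| with n1, n2 ~ N(0, sigma).
# This is the noise distribution of magnitude-reconstructed MRI data and is
# strictly non-negative.
add_rician <- function(x, sigma) {
  if (sigma == 0) return(x)
  sqrt((x + stats::rnorm(length(x), 0, sigma))^2 +
         stats::rnorm(length(x), 0, sigma)^2)
}

#' Simulate a CEST saturation image series from a phantom
#'
#' Runs the summed-Lorentzian model forwards at every masked pixel: signal
#' at offset f equals reference x Z(f) with the pixel's pool parameters and
#' B0 shift, plus Rician noise of scale `noise_sigma` x reference. Pixels
#' outside the mask carry the reference signal (unsaturated background).
#' The unsaturated reference image (nominally acquired far off-resonance,
#' 8000 ppm by default) is included.
#'
#' @param truth A [make_phantom()] result.
#' @param config An [acq_config()]; must share `grid_size` with `truth`.
#' @return Object of class `cest_series`: `offsets` (ppm), `signal`
#'   (grid x grid x offsets array), `reference` (grid matrix), `mask`.
#' @export
simulate_cest_series <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(config, "acq_config"))
  n <- config$grid_size
  if (nrow(truth$mask) != n) stop("phantom and config grid sizes differ")
  offsets <- acq_offsets(config)
  set.seed(config$seed)

  reference <- matrix(1000, n, n)  # uniform S0 in arbitrary units
  signal <- array(NA_real_, c(n, n, length(offsets)))
  centers <- vapply(truth$pools, function(p) p$center[1, 1], 0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (truth$mask[i, j]) {
      z <- model_zspectrum(
        offsets,
        centers = vapply(truth$pools, function(p) p$center[i, j], 0),
        amplitudes = vapply(truth$pools, function(p) p$amplitude[i, j], 0),
        fwhms = vapply(truth$pools, function(p) p$fwhm[i, j], 0),
        b0_shift = truth$b0_shift_map[i, j]
      )
    } else {
      z <- rep(1, length(offsets))
    }
    signal[i, j, ] <- z * reference[i, j]
  }
  sigma <- config$noise_sigma * reference[1, 1]
  signal <- array(add_rician(signal, sigma), dim(signal))
  reference <- matrix(add_rician(reference, sigma), n, n)

  structure(list(offsets = offsets, signal = signal,
                 reference = reference, mask = truth$mask),
            class = "cest_series")
}

#' Simulate a relaxometry image series (diffusion, T1 or T2)
#'
#' Forward models: diffusion S(b) = S0 exp(-b ADC); inversion recovery
#' (Look-Locker) S(TI) = |A - B exp(-TI/T1*)| with apparent
#' T1* = T1 / (B/A - 1), so that the standard Look-Locker correction
#' T1 = T1* (B/A - 1) recovers the map value; multi-echo T2
#' S(TE) = S0 exp(-TE/T2). Rician noise as for CEST.
#'
#' @param truth A [make_phantom()] result.
#' @param config An [acq_config()].
#' @param modality One of `"diffusion"`, `"t1"`, `"t2"`.
#' @param b_over_a Look-Locker B/A ratio (readout-dependent; 2 corresponds
#'   to an ideal inversion with no readout perturbation).
#' @return A [relaxometry_series()] object.
#' @export
simulate_relaxometry <- function(truth, config = truth$config,
                                 modality = c("diffusion", "t1", "t2"),
                                 b_over_a = 1.8) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(config, "acq_config"))
  modality <- match.arg(modality)
  n <- config$grid_size
  if (nrow(truth$mask) != n) stop("phantom and config grid sizes differ")
  s0 <- 1000
  control <- switch(modality,
    diffusion = config$b_values,
    t1 = config$inversion_times,
    t2 = config$echo_times)
  set.seed(config$seed + match(modality, c("diffusion", "t1", "t2")))

  signal <- array(NA_real_, c(n, n, length(control)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- switch(modality,
      diffusion = s0 * exp(-control * truth$adc_map[i, j]),
      t1 = {
        a <- s0; b <- b_over_a * s0
        t1_star <- truth$t1_map[i, j] / (b_over_a - 1)
        abs(a - b * exp(-control / t1_star))
      },
      t2 = s0 * exp(-control / truth$t2_map[i, j]))
    if (!truth$mask[i, j]) s <- rep(s0, length(control))
    signal[i, j, ] <- s
  }
  sigma <- config$noise_sigma * s0
  signal <- array(add_rician(signal, sigma), dim(signal))
  relaxometry_series(modality, control, signal, truth$mask)
}

#' Two-pool continuous-wave Bloch-McConnell steady state
#'
#' Solves the 6x6 steady-state Bloch-McConnell system for water plus one
#' exchanging solute pool under continuous-wave saturation, returning the
#' longitudinal water polarization Z at each offset. This is a physical
#' forward model, independent of the Lorentzian parameterization, and is
#' used to check that Lorentzian fitting of physically generated spectra
#' places the solute peak near the simulated pool offset.
#'
#' @param offsets Saturation offsets, ppm.
#' @param exchange_rate Solute-to-water exchange rate k (1/s), positive.
#' @param pool_fraction Solute pool fraction (0, 0.1].
#' @param pool_offset Solute chemical shift, ppm.
#' @param t1_water,t2_water,t1_solute,t2_solute Relaxation times, s.
#' @param b1 Saturation amplitude, microtesla; must be > 0 (the b1 -> 0
#'   limit Z -> 1 holds continuously).
#' @param field_mhz Water Larmor frequency, MHz (9.4 T -> 400 MHz); sets
#'   the ppm-to-rad/s conversion.
#' @return Z values at `offsets`.
#' @export
simulate_two_pool_bm <- function(offsets, exchange_rate, pool_fraction,
                                 pool_offset,
                                 t1_water = 1.5, t2_water = 0.06,
                                 t1_solute = 1.0, t2_solute = 0.01,
                                 b1 = 3, field_mhz = 400) {
  if (exchange_rate <= 0) stop("exchange_rate must be positive")
  if (pool_fraction < 0 || pool_fraction > 0.1)
    stop("pool_fraction must lie in [0, 0.1]")
  if (b1 <= 0) stop("b1 must be positive")
  if (any(c(t1_water, t2_water, t1_solute, t2_solute) <= 0))
    stop("relaxation times must be positive")

  gamma <- 267.522  # rad s^-1 uT^-1 for 1H
  w1 <- gamma * b1
  ppm_to_rad <- 2 * pi * field_mhz  # rad/s per ppm
  r1a <- 1 / t1_water; r2a <- 1 / t2_water
  r1b <- 1 / t1_solute; r2b <- 1 / t2_solute
  fb <- pool_fraction
  kba <- exchange_rate        # solute -> water
  kab <- exchange_rate * fb   # water -> solute (detailed balance)
  m0a <- 1; m0b <- fb

  vapply(offsets, function(ppm) {
    da <- (0 - ppm) * ppm_to_rad          # water offset in rotating frame
    db <- (pool_offset - ppm) * ppm_to_rad
    # state (Max, May, Maz, Mbx, Mby, Mbz); dM/dt = A M + c = 0
    A <- matrix(0, 6, 6)
    A[1, ] <- c(-(r2a + kab), -da, 0, kba, 0, 0)
    A[2, ] <- c(da, -(r2a + kab), w1, 0, kba, 0)
    A[3, ] <- c(0, -w1, -(r1a + kab), 0, 0, kba)
    A[4, ] <- c(kab, 0, 0, -(r2b + kba), -db, 0)
    A[5, ] <- c(0, kab, 0, db, -(r2b + kba), w1)
    A[6, ] <- c(0, 0, kab, 0, -w1, -(r1b + kba))
    cvec <- c(0, 0, r1a * m0a, 0, 0, r1b * m0b)
    m <- solve(A, -cvec)
    m[3] / m0a
  }, 0)
}
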