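#' Lorentzian line-shape value
#'
#' Evaluates the amplitude/FWHM parameterization of the Lorentzian
#' absorption line, L(f) = A / (1 + ((f - c) / (w/2))^2), which attains its
#' maximum A at f = c and half its maximum at f = c +/- w/2.
#'
#' @param f Saturation offset(s), ppm.
#' @param center Peak center c, ppm.
#' @param amplitude Peak amplitude A (fraction of the normalized signal).
#' @param fwhm Full width at half maximum w, ppm; must be positive.
#' @return Dimensionless absorption value(s), same length as `f`.
#' @export
lorentzian_value <- function(f, center, amplitude, fwhm) {
  if (fwhm <= 0) stop("fwhm must be positive")
  u <- (f - center) / (fwhm / 2)
  amplitude / (1 + u^2)
}

#' Area under a Lorentzian peak
#'
#' Closed form of the full-line integral of the amplitude/FWHM Lorentzian:
#' area = (pi/2) * amplitude * fwhm.
#'
#' @param amplitude Peak amplitude.
#' @param fwhm Full width at half maximum, ppm.
#' @return Area in ppm x dimensionless units.
#' @export
peak_area <- function(amplitude, fwhm) {
  (pi / 2) * amplitude * fwhm
}

# Canonical pool order used throughout: parameter vectors, map names, priors.
.pool_names <- c("water", "hydroxyl", "amine", "amide", "noe_mt")

#' Five-pool peak model: priors and bounds
#'
#' Specifies the summed-Lorentzian Z-spectrum model: one pool each for
#' water (0 ppm), hydroxyl (1.2 ppm), amine (2.4 ppm, possibly including a
#' guanidinium contribution), amide (3.5 ppm) and a single broad combined
#' NOE/MT pool (negative offsets), plus a global B0 frequency shift applied
#' to all centers. The fine exchange pools carry Gaussian priors on their
#' centers (s.d. `center_prior_sd`) within hard windows; the NOE/MT center
#' is free within `[-5, -1]` ppm, and the B0 shift within +/-0.3 ppm.
#' Amplitudes are bounded to `[0, 1]`; FWHM bounds are 0.2-3 ppm for fine
#' peaks, 0.5-6 ppm for water and 2-12 ppm for NOE/MT. Widths additionally
#' carry weak lognormal priors about their nominal tissue values
#' (s.d. `fwhm_prior_sd` on the log scale); without them the strongly
#' overlapping pools near water are barely identifiable at realistic noise
#' and area estimates become heavy-tailed.
#'
#' @param center_prior_sd Prior s.d. on fine-peak centers, ppm.
#' @param fwhm_prior_sd Prior s.d. on log(FWHM / nominal FWHM) for the
#'   fine exchange pools; water and NOE/MT use `1.5 x` this value.
#' @param center_window Half-width of the hard window around each nominal
#'   fine-peak center, ppm.
#' @param b0_bound Half-width of the uniform B0-shift window, ppm.
#' @param noise_scale Assumed measurement noise (dimensionless Z units);
#'   sets the relative weight of the priors in the MAP objective.
#' @param min_separation Minimum amine-amide center separation enforced by
#'   a one-sided penalty, ppm; fits where the penalty is active are flagged.
#' @return An object of class `peak_model`.
#' @export
peak_model <- function(center_prior_sd = 0.2, center_window = 0.5,
                       b0_bound = 0.3, noise_scale = 0.01,
                       min_separation = 0.5, fwhm_prior_sd = 0.35) {
  stopifnot(center_prior_sd > 0, center_window > 0, b0_bound > 0,
            noise_scale > 0, min_separation >= 0, fwhm_prior_sd > 0)
  nominal <- c(water = 0, hydroxyl = 1.2, amine = 2.4, amide = 3.5, noe_mt = -3.0)
  peaks <- data.frame(
    name = .pool_names,
    center_nominal = unname(nominal[.pool_names]),
    center_prior_sd = c(NA, center_prior_sd, center_prior_sd, center_prior_sd, NA),
    fwhm_nominal = c(2.0, 1.0, 1.2, 1.0, 5.0),
    fwhm_prior_sd = fwhm_prior_sd * c(1.5, 1, 1, 1, 1.5),
    center_lower = c(0, 1.2 - center_window, 2.4 - center_window,
                     3.5 - center_window, -5),
    center_upper = c(0, 1.2 + center_window, 2.4 + center_window,
                     3.5 + center_window, -1),
    amp_lower = rep(0, 5),
    amp_upper = rep(1, 5),
    fwhm_lower = c(0.5, 0.2, 0.2, 0.2, 2),
    fwhm_upper = c(6, 3, 3, 3, 12),
    stringsAsFactors = FALSE
  )
  structure(list(peaks = peaks, b0_bound = b0_bound,
                 noise_scale = noise_scale,
                 min_separation = min_separation),
            class = "peak_model")
}

#' Forward summed-Lorentzian Z-spectrum
#'
#' Z(f) = 1 - sum_i L(f - b0_shift; center_i, amplitude_i, fwhm_i), clipped
#' at 0 from below (magnitude data cannot be negative).
#'
#' @param offsets Saturation offsets, ppm.
#' @param centers,amplitudes,fwhms Numeric vectors of per-pool parameters
#'   (equal length).
#' @param b0_shift Global frequency shift, ppm.
#' @return Z values at `offsets`.
#' @export
model_zspectrum <- function(offsets, centers, amplitudes, fwhms, b0_shift = 0) {
  stopifnot(length(centers) == length(amplitudes),
            length(centers) == length(fwhms))
  z <- rep(1, length(offsets))
  for (i in seq_along(centers)) {
    z <- z - lorentzian_value(offsets - b0_shift, centers[i], amplitudes[i], fwhms[i])
  }
  pmax(z, 0)
}
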