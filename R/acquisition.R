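#' Acquisition configuration
#'
#' Bundles the acquisition parameters shared by all simulators: the CEST
#' saturation-offset grid, the diffusion b-value ladder, inversion and echo
#' times for relaxometry, the image grid size and the noise level.
#'
#' Defaults mirror a typical preclinical protocol: saturation offsets from
#' -6 to 6 ppm in steps of 0.12 ppm (101 samples), a reference image at
#' 8000 ppm (far enough off-resonance that saturation has no effect),
#' b-values spanning 150 to 1070 s/mm^2, and Rician noise at 1% of the
#' reference signal.
#'
#' @param offset_min,offset_max,offset_step Saturation offset grid (ppm).
#' @param reference_offset Offset of the unsaturated reference image (ppm).
#' @param b_values Diffusion weightings (s/mm^2).
#' @param inversion_times Inversion times for T1 mapping (ms).
#' @param echo_times Echo times for T2 mapping (ms).
#' @param grid_size Image matrix size (pixels per side, single slice).
#' @param noise_sigma Rician noise scale as a fraction of the per-pixel
#'   reference signal; 0 disables noise.
#' @param seed Integer seed; identical seed and config give bit-identical
#'   simulated outputs.
#' @return An object of class `acq_config`.
#' @export
acq_config <- function(offset_min = -6, offset_max = 6, offset_step = 0.12,
                       reference_offset = 8000,
                       b_values = seq(150, 1070, length.out = 6),
                       inversion_times = c(100, 250, 500, 800, 1200, 1800, 2600, 3500),
                       echo_times = seq(10, 80, by = 10),
                       grid_size = 32,
                       noise_sigma = 0.01,
                       seed = 1L) {
  if (offset_min >= offset_max) stop("offset_min must be < offset_max")
  if (offset_step <= 0) stop("offset_step must be positive")
  if (grid_size < 1) stop("grid_size must be a positive integer")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (any(diff(b_values) <= 0)) stop("b_values must be strictly increasing")
  offsets <- seq(offset_min, offset_max, by = offset_step)
  if (min(abs(offsets)) > offset_step / 2)
    stop("offset grid must include a sample within offset_step/2 of 0 ppm")
  structure(list(
    offset_min = offset_min, offset_max = offset_max, offset_step = offset_step,
    reference_offset = reference_offset,
    b_values = as.numeric(b_values),
    inversion_times = as.numeric(inversion_times),
    echo_times = as.numeric(echo_times),
    grid_size = as.integer(grid_size),
    noise_sigma = noise_sigma,
    seed = as.integer(seed)
  ), class = "acq_config")
}

#' Saturation offset grid of a configuration
#'
#' @param config An `acq_config`.
#' @return Strictly ascending numeric vector of offsets (ppm).
#' @export
acq_offsets <- function(config) {
  stopifnot(inherits(config, "acq_config"))
  seq(config$offset_min, config$offset_max, by = config$offset_step)
}

#' @export
print.acq_config <- function(x, ...) {
  cat("<acq_config>\n")
  cat(sprintf("  CEST offsets : %g to %g ppm, step %g (%d samples), reference %g ppm\n",
              x$offset_min, x$offset_max, x$offset_step,
              length(acq_offsets(x)), x$reference_offset))
  cat(sprintf("  b-values     : %s s/mm^2\n", paste(signif(x$b_values, 4), collapse = ", ")))
  cat(sprintf("  TI           : %s ms\n", paste(x$inversion_times, collapse = ", ")))
  cat(sprintf("  TE           : %s ms\n", paste(x$echo_times, collapse = ", ")))
  cat(sprintf("  grid %dx%d, noise sigma %g, seed %d\n",
              x$grid_size, x$grid_size, x$noise_sigma, x$seed))
  invisible(x)
}
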