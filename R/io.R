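# Interchange dialect: NIfTI volumes plus a JSON sidecar carrying the
# acquisition metadata (offsets/b/TI/TE lists at full precision), and
# comma-separated UTF-8 CSV with a header row for tables.

.sidecar_path <- function(prefix) paste0(prefix, ".json")

.read_sidecar <- function(prefix) {
  path <- .sidecar_path(prefix)
  if (!file.exists(path)) stop("sidecar not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write an image series (CEST or relaxometry) to NIfTI + JSON sidecar
#'
#' The signal array, reference image (CEST only) and mask are written as
#' NIfTI volumes `<prefix>_signal.nii.gz`, `<prefix>_reference.nii.gz`,
#' `<prefix>_mask.nii.gz`; offsets or control values go into
#' `<prefix>.json` at full precision.
#'
#' @param x A `cest_series` or `relaxometry_series`.
#' @param prefix Output path prefix (directories must exist).
#' @return `prefix`, invisibly.
#' @export
write_image_series <- function(x, prefix) {
  if (inherits(x, "cest_series")) {
    RNifti::writeNifti(x$signal, paste0(prefix, "_signal.nii.gz"))
    RNifti::writeNifti(x$reference, paste0(prefix, "_reference.nii.gz"))
    RNifti::writeNifti(x$mask * 1L, paste0(prefix, "_mask.nii.gz"))
    # numeric lists are serialized as %.17g strings: JSON double emission
    # rounds the last ULP, and the offsets contract is full precision
    meta <- list(type = "cest", offsets_ppm = I(sprintf("%.17g", x$offsets)),
                 n_volumes = dim(x$signal)[3])
  } else if (inherits(x, "relaxometry_series")) {
    RNifti::writeNifti(x$signal, paste0(prefix, "_signal.nii.gz"))
    RNifti::writeNifti(x$mask * 1L, paste0(prefix, "_mask.nii.gz"))
    meta <- list(type = "relaxometry", modality = x$modality,
                 control = I(sprintf("%.17g", x$control)),
                 n_volumes = dim(x$signal)[3])
  } else stop("unsupported series class")
  jsonlite::write_json(meta, .sidecar_path(prefix), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read an image series written by [write_image_series()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `cest_series` or `relaxometry_series`, validated against the
#'   sidecar (volume count mismatches and missing fields are errors naming
#'   the offending field).
#' @export
read_image_series <- function(prefix) {
  meta <- .read_sidecar(prefix)
  if (is.null(meta$type)) stop("sidecar field missing: type")
  signal <- array(as.numeric(RNifti::readNifti(paste0(prefix, "_signal.nii.gz"))),
                  dim(RNifti::readNifti(paste0(prefix, "_signal.nii.gz"))))
  mask <- matrix(as.numeric(RNifti::readNifti(paste0(prefix, "_mask.nii.gz"))) > 0,
                 dim(signal)[1], dim(signal)[2])
  if (!identical(as.integer(dim(signal)[3]), as.integer(meta$n_volumes)))
    stop("sidecar field n_volumes does not match the signal volume count")
  if (meta$type == "cest") {
    if (is.null(meta$offsets_ppm)) stop("sidecar field missing: offsets_ppm")
    if (length(meta$offsets_ppm) != dim(signal)[3])
      stop("sidecar field offsets_ppm length does not match volume count")
    reference <- matrix(as.numeric(RNifti::readNifti(paste0(prefix, "_reference.nii.gz"))),
                        dim(signal)[1], dim(signal)[2])
    structure(list(offsets = unname(as.numeric(meta$offsets_ppm)), signal = signal,
                   reference = reference, mask = mask),
              class = "cest_series")
  } else if (meta$type == "relaxometry") {
    if (is.null(meta$modality)) stop("sidecar field missing: modality")
    if (is.null(meta$control)) stop("sidecar field missing: control")
    relaxometry_series(meta$modality, as.numeric(meta$control), signal, mask)
  } else stop("unknown series type in sidecar: ", meta$type)
}

#' Write a parametric map to NIfTI + JSON sidecar
#' @param map A [parametric_map()].
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_map <- function(map, prefix) {
  stopifnot(inherits(map, "parametric_map"))
  RNifti::writeNifti(map$values, paste0(prefix, "_map.nii.gz"))
  RNifti::writeNifti(map$mask * 1L, paste0(prefix, "_mask.nii.gz"))
  jsonlite::write_json(list(type = "map", name = map$name, units = map$units),
                       .sidecar_path(prefix), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a parametric map written by [write_map()]
#' @param prefix Path prefix used when writing.
#' @return A [parametric_map()].
#' @export
read_map <- function(prefix) {
  meta <- .read_sidecar(prefix)
  if (is.null(meta$name)) stop("sidecar field missing: name")
  vals <- RNifti::readNifti(paste0(prefix, "_map.nii.gz"))
  vals <- matrix(as.numeric(vals), dim(vals)[1], dim(vals)[2])
  mask <- RNifti::readNifti(paste0(prefix, "_mask.nii.gz"))
  mask <- matrix(as.numeric(mask) > 0, dim(vals)[1], dim(vals)[2])
  parametric_map(vals, meta$name, meta$units, mask)
}

#' Write / read a cohort record table as CSV
#' @param records Cohort record data frame.
#' @param path CSV path.
#' @return `path` invisibly (write); the data frame (read).
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject", "tumor_type", "dose", "timepoint")
  missing <- setdiff(needed, names(rec))
  if (length(missing)) stop("records CSV missing column(s): ",
                            paste(missing, collapse = ", "))
  rec
}

# polynomial rolling hash of the JSON serialization (mod 2^31 - 1);
# stable provenance tag for configs
.config_hash <- function(x) {
  bytes <- utf8ToInt(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Serializable bundle of everything the end-to-end demo needs: the
#' acquisition settings, simulation design, peak-model hyperparameters and
#' the seed. Round-trips losslessly through JSON.
#'
#' @param grid_size Phantom matrix size.
#' @param tumor_types,doses,n_per_group,timepoints Cohort design.
#' @param noise_sigma Image noise level (fraction of reference signal).
#' @param seed Integer seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(grid_size = 16,
                            tumor_types = c("sensitive", "resistant"),
                            doses = c(0, 8, 9.5, 11), n_per_group = 3,
                            timepoints = c(0, 24, 72),
                            noise_sigma = 0.01, seed = 1L) {
  if (n_per_group < 1) stop("pipeline config invalid: zero subjects per group")
  structure(list(grid_size = grid_size, tumor_types = tumor_types,
                 doses = doses, n_per_group = n_per_group,
                 timepoints = timepoints, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

#' Run the full demo pipeline: simulate, fit, aggregate, report
#'
#' Simulates a dosing cohort of digital tumor phantoms, fits every CEST and
#' diffusion series pixel-by-pixel, reduces maps to ROI medians, and runs
#' the cohort statistics (two-way ANOVA contrasts on amide area, dose
#' correlations for amide and amine at the final timepoint). All outputs
#' carry provenance (config hash, seed, package version).
#'
#' @param config A [pipeline_config()] (or path to its JSON).
#' @param out_dir Output directory; created if needed. NULL skips writing.
#' @return List of class `pipeline_result`: `records`, `contrasts`,
#'   `correlations`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (config$n_per_group < 1) stop("pipeline config invalid: zero subjects")

  acq <- acq_config(grid_size = config$grid_size,
                    noise_sigma = config$noise_sigma, seed = config$seed)
  sim <- simulate_cohort(tumor_types = config$tumor_types,
                         doses = config$doses,
                         n_per_group = config$n_per_group,
                         timepoints = config$timepoints,
                         config = acq, seed = config$seed)
  records <- fit_cohort(sim)
  contrasts <- group_contrasts(records[records$tumor_type == config$tumor_types[1], ],
                               "amide_area")
  tmax <- max(config$timepoints)
  correlations <- lapply(c("amide_area", "amine_area", "adc"), function(p)
    dose_correlation(records, p, config$tumor_types[1], tmax))
  names(correlations) <- c("amide_area", "amine_area", "adc")

  log <- list(config_hash = .config_hash(unclass(config)),
              seed = config$seed,
              package_version = as.character(utils::packageVersion("qcest")),
              n_subjects = length(sim$subjects),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_records(records, file.path(out_dir, "records.csv"))
    jsonlite::write_json(
      list(log = log,
           anova = contrasts$anova,
           between = contrasts$between,
           within = contrasts$within,
           correlations = correlations),
      file.path(out_dir, "stats_report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  structure(list(records = records, contrasts = contrasts,
                 correlations = correlations, log = log),
            class = "pipeline_result")
}
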