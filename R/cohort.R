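#' ROI median of a parametric map
#'
#' Median over valid (finite, masked) pixels — the paper-style robust
#' per-tumor summary, insensitive to fitting outliers. Missing-valued
#' pixels are ignored.
#'
#' @param map A [parametric_map()].
#' @return Scalar median, or NA (with a message) if no valid pixel exists.
#' @export
roi_median <- function(map) {
  stopifnot(inherits(map, "parametric_map"))
  v <- map$values[map$mask]
  v <- v[is.finite(v)]
  if (length(v) == 0) {
    message("roi_median: no valid pixels in mask for ", map$name)
    return(NA_real_)
  }
  stats::median(v)
}

#' Caliper tumor volume
#'
#' V = w^2 l / 2, with l the maximal tumor diameter and w the diameter
#' orthogonal to it (both mm). If l < w the arguments were likely swapped;
#' a warning is issued but the value is still computed as given.
#'
#' @param l Maximal diameter, mm.
#' @param w Orthogonal diameter, mm.
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(l, w) {
  if (any(l <= 0) || any(w <= 0)) stop("tumor diameters must be positive")
  if (any(l < w)) warning("l < w: maximal diameter should be first")
  w^2 * l / 2
}

#' Default dose-effect model for cohort simulation
#'
#' Multiplicative effects applied to the amide and amine pool amplitudes,
#' the ADC map and the tumor volume, per (tumor type, dose, timepoint).
#' The "sensitive" type has amide/amine multipliers increasing linearly
#' with dose at 72 h (slope 0.03 and 0.025 per mg/kg) and half that at
#' 24 h; the "resistant" type is near-flat. ADC effects peak at the
#' mid-high doses (+41.5% at 9.5 mg/kg for the sensitive type); volume
#' growth is inhibited at 9.5 and 11 mg/kg and mildly stimulated at
#' 8 mg/kg relative to vehicle.
#'
#' @param null If TRUE, all multipliers are 1 (no treatment effect) —
#'   useful for type-I-error calibration.
#' @return Data frame with columns `tumor_type`, `dose`, `timepoint`,
#'   `amide_mult`, `amine_mult`, `adc_mult`, `volume_mult`.
#' @export
default_effect_model <- function(null = FALSE) {
  doses <- c(0, 8, 9.5, 11)
  grid <- expand.grid(tumor_type = c("sensitive", "resistant"),
                      dose = doses, timepoint = c(0, 24, 72),
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  em <- data.frame(grid, amide_mult = rep(1, n), amine_mult = rep(1, n),
                   adc_mult = rep(1, n), volume_mult = rep(1, n))
  if (null) return(em)
  adc72 <- c(`0` = 1, `8` = 1.10, `9.5` = 1.415, `11` = 1.22)
  adc72_res <- c(`0` = 1, `8` = 1.05, `9.5` = 1.55, `11` = 1.10)
  vol72 <- c(`0` = 1.60, `8` = 1.80, `9.5` = 1.15, `11` = 1.05)
  for (r in seq_len(n)) {
    tp <- em$timepoint[r]; d <- em$dose[r]; key <- as.character(d)
    if (tp == 0) next
    frac <- if (tp == 24) 0.5 else 1
    if (em$tumor_type[r] == "sensitive") {
      em$amide_mult[r] <- 1 + frac * 0.030 * d
      em$amine_mult[r] <- 1 + frac * 0.025 * d
      em$adc_mult[r] <- 1 + frac * (adc72[[key]] - 1)
      em$volume_mult[r] <- 1 + frac * (vol72[[key]] - 1)
    } else {
      em$amide_mult[r] <- 1 + frac * 0.004 * d
      em$amine_mult[r] <- 1 + frac * 0.003 * d
      em$adc_mult[r] <- 1 + frac * (adc72_res[[key]] - 1)
      em$volume_mult[r] <- 1 + frac * 0.9 * (vol72[[key]] - 1)
    }
  }
  em
}

.effect_lookup <- function(effect_model, tumor_type, dose, timepoint) {
  row <- effect_model[effect_model$tumor_type == tumor_type &
                        effect_model$dose == dose &
                        effect_model$timepoint == timepoint, ]
  if (nrow(row) != 1)
    stop(sprintf("effect model has no entry for (%s, %g mg/kg, %g h)",
                 tumor_type, dose, timepoint))
  row
}

#' Simulate a longitudinal dosing cohort
#'
#' Gives each subject a digital tumor phantom with mild subject-level
#' variation, then applies the effect model's multiplicative amide/amine/
#' ADC/volume changes at each timepoint. With `images = TRUE` the full
#' noisy CEST and diffusion image series are generated per subject and
#' timepoint (to be processed with [fit_cohort()]); with `images = FALSE`
#' only ROI-median records are generated directly (truth medians times
#' effect multipliers, with lognormal subject and measurement variation) —
#' a fast path for statistical calibration studies.
#'
#' @param tumor_types Character vector of types present in `effect_model`.
#' @param doses Dose levels, mg/kg (0 = vehicle).
#' @param n_per_group Subjects per (type, dose) group.
#' @param timepoints Hours; must include the baseline 0.
#' @param config An [acq_config()] used for per-subject phantoms/series.
#' @param effect_model See [default_effect_model()].
#' @param seed Integer seed.
#' @param images Generate image series (TRUE) or records only (FALSE).
#' @param subject_cv,measurement_cv Lognormal coefficients of variation for
#'   between-subject baseline spread and per-measurement error (records
#'   fast path).
#' @return With images: list of class `cohort_sim` with `subjects` (each
#'   carrying `tumor_type`, `dose`, per-timepoint `series` of CEST +
#'   diffusion and truth), and `volumes` data frame. Without images: a
#'   `CohortRecord`-style data frame (subject, tumor_type, dose, timepoint,
#'   volume_mm3, amide_area, amine_area, hydroxyl_area, noe_mt_area, adc).
#' @export
simulate_cohort <- function(tumor_types = c("sensitive", "resistant"),
                            doses = c(0, 8, 9.5, 11),
                            n_per_group = 3,
                            timepoints = c(0, 24, 72),
                            config = acq_config(grid_size = 16),
                            effect_model = default_effect_model(),
                            seed = 1L, images = TRUE,
                            subject_cv = 0.05, measurement_cv = 0.03) {
  if (n_per_group < 1) stop("need at least one subject per group")
  if (!0 %in% timepoints) stop("timepoints must include baseline 0 h")
  missing_doses <- setdiff(doses, unique(effect_model$dose))
  if (length(missing_doses))
    stop("unknown dose label(s): ", paste(missing_doses, collapse = ", "))
  set.seed(as.integer(seed))

  groups <- expand.grid(tumor_type = tumor_types, dose = doses,
                        stringsAsFactors = FALSE)
  subjects <- list()
  records <- list()
  volumes <- list()
  sid <- 0L
  for (g in seq_len(nrow(groups))) {
    type <- groups$tumor_type[g]; dose <- groups$dose[g]
    for (k in seq_len(n_per_group)) {
      sid <- sid + 1L
      subj_id <- sprintf("S%03d", sid)
      # subject-level baseline variation on amide/amine/ADC and geometry
      jit <- exp(stats::rnorm(3, 0, subject_cv))
      l0 <- stats::runif(1, 9, 12); w0 <- stats::runif(1, 6, 9)
      v0 <- tumor_volume(l0, w0)
      base_truth <- make_phantom(config, truth_overrides = list(
        amide_amplitude = min(0.05 * jit[1], 1),
        amine_amplitude = min(0.04 * jit[2], 1),
        adc = 1.0e-3 * jit[3]))

      subj <- list(subject = subj_id, tumor_type = type, dose = dose,
                   baseline_volume = v0, timepoints = timepoints,
                   truth = base_truth, series = list())
      for (tp in timepoints) {
        eff <- .effect_lookup(effect_model, type, dose, tp)
        truth_tp <- scale_phantom_effect(base_truth,
                                         amide_mult = eff$amide_mult,
                                         amine_mult = eff$amine_mult,
                                         adc_mult = eff$adc_mult)
        vol <- v0 * eff$volume_mult * exp(stats::rnorm(1, 0, measurement_cv))
        volumes[[length(volumes) + 1L]] <- data.frame(
          subject = subj_id, tumor_type = type, dose = dose,
          timepoint = tp, volume_mm3 = vol)
        if (images) {
          cfg_tp <- config
          cfg_tp$seed <- as.integer((seed * 1000L + sid * 7L + tp) %% .Machine$integer.max)
          subj$series[[as.character(tp)]] <- list(
            truth = truth_tp,
            cest = simulate_cest_series(truth_tp, cfg_tp),
            diffusion = simulate_relaxometry(truth_tp, cfg_tp, "diffusion"))
        } else {
          med <- function(m) stats::median(m[base_truth$mask])
          noise <- function() exp(stats::rnorm(1, 0, measurement_cv))
          p <- base_truth$pools
          records[[length(records) + 1L]] <- data.frame(
            subject = subj_id, tumor_type = type, dose = dose,
            timepoint = tp, volume_mm3 = vol,
            amide_area = peak_area(med(p$amide$amplitude) * eff$amide_mult,
                                   p$amide$fwhm[1, 1]) * noise(),
            amine_area = peak_area(med(p$amine$amplitude) * eff$amine_mult,
                                   p$amine$fwhm[1, 1]) * noise(),
            hydroxyl_area = peak_area(med(p$hydroxyl$amplitude),
                                      p$hydroxyl$fwhm[1, 1]) * noise(),
            noe_mt_area = peak_area(med(p$noe_mt$amplitude),
                                    p$noe_mt$fwhm[1, 1]) * noise(),
            adc = med(base_truth$adc_map) * eff$adc_mult * noise())
        }
      }
      if (images) subjects[[subj_id]] <- subj
    }
  }
  vol_df <- do.call(rbind, volumes)
  if (!images) {
    rec <- do.call(rbind, records)
    rownames(rec) <- NULL
    return(rec)
  }
  structure(list(subjects = subjects, volumes = vol_df,
                 effect_model = effect_model, config = config, seed = seed),
            class = "cohort_sim")
}

#' Fit every image series of a simulated cohort into a record table
#'
#' Runs the pixel-wise CEST fit ([fit_image()]) and the ADC fit
#' ([fit_adc()]) on each subject and timepoint, then reduces the parametric
#' maps to ROI medians.
#'
#' @param sim A `cohort_sim` from [simulate_cohort()].
#' @param model A [peak_model()].
#' @return Data frame with one row per (subject, timepoint): subject,
#'   tumor_type, dose, timepoint, volume_mm3, amide_area, amine_area,
#'   hydroxyl_area, noe_mt_area, b0_shift, adc.
#' @export
fit_cohort <- function(sim, model = peak_model()) {
  stopifnot(inherits(sim, "cohort_sim"))
  rows <- list()
  for (subj in sim$subjects) {
    for (tp in names(subj$series)) {
      ser <- subj$series[[tp]]
      zg <- normalize_zspectrum(ser$cest)
      maps <- fit_image(zg, model)
      adc_map <- fit_adc(ser$diffusion)
      vol <- sim$volumes$volume_mm3[sim$volumes$subject == subj$subject &
                                      sim$volumes$timepoint == as.numeric(tp)]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj$subject, tumor_type = subj$tumor_type,
        dose = subj$dose, timepoint = as.numeric(tp), volume_mm3 = vol,
        amide_area = roi_median(maps$amide_area),
        amine_area = roi_median(maps$amine_area),
        hydroxyl_area = roi_median(maps$hydroxyl_area),
        noe_mt_area = roi_median(maps$noe_mt_area),
        b0_shift = roi_median(maps$b0_shift),
        adc = roi_median(adc_map))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-subject percent change from baseline
#'
#' 100 x (value_t - value_0) / value_0 for each subject, with the
#' pre-dosing (0 h) measurement as baseline. Subjects with a missing or
#' zero baseline give NA (with a message).
#'
#' @param records Cohort record data frame (one row per subject-timepoint).
#' @param parameter Column name to normalize.
#' @return `records` with an added `pct_change` column.
#' @export
percent_change <- function(records, parameter) {
  stopifnot(parameter %in% names(records),
            all(c("subject", "timepoint") %in% names(records)))
  records$pct_change <- NA_real_
  for (s in unique(records$subject)) {
    sel <- records$subject == s
    b_row <- sel & records$timepoint == 0
    if (!any(b_row)) { message("percent_change: no baseline for ", s); next }
    b <- records[[parameter]][b_row][1]
    if (!is.finite(b) || b == 0) {
      message("percent_change: missing/zero baseline for ", s)
      next
    }
    records$pct_change[sel] <- 100 * (records[[parameter]][sel] - b) / b
  }
  records
}

#' Two-way ANOVA and treatment contrasts on a cohort parameter
#'
#' Works on per-subject percent change from baseline. Fits a two-way
#' dose x timepoint ANOVA over the post-baseline measurements, then the
#' two contrast families reported in dose-response imaging studies:
#' treated vs vehicle at matched timepoints (between-group, Welch t) and
#' post-treatment vs baseline within each group (one-sample t on the
#' percent change). The nominal significance threshold (0.05) is reported
#' alongside raw p-values; no values are filtered by it and no
#' multiple-testing adjustment is applied.
#'
#' @param records Cohort record data frame.
#' @param parameter Column to analyze.
#' @return List of class `cohort_contrasts`: `anova` (data frame),
#'   `between` and `within` contrast data frames, `parameter`, `alpha`.
#' @export
group_contrasts <- function(records, parameter) {
  pc <- percent_change(records, parameter)
  post <- pc[pc$timepoint != 0 & is.finite(pc$pct_change), ]
  if (length(unique(post$dose)) < 2)
    stop("need at least 2 dose groups")
  counts <- table(post$dose[post$timepoint == max(post$timepoint)])
  if (sum(counts >= 2) < 2)
    stop("need at least 2 groups with >= 2 subjects")

  post$dose_f <- factor(post$dose)
  post$time_f <- factor(post$timepoint)
  # full two-way decomposition when both factors vary; one-way otherwise
  form <- if (nlevels(post$time_f) >= 2) pct_change ~ dose_f * time_f
          else pct_change ~ dose_f
  aov_fit <- stats::aov(form, data = post)
  an <- as.data.frame(summary(aov_fit)[[1]])
  an$term <- trimws(rownames(an))
  rownames(an) <- NULL

  between <- list()
  for (tp in sort(unique(post$timepoint))) {
    ctrl <- post$pct_change[post$dose == 0 & post$timepoint == tp]
    for (d in setdiff(sort(unique(post$dose)), 0)) {
      trt <- post$pct_change[post$dose == d & post$timepoint == tp]
      if (length(ctrl) < 2 || length(trt) < 2) {
        between[[length(between) + 1L]] <- data.frame(
          dose = d, timepoint = tp, estimate = mean(trt) - mean(ctrl),
          statistic = NA_real_, p_value = NA_real_, n_treated = length(trt),
          n_control = length(ctrl))
        next
      }
      tt <- stats::t.test(trt, ctrl)
      between[[length(between) + 1L]] <- data.frame(
        dose = d, timepoint = tp,
        estimate = unname(diff(rev(tt$estimate))),
        statistic = unname(tt$statistic), p_value = tt$p.value,
        n_treated = length(trt), n_control = length(ctrl))
    }
  }

  within <- list()
  for (d in sort(unique(post$dose))) for (tp in sort(unique(post$timepoint))) {
    x <- post$pct_change[post$dose == d & post$timepoint == tp]
    if (length(x) < 2) next
    tt <- stats::t.test(x, mu = 0)
    within[[length(within) + 1L]] <- data.frame(
      dose = d, timepoint = tp, mean_pct_change = mean(x),
      statistic = unname(tt$statistic), p_value = tt$p.value, n = length(x))
  }

  structure(list(anova = an,
                 between = do.call(rbind, between),
                 within = do.call(rbind, within),
                 parameter = parameter, alpha = 0.05),
            class = "cohort_contrasts")
}

#' @export
print.cohort_contrasts <- function(x, ...) {
  cat(sprintf("<cohort_contrasts> parameter: %s (alpha = %g, unadjusted)\n",
              x$parameter, x$alpha))
  cat("Two-way ANOVA:\n"); print(x$anova, digits = 4)
  cat("Treated vs vehicle (matched timepoint):\n")
  print(x$between, digits = 4, row.names = FALSE)
  cat("Vs baseline (within group):\n")
  print(x$within, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Spearman correlation between dose and parameter change
#'
#' Rank correlation (average ranks for ties; exact p for small n without
#' ties, t-approximation otherwise, per `stats::cor.test`) between dose
#' level and the percent change of a parameter at one timepoint, for one
#' tumor type. By default group means of the per-subject changes are
#' correlated against the dose levels; set `group_means = FALSE` to use
#' individual subjects.
#'
#' @param records Cohort record data frame.
#' @param parameter Column to analyze.
#' @param tumor_type Tumor type to subset.
#' @param timepoint Timepoint (h) to analyze.
#' @param group_means Correlate dose-group means (default) or subjects.
#' @return List: `rho`, `p_value`, `n`, `parameter`, `timepoint`;
#'   `rho` is NA (with a message) when the input is constant.
#' @export
dose_correlation <- function(records, parameter, tumor_type, timepoint,
                             group_means = TRUE) {
  pc <- percent_change(records, parameter)
  sub <- pc[pc$tumor_type == tumor_type & pc$timepoint == timepoint &
              is.finite(pc$pct_change), ]
  if (length(unique(sub$dose)) < 3)
    stop("need at least 3 dose levels for a correlation")
  if (group_means) {
    agg <- stats::aggregate(pct_change ~ dose, data = sub, FUN = mean)
    x <- agg$dose; y <- agg$pct_change
  } else {
    x <- sub$dose; y <- sub$pct_change
  }
  if (stats::sd(y) == 0 || stats::sd(x) == 0) {
    message("dose_correlation: constant input, correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x),
                parameter = parameter, timepoint = timepoint))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       parameter = parameter, timepoint = timepoint)
}
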