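#' Relaxometry image series
#'
#' Container for a diffusion (signal vs b-value), inversion-recovery
#' (signal vs TI) or multi-echo (signal vs TE) series on an image grid.
#'
#' @param modality One of `"diffusion"`, `"t1"`, `"t2"`.
#' @param control Control variable: b (s/mm^2), TI (ms) or TE (ms);
#'   strictly increasing, at least 3 points.
#' @param signal grid x grid x control array of non-negative magnitudes.
#' @param mask Logical matrix.
#' @return Object of class `relaxometry_series`.
#' @export
relaxometry_series <- function(modality, control, signal, mask) {
  modality <- match.arg(modality, c("diffusion", "t1", "t2"))
  control <- as.numeric(control)
  if (length(control) < 3) stop("need at least 3 control points")
  if (any(diff(control) <= 0)) stop("control values must be strictly increasing")
  stopifnot(is.array(signal), length(dim(signal)) == 3,
            dim(signal)[3] == length(control),
            all(dim(mask) == dim(signal)[1:2]))
  if (any(signal < 0, na.rm = TRUE)) stop("signals must be non-negative")
  structure(list(modality = modality, control = control,
                 signal = signal, mask = mask),
            class = "relaxometry_series")
}

# log-linear seed for monoexponential decay S = s0 exp(-rate * x);
# returns c(s0, rate) or NULL for degenerate pixels
.loglin_seed <- function(x, s) {
  ok <- is.finite(s) & s > 0
  if (sum(ok) < 2) return(NULL)
  co <- stats::coef(stats::lm(log(s[ok]) ~ x[ok]))
  c(exp(co[1]), -co[2])
}

.fit_monoexp <- function(x, s, rate_upper = Inf) {
  seed <- .loglin_seed(x, s)
  if (is.null(seed) || !all(is.finite(seed))) return(NULL)
  start <- c(max(seed[1], 1e-12), min(max(seed[2], 0), rate_upper))
  fit <- tryCatch(minpack.lm::nls.lm(
    par = start, lower = c(0, 0), upper = c(Inf, rate_upper),
    fn = function(p) p[1] * exp(-p[2] * x) - s,
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  fit$par
}

#' Apparent diffusion coefficient map
#'
#' Per-pixel bounded nonlinear least-squares fit of the monoexponential
#' diffusion decay S(b) = S0 exp(-b ADC), seeded by log-linear regression,
#' with ADC constrained non-negative. Degenerate pixels (all-zero or
#' non-finite) are set to NaN and counted.
#'
#' @param series A diffusion [relaxometry_series()].
#' @return A [parametric_map()] of ADC in mm^2/s, with attribute `n_failed`.
#' @export
fit_adc <- function(series) {
  stopifnot(inherits(series, "relaxometry_series"))
  if (series$modality != "diffusion") stop("series modality must be 'diffusion'")
  n <- nrow(series$mask)
  out <- matrix(NaN, n, n)
  n_failed <- 0L
  idx <- which(series$mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    p <- .fit_monoexp(series$control, series$signal[i, j, ])
    if (is.null(p)) n_failed <- n_failed + 1L else out[i, j] <- p[2]
  }
  m <- parametric_map(out, "adc", "mm^2/s", series$mask)
  attr(m, "n_failed") <- n_failed
  m
}

#' T2 map from a multi-echo series
#'
#' Per-pixel fit of S(TE) = S0 exp(-TE/T2) with T2 > 0, seeded by
#' log-linear regression. Non-decaying or degenerate pixels give NaN.
#'
#' @param series A t2 [relaxometry_series()].
#' @return A [parametric_map()] of T2 in ms, with attribute `n_failed`.
#' @export
fit_t2 <- function(series) {
  stopifnot(inherits(series, "relaxometry_series"))
  if (series$modality != "t2") stop("series modality must be 't2'")
  n <- nrow(series$mask)
  out <- matrix(NaN, n, n)
  n_failed <- 0L
  idx <- which(series$mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    p <- .fit_monoexp(series$control, series$signal[i, j, ])
    if (is.null(p) || p[2] <= 0) n_failed <- n_failed + 1L
    else out[i, j] <- 1 / p[2]
  }
  m <- parametric_map(out, "t2", "ms", series$mask)
  attr(m, "n_failed") <- n_failed
  m
}

# 3-parameter signed inversion-recovery fit with magnitude-polarity
# restoration: for each candidate null index k the first k points are
# negated, the signed model A - B exp(-TI/T1star) is fitted, and the
# lowest-residual solution wins.
.fit_ir_pixel <- function(ti, s) {
  if (!any(is.finite(s)) || max(s, na.rm = TRUE) <= 0) return(NULL)
  a0 <- max(s)
  null_idx <- which.min(s)
  candidates <- unique(pmax(pmin(c(null_idx - 1, null_idx, null_idx + 1),
                                 length(ti)), 0))
  best <- NULL
  for (k in candidates) {
    sgn <- ifelse(seq_along(ti) <= k, -1, 1)
    ss <- sgn * s
    start <- c(a0, 2 * a0, max(ti[null_idx] / log(2), ti[1]))
    fit <- tryCatch(minpack.lm::nls.lm(
      par = start, lower = c(1e-12, 1e-12, 1), upper = c(Inf, Inf, 1e6),
      fn = function(p) (p[1] - p[2] * exp(-ti / p[3])) - ss,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) return(NULL)
  best$par
}

#' T1 map from a Look-Locker inversion-recovery series
#'
#' Per-pixel 3-parameter magnitude fit S(TI) = |A - B exp(-TI/T1*)|, with
#' polarity restored by trying sign patterns around the signal null, then
#' the Look-Locker correction T1 = T1* (B/A - 1). Pixels with B/A <= 1
#' (uncorrectable) give NaN.
#'
#' @param series A t1 [relaxometry_series()].
#' @return A [parametric_map()] of corrected T1 in ms, with attribute
#'   `n_failed`.
#' @export
fit_t1_look_locker <- function(series) {
  stopifnot(inherits(series, "relaxometry_series"))
  if (series$modality != "t1") stop("series modality must be 't1'")
  if (length(series$control) < 4) stop("need at least 4 inversion times")
  n <- nrow(series$mask)
  out <- matrix(NaN, n, n)
  n_failed <- 0L
  idx <- which(series$mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    p <- .fit_ir_pixel(series$control, series$signal[i, j, ])
    if (is.null(p) || p[2] / p[1] <= 1) { n_failed <- n_failed + 1L; next }
    out[i, j] <- p[3] * (p[2] / p[1] - 1)
  }
  m <- parametric_map(out, "t1", "ms", series$mask)
  attr(m, "n_failed") <- n_failed
  m
}
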