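# Nominal five-pool truth used across tests (centers at the standard
# amide/amine/hydroxyl assignments, one broad NOE/MT pool).
nominal_truth <- function() {
  list(centers = c(0, 1.2, 2.4, 3.5, -3.0),
       amplitudes = c(0.8, 0.03, 0.04, 0.05, 0.10),
       fwhms = c(2.0, 1.0, 1.2, 1.0, 5.0))
}

default_offsets <- function() seq(-6, 6, by = 0.12)

# Random five-pool truth within the prior windows and sensible tissue-like
# amplitude/width ranges; b0 within the observed stability bound.
random_truth <- function() {
  list(centers = c(0,
                   1.2 + stats::runif(1, -0.2, 0.2),
                   2.4 + stats::runif(1, -0.2, 0.2),
                   3.5 + stats::runif(1, -0.2, 0.2),
                   stats::runif(1, -4, -2)),
       amplitudes = c(stats::runif(1, 0.6, 0.9),
                      stats::runif(1, 0.02, 0.08),
                      stats::runif(1, 0.02, 0.08),
                      stats::runif(1, 0.02, 0.08),
                      stats::runif(1, 0.05, 0.2)),
       fwhms = c(stats::runif(1, 1.5, 3),
                 stats::runif(1, 0.5, 1.5),
                 stats::runif(1, 0.5, 1.5),
                 stats::runif(1, 0.5, 1.5),
                 stats::runif(1, 3, 7)),
       b0 = stats::runif(1, -0.1, 0.1))
}

# relative error with a floor on the denominator, so near-zero truths
# (centers, b0) are judged on an absolute ppm scale
rel_err <- function(est, truth) abs(est - truth) / pmax(abs(truth), 1)
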