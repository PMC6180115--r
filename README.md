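# qcest

Quantitative MRI analysis of tumor response to proteasome inhibition:
multi-pool CEST Z-spectrum fitting, ADC/T1/T2 relaxometry, biphasic
dose-response (EC50/IC50) estimation, and cohort-level biomarker
statistics — with a synthetic digital-phantom module so every stage is
testable by parameter recovery.

## Who this is for

Proteasome inhibitors block protein degradation; the resulting
accumulation of mobile proteins and peptides raises the chemical
exchange saturation transfer (CEST) MRI signal of amide and amine
protons, and treatment-induced cell death raises the apparent diffusion
coefficient (ADC). `qcest` is for imaging scientists who want to turn
raw saturation image series, diffusion/relaxometry series and MTT plate
tables into per-tumor biomarkers and cohort statistics, or to prototype
such analyses on simulated data with known ground truth.

## The core model

Each pixel's Z-spectrum, Z(f) = S(f)/S₀, is decomposed into five
Lorentzian pools — water (0 ppm), hydroxyl (1.2 ppm), amine (2.4 ppm),
amide (3.5 ppm) and one broad combined NOE/MT pool — plus a global B0
frequency shift δ₀:

    Z(f) = 1 − Σᵢ Aᵢ / (1 + ((f − δ₀ − cᵢ) / (wᵢ/2))²)

fitted per pixel by MAP estimation (bounded Levenberg–Marquardt with
Gaussian priors on the fine-peak centers and weak lognormal priors on
widths). Peak area, the biomarker carried into statistics, is
(π/2)·A·w. Companion models: monoexponential diffusion decay
S(b) = S₀·exp(−b·ADC); Look-Locker inversion recovery
S(TI) = |A − B·exp(−TI/T1\*)| with T1 = T1\*(B/A − 1); multi-echo
S(TE) = S₀·exp(−TE/T2); and a biphasic (hormetic) Hill dose-response

    V(C) = V₀ + Smax·C^hs/(EC50^hs + C^hs) − Imax·C^hi/(IC50^hi + C^hi)

fitted on log-concentration, from which EC50 (half-maximal stimulation)
and IC50 (half-maximal inhibition) are estimated. Receptor occupancy
uses single-site binding: unbound % = 100·Ki/(Ki + C).

## Worked example

Fit a noiseless five-pool spectrum sampled at the default acquisition
grid (−6…6 ppm at 0.12 ppm):

```r
library(qcest)
off <- acq_offsets(acq_config())
z <- model_zspectrum(off, centers = c(0, 1.2, 2.4, 3.5, -3),
                     amplitudes = c(0.8, 0.03, 0.04, 0.05, 0.10),
                     fwhms = c(2, 1, 1.2, 1, 5))
fit_pixel(z, off)
#> <zfit_result> converged: TRUE, residual RMS 6.83e-17, B0 shift +0.000 ppm
#>      name center amplitude fwhm    area
#>     water    0.0      0.80  2.0 2.51327
#>  hydroxyl    1.2      0.03  1.0 0.04712
#>     amine    2.4      0.04  1.2 0.07540
#>     amide    3.5      0.05  1.0 0.07854
#>    noe_mt   -3.0      0.10  5.0 0.78540
```

Every pool is recovered exactly: the amide center at 3.5 ppm with area
(π/2)·0.05·1.0 = 0.0785 ppm, the amine at 2.4 ppm, the hydroxyl at
1.2 ppm. On noisy data the same call returns standard errors and a
convergence flag, and `fit_image()` runs it over a whole masked grid
into parametric maps.

Fit a simulated MTT plate (2-fold ladder 1.6–400 nM, 12 replicates, 5%
noise) generated from a hormetic truth with IC50 = 12.6 nM:

```r
truth <- hill_params(V0 = 100, Smax = 30, EC50 = 3, hs = 1.5,
                     Imax = 90, IC50 = 12.6, hi = 1.5)
plate <- simulate_mtt_plate(truth, replicates = 12, noise_sigma = 5, seed = 42)
fit_hill(plate)
#> <hill_fit> converged: TRUE; biphasic supported: TRUE
#>   V0 116.3%  Smax 15.9%  EC50 3.77 nM (hs 6.00)
#>   Imax 92.8%  IC50 10.3 nM (hi 1.24)  RSS 2547.1 (n=108)
```

The recovered IC50 (10.3 nM) sits within the ~15–25% single-plate
uncertainty of this weakly identified hormetic model — which is why
plate-level summaries in this package use medians over replicate plates
(see the methods vignette). The hormetic bump itself is flagged as
supported by the AICc comparison.

End-to-end demo — simulate a dosing cohort of digital tumor phantoms,
fit every series, and run the statistics:

```r
res <- run_pipeline(pipeline_config(grid_size = 16, n_per_group = 3, seed = 1),
                    out_dir = "demo_out")
res$correlations$amide_area$rho   # Spearman rho, dose vs amide-area change
```

A thin command-line wrapper with the same entry points
(`run-demo`, `simulate-phantom`, `fit-cest`, `fit-adc`, `fit-t1`,
`fit-t2`, `fit-dose`, `cohort-stats`) is installed at
`inst/cli/qcest`.

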