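---
title: "Quantitative CEST MRI and dose-response analysis with qcest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CEST MRI and dose-response analysis with qcest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcest)
```

## What this package computes

`qcest` quantifies tumor response to proteasome-inhibitor therapy from
multi-modal quantitative MRI. Proteasome inhibition disrupts protein
homeostasis; the resulting accumulation of mobile proteins and peptides
raises the chemical exchange saturation transfer (CEST) signal of amide
(backbone) and amine protons, while treatment-induced cell death raises
the apparent diffusion coefficient (ADC). The package implements the full
chain from raw saturation image series to cohort-level statistics, and a
synthetic phantom module that generates every input with known ground
truth, so each stage is validated by parameter recovery.

## The Z-spectrum model

For each pixel, the Z-spectrum is the normalized water signal
$Z(f) = S(f)/S_0$ at saturation offset $f$ (ppm from water), with $S_0$
acquired far off-resonance (8000 ppm). The model is a sum of five
Lorentzian absorption lines,

$$Z(f) = 1 - \sum_{i=1}^{5} \frac{A_i}{1 + \left(\frac{f - \delta_0 - c_i}{w_i/2}\right)^2},$$

with amplitude $A_i \in [0,1]$, center $c_i$, full width at half maximum
$w_i$, and a single global frequency shift $\delta_0$ (B0 drift) applied
to all centers. The pools are water (0 ppm), hydroxyl (1.2 ppm), amine
(2.4 ppm, possibly containing a guanidinium contribution), amide
(3.5 ppm), and one broad combined NOE/MT pool for the relayed nuclear
Overhauser effect, semi-solid magnetization transfer and lipids, whose
center is free in $[-5, -1]$ ppm. NOE and MT are deliberately not
separated: two broad overlapping upfield lines are not identifiable from
these data and a single pool is markedly more stable. The water peak is
always fitted, never excised. Positive offsets are downfield of water.

Peak area, the quantity carried into all downstream statistics, has the
closed form $\text{area} = (\pi/2)\, A\, w$ (the full-line integral of
this parameterization).

## Pixel-wise MAP estimation

`fit_pixel()` maximizes a posterior combining a Gaussian likelihood with:

* Gaussian priors on the fine-peak centers (mean at nominal position,
  s.d. 0.2 ppm) inside hard windows of ±0.5 ppm;
* weak lognormal priors on the widths (s.d. 0.35 on the log scale for the
  fine pools, 1.5× that for water and NOE/MT) about nominal tissue values
  (water 2, hydroxyl 1.0, amine 1.2, amide 1.0, NOE/MT 5 ppm);
* bound constraints: amplitudes [0, 1]; FWHM 0.2–3 ppm (fine pools),
  0.5–6 ppm (water), 2–12 ppm (NOE/MT); $\delta_0 \in [-0.3, 0.3]$ ppm;
* a stiff one-sided penalty keeping the amine and amide centers at least
  0.5 ppm apart; fits where it activates are flagged.

The width priors are a deliberate design choice beyond center priors
alone: the hydroxyl and amine pools overlap the water line strongly, and
without them the per-pixel area estimates at realistic (1%) noise are
heavy-tailed and noticeably biased. With them, amide and amine area
estimates are unbiased to within a few percent at 1% Rician noise (the
test suite measures this over 200 replicates); hydroxyl remains the least
reliable pool because of water coalescence, and should be interpreted
with caution.

Estimation is bounded Levenberg–Marquardt least squares with an analytic
Jacobian, the prior terms appended as extra residual rows scaled by the
assumed noise level. Five deterministic multi-starts jitter the widths,
B0 shift and NOE/MT center; iteration stops early once the data residual
reaches the noise floor. The prior weight is then recalibrated against
the residual RMS actually achieved and the fit repeated (up to four
times) — an empirical-Bayes step that removes prior shrinkage when the
data are effectively noiseless, which is what makes exact forward/inverse
round trips possible. Standard errors come from the Gauss–Newton
approximation of the posterior covariance at the optimum. Non-converged
pixels are recorded as NaN in all maps and counted; ROI medians ignore
them. A 64×64 image (a typical acquisition matrix) fits in well under a
minute on one CPU at ~15 ms per pixel.

```{r roundtrip}
off <- acq_offsets(acq_config())
z <- model_zspectrum(off, centers = c(0, 1.2, 2.4, 3.5, -3),
                     amplitudes = c(0.8, 0.03, 0.04, 0.05, 0.10),
                     fwhms = c(2, 1, 1.2, 1, 5))
fit_pixel(z, off)
```

## Relaxometry

* **ADC**: per-pixel bounded nonlinear fit of $S(b) = S_0 e^{-b\,\mathrm{ADC}}$
  (monoexponential only — no IVIM or kurtosis terms), seeded by
  log-linear regression. Default b-values span 150–1070 s/mm²; the exact
  ladder is configurable (six evenly spaced values by default).
* **T1 (Look-Locker)**: 3-parameter magnitude fit
  $S(TI) = |A - B e^{-TI/T_1^*}|$ with polarity restored by trying sign
  patterns around the signal null and keeping the lowest residual, then
  the standard correction $T_1 = T_1^* (B/A - 1)$. Pixels with
  $B/A \le 1$ are uncorrectable and recorded as NaN.
* **T2**: $S(TE) = S_0 e^{-TE/T_2}$ with $T_2 > 0$.

All three agree with their log-linear or closed-form oracles to better
than $10^{-6}$ relative on noiseless data, and ADC is unbiased within 2%
at 1% Rician noise.

## Dose-response model

MTT viabilities (% of control) are fitted with a biphasic, hormetic
extension of the Hill equation,

$$V(C) = V_0 + \frac{S_{max} C^{h_s}}{EC_{50}^{h_s} + C^{h_s}}
             - \frac{I_{max} C^{h_i}}{IC_{50}^{h_i} + C^{h_i}},$$

so that low concentrations can stimulate viability above baseline
(the experimentally observed hormetic bump) while high concentrations
inhibit. The exact published functional form of the "modified Hill
equation" is not available; this additive stimulation + inhibition form
reproduces the reported behavior (viability peaking around 120–130% of
control before declining) and nests the ordinary inhibitory curve at
$S_{max}=0$. Fitting is bounded least squares on log10 concentration,
with slopes bounded (0.3, 6), both half-maximal concentrations bounded
within one decade of the assay range, and multi-start over monophasic and
biphasic initializations. A small-sample information criterion (AICc)
comparison between the monophasic and biphasic candidates is reported
(`biphasic_supported`) but never applied silently: the returned estimate
is always the full biphasic fit. Per-timepoint curves are fitted
independently.

The hormetic model is weakly identified when stimulation and inhibition
overlap: a single 9-concentration × 12-replicate plate at 5% noise
determines IC50 only to roughly 15–25%, and the per-plate estimate is
multimodal. Summaries over replicate plates therefore use the median.

Receptor occupancy uses single-site competitive binding: the unbound
fraction is $100\,K_i/(K_i + C)$, with $K_i = 0.93$ nM as default, so the
half-unbound concentration equals $K_i$ exactly.

## The synthetic phantom and cohort generator

`make_phantom()` builds a single-slice digital tumor: a centered ellipse
(semi-axes 0.35 and 0.28 of the grid, ~31% coverage) with truth maps that
vary as low-order linear ramps (±20% by default) so parametric maps have
recoverable structure. Default tissue values: water A = 0.8, w = 2 ppm;
hydroxyl 0.03/1.0; amine 0.04/1.2; amide 0.05/1.0; NOE/MT 0.10/5.0;
ADC 1.0×10⁻³ mm²/s; T1 1500 ms; T2 40 ms; B0 drift a smooth ramp within
±0.1 ppm (the experimentally observed stability bound). Noise is Rician
(the distribution of magnitude MRI), with scale expressed as a fraction
of the per-pixel reference signal; the default 1% is a realistic
preclinical level, chosen once — no published noise level exists for
these acquisitions. CEST offsets default to −6…6 ppm at 0.12 ppm
(101 samples) with the reference at 8000 ppm.

The cohort generator applies multiplicative treatment effects per
(tumor type, dose, timepoint) to the amide and amine amplitudes, ADC and
tumor volume. The default effect model is anchored to the reported
dose-response pattern: for the drug-sensitive type the amide multiplier
rises linearly with dose (1 + 0.03·dose at 72 h, half that at 24 h;
amine slope 0.025), ADC peaks at the mid-high doses (+41.5% at
9.5 mg/kg), growth is inhibited at 9.5 and 11 mg/kg and mildly stimulated
at 8 mg/kg; the resistant type is near-flat in amide/amine. Only the
monotonicity of these effects is empirically anchored; their magnitudes
are simulation choices. Timepoints are configurable with default
{0, 24, 72} h (the source protocol is internally inconsistent about a
48 h session; the reported results use 24 h and 72 h). MTT plates
simulate viability directly (truth curve + Gaussian noise) rather than
absorbance, since absorbance is reduced to % of control before any
analysis. A continuous-wave two-pool Bloch–McConnell steady-state solver
(`simulate_two_pool_bm()`) provides a physics-based cross-check that is
independent of the Lorentzian parameterization: Lorentzian fits of its
spectra must locate the solute pool within 0.3 ppm.

What the phantoms do **not** emulate: realistic anatomy, multi-slice
geometry, pulse-train saturation dynamics and k-space effects, pH or
exchange-rate variation (the Lorentzian model is phenomenological and
amplitudes are specific to the 3 µT saturation power), partial-volume
edges, or motion. Passing recovery tests therefore demonstrates
correctness of the estimators under the stated forward models, not
robustness to everything real data can present.

## Cohort statistics

Per-tumor summaries are ROI medians (robust to fitting outliers);
longitudinal values are expressed as percent change from the pre-dosing
baseline. `group_contrasts()` fits a two-way dose × timepoint ANOVA on
the post-baseline percent changes and reports the two contrast families
used in dose-response imaging studies — treated vs vehicle at matched
timepoints (Welch t) and post-treatment vs baseline within group
(one-sample t). Raw p-values are reported against a nominal α = 0.05 and
no multiple-testing adjustment is applied, matching the reporting style
this analysis reproduces; this is stated in every report.
`dose_correlation()` uses Spearman's rank correlation (via
`stats::cor.test`: average ranks under ties, exact p for small n, else
the t approximation) between dose and, by default, dose-group means of
the per-subject changes — with four dose levels the printed correlations
are only consistent with group means, which resolves the ambiguity in
the source description.

## Numerical and design notes

* **Missing values**: NaN is the sentinel in all maps; medians skip it.
* **Normalization guards**: pixels with non-positive reference signal, or
  any normalized value above 1.5, are dropped from the mask and counted.
* **Determinism**: every simulator takes a seed and identical
  (config, seed) give bit-identical outputs; CLI commands are idempotent.
* **Serialization**: NIfTI volumes + JSON sidecars; numeric metadata
  lists are serialized as 17-significant-digit strings because JSON
  double emission rounds the final ULP, and offsets must round-trip
  exactly. No baseline scale factor is fitted alongside the B0 shift:
  with $S_0$ normalization the far-off-resonance level is 1 by
  construction.
* **Problem sizes in the test suite** (chosen to keep recovery claims
  well-powered): single-pixel round trips use the full 101-offset grid;
  image round trips use 10–24 px grids; the cohort dose-trend check uses
  6 subjects/group on 20×20 grids, sized against the ~4% ROI-median
  noise measured at 1% image noise, because adjacent dose groups differ
  by only ~4.5 points of amide-area change; IC50 recovery is summarized
  over replicate plates (median), reflecting the weak identifiability
  discussed above; null-calibration uses 200 record-level cohorts.

## Known limitations

* Hydroxyl-peak quantities are unreliable whenever the water line is
  broad (coalescence); they are reported but should be down-weighted.
* The Lorentzian decomposition is semi-quantitative: it cannot separate
  exchange rate from pool size (no pH quantification), and parameter
  values are specific to the saturation power.
* The biphasic Hill fit should be treated as an interval estimate at
  plate scale; report the AICc comparison and uncertainty, not just the
  point estimate.
* `group_contrasts()` reports unadjusted p-values by design; apply your
  own multiplicity control when screening many parameters.
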