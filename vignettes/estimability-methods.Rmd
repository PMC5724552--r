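---
title: "Predicting CT volumetry precision with the estimability index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting CT volumetry precision with the estimability index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estimact)
```

## The problem

The volume of a lung nodule, measured from CT, is a biomarker: its change
over time informs diagnosis and treatment response. A volume change is only
meaningful if it exceeds the measurement's repeatability, and repeatability
depends on everything in the chain — dose, reconstruction, slice thickness,
lesion size and contrast, and the segmentation software. Measuring it
empirically means repeated scans and thousands of segmentations per protocol
space. `estimact` implements the model-based shortcut: a Fourier-domain
**estimability index e′** computed from a small set of image-quality
measurements, calibrated once against empirical repeatability, and then used
to predict precision across the whole protocol space.

## The model and its assumptions

Volumetry is treated as edge detection carried out by cross-correlating the
image with a template. Four spectral quantities on one 3-D frequency grid
enter:

* the noise power spectrum **NPS** (HU² mm³), whose integral is the noise
  variance;
* the task transfer function **TTF**, the system resolution measured at
  task-relevant contrast, normalized to 1 at DC;
* the **task function** |W~task~|: the magnitude 3-D Fourier spectrum of the
  nodule's Laplacian edge profile, rescaled so its frequency-domain integral
  equals the nodule's spatial integral ("the power of the task equals the
  power of the nodule");
* the **template function** |W~temp~|: the software's expected nodule, built
  by the identical construction, hence equal to |W~task~| for a perfectly
  spherical lesion.

They combine in the nonprewhitening form

$$\frac{1}{e'^2} \;=\;
  \frac{\iiint \mathrm{NPS}\;\mathrm{TTF}^2\,
        |W_{task}|\,|W_{temp}|\;du\,dv\,dw}
       {\Bigl(\iiint \mathrm{TTF}^2\,
        |W_{task}|\,|W_{temp}|\;du\,dv\,dw\Bigr)^{2}}.$$

The numerator is the noise-driven fluctuation of the nodule–template cross
correlation; the denominator is its strength. Under this definition e′ is a
signal-to-noise-like quantity: doubling the noise variance divides e′ by
√2, scaling the TTF by t scales e′ by t, doubling lesion contrast doubles
e′. The tests assert these scalings exactly, together with a brute-force
triple-loop evaluation of the integrals.

**Direction convention.** Because e′ is SNR-like, *higher e′ means better
expected precision*, and the quantity that repeatability is regressed
against is the **imprecision predictor 1/e′** — the natural abscissa for a
precision-versus-image-quality plot. All results tables carry both
`e_prime` and `inv_e_prime` so either convention can be read off directly.

Key modeling assumptions, inherited by everything downstream:

* the imaging chain is locally linear and shift invariant (blur acts as
  multiplication by the TTF in the frequency domain);
* noise is stationary within the measurement region, so a single NPS
  describes it; structured backgrounds are handled only by rescaling the
  NPS magnitude to the noise variance measured in the structured region,
  leaving the texture unchanged;
* the segmentation is summarized by a template; software-specific behaviour
  beyond template mismatch (internal decision noise, heuristics) is outside
  the model and is exactly why the e′→PRC calibration is fitted per
  software.

## Numerical conventions

**Transform normalization.** The forward DFT is multiplied by the voxel
volume $dx\,dy\,dz$, approximating the continuous Fourier integral, so
spectral objects carry physical units and Parseval's identity reads
$\sum |F|^2 \Delta u\Delta v\Delta w = \sum f^2\, dx\,dy\,dz$. Every module
shares this convention; it makes the e′ integrals stable under grid
refinement. All spectral storage is DC-centred; conversion to DFT order
happens only at FFT boundaries.

**DC exclusion.** The DC bin is excluded from both e′ integrals by default
(`exclude_dc = TRUE`): the NPS at DC is an artifact of the detrending
choice, and the task spectrum at DC is dominated by the normalization
rather than the edge content. The option exists because the choice is a
convention, not a theorem.

**"Power" normalization of the task function.** The task spectrum is
rescaled so that the *first-power* frequency integral of |W| equals the
spatial integral of the nodule. A Parseval-style alternative (|W|² matched
to the squared nodule) is implemented behind
`task_function(normalization = "parseval")` but is off by default; the
first-power reading follows the stated normalization contract, and only
relative comparisons of e′ enter the calibration anyway, so the choice
cancels there.

**Rasterization.** Spheres are rasterized with 3× per-axis supersampling of
the edge shell; at 0.25 mm voxels the discrete volume of a 9.5 mm sphere is
within 0.2% of $\tfrac43\pi r^3$. Task/template grids default to twice the
nodule extent (padding policy), and nodules must fit with a two-voxel
margin.

**Laplacian.** The 7-point spacing-aware stencil, exact on quadratics;
boundary voxels are set to zero. A 27-point stencil buys nothing here
because only the magnitude spectrum of the edge shell is used.

## Estimators

**NPS.** Ensemble-averaged periodogram over overlapping cubic ROIs
(default 32³, half-overlap), per-ROI mean detrending (a first-order
polynomial detrend is available), scaled by voxel volume over ROI voxel
count so the frequency integral equals the variance. `difference_pair` mode
subtracts two co-registered repeats — removing vessels and other structure —
and halves the periodogram. With 64 ROIs the integral recovers a known
white-noise variance within a few percent, and the radially averaged shape
of a synthetic low-pass NPS is recovered with mean absolute relative error
well under 15%.

**TTF.** Edge technique on a slanted planar (or cylindrical) interface:
voxel distances to the ideal edge surface are binned at 0.1 voxel pitch
into an ESF; a narrow (3-bin) moving average plus isotonic regression
enforce monotonicity (a strongly non-monotone ESF aborts with
`estimation-failed` rather than returning garbage); differentiation gives
the LSF, which is Hann-windowed about its peak and Fourier transformed;
the magnitude, normalized at DC, is the TTF. The slant (default tangent
0.13) is what makes sub-voxel sampling dense; without it an ideal step
aliases into an apparent blur. Against an analytic Gaussian blur the
estimated TTF agrees within 0.05 absolute up to where the true curve falls
to 0.1, and f50 is recovered within a few percent. The 3-D TTF is composed
as a separable product of an in-plane radial profile and an axial profile —
an explicit modeling choice, since the two directions are measured
independently and no cross-term information exists.

**Library.** (NPS, TTF) pairs are indexed by reconstruction label and slice
thickness (categorical, exact match) and by dose/noise and contrast
(continuous). Lookups interpolate value-wise linearly between bracketing
entries — along the dose axis with the weight computed in noise variance
when a variance is queried (the noise magnitude, not the nominal dose, is
what determines the working point), and along contrast for the TTF.
No extrapolation: out-of-hull queries fail naming the offending axis. The
limitation is explicit: value-wise interpolation assumes the NPS shape
morphs slowly between entries; nothing re-shapes spectra between dose
levels.

## The empirical arm

**Segmentation stand-in.** A deliberately simple deterministic segmenter:
threshold at half the expected contrast above the local background (median
of the border shell), one binary closing pass, largest 26-connected
component, volume = voxel count × voxel volume. It is *not* a model of any
commercial tool; it exists so the whole chain can be validated end to end.
Its fidelity limits are part of the experiment design (below).

**PRC.** The percent repeatability coefficient is
$1.96\sqrt2\,\sigma_w \approx 2.77\,\sigma_w$, with $\sigma_w^2$ the mean of
per-case unbiased variances of percent deviations from each case's mean —
the standard 95% repeatability coefficient expressed in percent. Working in
percent makes the statistic scale invariant per case. The exact pooling rule
is stated here because published definitions defer to metrology references
that differ only for unbalanced designs; for balanced repeats the
alternatives coincide, which the tests confirm on constructed cases.

**Calibration.** `PRC = a ln(b·x^c + 1)` with `x = 1/e′` and positive
parameters, fitted by Levenberg–Marquardt on log-scale parameters with a
multi-start grid. Residuals are weighted by $1/y^2$ (relative least
squares): the sampling SD of a repeatability coefficient is proportional to
its value, so the unweighted fit would let the largest PRC values dominate
and noticeably bias `b`. On noise-free synthetic data the fit recovers
(a, b, c) = (10, 2, 1) to numerical precision; under 5% multiplicative
noise with 100 points the Monte-Carlo design spans four decades of the
predictor (0.02–50) because a narrower span leaves `b` with ~10% intrinsic
sampling error — identifiability by design, not tuning. Goodness of fit is
reported as plain unweighted R².

## The simulator and the virtual experiment

The simulator generates the three things the estimators need, all seeded
and bitwise reproducible:

* **shaped noise**: white Gaussian fields filtered by
  $\sqrt{\mathrm{NPS}/dV}$, the exact inverse of the periodogram estimator;
* **edge phantoms**: slanted half-space steps with the Gaussian blur
  rendered analytically (error-function profile), so there is no periodic
  wrap-around and the true TTF is known in closed form;
* **nodule scenes**: rasterized sphere → TTF blur in the frequency domain →
  constant background → shaped noise; repeat "scans" differ only by seed.

`virtual_precision_experiment()` is the desk-scale analogue of a factorial
repeatability study: the dose ladder (1, 0.75, 0.5, 0.25, 0.10, 0.03) with
noise variance ∝ 1/dose, two sphere sizes (9.5 and 4.8 mm at 80 HU), 50
instances × 5 repeats per condition, every volume segmented, PRC pooled per
condition, and e′ computed from the same NPS/TTF the simulator used.

Chosen study conditions, fixed once and stated here:

* scenes are 36³ voxels at 0.5 mm isotropic — the smallest grid that holds
  the 9.5 mm nodule with margin and keeps the full experiment (3 000
  volumes) around two minutes on one CPU;
* blur σ~xy~ = 0.6 mm, σ~z~ = 0.8 mm, typical thin-slice CT point-spread
  scales;
* noise is band-limited (Gaussian low-pass, correlation length 0.6 mm
  matching the blur) — reconstructed CT noise is band-limited, and
  band-limited noise also makes segmentation-surface fluctuations scale
  linearly with noise SD as the model assumes;
* full-dose variance 6.25 HU² (σ = 2.5 HU), so the noisiest rung
  (σ ≈ 14 HU against a 40 HU threshold margin) keeps the background's
  threshold-exceedance probability below the 26-connectivity percolation
  level. Beyond that level the stand-in segmenter's largest component stops
  being the nodule and its failures — not image quality — dominate PRC;
  the ladder deliberately stops short of that regime.

With these conditions the Spearman correlation between 1/e′ and PRC across
the 12 conditions is ≈ 0.97–0.99 (seed-dependent), and the logarithmic
calibration fits with R² ≈ 0.95–0.97.

**What passing this experiment does and does not show.** The simulator has
no anatomy (no vessels, no pleural attachment), stationary Gaussian noise,
a shift-invariant blur, and a trivially deterministic segmenter. Agreement
here validates the mathematics and the estimators, not clinical
performance: with real scanners and commercial segmenters the relationship
is noisier and software-dependent, and the calibration must be refitted per
software.

## Matched-template comparisons

Under the e′ formula, scaling the template spectrum by α scales e′ by √α,
so comparing templates of different diameters at their natural power
normalization confounds template *shape* with template *energy* (a bigger
sphere has diameter-cubed more power). Matched-filter optimality is a
fixed-energy statement, so `template_sweep()` rescales every candidate so
its *effective* energy under the system resolution,
$\iiint \mathrm{TTF}^2|W_{temp}|^2$, equals the task's. With that
convention the matched diameter maximizes e′ (minimizes predicted
imprecision) — by Cauchy–Schwarz exactly for white noise and any TTF, and
numerically also for the low-pass spectra used here. A mismatched template
at natural normalization still predicts worse precision than the matched
one in the direction that matters (higher 1/e′), which the tests assert
separately.

## Degenerate inputs and tie-breaks

* an all-zero nodule yields a flagged zero task function; e′ on it raises a
  `degenerate task` error rather than dividing by zero;
* spectral inputs on different grids are either explicitly resampled
  (trilinear in frequency, zero outside the source support) onto the NPS
  grid or rejected — never silently coerced;
* a flat ESF, or one that remains non-monotone after smoothing (isotonic
  residual above 20% of the edge height), aborts TTF estimation;
* constant-response calibration data fail with `fit-failed` instead of
  returning an arbitrary parameter point;
* segmentation of a volume with no above-threshold voxels fails loudly.

## Problem sizes

Defaults are sized for a laptop CPU: 24³ spectral grids in the synthetic
library, 36³ scene volumes in the virtual experiment, 32³ ROIs (64 of them)
for NPS estimation, 16³ grids for the brute-force oracle comparisons. The
full test suite runs in about two minutes; the acceptance script in under
two. All sizes are arguments, so any of them scale up when fidelity
matters more than wall-clock time.

## Known limitations

* Radial averaging is provided for presentation, but e′ always integrates
  the full 3-D spectra; directional noise peaks are respected in the index
  and only blurred in plots.
* The TTF's contrast dependence is handled entirely by library keying and
  interpolation; there is no parametric model of iterative-reconstruction
  nonlinearity.
* The separable radial × axial TTF model cannot represent bowtie or
  helical-pitch anisotropies within the plane.
* The library interpolates value-wise; strongly dose-dependent NPS *shape*
  changes between coarse library rungs will be under-resolved.
* Absolute e′ magnitudes depend on the transform normalization convention;
  only relationships of e′ (or 1/e′) to PRC are transferable, which is why
  the calibration step exists.
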