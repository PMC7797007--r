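---
title: "The estimability index for coronary stenosis quantification: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The estimability index: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ctaEprime)
```

# The estimation task

Coronary stenosis is reported as fractional diameter narrowing: a
lesion of severity $s \in [0, 1]$ in a segment of reference lumen
diameter $d$ leaves a stenosed lumen of diameter $(1 - s)\,d$. The
question this package answers is *how precisely $s$ can in principle be
estimated* from a cardiac CTA image of that lesion, given the patient
(vessel size, motion, plaque composition, luminal enhancement) and the
scanner (blur, noise, temporal resolution, pixel size).

The answer is organized as a task-based measure: simulate the full
stochastic imaging chain many times, run an ideal estimator on each
realization, and summarize the spread of its estimates. The
**estimability index** is

$$ e' = \frac{1}{\mathrm{SD}(\hat s)} $$

with $\mathrm{SD}$ the sample standard deviation (denominator $n-1$) of
the ensemble of fractional-stenosis estimates. $e' = 25.58$ therefore
corresponds to a precision of $100/25.58 = 3.91$ percent stenosis and a
$\pm 2\,\mathrm{SD}$ (95%) interval of width $400/25.58 = 15.6$
percent. Practically e′ lives between about 3 and 120.

# The phantom

The disease-free artery is a uniform cylinder: contrast-enhanced lumen,
0.5 mm of concentric wall (default 50 HU), uniform background (default
−90 HU, an epicardial-fat surrogate; both configurable). A concentric
plaque annulus narrows the lumen; its attenuation defaults by material
class to −40 HU (noncalcified), 150 HU (mixed) and 500 HU (calcified)
at 120 kV. The cross-section is rendered on a *hyper-resolution* grid —
at least 10× finer than the reconstructed pixel — to model the
continuous-to-discrete imaging operation, with 4× sub-pixel
area-weighted anti-aliasing at material boundaries to suppress
discretization artifacts. `renderCrossSection()` exposes this;
rendered region areas agree with the analytic circle/annulus areas to
well within $2/\mathrm{hyperFactor}$ relative error (tested).

Two lookup tables, shipped as editable CSVs under `inst/extdata/`, map
patient attributes to task parameters assuming a right-dominant
arterial tree: reference diameter by sex and AHA-style segment
(spanning 1.5–5.0 mm), and vessel speed as an affine function of
resting heart rate per sex/segment, clamped to the physiologic
15–35 mm/s range. The published literature this kind of table derives
from does not fix unique values, so the shipped numbers are documented,
plausible defaults — users with better segment data should edit the
CSVs.

Volume averaging: as the stenosed lumen approaches the size of a
reconstructed pixel, its rendered attenuation is pulled from the aortic
enhancement toward the plaque value by the area fraction of the lumen
within one clinical pixel footprint (`adjustedLumenHu()`). This is a
documented stand-in for the (unpublished) adjustment rule of the
original measurement protocol; it is exact in both limits and monotone
in between.

# The imaging chain

All deterministic operators are linear and shift-invariant, applied in
the frequency domain on a replicate-padded canvas whose margin exceeds
the blur support (padding is trimmed afterwards, tested against direct
convolution).

**System blur.** A task transfer function (TTF) — a task-specific MTF —
describes the scanner/kernel/material condition. Since measured curves
from clinical scanners are proprietary per-site data, the package ships
two parametric radially symmetric families pinned to the 50% frequency
$f_{50}$: a Gaussian (default) and a heavier-tailed logistic form
$1/(1+(f/f_{50})^4)$, plus a reader for user-tabulated two-column CSV
curves. One TTF per case is selected by the plaque material (defaults
0.38/0.42/0.46 mm⁻¹ for noncalcified/mixed/calcified), standing in for
"the measured TTF matching the primary contrast edge".

**Motion.** During a half-scan acquisition the vessel moves with
constant velocity (magnitude from the heart-rate model, direction
uniformly random per acquisition, as is the source start angle). Only
displacement along the detector channel direction
$s(\theta) = [\sin\theta, -\cos\theta]$ produces projection
inconsistencies, so the image-domain motion PSF deposits, for every
projection angle $\theta_i$ at acquisition time $t_i$, the weight of
that angle at the point $(v\,t_i \cdot s(\theta_i))\,s(\theta_i)$
(sub-pixel bilinear splatting). Dual-source and multisegment
acquisitions partition the span into contiguous angular subsets, each
acquired over the shorter effective temporal window
$$ T_\text{eff} = \frac{\text{rotation time} \times \text{span}/2\pi}
   {n_\text{sources} \times n_\text{segments}}, $$
which is also what `effectiveTemporalResolution()` reports (165 ms for
a 0.33 s single-source half-scan; 82.5 ms dual-source). Idealizations,
stated: parallel-beam span of exactly π (fan-angle extension via
`reconSpan`), perfect phase consistency across multisegment heartbeats,
uniform reconstruction weights by default (a cosine-tapered
"smooth-transition" option exists), no craniocaudal motion, no
time-varying velocity within the window.

**Noise.** Correlated noise is white Gaussian noise filtered by the
square root of a radial NPS — either flat (white) or the band-pass
ramp family $(f/f_p)\exp(1-f/f_p)$ typical of filtered backprojection,
parameterized by its peak $f_p$ (default 0.25 mm⁻¹) — then rescaled so
the *sample* SD equals the case σ exactly. Exact-σ matching (rather
than matching in expectation) honors per-case noise-magnitude matching
and removes a nuisance source of run-to-run variability; its side
effect (a per-field scale factor of order $1 \pm 1/\sqrt{2N}$) is
negligible at the field sizes used.

Noise is added after downsampling, at clinical resolution, following
the chain order: system blur → motion blur → downsample → noise.

# The estimator and e′

The observer is an ideal maximum-likelihood estimator without
prewhitening: each noisy instance is compared against a bank of
noise-free templates (stenosis 0.15–0.85 in steps of 0.01, 71
templates, full-ROI pixel-wise squared difference, no mask) and the
stenosis of the global minimizer is the estimate; residual ties within
1e−9 relative average the tied stenosis values, reflecting the small
null space of the blurred task.

Templates are **motion-free by default**: the motion direction is
stochastic and unknown to the observer, so its asymmetric blur cannot
be prewhitened into the templates. Two alternatives are provided and
tested — a direction-averaged nominal motion blur at the case velocity
(`motionMode = "nominal"`), and a full velocity × stenosis bank
(`"axis"`), where the estimate remains the stenosis coordinate of the
global argmin. With motion-free templates the motion mismatch
contributes both variance and bias to the estimate ensemble; that is a
property of the task, not a defect of the estimator, and e′ uses only
the SD.

Degeneracy rules: a case with local plaque CNR ≤ 1 (volume-averaged
lumen-to-plaque contrast over σ) or vessel speed ≥ 40 mm/s is
nondiagnostic and reports e′ = 0 with a flag. The package adds one
further rule of the same character: when at least half of the ensemble
estimates are clipped at the template-grid edge, the ensemble is
*saturated* — the truncated SD no longer measures estimation ability
(it can even approach zero, which would absurdly report a near-infinite
e′ for a hopeless case) — and e′ = 0 is reported with the `saturated`
flag. A zero-variance ensemble with no clipping (exact noise-free
recovery) instead reports an `Inf` sentinel flagged `zero_variance`,
not used downstream. Estimate clipping at the grid edge always raises
a warning counter.

An analytic cross-check, `closedFormEprimeWhiteNoise()`, gives the
local-linearization matched-filter value
$e' = \lVert \partial T/\partial s \rVert / \sigma$ from the
finite-difference template gradient; the Monte-Carlo estimator agrees
with it within 5% at $n = 2300$ in the white-noise, motion-free
regime (tested). The 0.01 stenosis grid step contributes quantization
variance of only $0.01^2/12$, well under that tolerance at the σ used.

# Numerical implementation

The per-instance hot loop exploits linearity: a clinical pixel of a
motion-blurred, downsampled instance equals the weighted sum, over the
motion PSF's splat points, of the box-filtered system-blurred phantom
sampled bilinearly at the shifted block start — algebraically identical
to splat-convolve-average (tested to machine precision against the
direct path) but free of per-instance FFTs. This, plus one batched FFT
chain per template bank, runs in compiled code (RcppArmadillo). RNG
discipline: every stochastic quantity of instance $i$ (direction, start
angle, noise field) is drawn from a seed derived deterministically from
the root seed and $i$, so ensembles are reproducible and independent of
evaluation order.

Grids: the field of view is the vessel outer diameter plus a 1.5 mm
margin per side, at least 16 clinical pixels, hyper factor 10.
Convolution margins always cover the effective blur support (kernels
trimmed at 1−1e−7 absolute mass).

# Cohort validation harness

Since the clinical images behind the two-cohort benchmark are not
distributable, the package ships a synthetic cohort generator that
emulates the published class-conditional profiles: heart rate 64±9 /
69±11 bpm, contrast 578±154 / 230±192 HU, noise 32±11 / 41±16 HU and
stenosis severity 33.6±16 / 38.3±10.5 % for the high / low class,
drawn as truncated normals (HR ≥ 30 bpm, contrast ≥ 0 HU, σ ≥ 1 HU,
stenosis within the 15–85% bank range — the low-class contrast spread
would otherwise go negative); plaque class frequencies per cohort
(lesions with no reported plaque mapped to noncalcified — the mapping
reproduces the published class-conditional CNR of about 20 vs 7);
scanner geometry drawn from an editable catalogue of rotation times,
dual-source and multisegment capability patterned on the trial's
scanner mix (the per-model values are editorial choices, not published
data). Quality labels are assigned by construction — the generating
class — standing in for the reader-score-plus-concordance surrogate,
which requires human reads.

What passing the cohort test shows, and what it does not: e′ separates
the two synthetic classes (AUC well above 0.5 with a stable
bootstrapped threshold) because the class profiles differ in contrast
and noise exactly as published; it does not certify performance on real
clinical-trial images, whose reader-based labels, spectral artifacts
and protocol diversity the generator does not emulate.

ROC conventions: AUC is the pairwise concordance statistic with ties
counting ½ (exactly equal to brute-force pair counting, tested);
candidate thresholds are midpoints between consecutive observed scores,
the optimal threshold minimizes the distance to the ideal corner (0,1)
with ties broken toward higher sensitivity; bootstrap resamples within
class, preserving size and class ratio; cross-validation is stratified
with the threshold fit on training folds only. Midpoint thresholds make
the trained threshold generalize on separable data, which the
leave-out evaluation requires.

# Protocol optimization

`factorialGrid()` builds full factorial designs over the protocol
factor space (diameter 1.5–5 mm, stenosis 30–70%, velocity 15–35 mm/s,
material, contrast 300–600 HU, pixel 0.35–0.55 mm, σ 15–45 HU,
rotation 0.25–0.35 s, dual source off/on, f50 0.32–0.52 mm⁻¹), three
levels per continuous factor by default — a finer-granularity full
sweep grows combinatorially, and the default design already identifies
the response-surface structure. `runSweep()` computes e′
per row (500 instances by default for sweeps versus 2300 for
single-case runs — a documented fidelity/runtime trade) with per-row
derived seeds and checkpointing; degenerate rows are flagged, never
dropped. The response variable for fitting is the *precision*
(fractional stenosis SD = 1/e′), matching the units in which such
models are reported.

`fitResponseModel()` fits intercept + linear + squared (continuous) +
all pairwise interactions by least squares, prunes terms whose
coefficients all have p ≥ 0.01, and refits; the retained term count is
reported, not asserted. Pruning is skipped for (near-)exact fits where
p-values are undefined. Exact recovery of known quadratic responses
(R² = 1 noise-free, > 0.95 under 5% multiplicative noise) and exact
agreement of `partialDependence()` with brute-force group means are
tested. `predictSlice()` returns the fitted slice with 95% confidence
bands from the coefficient covariance and warns on extrapolation.

# Study conditions used by the shipped tests

Trend (monotonicity) tests use a well-conditioned dual-source base case
— 50% stenosis, mixed plaque, 3.0 mm vessel, 450 HU contrast, σ 30 HU,
20 mm/s, 0.28 s dual-source rotation — because factor trends are only
defined in the diagnostic regime: at extreme factor values the
degeneracy rules correctly zero e′ and other factors' influence
disappears. Ensemble sizes follow the framework's own conventions:
2300 instances for single-case results and the closed-form comparison,
500 for sweep rows, 300 per case for the 88/44 cohort run.

# Known limitations

In-plane 2D model only (slice thickness/interval are carried as
metadata); no spectral physics (beam hardening, calcium blooming), so
heavily calcified cases are optimistic; parametric TTF/NPS families
rather than measured curves; concentric plaque by default (a
crescent-shaped plaque is available through the `eccentricity`
parameter of `vesselSpec()`, but the case engine's morphology is
concentric);
segment diameter/velocity tables are editable defaults, not population
data; the ideal estimator bounds achievable precision and does not model
human readers.
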