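# ctaEprime

Task-based image-quality assessment for coronary stenosis quantification
in cardiac CT angiography (CTA).

Percent diameter stenosis is the workhorse measurement of coronary CTA,
and its precision is limited jointly by image noise, system blur, plaque
composition, and — uniquely in cardiac imaging — stochastic motion
artifacts from half-scan acquisition of a moving vessel. `ctaEprime`
implements a computational framework that turns all of these factors
into a single scalar figure of merit, the **estimability index e′**:

1. A stenosed coronary cross-section is rendered as a hyper-resolution
   ground-truth phantom: a contrast-enhanced lumen narrowed to
   `(1 − s) · d_ref` by a concentric plaque (noncalcified −40 HU, mixed
   150 HU, calcified 500 HU at 120 kV) inside 0.5 mm of vessel wall.
2. The imaging chain is applied: the deterministic system blur as a
   task transfer function (TTF, a task-specific MTF parameterized by its
   50% frequency f50), one stochastic asymmetric motion PSF per
   acquisition — built by projecting the vessel motion vector onto the
   detector channel direction `s(θ) = [sin θ, −cos θ]` over the
   reconstruction span, with dual-source and multisegment geometries
   shortening the effective temporal window — downsampling to the
   clinical grid, and correlated noise synthesized from a noise power
   spectrum (NPS) with exactly matched magnitude σ.
3. An ideal maximum-likelihood estimator (pixel-wise squared-difference
   template matching against a bank of noise-free templates over
   stenosis 15–85%) is run on an ensemble of stochastic instances
   (2300 by default). The ensemble standard deviation SD(ŝ) of the
   fractional stenosis estimates gives

   **e′ = 1 / SD(ŝ)**

   so e′ = 25.58 corresponds to a stenosis precision of 3.91% and a
   ±2 SD (95%) interval 15.6% wide. Nondiagnostic conditions (local
   plaque CNR ≤ 1, vessel speed ≥ 40 mm/s, or an estimate ensemble
   pinned at the template-grid edge) are flagged and report e′ = 0.

On top of the single-case engine the package provides a cohort-level
validation harness (synthetic two-class cohort generator, concordance
AUC, optimal-threshold selection, within-class bootstrap, stratified
cross-validation) and a protocol-optimization workflow (full factorial
e′ sweeps, quadratic response-surface fit, partial dependence, slice
predictions with confidence bands).

## Worked example

```r
library(ctaEprime)

case <- readCaseJson(system.file("extdata", "example_case.json",
                                 package = "ctaEprime"))
case
#> CaseSpec 'example': F, HR 64 bpm, LAD_prox, stenosis 50%, mixed plaque,
#>   contrast 450 HU, sigma 30 HU

computeEprime(case, nInstances = 2300, seed = 7)
#> EstimabilityResult: e' = 36.20 (precision 2.76%), n = 2300
```

A 50%-stenosed, mixed-plaque proximal LAD lesion (3.0 mm reference
lumen, 450 HU enhancement, σ = 30 HU) moving at 20 mm/s, imaged on a
dual-source scanner at 0.28 s rotation (70 ms effective temporal
resolution), is estimable to a standard deviation of 2.76% diameter
stenosis — an e′ of 36.2, above the 25.58 operating point that
separates high- from low-quality exams, as expected for a
well-conditioned dual-source acquisition.

The same computation is scriptable from a shell:

```sh
Rscript inst/scripts/eprime.R compute \
    --case inst/extdata/example_case.json --n 2300 --seed 7 --out result.json
```

with subcommands `phantom`, `mpsf`, `compute`, `cohort`, `roc`, `sweep`
and `fit` covering the rest of the workflow; every output is
accompanied by a run-manifest JSON recording the options, seed and
package version.

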