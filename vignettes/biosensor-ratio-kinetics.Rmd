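---
title: "Quantifying biosensor recruitment to organelle membranes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biosensor recruitment to organelle membranes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctaratio)
```

## The measurement problem

Live-cell experiments on low-abundance signalling lipids such as
PI(3,5)P₂ read out lipid levels indirectly: a fluorescently tagged
lipid-binding domain (a *biosensor*, e.g. SnxA or an EEA1-FYVE domain)
relocates between the cytosol and the membranes that carry the lipid.
When an inhibitor such as apilimod blocks the synthesising kinase, the
biosensor falls off the membranes; when a kinase is acutely recruited to
a compartment by chemically induced FKBP/FRB dimerisation, the biosensor
follows it there. The quantity of interest is therefore *how enriched the
biosensor is on a defined membrane compartment, relative to the whole
cell, as a function of time around a treatment*.

`punctaratio` implements that measurement as a four-stage pipeline:

1. **Mask** the compartment from a membrane-marker channel (LAMP1, Rab5,
   dextran, a mitochondrial anchor) with a multiscale wavelet-product
   segmentation.
2. **Ratio**: per frame, mean background-subtracted biosensor intensity
   inside the mask ∩ cell ROI divided by the mean over the whole-cell
   ROI.
3. **Aggregate** per-cell traces to a grand mean ± SEM across
   independent experiments.
4. **Fit** a constrained one-phase exponential to the post-treatment
   trace and report τ with a 95% confidence interval, R² and degrees of
   freedom.

Because the movies such experiments produce are rarely deposited, the
package also ships a seeded synthetic-movie generator with full ground
truth, and every stage is validated against it.

## The segmentation recipe

The marker frame is blurred with isotropic Gaussians at 1×, 2×, 3× and
4× the Airy-disc size of the fluorophore, where the Airy radius is
$1.22\lambda/(2\,\mathrm{NA})$ converted to pixels. Each blurred image is
subtracted from the next-smaller-scale one, giving three band-pass
planes that respond to spot-like structures; the planes are multiplied
pixel-wise and the product is thresholded at 3× the standard deviation
of the *original* frame, then dilated once (optionally twice) with a
3×3 element.

Choices the recipe's verbal description leaves open, and how this
package resolves them:

* **"Size of the Airy disc."** Read as the Airy *radius used directly as
  the Gaussian σ*. The alternatives (diameter-as-σ, radius-as-FWHM) are
  config switches on `wavelet_params()` / `airy_sigma_px()`; the default
  is the middle of the three in effective scale.
* **Subtraction direction.** Smaller scale minus next larger scale, so
  planes are positive at puncta.
* **Negative plane values** are clamped to zero before multiplying.
  With three planes, an odd number of negative factors would otherwise
  create spurious positive product pixels at structureless locations.
* **The SD defining the threshold** is computed on the whole original
  frame, per frame independently. An ROI-restricted SD is available
  (`sd_on_roi`), since it is not knowable whether the original FIJI
  workflow measured SD inside the drawn ROI only.
* **Border handling** is reflect padding. Zero padding would darken the
  borders of every blurred image, inflate the band-pass planes near the
  edge and depress nothing (the threshold comes from the unpadded
  frame); reflect padding avoids manufacturing edge responses.
* **Scale invariance.** The product of $k-1$ planes scales as $c^{k-1}$
  under $I \mapsto cI$ while the threshold scales as $c$, so the mask is
  only scale-invariant when two multipliers (one plane) are used. This
  is a property of the published recipe itself, not of this
  implementation; the tests pin the documented scaling behaviour rather
  than pretending invariance.
* **Degenerate frames.** A zero-variance frame yields threshold 0; the
  strict `>` inequality keeps zero-product pixels out and the result is
  flagged `degenerate`.

The Gaussian blur and the binary dilation are implemented in-package as
separable convolution and shift-OR dilation, because the whole chain is
verified pixel-for-pixel against a direct per-pixel convolution oracle
in the test suite, and that comparison needs full control of kernel
truncation (4σ) and boundary policy.

## The ratio metric

"Intensity" is the **mean** pixel value over a region, not the sum — a
sum would scale trivially with mask area, and baseline ratios near 1–3
are only meaningful for means. (`statistic = "integrated"` provides the
sum for completeness.) Background is estimated per frame as 1.5× the
mode of an integer-binned intensity histogram — for a
background-dominated frame the modal bin sits at the camera
offset — and subtracted from the biosensor channel with clamping at
zero before both numerator and denominator. Modal ties are broken
toward the lowest bin and flagged. The numerator region is
`mask ∩ cell ROI`, so a neighbouring cell's vesicles cannot leak into a
trace. An empty intersection yields a *missing* frame (`NA`), never a
zero, and missing values are not interpolated; the fit simply ignores
them.

Cell ROIs are user-supplied (mask TIFF or a 0-based y,x polygon file),
matching the manual-ROI convention of the original workflow; for
synthetic data an automatic fallback thresholds the movie-averaged
biosensor channel at 1.05× its modal level and keeps the largest
connected component. A `qc_exclude()` flag mirrors the manual exclusion
of moving or dying cells; the judgement itself is deliberately not
automated.

Z-stacks are reduced before any measurement by averaging the central
slices (11 by default, the convention for 0.175 µm step stacks spanning
10 µm); with an even slice count the window ties toward the lower
index.

## Aggregation

Cells are averaged within an experiment first; the grand mean is the
mean of per-experiment means and the SEM is the SD of those means over
√(number of experiments). This two-level convention weights experiments,
not cells, equally. With one experiment the SEM is reported as 0 and the
result flagged — a single experiment has no between-experiment
variance to estimate. A flat hierarchy (one cell per experiment)
reduces exactly to the ordinary mean ± SEM.

## Kinetics

The model is $y = \mathrm{plateau} + (y_0 - \mathrm{plateau})
e^{-K (t - t_0)}$ for $t \ge t_0$, fitted by bounded
Levenberg–Marquardt with $K > 0$ enforced as a box constraint rather
than by reparameterising (e.g. fitting $\log K$), so the parameter
covariance stays on the natural scale. Decay and association are the
same curve approached from opposite sides. The fit window starts at the
treatment time; pre-treatment points can optionally enter as a flat
$y_0$ segment (`include_baseline = TRUE`). Starting values are
$y_0$ = first value in the window, plateau = window extremum, and
$K = \ln 2 / (\text{half the window span})$; convergence tolerances are
$10^{-10}$ on the cost with a 10⁴ evaluation cap.

τ = 1/K is reported with a 95% CI from the asymptotic variance of K and
the delta method ($\mathrm{var}(\tau) = \mathrm{var}(K)/K^4$) with a
Student-t critical value at $df = n - 3$, matching common
curve-fitting-software behaviour; a profile-likelihood interval is
available (`ci = "profile"`), exploiting that the model is linear in
(plateau, amplitude) for fixed K. R² is computed about the mean of the
fit window. Constant or near-constant traces drive K to the constraint
boundary or blow up the covariance; such fits are flagged
`identifiable = FALSE` with an unbounded τ interval instead of
reporting a fictitious precision.

Aggregate-level fitting (fit the grand-mean trace, as `cmd_run` does)
and per-cell fitting are both possible; a published DF of ~30 for such
fits is consistent with fitting one mean trace of ~32 time points with
3 parameters, but which convention produced any given published CI is
an inference, not a statement, so both modes are exposed.

## The synthetic scenes

`synthetic_scene()` emulates the experiment designs this pipeline
targets: a superellipse cell footprint with cytosolic signal,
20–60 static vesicles rendered as isotropic Gaussian spots
(σ = radius/2 — spot-like, as diffraction-limited endosomes appear),
a marker channel with constant vesicle intensity, and biosensor
channels whose vesicular amplitude follows a constant, one-phase-decay
or one-phase-association enrichment curve around the treatment time.
The PSF is a Gaussian of σ = 0.21λ/NA (the standard Gaussian
approximation of a confocal Airy pattern), and noise is Poisson on
expected counts followed by a camera offset and additive Gaussian read
noise — the standard confocal noise model. Both PSF and noise can be
switched off; with identical seed and parameters rendering is
bit-identical.

The biosensor spot amplitude is *calibrated per frame against the
PSF-blurred scene components* so that, measured with the true vesicle
mask and the footprint as ROI, the noise-free mask-to-cell ratio equals
the analytic enrichment curve exactly. This makes the generator a
closed-loop oracle for the ratio stage. A consequence is that the
baseline ratio must exceed the cytosol-only floor (≈1.005, from PSF
rolloff at the footprint edge); preset baselines use 1.1–2.0.

Defaults follow the imaging conditions the pipeline is meant for:
256×256 px at 70 nm/px, NA 1.45, frames every 30 s, 2 min of baseline
before treatment, decay τ = 9.5 min from baseline ratio 2.0 to plateau
1.1 (inhibitor-style), association τ = 2 min to plateau 2.0
(dimerisation-style recruitment), constant 1.5 for the kinase-dead
control. Detector gain and offset are not published quantities for such
experiments; the defaults (offset 100, read SD 2 counts, marker
cytosol 25, biosensor cytosol 150, vesicle peak ~1200 counts) give a
plausible confocal SNR and are all config-exposed. Vesicle radii are
5–8 px (0.7–1.1 µm diameters, typical of the late
endosomes/lysosomes these markers label): the wavelet recipe's 1×/2×
Airy-scale planes bound the detectable blob at a ~8–9 px radius, so
genuinely sub-resolution spots would be segmented as blobs several-fold
larger than their true extent and a mask-overlap score against true
disks would be dominated by that scale mismatch rather than by
segmentation quality.

What the generator deliberately does **not** emulate: cell movement and
death (excluded manually in real analyses; `qc_exclude()` represents
the decision), vesicle motion and fusion, vacuolation morphology, DIC
channels, uneven illumination, and bleaching. Passing tests on
synthetic movies therefore validate the *computational chain* — mask
geometry, ratio arithmetic, aggregation and fitting — not robustness to
every artefact of real microscopy.

## Problem sizes and numerical checks

The test suite and the acceptance script run entirely on generated
data, at sizes chosen to exercise every code path while staying quick:
oracle equivalence on fifty ≤16×16 frames against a per-pixel
convolution reference; segmentation accuracy on a 64-frame 256×256
decay movie (mask-vs-truth Jaccard ≥ 0.5 at every frame at default SNR,
and zero false-positive area on a no-cell noise movie); ratio
correctness to machine precision on noise-free renders; τ recovery to
10⁻⁶ relative on noise-free traces; and 200-simulation recovery and CI
coverage runs at 5% noise. For the 30-point, 30 s-spacing,
τ = 9.5 min simulation design the fit window spans only ~1.5τ, and the
asymptotic information bound puts SE(τ̂)/τ at ~21% — the package's
estimator sits at that bound (median error ~9–15% depending on seed,
with ~91–96% CI coverage), which is the correct behaviour: a tighter
recovery under that design is not statistically possible, only a longer
window or lower noise improves it. The end-to-end fixture pipeline
(simulate, segment, quantify, aggregate, fit, twice for a determinism
check) completes in a few minutes on one CPU.

## Known limitations

* The wavelet product compares an intensity-cubed image against an
  intensity-scaled threshold; masks are therefore not invariant under
  global intensity rescaling (inherited from the published recipe, and
  documented rather than corrected).
* Per-vesicle instance segmentation, tracking and watershed splitting
  are out of scope: the ratio needs only a global binary mask.
* The modal background estimator assumes integer-like count data; on
  float-normalised input choose `bin_width` accordingly.
* One-phase kinetics only; no two-phase or stretched-exponential
  models, and no mixed-effects pooling across cells.
* TIFF I/O uses multi-page TIFF plus a JSON sidecar for axes and
  calibration rather than embedded OME-XML.
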