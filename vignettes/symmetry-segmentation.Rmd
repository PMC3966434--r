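---
title: "Symmetry-difference segmentation of brain lesions: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetry-difference segmentation of brain lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symseg)
```

## The model

A healthy axial brain slice is approximately zygomorphic: mirror-symmetric
about the inter-hemispheric midline. Both pipelines in this package start
from that observation. With `O` the slice and `R = reflect(O)` its
left–right mirror about the vertical image midline, the difference image
`D = O − R` vanishes over symmetric anatomy and carries a positive residual
wherever tissue is brighter than the tissue at its mirror position.

Three consequences shape the design:

1. `D` is mirror-antisymmetric: every bright lesion produces a positive
   residual at its own site and an equal negative one at the mirror site.
   All downstream stages therefore consume the **rectified** field
   `max(D, 0)`, which keeps each lesion's evidence at its true location.
   This is what lets the pipelines find a lesion in either hemisphere, or
   one in each, without being told which side to look at.
2. The decomposition is unsigned in anatomy but signed in intensity: only
   hyperintense asymmetries are detected. That matches the target use
   (lesions bright on the acquired contrast).
3. A lesion centered on the symmetry axis is its own mirror image and
   cancels in `D`. This failure mode is structural; `region_report()`
   detects the situation (a missed ground-truth component whose bounding
   box straddles the axis) and raises `midline_warning`.

**HASA** turns the rectified difference directly into a segmentation: the
field is thresholded at a fraction of its own maximum, 8-connected
components below a minimum area are dropped, and the surviving components
seed a Chan–Vese level set that evolves *on the rectified difference*.

**EHASA** instead thresholds the rectified difference at a fraction of the
*original slice's* maximum intensity, `T = 0.25 · max(O)`, multiplies the
binary mask back onto the original, and evolves the contour *on the masked
original*. Two distinct suppression mechanisms follow: residuals dimmer
than a quarter of the slice maximum never enter the mask at all, and
residuals that do pass are re-judged by the contour against **original**
intensities, where a non-tumor artifact is usually much dimmer than the
lesion. HASA's threshold, being relative to the residual field's own
maximum, adapts downward on clean slices and keeps such artifacts.

The asymmetry between the two final stages (difference image vs masked
original) is deliberate and is preserved here as the defining difference
between the two pipelines.

## The active contour

The final stage is a from-scratch two-phase piecewise-constant Chan–Vese
model. The energy is

$$E(\varphi) = \mu\,\mathrm{length}(\{\varphi = 0\})
 + \lambda_1 \!\!\int_{\varphi>0}\!\! (I - c_1)^2
 + \lambda_2 \!\!\int_{\varphi<0}\!\! (I - c_2)^2,$$

minimized by gradient descent on the level set $\varphi$ with the smoothed
Heaviside $H_\varepsilon(t) = \tfrac12\big(1 + \tfrac2\pi
\arctan(t/\varepsilon)\big)$ and its Dirac $\delta_\varepsilon$. The
descent update is

$$\varphi \leftarrow \varphi + \Delta t\,\delta_\varepsilon(\varphi)\,
\big(\mu\,\kappa - \lambda_1 (I - c_1)^2 + \lambda_2 (I - c_2)^2\big),$$

with $\kappa = \nabla\!\cdot\!(\nabla\varphi/|\nabla\varphi|)$ discretized
by central differences under replicate (Neumann) boundary conditions with a
$10^{-8}$ regularizer in the gradient-norm denominator.

Numerical choices worth knowing about:

* **Region means.** Inside the descent loop, $c_1, c_2$ are the plain
  means of the image over $\{\varphi > 0\}$ and $\{\varphi \le 0\}$ — the
  sharp ($\varepsilon \to 0$) limit, which is what reference
  implementations of this model iterate. The smoothed
  $H_\varepsilon$-weighted form is exported as `region_means()` and used by
  the energy diagnostic. The sharp form matters twice: with a
  checkerboard start the phases sample the image identically, and the
  smoothed means then sit at an unstable $c_1 = c_2$ equilibrium that can
  stall the evolution for hundreds of iterations; and with a
  signed-distance start of large amplitude, the arctan tails of
  $H_\varepsilon$ let tens of thousands of far-away background pixels
  dilute the inside mean even though none of them is meaningfully
  "inside".
* **Convergence.** Iteration stops when the mean absolute level-set
  update *over the active band* $\{|\varphi| < 2\varepsilon\}$ falls below
  `tol`, or when the band empties (the contour has vanished), or at
  `max_iter`. Averaging over the full frame instead would make the
  criterion depend on how much inert far-field the image happens to carry:
  on a 128×128 slice a localized contour's updates average below any
  useful tolerance from the very first iteration.
* **Degenerate phases.** If a phase empties, its mean falls back to the
  global image mean, so the force field stays finite and the phase can
  re-nucleate.
* **Initialization.** With seeds, $\varphi_0$ is the pointwise maximum of
  per-disk signed distances $r_i - \lVert x - x_i\rVert$ — the exact
  signed distance for disjoint disks. Without seeds (the unaided baseline)
  a $\sin(\pi r/10)\sin(\pi c/10)$ checkerboard puts both phases
  everywhere. Because the two phases are then label-symmetric, the
  baseline orients its output to the brighter phase before reporting.
* **No reinitialization by default.** The arctan Heaviside tolerates
  non-signed-distance $\varphi$; optional signed-distance rebuilding every
  `reinit_every` iterations is available but off.
* **Determinism.** There is no randomness anywhere in the solver, and all
  global reductions (region means, convergence norm) use a
  column-reversal-invariant summation, so a mirrored input yields the
  bit-exact mirrored segmentation: `run_hasa(reflect(x))` equals
  `reflect(run_hasa(x))` pixel for pixel, not merely up to float noise.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `mu` | 0.2 | energy per boundary pixel (unit-interval intensities) | contour-length weight; larger values smooth the contour and erode small faint regions |
| `lambda1`, `lambda2` | 1, 1 | — | inside/outside fidelity; rescale by $1/a^2$ to compensate an intensity rescale by $a$ |
| `dt` | 0.5 | iterations⁻¹ | descent step; chosen with `eps` so the disk benchmark descends monotonically |
| `eps` | 1 | pixels (level-set units) | Heaviside/Dirac smoothing width; also sets the active band (2·eps) |
| `tol` | 1e-3 | level-set units | band-mean update below which the contour is declared stationary |
| `max_iter` | 500 | — | iteration cap |

These are the standard published defaults of the model for images in
$[0,1]$; all are exposed through `chanvese_params()` and the pipeline
configuration.

Pipeline-stage parameters: the seed threshold fraction (0.5 of the
rectified maximum), minimum seed/region area (10 px), the no-asymmetry
noise floor (rectified maximum below 0.05 means "symmetric slice, stop"),
the EHASA binarization fraction (0.25), and the morphological disk radius
(2 px, opening by default). The description of the binarization step is
ambiguous about whether the cut is the defined quarter-max threshold or a
mean; the explicitly defined threshold is used, and a mean-of-difference
variant is available behind `ehasa$use_mean_threshold` for fidelity
experiments. Likewise, the step "apply the contour to the location found
by thresholding" leaves the seed definition open; the mask's 8-connected
components are the only locations available and are all used, which is
also what makes multiple simultaneous lesions detectable.

## Input handling

Slices arrive as single-frame grayscale DICOM, PNG, or TIFF. DICOM pixel
data passes through Rescale Slope/Intercept and then, when Window
Center/Width tags are present, the linear VOI window clipped to $[0,1]$;
files without window tags, and PNG/TIFF inputs, are min–max scaled. The
uniform $[0,1]$ normalization is what makes the quarter-max threshold
scale-free across 8-, 12- and 16-bit acquisitions. A constant (zero-range)
slice maps to the all-0.5 image by convention and flows through the
pipelines to a clean zero-region result rather than an error. Grayscale
morphology uses a disk structuring element with the window clipped at the
image border, so constants are fixed points and opening/closing stay
anti-/extensive everywhere including corners.

## The phantom generator

`make_phantom()` renders what the pipelines assume about their input: an
approximately bilaterally symmetric head — dark background (0.05), bright
elliptical brain (0.55), a brighter scalp/skull annulus (0.8) separated
from the brain by a dark CSF gap, mirrored dark ventricles (0.25) — plus
hyperintense elliptical lesions (ground truth), optional non-tumor bright
artifacts, a mild per-pixel multiplicative asymmetry on one hemisphere,
and additive Gaussian noise, clipped to $[0,1]$. Lesion contrast defaults
to +0.4 over local tissue: comfortably above the quarter-max threshold
after normalization, as typical for the enhancing lesions this method
family targets. Noise σ = 0.02 (SNR ≈ 27 against brain tissue) and
hemispheric jitter of 2% model a clean clinical acquisition with mild
natural asymmetry. Ground truth is rendered before jitter and noise, so it
never depends on the noise realization; renders are pure functions of the
spec (seeded, caller's RNG state restored).

The `standard_suite()` fixtures pin the six scenarios the claims rest on:
`symmetric` (null case), `left-lesion`/`right-lesion` (the right fixture
is declared as the left spec plus a mirror flag, so the pair is an *exact*
pixel mirror — the laterality-equivariance probe), `bilateral-two-lesions`
(one per hemisphere at non-mirroring positions), `midline-lesion` (the
documented failure), and `lesion-plus-artifact`. The artifact is a
bright streak outside the head with +0.22 contrast: above HASA's relative
seed threshold (≈0.20 on that fixture) but below EHASA's quarter-max cut
(≈0.235), so HASA reports it as a false region and EHASA never sees it —
the enhancement demonstrated through the paper's own mechanism. The skull
annulus exists chiefly for the unaided baseline, which segments scalp and
brain as separate bright components and thereby over-segments every head
slice; the CSF gap is 4–5 px so that a μ = 0.2 contour cannot bridge it.

What the phantoms do **not** emulate: Rician noise statistics, bias
fields, anatomical texture, partial-volume effects, skull-stripping
artifacts, or head tilt (an optional midline-shift search exists but the
suite keeps heads centered). Passing on phantoms therefore demonstrates
the pipeline logic — symmetry cancellation, residual localization,
threshold behavior, contour convergence, equivariance — not clinical
performance on real MR data.

Problem sizes used throughout the tests and the acceptance script: the
six 128×128 fixtures, a 64×64 analytic disk benchmark for the contour, and
one 512×512 single-lesion case matching a full-resolution acquisition
geometry.

## Evaluation

`dice()` implements $2|A\cap B| / (|A| + |B|)$ with the both-empty case
defined as 1, so a correct no-detection on a symmetric slice scores
perfect. `region_report()` adds per-component geometry, the count of
ground-truth lesions hit, the count of predicted regions overlapping no
truth (false regions), and the midline warning.

## Known limitations

* Midline lesions are undetectable by construction (flagged, not fixed).
* Strong head tilt or lateral decentering degrades the difference image;
  the optional integer-shift pre-registration only compensates small
  lateral offsets, and nothing compensates rotation.
* Only hyperintense lesions are sought; hypointense pathology would
  require rectifying the negative part instead.
* The quarter-max threshold presumes the lesion is among the brightest
  structures after normalization; a low-grade lesion dimmer than a quarter
  of the slice maximum falls back on HASA's relative threshold or is
  missed.
* Processing is strictly 2-D and slice-by-slice.
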