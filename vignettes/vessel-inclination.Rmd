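---
title: "Vessel inclination morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel inclination morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

angiomorph quantifies how retinal vessels are inclined relative to the optic
disc in fundus angiograms, and uses those measurements to separate healthy
from hypertensive subjects. This vignette documents the model, every tunable
that matters, and the design decisions taken where the method left genuine
freedom — so that results can be reproduced bit for bit.

## The measurement model

A fluorescein angiogram shows vessels as bright ridges with an approximately
Gaussian cross-section. The pipeline is:

1. **Median prefilter.** Each pixel is replaced by the median of its 3×3
   neighbourhood (`median3x3()`), removing impulse noise without blurring
   ridge edges. Borders are edge-replicated so image size is preserved and no
   dark rim is introduced that would later bias the response histogram.
2. **Oriented matched-filter sweep.** A bank of oriented masks is correlated
   with the filtered image at 1° steps over 0°–179° (`sweep_orientations()`).
   Each mask (`build_mask()`) is a Gaussian bright-ridge profile across the
   filter direction: at orientation θ the weight at offset (m, n) from the
   centre is
   `g(d) = eps_mi + (eps_ma − eps_mi) · exp(−d² / (2σ²))`,
   where `d = m·cosθ + n·sinθ` is the signed perpendicular distance to the
   oriented centre line. `eps_ma` (default 4) is the on-ridge weight,
   `eps_mi` (default −2) the surround, and σ (pixels) should match the
   expected vessel half-width. The rotation is analytic — no raster
   interpolation — so behaviour is identical at every angle. Per pixel, the
   maximal response `L_ma` and its orientation `L_θ` are kept; argmax ties go
   to the smallest angle for determinism.
3. **Otsu gating.** Responses are rescaled to 256 levels and thresholded at
   the level maximising between-class variance (`otsu_threshold()`); the cut
   is mapped back to response units halfway between the chosen level and the
   next, so it falls strictly between the classes. Pixels with response
   strictly above the threshold form the vessel mask; their `L_θ` values form
   the tangent-angle map `L_w`. A separate boolean mask distinguishes a
   genuine 0° tangent from background.
4. **Radial re-expression.** For each vessel pixel, the orientation of the
   ray from the disc centre is computed and the absolute difference to the
   tangent is folded into [0°, 90°] (`radialize()`): 0° = the vessel radiates
   from the disc, 90° = it runs concentric to it.
5. **Annulus morphometrics.** Within the standard 2r–3r measurement band
   (`annulus_mask()`, bounds inclusive), `compute_metrics()` reports: `z`,
   the number of 8-connected vessel objects; `phi_sr` and `phi_std`, mean and
   population SD of per-object mean angles; the 1°-bin histogram over
   [0°, 90°] and its mode `phi_max`; and `p_s`, the percentage of band pixels
   covered by vessels.
6. **Classification.** Per-subject feature tables (five attributes: `z`,
   `phi_sr`, `phi_std`, `phi_max`, `p_s`) feed a CART tree (`fit_cart()`,
   Gini impurity, midpoint thresholds, growth to purity), pruned by
   cost-complexity with the one-standard-error rule under stratified
   cross-validation (`prune_1se()`), and evaluated by pooling out-of-fold
   predictions into one confusion panel (`evaluate_attribute_trees()`).

## Angle convention

Nothing downstream is meaningful unless one orientation convention is used
everywhere. angiomorph uses: **0° = east (increasing column index), angles
increase counter-clockwise when the image is viewed with row 1 on top (y axis
up), line orientations taken modulo 180°.** The phantom generator, the filter
bank, and the radial fold all share this convention; the rotation-equivariance
tests (90° image rotations shift recovered angles by exactly 90°) pin it down.

## Why the sweep kernel is DC-balanced with an elliptical support

The ridge profile `g` alone is not a usable sweep kernel, for two measurable
reasons:

* its weights do not sum to zero, so the image's constant background level
  multiplies an orientation-dependent weight sum (the positive band covers
  more of a rectangular support along the diagonal) and systematically drags
  the argmax towards 45°/135°;
* even with a zero-sum kernel, a rectangular support intersects an oriented
  ridge over an orientation-dependent length, which biases wide, flat ridges
  the same way.

On straight-vessel phantoms the combined bias reaches ~13°. The sweep
therefore correlates with the `effective_kernel()`: the mask restricted to
the ellipse inscribed in its rectangular extent and mean-subtracted over that
support. With these two refinements the mean absolute tangent error on
noiseless phantoms of widths 1–3 px is below 1° at every tested orientation,
and a constant image produces a numerically zero response at all angles.
Both refinements can be disabled (`zero_mean = FALSE`,
`support = "rectangular"`) to study the raw profile.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `sigma` | 2 | px | ridge-profile SD; match to vessel half-width |
| `eps_ma`, `eps_mi` | 4, −2 | — | on-ridge and surround mask weights |
| `rows`, `cols` | `2⌈3σ⌉+1` | px | mask extent; `mask_params_29x19()` preserves the classic 29×19, σ = 1 parameterisation |
| `theta_step_deg` | 1 | deg | sweep resolution (must divide 180) |
| `preprocess.flatten_background` | off | — | optional large-window (101×101) median background subtraction |
| `metrics.pixel_weighted` | off | — | pixel-weighted rather than per-object `phi_sr`/`phi_std` |
| CV `folds` | 3 | — | stratified folds; 52 subjects split 18/17/17 with the 12 positives spread 4/4/4 |
| `min_leaf` | 1 | subjects | no minimum node size, appropriate for small cohorts |

`phi_sr`/`phi_std` average **per-object means** by default (each vessel
counts once regardless of calibre); the `pixel_weighted` switch provides the
pixel-level alternative since the verbal definition admits both readings.
`phi_max` is the histogram **mode** — the angle with the most pixels — not
the maximal observed angle; the latter reading is incompatible with observed
feature tables where `phi_max` lies well below the mean angle.

## The synthetic phantom: what it does and does not emulate

`generate_phantom()` renders bright curved vessels departing radially from
the disc rim over a noisy, unevenly lit background. Centrelines are
integrated at 0.25 px steps; the tangent at arc length `s` deviates from the
local radial direction by `A·sin(2πs/T)` (tortuosity) plus an optional
constant offset (90° traces an arc concentric with the disc — the extreme
case of the radial-angle scale). Cross-sections are Gaussian and rasterised
by max-blending profiles stamped at each step, which leaves no gaps at any
orientation; noise is additive Gaussian clipped to the intensity range, the
kind a 3×3 median removes. Ground truth (analytic tangent per support pixel,
its radial fold, the support mask) makes every downstream stage testable.

Defaults are chosen once to emulate acquisition-like conditions at desk
scale: 512×512 raster, disc radius 60 px (so the 2r–3r band fits with
margin), 12 vessels, 8-bit-like intensity scale (background 40, vessel peak
120, noise SD 4, illumination ramp 0.04 per pixel). The truth support is the
set of pixels where the noiseless vessel contribution exceeds 10% of peak —
a defined, testable definition that is deliberately generous: it includes the
faint Gaussian skirt below half maximum that any intensity segmentation
legitimately discards. Recovery checks of area-type quantities therefore
compare against the **full-width-at-half-maximum** footprint
(width `2·√(2 ln 2)·width_sd`), the conventional definition of a vessel's
width.

The phantom does **not** emulate photorealistic angiography: no fluorescein
transit kinetics, no vessel branching or crossing, no calibre taper, no
central light reflex. Passing phantom tests demonstrates the geometry and
statistics of the pipeline are right, not that segmentation quality matches
clinical images.

## Numerical choices and degenerate inputs

* Filtering borders: edge replication everywhere (median, sweep).
* The 2-D correlations run through an FFT filter; oracle tests bound the
  deviation from exact double-loop correlation at 10⁻⁹.
* Otsu on a constant response raster is a hard error (no threshold exists);
  a response exactly equal to the threshold is background (strict `>`).
* A vessel pixel exactly at the disc centre has no radial direction: dropped
  from the mask, with a message counting the drops.
* Annulus bounds inclusive at 2r and 3r; objects are clipped to the band
  before counting, so a vessel touching the band edge counts once.
* Empty metrics (`z = 0`): `p_s = 0`, angular summaries `NA` (undefined, not
  zero). Undefined confusion ratios (zero denominators) are `NA` with a
  warning, never silently zero.
* Leaf majority ties predict the negative (healthy) class; argmax ties take
  the smallest angle; the Otsu search takes the smallest level — all for
  determinism.
* The cross-validation cost of a subtree is the unweighted mean of per-fold
  misclassification rates; its SE is the SD of fold rates over √k. The
  chosen subtree is the smallest whose cost is within one SE of the minimum.
* Group sizes follow the consistent reading of the study population: 40
  negatives (healthy) and 12 positives (hypertensive), the only assignment
  compatible with every published confusion count (TP + FN = 12).
* Reference t-table entries (3.55 at 39 df; 4.43 at 11 df) are the exact
  quantiles truncated — not rounded — at two decimals; `t_critical()`
  returns the exact quantile.

## Open design points, resolved

* **Uneven-lighting correction** is claimed but never specified upstream;
  here it exists as an optional, documented background-flattening step
  (large-window median subtraction) that is off by default, so the mandatory
  pipeline contains only specified stages.
* **The radial correction formula** is reconstructed as the fold
  `min(|Δ| mod 180, 180 − |Δ| mod 180)` — the unique symmetric map onto the
  stated 0°–90° scale in which small values mean radiating and 90° means
  concentric.
* **Serialisation** of 16-bit rasters (angle maps, phantom truth) uses
  16-bit TIFF with sentinel 65535 for "undefined"; PNG is used for 8-bit
  images.

## Problem sizes

The test-suite phantoms run at 96–256 px with disc radii 9–30 px, and the
synthetic cohorts at the study's 52 subjects; the acceptance script runs one
full 512×512 phantom with the complete 180-orientation sweep and 200 cohort
replicates. These sizes were chosen so the whole suite exercises every stage,
including the full-resolution path, in a few minutes on one core.

## Known limitations

* Arterioles and venules are not distinguished; all vessels pool into one
  statistic.
* Vessel continuity is not repaired: one anatomical vessel interrupted by
  gating counts as multiple objects in `z`.
* The disc centre and radius must be supplied; there is no automatic disc
  localisation.
* Single-scale σ: calibres far from the chosen σ respond suboptimally
  (no multi-scale pyramid).
* DICOM input is not read directly; convert to PNG/TIFF first.
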