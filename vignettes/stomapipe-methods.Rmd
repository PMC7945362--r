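---
title: "Methods: detector-agnostic stomata segmentation with a statistical size filter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detector-agnostic stomata segmentation with a statistical size filter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stomapipe)
```

## The problem

Stomatal traits — count, density, area, orientation, axis lengths — are read
off leaf-surface micrographs that vary enormously between labs: macerated
and safranin-stained cuticles, nail-polish imprints, fluorescence, DIC and
SEM imaging, magnifications from tens to hundreds of times. Two properties
of such data drive this package's design:

1. **Appearance varies across datasets but not within an image.** Colour
   cast and contrast depend on preparation and optics, so a detector trained
   or tuned on one dataset degrades on the next. Within a single micrograph,
   however, magnification is fixed and stomatal sizes on one leaf are
   biologically narrow, so true detections cluster tightly in area.
2. **Boundaries matter.** Bounding boxes answer "how many" but not "how
   large, how elongated, which way" — the quantities stomatal physiology
   actually uses. The pipeline therefore treats instance masks, not boxes,
   as the primitive.

The package wraps four stages behind a detector-agnostic contract:
colour normalisation, detection, statistical size filtering, morphometry —
with an evaluation harness and a synthetic scene generator that make every
stage testable without any external imagery.

## Colour normalisation

`colour_normalise()` converts RGB to YCbCr (full-range BT.601 coefficients,
the common imaging default), applies Contrast Limited Adaptive Histogram
Equalisation to the luma channel only, converts back, and collapses to
grayscale (BT.601 luma) replicated on three channels — downstream detectors
expect 3-channel input. Chroma is deliberately discarded: after local
contrast is equalised, residual colour carries preparation bias rather than
morphology. CLAHE defaults (clip limit 2, 8×8 tiles) are exposed in
`preprocess_config()`; the colour-space and grayscale formulas are fixed
because changing them silently changes every downstream intensity.

Working scale: `resize_for_inference()` supports two conventions — scaling
the **longest side** to 1024 px and scaling the **width** to 1024 px. Both
occur in practice for this family of pipelines (training-time versus
inference-time conventions), and the package does not guess which a user's
detector expects; `longest_side` is the default and the applied factor is
recorded in `scale_factor` so measurements can be mapped back to original
pixels. All areas and IoUs are computed at working scale; with aspect ratio
preserved, IoU is invariant to the common rescaling of both masks, so this
choice only matters for absolute pixel areas, and `scale_factor` makes the
conversion explicit.

## The detector contract

`detect_stomata()` requires only: image in, instance masks with confidences
out, detections at or above the configured confidence threshold (default
0.5), no duplicate masks (pairwise IoU ≤ 0.9 — non-max suppression is the
detector's job), output in canonical order (descending confidence, ties by
descending area, then centroid raster-scan position — determinism for
everything downstream). `detector_config()` records the operating point a
CNN adapter should use (anchor scales 12–192 px across pyramid levels,
1024 px input). Training, transfer weights and augmentation are a detector
concern, outside this package; a trained segmenter plugs in through
`detector_adapter()`.

Two desk-scale detectors ship with the package. The **baseline detector**
(local-contrast thresholding → morphological opening → connected components
→ elliptical shape score) exists so the full pipeline runs end-to-end
without any trained model; its confidence is one minus the mean deviation of
the component boundary from its own moment-equivalent ellipse (clipped to
[0, 1]), so round-ish dark blobs score high and ragged noise scores low.
It is deterministic and adequate on clean imagery, and is documented as a
classical baseline, not a substitute for a CNN on hard data. The **oracle
detector** perturbs known ground truth with controlled error structure
(instance drops, smooth low-harmonic boundary jitter, Beta-distributed
confidences, injected off-scale elliptical false positives), which is how
the filter and the evaluation harness are tested against known truth.

## The statistical size filter

The core algorithm. Input: one image's detections with confidences and
pixel areas. Steps, with `q = 0.90`, `c_low = 0.65`, `c_high = 1.5` by
default:

1. Seed set `{A}`: detections with confidence at or above the nearest-rank
   `q`-quantile of all confidences.
2. Split `{A}` at its mean area into `{A_s}` (below) and `{A_l}` (at or
   above).
3. Choose the scale estimate `area_optimal`:
   * more large than small → mean area of `{A_l}` (a "large-stomata" image);
   * more small than large **and** `{A_s}` more confident on average → mean
     area of `{A_s}` (a genuinely "small-stomata" image);
   * more small but less confident → mean area of `{A_l}` (the small surplus
     is treated as noise);
   * equal counts → mean area of `{A}`.
4. Keep every original detection with
   `c_low·area_optimal < area ≤ c_high·area_optimal`, regardless of
   confidence. The band brackets a ~50% variation around the estimate
   (0.65 × 1.5 ≈ 1, 1 × 1.5 = 1.5); the bounds are strict below and
   inclusive above, exactly as stated, and the band-edge tests pin this.

Several details are underdetermined by the verbal description; the package
fixes them as follows, and these conventions are frozen by the test suite:

* **Percentile**: nearest-rank with membership by `≥`. A strict `>` empties
  the seed set whenever the top confidences tie (common with saturated
  detectors); with `≥`, `{A}` is never empty for non-empty input.
* **Equality at the mean** goes to `{A_l}`. This keeps the partition
  exhaustive and makes the single-detection case well defined (the
  detection survives its own band).
* **The "more small but less confident" branch** falls back to `{A_l}`:
  small spurious detections arising from noise are the motivating failure
  mode, so when the confident mass sits with the large side, that side is
  trusted.
* **Tied subset sizes** use the mean over all of `{A}` — unbiased and safe
  in degenerate cases.
* Detections below the detector's own confidence threshold never reach the
  filter, and the percentile is computed over the final (post-NMS) detector
  output.

Properties verified in the suite: equivalence with an independently coded
step-by-step reference on 1000 random detection sets (sizes 0–200, mixed
area/confidence distributions including ties); output always a subset of
input; invariance of the accepted index set under global area rescaling;
adding a below-threshold in-band detection never evicts accepted ones; and
on synthetic scenes with injected false positives, pooled precision with
the filter is at least pooled precision without, at the cost of recall —
the filter's intended trade. The filter can be bypassed
(`flt_cfg = NULL`, CLI `--no-filter`) when recall matters more.

`apply_statistical_filter()` attaches a complete `filter_trace` (seed set,
partition, branch, estimate, band, accepted indices) to its output;
`tidy()`, `glance()`, `autoplot()` and `filter_trace_json()` expose it.

## Geometry and morphometry

Masks live on 0-based pixel grids; pixel (row, col) is centred at
(x, y) = (col, row) and owns a unit square, matching VIA's vertex
convention. Polygon rasterisation is an even-odd scanline fill with
centre-of-pixel inclusion and half-open ties; boundary tracing
(raster → polygon) follows the 0.5-level contour of the padded binary grid,
which separates inside from outside pixel centres exactly, so
rasterise(trace(R)) reproduces R bit for bit (single-pixel masks export the
pixel's unit square). Holes are filled before tracing — stomata are simply
connected; sub-pixel boundaries are out of scope.

`measure_instance()` derives shape from second central moments of the pixel
set: the moment-equivalent ellipse gives major/minor axis lengths
(4√eigenvalue), orientation (angle of the major axis from +x towards +y in
image coordinates, reported in [−90, 90)), and eccentricity; the perimeter
is the traced boundary's arc length, which for pixelated boundaries runs a
few percent above the smooth-curve perimeter and is documented as such.
Pixel-count area is primary (the fitted ellipse's area is implied by the
axes); physical units appear only when the user supplies a pixel size —
microscope datasets have heterogeneous magnifications and no global
calibration is assumed. On rasterised analytic ellipses with axes of
40–200 px the estimators recover axes and area well within 2% and
orientation within 1° (worst case ~0.3% and ~0.2° in the acceptance
script); orientation accuracy degrades as the axis ratio approaches 1,
where the angle is ill-conditioned by symmetry, so near-circular fixtures
keep ratios ≥ 1.4.

## Evaluation protocol

Matching is greedy in descending prediction confidence; each prediction
claims the free ground-truth instance of highest mask IoU, if that IoU
reaches the threshold (default 0.5, standard instance-segmentation
practice; the matcher itself is a package decision since published tables
rarely state one). Precision, recall and F are percentages from pooled
true/false positives and negatives; per-image macro averages are reported
alongside, since both aggregations occur in the literature. Vacuous cases
log explicitly: no predictions and no truth → P = R = 100; no predictions
with truth present → P = 100, R = 0.

Segmentation quality is the union-pixel IoU per image —
|∪pred ∩ ∪gt| / |∪pred ∪ ∪gt| — so false positives and false negatives
both depress it; the bounding-box variant replaces every instance by its
filled box. For an axis-aligned ellipse inside its own box the area ratio
is π/4 ≈ 0.785, which is the analytic mechanism behind boxes scoring ~7
IoU points below masks on elliptical objects. Two rasterisation caveats:
the box of a w×h-pixel instance is (w+1)(h+1)-ish, biasing small instances
below π/4, and a rotated ellipse's axis-aligned box is larger than 2a×2b,
biasing further down — so the π/4 check uses axis-aligned instances with
minor axes ≥ ~76 px, where discretisation sits within ±0.02.

## The synthetic scene generator

`generate_scene()` emulates the statistical structure the pipeline assumes,
not photorealism: elliptical stomata rendered as a darker guard-cell ring
with a lighter central pore on a textured background. The defaults encode
the study conditions: per-image size and shape are single draws (major axis
uniform on 50–90 px at the default 512² size; axis ratio uniform on
1.5–3) with only ±10% / ±5% per-stoma jitter — within-image size
uniformity is precisely the assumption the statistical filter relies on.
Quality tiers mirror the field's high/medium/low categories: blur σ
0.5/1.5/3 px, grain noise sd 0.01/0.03/0.06, contrast 1/0.7/0.45, and
bubble/vein artifact counts 0/2/5 by default. Grain noise is applied before
the defocus blur, so lower tiers have strictly lower gradient energy, the
observable that separates tiers. Colour casts are per-channel gains applied
last. Ground-truth masks are the rasterised ellipse supports fixed before
any degradation, so they are exact by construction; instances are packed by
rejection sampling with a directional ellipse-radius separation test, and
infeasible requests (instances exceeding ~30% of the image) fail loudly
rather than silently under-placing.

What passing tests on these scenes does **not** show: robustness to real
staining chemistry, anisotropic cell patterning, overlapping or touching
stomata, open/closed pore states, or CNN-specific failure modes. The
synthetic scenes validate the geometry, statistics and plumbing around a
detector; they say nothing about any particular detector's accuracy on real
micrographs.

## Problem sizes and numerical choices

The shipped suites run the filter-equivalence sweep at 1000 random sets of
up to 200 detections, the filter-effect experiment at 100 scenes of 10
stomata on 384² grids (4 injected false positives, 10% drops, 1 px jitter),
the identity loop at 20 scenes of 12 stomata on 448², morphometry at 50
ellipses on 212² grids, and the colour-cast twin experiment at 20 pairs on
192² — sizes chosen so the whole suite completes in a few minutes on one
core while keeping every estimate's direction unambiguous. Seeds are fixed
in tests and derived from `--seed` in the acceptance script; all
generator randomness flows through per-call seeds (`withr::with_seed`), so
no global RNG state leaks between calls.

Known limitations: the filter assumes unimodal within-image stomata size
and will mis-serve genuinely bimodal images (stated out of scope); the
baseline detector is contrast-based and degrades quickly below the "high"
tier; VIA files do not record image dimensions, so `read_via()` needs grid
sizes for exact raster alignment (it otherwise infers the smallest
containing grid); pore-aperture and guard-cell-width measurement are future
work, not provided.
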