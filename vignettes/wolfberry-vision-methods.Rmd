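---
title: "Methods: chroma-fusion fruit segmentation and Lab-clustering branch localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chroma-fusion fruit segmentation and Lab-clustering branch localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gojivision)
```

This vignette is the package's account of its method: the model behind each
stage, the assumptions it rests on, the tunable parameters and their
defaults, the numerical choices, and what the synthetic test bed does and
does not establish about field data.

## The problem

A wolfberry-harvesting robot images shrubs at 20–30 cm with an RGB-D
camera (nominally 640 × 480) and must (i) localize ripe red fruits and
(ii) find a clamp point on a supporting branch. Field lighting is
uncontrolled — front-lit, backlit, side-lit, overcast — so any method
keyed to absolute intensity fails. Both pipelines here are classical and
training-free: they need no labeled data and run on modest embedded CPUs.

## Fruit segmentation by chroma-feature fusion

### Feature channels

Two chroma features separate ripe wolfberries from green foliage:

- **a\*-channel.** RGB is first reduced to chromaticities
  `r, g, b = R,G,B / (R+G+B)`, which cancels any multiplicative
  illumination gain exactly; a fixed 3 × 3 matrix maps `(r, g, b)` to an
  XYZ triple, and `a* = 500(f(X) − f(Y))` with the usual cube-root `f`
  (linear branch `7.787 t + 16/116` below `t = 0.008856`). Red fruit
  pixels have large positive a\*, green foliage strongly negative a\*.
- **I-channel.** The NTSC chroma axis
  `I = 0.5957 R − 0.2745 G − 0.3213 B`, applied to the raw 8-bit values.
  It is not gain-invariant, but is insensitive to the green–magenta
  variation that dominates foliage texture.

Two deliberate conventions differ from textbook CIE Lab and are applied
*consistently everywhere* (pipelines, generator contract, tests):

- **No reference-white division.** `f` is applied to X, Y, Z directly.
  A consequence worth knowing: the XYZ matrix's first row sums to 1.1
  while the other two sum to 1.0, so an achromatic pixel (R = G = B) has
  X ≠ Y and a *constant, non-zero* a\* (≈ 11.19) rather than a\* = 0. Only
  constancy matters for segmentation — the plane carries no spatial
  structure on achromatic regions.
- **Black pixels** (R + G + B = 0) take chromaticity (0, 0, 0), the
  continuous limit, so no NaN enters the pipeline.

The I transform consumes raw 0–255 RGB (the natural reading of its 8-bit
scale); since each channel is min–max rescaled to [0, 255] before fusion
anyway, this choice only fixes the recorded `display_range`.

### Wavelet fusion

Each rescaled channel is decomposed by a 3-level 2-D discrete wavelet
transform. Three levels balance detail extraction against cost; the count
is exposed as `levels` in `pipeline_config()`. Fusion combines the two
pyramids coefficient-wise:

- **Detail (high-frequency) bands:** the coefficient of larger absolute
  value wins, sign preserved — edges and texture present in either channel
  survive. Exact ties keep the a-channel coefficient (a documented,
  deterministic tie-break).
- **Approximation (low-frequency) plane:** the weighted average
  `α A_a + β A_I`, defaults α = β = 0.5 with α + β = 1 enforced.

The inverse transform yields the fused feature image, clamped to
[0, 255] (reconstruction can overshoot by a fraction of a gray level at
hard edges).

**Transform details.** The DWT is implemented in the package (periodized
orthogonal filter bank; Daubechies `db2` by default, `haar` and `db4`
available). Periodization keeps the analysis operator exactly orthogonal,
so `reconstruct(decompose(x))` returns `x` to machine precision — the
property the fusion correctness tests lean on. Images whose sides are not
multiples of `2^levels` are padded by symmetric (edge-mirroring) extension
on the bottom/right and cropped back after reconstruction, so border
content — not wrap-around — dominates boundary coefficients. Arithmetic is
double precision throughout.

### Valley thresholding

The fused image of a fruit scene is bimodal: a tall background mode at low
gray and a smaller fruit mode at high gray. `valley_threshold()`:

1. smooths the 256-bin histogram with a width-5 moving average (partial
   windows at the ends);
2. finds local maxima (plateaus count once, at their center) and takes the
   two tallest peaks that are at least `min_separation = 32` bins apart —
   closer maxima are ripples of one textured mode, not bimodality; the
   method's own premise is a *widely* separated fruit/background pair;
3. places the threshold at the valley: the midpoint of the longest run of
   bins whose smoothed count lies within `valley_tolerance = 1e-4` of the
   pixel total above the minimum. A flat zero plateau therefore resolves
   to its midpoint; more importantly, the thin smear of anti-aliased edge
   pixels that crosses any real valley floor cannot pin the threshold
   against one of the modes.
4. If no two such peaks exist — the fruit mode can be submerged when
   fruits are few — the threshold falls back to the variance-maximizing
   (Otsu) split, and the result records `method = "otsu"` so callers can
   see the fallback fired.

Binarization takes bright-is-foreground (`value > t`) by default: fruit
gray values exceed the background's in the fused image. The polarity is a
config switch (`fruit_polarity`) because the same primitive serves
dark-foreground tasks.

### Cleanup and localization

Morphological opening with a 3 × 3 square kernel (the fruit-stage size is
not pinned by the method; 3 × 3 removes 1–2 px speckle while preserving
≥ 100 px fruits, and is configurable) is followed by an area filter that
removes 8-connected components with *fewer than* 100 pixels — a 100-px
component survives, a 99-px one does not. Each surviving component is
reported with its first-moment centroid (mean of member pixel
coordinates), area and bounding box. With a depth map, the depth at the
centroid's nearest integer pixel back-projects to camera coordinates; no
RGB-depth re-registration is attempted (none is available), so a small
parallax error is inherent. Invalid (zero) depth flags the point rather
than raising.

Coordinates are 0-based throughout: x = column, y = row, pixel centers at
integers.

## Branch segmentation and grip-point localization

1. **Clustering.** Pixels are clustered on full (L\*, a\*, b\*) vectors
   (`kmeans_features = "lab"`; an `"ab"` chroma-only option supports
   illumination-robustness experiments). K = 8 by default. Lloyd's
   algorithm is implemented directly: seeded uniform sampling of k
   distinct pixels as initial centers (a plus-plus option exists but is
   off by default), Euclidean nearest-center assignment, mean update,
   termination when assignments stabilize, centers move less than
   `kmeans_tol = 1e-4`, or `kmeans_max_iter = 300` is reached. Empty
   clusters are re-seeded from the farthest point *before* the mean
   update — each sub-step then lowers the objective, so the recorded
   inertia trace is non-increasing by construction (and asserted in
   tests). A given seed fully determines the result.
2. **Cluster-level thresholding.** The clustered image is rendered at one
   gray level per cluster (the center's L\*; levels min–max rescaled, with
   an epsilon guard so float-identical centers are not stretched apart).
   The histogram of such an image is a handful of spikes, where smooth
   peak/valley search degenerates, so the dark/bright split is computed on
   the levels themselves: levels holding under 0.5 % of pixels are set
   aside first (isolated-noise clusters — impulse noise reliably captures
   one — cannot constitute a mode), and the remaining sorted levels are
   cut at the point minimizing within-group variance of the level values.
   The mass-unweighted form matters: a pixel-weighted (Otsu-style) split
   lets the dominant foliage mass absorb the cut into its own interior.
   Whole clusters are kept or dropped, never split. The dark group is the
   branch candidate (`branch_polarity = "dark"`); if it covers more than
   90 % of the frame there is no minority structure to call a branch and
   a `no-region` error is raised.
3. **Longest region.** Among 8-connected components, the one with the
   largest bounding-rectangle height wins (ties: larger area, then smaller
   top row). This is the method's own notion of "longest" and is biased
   toward upright branches — a horizontal branch would be mis-ranked; see
   limitations.
4. **Refinement.** Median filter (window 3, symmetric borders; on a
   binary mask this is an exact majority vote) then opening with a 2 × 2
   kernel (origin at the kernel's top-left cell — with an even kernel
   there is no center pixel, and the opening composition is
   origin-independent). The longest region is re-selected afterwards.
5. **Grip point.** The region centroid, rounded to the nearest pixel, is
   the grip point if it is foreground (`on_centroid = TRUE`); otherwise
   the foreground pixel nearest the unrounded centroid (ties: smaller y,
   then smaller x). By construction the grip point always lies on the
   final mask — a hard invariant the tests enforce across all seeds.

## The synthetic scene generator

`scene_spec()` / `generate_scene()` emulate the acquisition conditions the
pipelines target, with every default chosen once as field-realistic:

- geometry 640 × 480 (batteries use smaller frames, below); five fruits of
  10–18 px semi-major axis (at 20–30 cm a ~1 cm berry spans tens of
  pixels), anti-aliased ellipses, ≥ 8 px separation;
- colors: fruit (196, 30, 40), foliage (64, 115, 48), branch
  (101, 72, 47), ±12 uniform per-object jitter, per-pixel Gaussian foliage
  mottle (σ = 6). The contract a\*(fruit) > a\*(foliage) — the method's
  applicability condition — is asserted at generation time;
- a vertical-ish curved branch stroke (width 9 px) with its analytic
  midline recorded; `sky_fraction` defaults to 0 because the close working
  distance fills the frame with canopy;
- illumination: a multiplicative linear gradient (direction, strength);
  the battery cycles front-lit (0.35), backlit (0.50), side-lit (0.35) and
  cloudy (0.08) analogues. Because the gradient is multiplicative, the
  a\*-channel is immune to it except where 8-bit clamping distorts hue —
  exactly the regime that degrades single channels in the ordering
  experiment;
- occlusion: foliage-colored rounded patches grown over a fruit's border
  until the target fraction of its pixels is covered; applied after ground
  truth is recorded;
- impulse (salt-and-pepper) noise at rate 0.005, last;
- depth: fruits and branch at 200–300 units (mm), background 500–1500,
  smooth within objects.

Ground truth (per-fruit masks and centroids, branch mask and midline,
depth) reflects the clean scene; corruptions touch only the rendered
image.

**What passing these batteries does and does not show.** The generator
provides controlled lighting/occlusion stress with exact truth, which is
what the property-based tests need. It does not reproduce real canopies:
no specular highlights, no unripe (green-orange) fruit, no cluster
adhesion of touching berries, no camera noise model, no RGB-depth
parallax. Results on the batteries demonstrate internal correctness and
the *directional* benefit of fusion, not field accuracy figures.

**Scene composition per battery.** Fruit-recovery and channel-ordering
batteries use branch-free scenes: those criteria target fruit recovery,
and a grey-brown branch is itself redder than foliage in a\*, so it forms
a third histogram mode and adheres to overlapping fruits — a real
limitation of single-threshold segmentation (shared with the original
method) that the fruit metrics are not designed to absorb. The branch
battery keeps all five fruits as distractors.

## Problem sizes and tolerances

Acceptance-style checks run 200-scene batteries at 256 × 192 — the
pipelines are resolution-independent and this size keeps the full suite in
a few CPU-minutes — with 10,000-pixel random batteries for the
color-transform oracle and 100 random 64 × 64 images for the wavelet round
trip. Numerical tolerances: 1e-9 for linear-map equivalence, 1e-8 for
wavelet reconstruction, 1e-6 for end-to-end self-fusion identity, exact
equality for the median-filter-vs-oracle check.

## Known limitations

- The printed centroid formulas the field uses reduce to sums of pixel
  values over N and cannot yield a coordinate as written; the package
  implements the standard first moment, which is what marked-centroid
  figures in this literature actually depict.
- "Longest = bounding-box height" mis-ranks horizontal branches.
- Adhered fruit clusters are not split (no watershed stage), and fruits
  overlapping the branch can merge with it in the fruit channel.
- Field-scale accuracy depends on orchard imagery that is not
  redistributable; the package's batteries establish the *ordering*
  property (fused recall at least matches either single channel), not
  absolute field rates.
- No ICC color management; the Lab variant is the method's own, not CIE.
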