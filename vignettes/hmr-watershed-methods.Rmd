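---
title: "Hybrid morphological reconstruction and marker-controlled watershed: methods"
author: "hmrseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid morphological reconstruction and marker-controlled watershed: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmrseg)
```

## The problem and the model

Medical-style raster images — cross-sections of a coronary artery with
plaque narrowing the lumen, or fundus photographs with exudates and
hemorrhages — consist of a few roughly homogeneous structures separated by
intensity edges, overlaid with acquisition noise. The package implements a
two-stage hybrid: a *hybrid morphological reconstruction* (HMR) enhancement
that flattens intensity variation inside structures while preserving their
contours exactly, followed by a *marker-controlled watershed* of the Sobel
gradient magnitude that partitions the image into one catchment basin per
structure.

### Enhancement

All enhancement is built from grayscale geodesic reconstruction. The
reconstruction by dilation of a *marker* image under a *mask* image is the
limit of iterating "dilate the marker by the unit connectivity
neighborhood, then clip pointwise to the mask". Eroding an image with a
structuring element $S$ and reconstructing under the original is the
*opening by reconstruction*: bright structures that cannot contain $S$ are
removed, and every surviving structure is restored to its exact original
shape — unlike a plain opening, which rounds corners. The complement-dual
filter (*closing by reconstruction*) removes small dark structures.

The four-step HMR chain on an 8-bit image $R$ is

1. $\bar R = 255 - R$ (complement),
2. $\bar R_{obr}$ = opening by reconstruction of $\bar R$,
3. $\bar R_{obrcbr}$ = closing by reconstruction of $\bar R_{obr}$,
4. $\bar R' = 255 - \bar R_{obrcbr}$ (complement back).

Because both filters are idempotent, anti-extensive/extensive, and act only
on structures below the $S$ scale, the chain removes bright and dark
speckle below the structuring-element size and returns an image that is
piecewise near-constant inside structures, which is exactly what the
marker and gradient stages need. `hmr_enhance()` is tested to be
bit-identical to the hand-composed chain.

### Segmentation

The watershed transform views a surface as topography flooded from its
regional minima; pixels where water from two minima would meet are divide
(watershed-line) pixels. `watershed_flood()` realizes this as priority
flooding in increasing surface order: each pixel drains along its
minimum-valued lower neighbor(s), plateaus are resolved by FIFO geodesic
first-arrival from their draining exits, and a pixel whose tied steepest
routes (or geodesically equidistant plateau arrivals) lead to different
basins becomes a line pixel with label 0. On surfaces without ties this
reduces exactly to steepest-descent drainage, and the test suite holds the
implementation to that definition with an independent brute-force oracle.

Flooding the raw gradient of a natural image over-segments (every noise
dimple seeds a basin), so the pipeline runs *marker-controlled*: the
regional maxima of the HMR-enhanced image — connected constant-intensity
plateaus whose external neighbors are all strictly lower — mark structure
interiors, `impose_minima()` rewrites the gradient surface so that exactly
those components are its regional minima (markers forced below the global
minimum, everything else raised by a reconstruction by erosion so no
spurious minimum survives), and the flood then grows one basin per marker.

## The pipeline and its parameters

`run_pipeline()` executes: grayscale conversion (luma weights
0.2989/0.5870/0.1140, round half-up) → optional polarity complement → HMR
→ Sobel gradient magnitude (3×3 kernels, replicate border padding, output
kept as floats) → marker extraction → minima imposition and flood →
overlay and per-basin statistics.

Parameters that matter, with defaults and reasoning:

* **Structuring element** (`se_shape`, `se_radius`): disk of radius
  $\max(3, \mathrm{round}(0.02\,\min(h,w)))$ pixels. The radius sets the
  smallest structure the enhancement preserves; a scale-relative default
  keeps behavior stable across image sizes, and both shape and radius are
  configurable because no single value suits all content.
* **Connectivity** (`connectivity`, default 4 in the pipeline; module
  functions default to 8): the flood and the minima imposition run
  4-connected by design. Under 8-connectivity a flooding path may slip
  *diagonally between* two pixels of a gradient band, so the effective
  barrier between two basins collapses to a rasterization accident rather
  than scaling with the edge contrast; with 4-connectivity every crossing
  must step on a band pixel and barriers order themselves by contrast.
  Marker extraction always treats plateaus as 8-connected — one structure
  is one marker however its pixels touch — and basins that a 4-connected
  flood splits inside a single 8-connected marker are merged back.
* **Marker consolidation**: maxima whose separating valley is at most
  `marker_merge_depth` intensity units deep (default 4) are first merged
  by reconstructing `enhanced - depth` under `enhanced`; on noisy inputs
  the enhancement flattens a region to its top level with occasional
  one-unit-deep channels, and without the merge each fragment would seed
  its own basin. The default sits above that residual jitter and far
  below any plausible structure contrast. Components smaller than
  `marker_min_area` (default: the SE footprint area) are dropped; a
  radius-2 closing seals pinhole gaps so that the subsequent radius-2
  erosion — which pulls markers off the gradient crest — cannot shatter
  them; finally markers are confined to their source plateau so the
  closing can never leak a marker across an edge. The erosion matters:
  a plateau marker reaches the very edge of its structure, and imposing
  minima on an un-eroded marker deletes the inner half of the edge's
  gradient band, which systematically drags the outer half into the
  marker's basin (a one-pixel dilation of every basin).
* **Polarity** (`polarity`): the enhancement chain and the maxima markers
  key on bright structures; `"invert"` complements the input first for
  images whose targets are dark. Exposed as a flag rather than guessed.
* **Stage order** (`legacy_order`): the declared model enhances before
  taking the gradient; the flag instead computes the flooding surface from
  the raw grayscale (markers still come from the enhanced image), the
  order some presentations of this pipeline narrate, kept for comparison.
* **Statistics** are always measured on the original (pre-enhancement)
  intensities so the measurement is not conflated with the method:
  per-basin area (pixel count), perimeter (exposed unit-edge count, so a
  $w\times h$ rectangle measures exactly $2(w+h)$), and per-channel
  standard deviation, Fisher–Pearson skewness $g_1 = m_3/m_2^{3/2}$ and
  median. Population moments are the default (`sample = TRUE` switches to
  $n-1$) because the convention of the original measurement tool cannot
  be verified; the median uses the lower-of-two-middles rule so medians
  of integer images stay deterministic integers; $g_1$ is defined as 0
  when $m_2 = 0$.

## The phantom generator

No clinical images of the kind the method targets are publicly deposited,
so the package ships a generator whose outputs carry exact ground truth.

The **artery phantom** renders concentric discs — background, adventitia,
media, intima, lumen, with radii as fractions of the half-size (defaults
0.78/0.58/0.42/0.30) — and fills a requested fraction of the lumen disc
with plaque accreted from the intima wall inward around a seeded random
angular position, mimicking an eccentric occlusion rather than a
symmetric shrinkage. The palette (background 20, adventitia 200, media
120, intima 90, plaque 140, lumen 250) gives every interface a clear
contrast and makes the lumen and the adventitia ring the two regional
maxima, so the default pipeline seeds exactly the open lumen and the
wall; the lumen/plaque edge carries the largest contrast, which is where
the watershed divide must fall for the open-lumen basin to be correct.
A mild per-channel tint (1.0/0.9/0.8) makes the output RGB. Plaque pixel
count is exact by construction, so ground-truth open-lumen areas are
strictly decreasing in the occlusion fraction.

The **retina phantom** renders a fundus-like disc with quadratic radial
falloff (center 190 to edge 120) on a dark surround, places compact
bright exudate blobs (radius 7–10 px, intensity 240) and dark hemorrhage
blobs (radius 5–9 px, intensity 40) at seeded non-overlapping positions
with a 4-px clearance band, and tints toward red (1.0/0.62/0.45). Lesion
placement retries are bounded; an impossible load raises an error rather
than overlapping silently.

Both generators draw all randomness from one seeded generator and restore
the caller's RNG state, so identical specs give bit-identical phantoms.
Noise is additive Gaussian per channel, clipped and rounded to 8 bits;
the default `noise_sd` of 5 intensity units is a moderate acquisition
noise for 8-bit imagery.

What the phantoms do *not* emulate: texture inside tissue layers,
illumination gradients across the field, vessel trees, lesion shape
irregularity, and partial-volume edge blur. Passing the phantom-recovery
tests therefore demonstrates that the implementation is faithful and that
the method behaves as designed on piecewise-homogeneous content with
moderate noise — not that it segments clinical images at any particular
accuracy.

## Numerical choices and degenerate inputs

* Border handling restricts the structuring element to the image domain
  (no padding value is invented); the Sobel kernels use replicate
  padding so edge-adjacent magnitudes stay finite.
* The gradient surface is kept float-valued into the watershed;
  rescaling to 8 bits would merge shallow basins and change the
  topology. An 8-bit rescaled export exists only for visualization.
* The regional maxima of a constant image are the whole image (the
  strictly-lower-neighbor condition is vacuous); the watershed of a
  constant surface is a single basin with no lines; both degenerate
  cases are deterministic and tested.
* Reconstruction is implemented with a raster-sweep-plus-queue algorithm
  whose fixed point is provably the iterated-geodesic-dilation limit;
  the tests enforce equality with an explicit iteration oracle, so the
  speedup cannot drift from the definition.
* Basins are numbered 1..K by raster order of each seeding minimum (or
  marker component), and plateau conflicts resolve by FIFO first
  arrival, so label maps are reproducible across runs and platforms.
* Minima imposition uses a step of one intensity unit above the surface
  for non-marker pixels — any positive value works; one unit matches the
  8-bit scale the gradients derive from.
* An all-constant marker is a fixed point of geodesic erosion (eroding a
  constant changes nothing), so `reconstruct_by_erosion(255, c)` returns
  255, not `c`; the suite pins this with a spike-marker case that does
  descend.

## Problem sizes in the test suite

The oracle-equivalence tests run the compiled operators against pure-R
brute-force references on 100 random images up to 32×32 per operator;
recovery experiments run the full pipeline on 256-px phantoms over
occlusions {0, 0.1, 0.5, 0.8} × 20 seeds × noise {0, 5} for the artery
and 20 seeds for the retina. These sizes were chosen to exercise every
code path at full pipeline scale while keeping the default suite quick
to run during development.

## Known limitations

* 2-D, single-frame, 8-bit only; no 3-D morphology and no non-flat
  structuring elements.
* The watershed is the classical single-scale transform — no
  hierarchical or waterfall variants — so structures whose interior
  contrast rivals their edge contrast will still split or merge.
* Marker extraction assumes the structures of interest are intensity
  plateaus after enhancement; heavily textured regions would need a
  different marker policy (the `marker_mode = "mask"` escape hatch
  accepts externally computed markers).
* The perimeter is an exposed-edge count, which overestimates the length
  of diagonal boundaries relative to chain-code or Crofton estimators;
  it was chosen because it is exactly testable and deterministic.
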