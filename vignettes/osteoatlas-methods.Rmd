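---
title: "Methods: desk-scale osteocyte connectomics with osteoatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale osteocyte connectomics with osteoatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoatlas)
```

## The problem

Osteocytes — the most abundant cells of bone — live in lacunae and reach
each other through dendritic processes running in canaliculi. The resulting
lacunocanalicular network is bone's "connectome": its connectivity degrades
with age and disease, and the loss of connected, viable cells plausibly
degrades the tissue's capacity to move information between cells. Multibeam
scanning electron microscopy (mSEM) can image this network over square
millimetres at ~12 nm pixels, but such maps run to terabytes and must be
stitched, searched for cells, and classified automatically.

`osteoatlas` re-creates that workflow at desk scale: a seeded synthetic
phantom stands in for the (undeposited, multi-terabyte) mSEM maps, so every
stage — stitching, detection, classification, network analysis, atlas
export — runs in seconds to minutes on one CPU against a known ground
truth.

## The phantom: what it emulates, and what it does not

`generate_phantom()` renders an 8-bit field in which cellular material is
dark on a light resin background, as in backscatter imaging of
carbon-coated PMMA blocks: background ~200, somata ~60. Each cell is an
elliptical soma (default full axes 20 × 12 px) with 0–8 thin radial rays
(default length 40 px, width 2 px, minimum angular separation 22°). Status
is tied to process count by construction: viable cells draw 3–8 rays,
pyknotic cells 0–2. Ghost lacunae — resin-filled empty lacunae with no
cellular content — render as a smooth elliptical outline with a
featureless, slightly darker fill and no rays; they get ground-truth boxes
but are excluded from accuracy denominators, since they are a known
confounder of process-count classification. The default composition is
200 objects: 5% ghosts, and a viable fraction of 600/650 ≈ 0.923 among the
rest, mirroring the 600 : 50 viable : pyknotic balance of the manual
annotation set this pipeline family was trained on.

Placement is uniform with rejection sampling (minimum centre spacing =
twice the major soma axis, 40 px) — no published spatial statistics exist
for osteocyte fields at this scale, so we deliberately choose the simplest
null model. Gaussian grey noise (default sd 8) is added panorama-wide.

The phantom does **not** emulate: electron-optics artifacts (charging,
beam-to-beam gain differences), canaliculi as continuous inter-cell
channels (rays are local stubs), blood vessels, bone-lining cells, tissue
boundaries, or 3-D structure. Passing the benchmark therefore shows that
the pipeline's contract and bookkeeping are correct and that the detector
and counter work under additive noise; it says nothing about performance
on real backscatter images, whose soma size and intensity statistics are
unknown here. Phantom geometry defaults are plausible placeholders, not
calibrated values.

Determinism: a fixed (spec, geometry, seed) gives byte-identical tiles;
the seeded RNG is restored after generation so callers' streams are
untouched.

## Geometry and stitching

`acquisition_geometry()` models tiles-per-mFOV accounting (default 61
beams, matching the hexagonal 1 + 6 + 12 + 18 + 24 beam array) and the
tile layout. `expected_tile_count(n_mfov, beams)` is exact integer
arithmetic; `storage_estimate()` uses 1 byte/px greyscale, 10^6 px per
megapixel and 10^12 bytes per TB, which reproduces the first-generation
map's printed size at rounding precision (later generations' published
sizes imply different per-pixel overheads and are not reconciled).

`stitch()` copies tiles at their recorded stage coordinates — no
correlation refinement, no resampling. Overlaps are resolved
last-writer-wins (a mean-blend option exists behind a flag): deterministic
and an exact inverse of `tile_partition()`, whose overlap regions are
copies of the same pixels. The round trip `stitch(tile_partition(P)) == P`
is asserted pixel-exactly in the tests. Rectangular layouts tile the plane
exactly; hexagonal layouts leave background-filled scallops at panorama
edges (stitch fills them with the background level), and the phantom
places cells only on covered footprints. The default phantom geometry is
rectangular — 2 × 2 mFOVs of 4 × 4 tiles, 256 px tiles, 32 px overlap —
giving an 1824² px panorama.

`downscale_for_detection()` computes `scale = min(1, target / native)` —
never upsampling — with exact box-filter (area-averaging) resampling
implemented on a summed-area table, so fractional scales introduce no
aliasing; the composite pixel size is tracked as `pixel_size_nm / scale`.
The display target is ~200 px per cell; the phantom's cells (soma plus
processes ≈ 100 px) are already below it, so the benchmark runs at native
scale.

## Detection

The detector honours the single-pass grid contract: a square 448 px input
canvas, an S × S grid (S = 7, the classic default; 64 px grid cells), at
most one candidate box per grid cell, five predictions (X, Y, W, H, p) per
box, greedy non-max suppression, and a strict 0.5 confidence floor.

The backend is deterministic: normalized cross-correlation (NCC) against a
bank of elliptical soma templates (default: 6 orientations over 180°, one
scale, rendered from the configured soma axes). Correlation is computed by
FFT; window means and variances come from summed-area tables, so the NCC
map is exact. Confidence is a fixed, documented mapping: NCC scores in
[0.2, 0.9] map linearly (clipped) onto p ∈ [0, 1]. A learned detector can
be substituted behind the same contract; it is deliberately not required —
the value at desk scale is the pipeline contract, not GPU weights.

Images no larger than the canvas are letterboxed (aspect-preserving,
background-padded, centred; the affine transform back to source pixels is
returned and inverted for the output). Stitched panoramas are scanned at
native resolution with the same 64 px grid-cell size and two grid phases
per axis (offsets 0 and 32 px): a literal resize of an ~1800 px panorama
onto 448 px would shrink somata below the template size, while phase
pooling recovers the occasional pair of cells sharing one grid cell.
Candidates from all phases are pooled before NMS, so duplicates are
suppressed.

NMS is greedy by descending p (ties by X, then Y); a box is suppressed
when its IoU with a kept box exceeds 0.5; kept boxes with p ≤ 0.5 are then
dropped. Suppression-then-floor is the chosen order: for every input in
which ordering matters the two readings differ only when a sub-floor box
would shield a kept one, and suppressing first keeps the invariant simple.
The tests check equivalence against an independent max-pick oracle on 200
random box sets.

Evaluation matches detections to truth one-to-one, greedily by descending
IoU with a 0.5 floor. The headline metric — the surrogate for the printed
92% accuracy figure, whose exact definition (detection-only vs. joint,
matching rule) is not published — is joint detection-plus-classification
accuracy: matched non-ghost truth cells with the correct predicted class,
divided by all non-ghost truth cells. Ghost-matching detections count
against precision (not accuracy) unless ghost-tolerant mode is on.

## Augmentation bookkeeping

`augmentation_spec()` builds a deterministic transform grid: 30 rotations
(0–348° in 12° steps) × a 53-row jitter list. The jitter list is the
identity plus one-factor-at-a-time perturbations — 8 scales (0.80–1.20),
8 contrast gains (0.70–1.30), 36 translations (±2 to ±10 px per axis) —
rather than a full cross product; a full product of those factors would
explode past 10^9, while 30 × 53 = 1,590 transforms expand 629 annotations
to exactly 1,000,110 ≥ 10^6 examples. Augmented examples are
transform-parameter records traceable to their source annotation; patches
are materialized only on demand (`apply_augmentation()`). Splitting is by
source annotation — every augmentation of one cell lands on the same side
— which prevents augmentation leakage between train and test; this is a
deliberate strengthening over splitting raw examples.

## Classification

For each detection a patch of 1.5 × the box is cropped, thresholded at
grey level 130 (the soma/background midpoint), closed with a 1 px-radius
disc, and reduced to the connected component containing the patch centre.
Process counting places an annulus just outside the soma: the soma body is
isolated by a 7 px disc opening; the soma-equivalent radius is the
**maximum** centroid-to-boundary distance of that component (for a 20 × 12
px ellipse, a root-area radius of 9.3 px would fall *inside* the soma
along the major axis, so the maximum is the right notion for eccentric
somata); the annulus sits at 1.2 × that radius plus a 1 px guard band
(the opening slightly shaves high-curvature soma tips). The ring is
sampled at 1° at three radii across the annulus; runs of foreground are
crossing arcs, and arcs whose centres lie within 15° merge into one
process. For the ~2 px rays rendered here, mask crossings coincide with
skeleton crossings, and the exhaustive 0–8-ray sweep against the
renderer's ground truth passes at every orientation tested. The annulus
factor, merge window, threshold and opening size are configuration
constants — "visible process" has no operational definition in the
literature this emulates, so the constants are ours and exposed.

Classification is a pure threshold: **three or more processes = viable,
fewer = pyknotic**. The published body text leaves exactly-3 undefined
("less than three" pyknotic, "more than three" viable); the figure note's
"three or more processes" resolves the tie toward viable, and that is the
rule implemented. Cells whose central disc is bright (mean > 140) are
flagged `ghost_suspect` rather than trusted — ghosts were a reported flaw
of the original scheme, and 2-D process counts are explicitly *not* a
validated viability measure; the package implements the surrogate
classifier without claiming biological validity.

## Connectome

Canaliculi are not traced, so edges are a documented stand-in: cells
within 60 µm connect, pruned to each node's 12 nearest neighbours with
mutual pruning (both endpoints must keep the edge); ties break by node id,
so graphs are deterministic. Both constants are configuration parameters.

"Information transfer" is operationalized as **global efficiency**: the
mean over ordered node pairs of inverse shortest-path length in hops
(1/∞ = 0; empty or single-node graphs score 0). Hop counts, not µm-
weighted paths, are the default (weighting is a flag) to match the
schematic network-node framing. The choice is parameter-free, brute-force
checkable (the tests compare against Floyd–Warshall on 200 random graphs),
and bounded in [0, 1].

Node-removal curves use efficiency **over the original pair count**:
removing nodes both deletes pair terms and lengthens surviving paths, so
this quantity is provably non-increasing — whereas efficiency over
remaining pairs can rise when a peripheral node is removed, which would
make monotonicity untestable. Curves are normalized by the intact-graph
value (start at 1, end at 0). Strategies: `random` permutations per
replicate; `pyknotic_first` (all pyknotic in random order, then viable —
reducing to `random` when no pyknotic cells exist); `degree_targeted`
(descending intact-graph degree, ties by id, deterministic).
`compare_strategies()` reports trapezoidal AUC per strategy; targeted
attack is expected to be most destructive, and the tests check that
ordering in ≥ 95% of seeded trials rather than asserting it per-instance.

## Atlas export

The pyramid is a flat-plane XYZ slippy map (y down, no projection):
native resolution at `max_zoom = ceil(log2(max_dim / 256))`, each coarser
level an exact 2 × 2 area average, level 0 fitting one 256 px tile, edge
tiles background-padded. Pins use normalized map coordinates
`u = x / width`, exactly invertible at native resolution. The display
filter keeps cells with confidence **strictly** greater than 0.7 —
"greater than 70%" read literally; the floor is a parameter. Output is
`tiles/{z}/{x}/{y}.png`, `pins.geojson` (point features with status,
confidence and process count; viable green, pyknotic red) and a CSV
mirror. A minimal static viewer page can be emitted but is not a tested
surface.

## Numerical choices and degenerate inputs

* Coordinates are 0-based pixels, origin top-left, x rightward, y
  downward; physical coordinates are `pixel × pixel_size_nm` (µm in the
  listings).
* Rendering composes by darkening (minimum), so crossing rays of
  neighbouring cells do not create seams; tiles are written as
  uncompressed 8-bit TIFF, making determinism byte-testable.
* NCC denominators are floored at 1e-9; flat windows score ~0 rather than
  NaN. Empty detection lists, empty graphs, blank patches and zero-cell
  phantoms are all valid and tested.
* `split_examples()` clamps so neither side is empty;
  `node_removal_curve()` defines transfer at fraction 0 as 1 even for
  graphs with zero intact efficiency.

## Problem sizes

The shipped benchmark and tests use: a 200-object phantom on an 1824² px
panorama (the acceptance benchmark, ~30 s end to end), 20-cell phantoms on
~900² panoramas for detector properties, 200-case property sweeps for NMS
and efficiency oracles (≤ 12 boxes, ≤ 8 nodes), 20 random phantoms for the
stitching round trip, and 15–20-node graphs with 5–25 replicates for curve
properties. These sizes were chosen so the whole suite runs in about a
minute on one CPU while every property is exercised at a scale where its
brute-force oracle is exact.

## Known limitations

* The phantom is a null model; no claim transfers to real mSEM data
  without recalibrating soma geometry, intensity and noise.
* Process counts from single 2-D sections undercount 3-D dendrites; no
  correction is attempted, and process count is itself an imperfect
  viability surrogate.
* The hexagonal layout's edge scallops mean "complete coverage" holds
  only for rectangular layouts.
* The stitcher trusts recorded coordinates; there is no illumination
  correction or sub-pixel registration, and multi-terabyte streaming is
  out of scope.
* The transfer metric and linking rule are stand-ins chosen for
  testability; published curves for the real network are not recoverable
  and are not used as targets.
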