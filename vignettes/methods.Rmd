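---
title: "Methods: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`wormvision` quantifies four *C. elegans* plate phenotypes — survival,
locomotion speed, body length and egg laying — from ordinary dissecting
scope images and videos. This vignette records the models behind each
engine, the parameters that matter and why their defaults are what they
are, the numerical choices, and what the simulator-based validation does
and does not demonstrate.

## Shared imaging core

**Coordinates.** All code uses 1-based `(row, col)` matrix indexing with
inclusive bounding boxes — the natural R convention. Row 1 is the top of
the image; intensities are integers in 0–255.

**Adaptive thresholding.** Segmentation everywhere is local-mean
(integral-image) thresholding: a pixel is foreground when
`I < mean_window × (1 − f)`. Because the reference is a local window, the
rule survives shadowed wells, the bright/dark structure of an OP50 lawn,
and smooth illumination gradients — a single global threshold does not.
The window defaults to one eighth of the image's smaller dimension
(comfortably larger than any worm, smaller than illumination structure)
and the offset fraction `f` to 0.15, a standard choice for this family of
algorithms; both are exposed in every engine's parameter object. The
summed-area table makes the cost independent of window size. Truncated
windows at the borders use the true pixel count, so border behavior is the
same as an explicit per-pixel mean (the test suite checks exact agreement
with a brute-force oracle).

**Labeling and morphology.** Connected components come from
`EBImage::bwlabel` (4-connected), with 8-connectivity obtained by merging
diagonally adjacent labels through a union–find over the label adjacency
pairs; a brute-force pixel-level union–find serves as the test oracle.
Each region carries area, centroid, bounding box, boundary-pixel
perimeter, and an eccentricity plus equivalent-ellipse semi-axes from the
central second moments.

**Skeletonization.** Zhang–Suen thinning, followed by a condensation pass
that removes residual 2-pixel staircase redundancy: a pixel is deleted
when it is not an endpoint and its Yokoi connectivity number (for
8-connected foreground) is 1, processed in four checkerboard phases so
parallel deletions cannot disconnect the curve. The condensed skeleton may
cut a one-pixel corner (an L-corner becomes a diagonal step); for length
measurement this is a sub-0.1 px effect. Branch points are skeleton pixels
with three or more skeleton neighbors; endpoints have exactly one. Short
spurs — thinning artifacts of boundary roughness — can be pruned by
walking inward from each endpoint and deleting walks that reach a branch
point within the pruning length.

**Edges and contours.** Canny edge detection (Gaussian blur, Sobel
gradients, non-maximum suppression quantized to four directions,
hysteresis linking through 8-connected components) feeds the egg counter's
single-egg stage. Contour repair is morphological closing with a disc
sized to bridge breaks up to `max_gap`, then `EBImage::fillHull`.

## Simulator

Virtual worms are constant-thickness bands swept along a sinusoidal
midline: lateral offset `A sin(2πu/λ + φ)` over a centered support
`u ∈ [−E/2, E/2]`. Two properties make the ground truth exact:

* **Centroid exactness.** When the support holds an integer number of
  waves (`E = kλ`), the curve centroid equals the nominal worm position
  for *every* phase, so a moving worm's true centroid advances at exactly
  its configured speed while the phase modulation only changes posture.
  Video worms default to one full wave (`k = 1`), amplitude 4 px, body
  length 40 px, thickness 3 px — proportions of an adult at 20 µm/px on a
  640×480 frame. Positions are kept in floating point; rounding happens
  only at rasterization.
* **Analytic arc length.** Length-plate manifests record the arc length
  by adaptive quadrature of `∫√(1 + w′(u)²) du`; because the amplitude is
  proportional to the support, the support solving a target arc length is
  a closed-form rescaling.

Placement is seeded rejection sampling. For videos the whole *trajectory*
is checked: no worm leaves the frame and all pairwise clearances hold for
every frame, so validation videos measure tracking identity rather than
collision handling (identity re-linking across collisions is explicitly
out of scope). Time-lapse pairs displace movers by 10 px — deliberately
less than a body length so a mover's old and new silhouettes stay
connected in the difference image; full-body displacements would make the
vacated silhouette a separate difference blob, which the counting engine
would have to (and does) reject by checking that a recovered region is
dark in the second image.

Egg plates render eggs as crisp dark ellipses (semi-axes about 5 × 3.25 px
at the egg-assay calibration of 5 µm/px, ±12 % jitter, gray 60–160 on a
200 background), a configurable fraction placed in touching pairs/triples,
plus two debris classes: lumpy unions of dark discs (gray 40–90) and thin
curvilinear track-like marks (gray 90–150) that emulate surface scratches
from crawling worms.

The simulator emulates geometry, intensity contrast, sensor noise
(Gaussian, sd 6) and clutter. It does **not** emulate optics (point-spread
blur, vignetting), omega turns or reversals, worms crawling along the dark
well wall, or developmental size variation. Passing the validation suite
therefore demonstrates correctness of the measurement pipeline under
realistic contrast and clutter, not robustness to every real-plate
artifact; the engines' parameters are exposed precisely because real rigs
differ.

## Lifespan engine

A worm-sized region of the second image is "moving" when the number of
changed (difference-foreground) pixels inside it reaches
`max(10, 0.25 × area)` — a fraction of area rather than a fixed count so
the evidence requirement scales from L4 to adult. Worm size limits default
to 40–2000 px² at 20 µm/px. The difference image is the *absolute*
difference binarized with bright-object polarity, which sidesteps any
choice of subtraction order. Difference components of worm-like size that
do not intersect any candidate's bounding box are added as extra movers,
recovering worms fused with large dark debris in the second image — with
the guard that at least 30 % of such a component must be foreground in
the second image (the worm must *be* there; vacated silhouettes are
background and would otherwise double-count).

The step-wise decrease filter is the right-to-left running maximum — the
minimal monotone correction that never lowers a later, more trustworthy
count; it is idempotent. Deaths are assigned to the day of the observed
drop (the first scan that detects the transition; the alternative — the
preceding day — is unknowable from daily scans), and mean lifespan is the
death-weighted mean day. A series with no observed deaths has an undefined
mean lifespan and is flagged censored rather than silently zeroed.

## Locomotion engine

Frame detections keep regions with worm-like area and eccentricity ≥ 0.7
(a bent adult still projects an elongated second-moment ellipse; round
debris does not). Association is greedy nearest-centroid, gated by
`max_step` = 10 px/frame and ±60 % area change, ties broken by the smaller
area difference. A track ends on: contested region or region larger than
1.6× the track's running median area (collision/merge), bounding box
touching the frame edge (boundary), no gated region (lost), or video end.
Tracks shorter than 14 frames (2 s at 7 fps) are discarded.

Trails are smoothed by least-squares cubic fits over sliding 7-sample
windows with 3-sample overlap, cross-faded with triangular weights —
enough to suppress frame-to-frame centroid flicker without distorting
genuine curvature. Velocity uses the smoothed path (that is the stated
purpose of smoothing) but sums step distances at a 14-frame stride
(2 s): per-frame summation lets residual jitter accumulate into a
spurious random-walk length that biases slow worms high by tens of
percent, while 2-s chords leave real path curvature (radii far above one
chord) intact. The remaining oscillation source is physical: the
pixel-area centroid of an undulating body breathes by a fraction of a
pixel as pixel density shifts with local slope. Trails whose whole
smoothed extent fits in a 5 px box are excluded from population statistics
as non-moving objects.

With the rig's 20 µm/px and 7 fps, one pixel per frame is 140 µm/s; speeds
below ~0.25 px/frame approach the rasterization floor, which is why the
validation ladder starts there.

## Length engine

Candidates pass area (100–4000 px² at 20 µm/px; raised for the large
synthetic worms of the validation plates) and bounding-box filters, then
are skeletonized. The body half-width is estimated robustly as the
*median* distance-transform height along the raw skeleton — the maximum
would be inflated by an attached egg, which must not raise its own
pruning threshold. If the skeleton branches, spurs up to
`1.4 × half-width + 2` px are pruned: boundary-roughness spurs run about
half a body width, while forks induced by an attached egg or crossing worm
run a full width or more and survive, so the candidate is rejected as
`branched` — consistent with treating distorted skeletons as invalid
findings to be removed, not repaired.

The exported `skeleton_length()` is the pixel-tracing metric: unit steps
horizontally/vertically, √2 diagonally. For the *reported* measurement,
`measure_worms()` smooths the traced path locally (11-pixel windows)
before summing Euclidean steps: the raw 8-connected chain metric
systematically overestimates oblique digital curves — up to +8 % at
22.5°, about +5.5 % averaged over orientations — an error far larger than
the accuracy the method achieves, while smoothing removes exactly that
staircase quantization. Tips are then extended: thinning stops near the
center of each rounded tip, so the path is extended along the terminal
direction to the silhouette edge and the half-width of the rounded cap is
taken back off. The toggle `tip_correction = FALSE` reproduces the
uncorrected behavior. Fatness (area / skeleton length ≈ mean width,
default band 2–8 px at 20 µm/px) rejects compact blobs and hair-like
marks.

Validation plates draw worms with arc lengths 600–1500 px on
2200×2200 px canvases (assembled-well scale), thickness 9 px, amplitudes
4–10 % of the support and 1–2 body waves; 46 worms across six plates
mirror the original study size. Rotation robustness (same capsule at 0°,
30°, 45°, 90° within 3 %) and exact scale linearity are asserted
separately in the unit suite.

## Egg engine

The five stages and their parameters:

1. **Singles.** Canny (thresholds 15/40 on gradient magnitude), gap
   closing (2 px), fill, label. A single egg must be ellipse-consistent
   (pixel area within 18 % of its moment-equivalent ellipse area —
   true for real filled ellipses, false for lumpy debris), solid
   (solidity ≥ 0.85), eccentricity 0.35–0.92, and of plausible egg size.
   The size band comes from biology: eggs are stereotyped (~50 × 30 µm),
   so a calibrated image bounds the footprint (0.35–2.5× the nominal
   area at the image's µm/px). Among survivors, the largest
   mutually-similar group in area and gray value anchors the priors —
   eggs on one plate are near-uniform while debris fragments are
   heterogeneous. Each anchor egg is re-measured at its own midpoint
   threshold because the filled Canny contour overestimates the footprint
   by the closing dilation. A plate with no plausible candidates at all
   counts zero; a plate with candidates but no valid single aborts with a
   `wv_no_priors` error rather than reporting a silent zero.
2. **Priors.** `ref_area`, `ref_gray`, the plate-specific eccentricity
   band, and the singles' gray range.
3. **Multi-thresholding.** Global binarization at every level of 30–230
   step 10 (21 levels; at least 10 required). Levels where foreground
   exceeds half the image (background flood) are skipped.
4. **Morphology per level.** Singles: area within 0.5–1.5× `ref_area`,
   plate eccentricity band, ellipse consistency within 25 %. Aggregates up
   to 5× `ref_area` are accepted as egg *chains* only if their
   distance-transform half-width matches the egg minor radius
   (0.6–1.45×) — thin track marks fall below, lumpy debris above — and
   their major extent is consistent with `k = round(area/ref_area)` eggs
   (an egg fused with a long track mark is too extended and must not be
   split; `k ≥ 3` eggs cannot pack into less than half a chain's extent).
   Blobs darker than any egg the plate exhibits (25 gray below the
   singles' range) are debris and skipped.
5. **Clustering.** Greedy density-seeded grouping: repeatedly seed at the
   detection with the most neighbors within `merge_radius` and claim
   them. Unlike single linkage this cannot chain two adjacent touching
   eggs together through intermediate jittered split points. The default
   radius is half the reference equivalent diameter (~4 px): large enough
   to absorb split-point jitter, small enough that touching eggs (centers
   one minor axis apart, ~6.5 px) stay distinct. A cluster needs
   detections at ≥ 3 distinct levels *and* must persist to within 45 gray
   of the background: an isolated egg remains its own component until the
   threshold nearly reaches the background, whereas an egg-sized lobe of
   a larger dark mass merges into its parent once the threshold passes
   the mass's gray value.

Residual errors are dominated by debris that genuinely mimics an egg
chain — egg-wide, egg-dark, chain-proportioned — and by clusters whose
split count is off by one; both are also the practical failure modes on
real plates, where accuracy of a few eggs per plate is the realistic
envelope. `egg_laying_rate()` implements the eggs/worm/hour arithmetic of
the timed assay.

## Reports, assembly, corrections

Wells scanned as 3×4 tiles of 640×480 px assemble row-major into
1440×2560 mosaics (overlap default 0; cropped when stated). All reports
are UTF-8 TSV with a comment header carrying the md5 of the run config,
so identical inputs and config provably yield identical files. Manual
inspection is file-based: a corrections TSV (`delete`/`edit`/`add` by
record id) is validated atomically — one unknown id rejects the whole
file — and applied with an audit column. This is faithful to the
function of interactive inspection without a GUI.

## Validation protocol sizes

The acceptance suite runs: 11 videos (30 s, 7 fps, 640×480, six worms
each, speeds 0.25–2 px/frame) for velocity; one 20-worm two-cohort video
for track recovery; 46 worms across six plates for length; 42 plates of
10–80 eggs (30 % clustered, 5–15 debris) for egg counting; and 26 wells
spanning 0–100 movers (plus 5–20 stationary worms and 3–8 debris) for
moving-worm counting — the original studies' sample sizes. All randomness
derives from a single seed; identical seeds give bit-identical assets.

## Known limitations

* Identity is not re-linked across collisions; crossing worms end both
  tracks (by design — velocities from partial tracks remain unbiased).
* The lifespan engine measures *healthy* (moving) lifespan: paralyzed but
  living animals are scored dead, and worms at the dark well edge are
  invisible — both inherent to movement-based scoring.
* Egg counting needs at least one isolated single egg per image to anchor
  priors; it aborts loudly otherwise.
* The rounded-tip length correction assumes blunt tips; for sharply
  tapered tips disable `tip_correction` (lengths then bias low by about
  one body width).
* Speeds below ~0.25 px/frame are at the calibration floor of a 20 µm/px
  rig.
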