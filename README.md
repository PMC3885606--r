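# wormvision

Automated image analysis for *Caenorhabditis elegans* plate phenotyping.

Manual scoring of worm assays — poking animals with a platinum wire to
count survivors, measuring bodies in an image editor, counting eggs under
a dissecting scope — is the throughput bottleneck of nematode genetics.
`wormvision` replaces those bench steps with four image-analysis engines
that consume ordinary plate images and videos:

* **Lifespan** — counts *moving* (living) worms from two images of the
  same well taken ~2 minutes apart. The absolute difference image is
  binarized by adaptive local-mean thresholding; a worm-sized region of
  the second image is alive when enough changed pixels fall inside it, and
  movers fused with dark debris are recovered from the difference image
  itself. Daily counts are made monotone with the step-wise decrease
  filter `n'(t) = max(n(t), n(t+1), …)` and summarized as a death-day
  distribution and mean lifespan.
* **Locomotion** — tracks every moving worm through a video by greedy
  nearest-centroid association, smooths each trail with piecewise cubic
  least-squares fits, and reports per-track and population velocity
  `v = path length / elapsed time` in µm/s, with histogram and cumulative
  distribution tables. Trails confined to a tiny bounding box are excluded
  as non-moving objects.
* **Length** — measures body length from a still image as the traced
  length of the branch-free skeleton curve through the middle of the worm
  (thinning → spur pruning → path tracing; steps count 1 horizontally or
  vertically and √2 diagonally via `skeleton_length()`), with local path
  smoothing and rounded-tip extension for the reported measurement.
  Branched skeletons (worm touching an egg or another worm), and blobs
  failing area, bounding-box or fatness (area per skeleton length) limits,
  are flagged rather than measured.
* **Egg** — counts eggs with a multi-threshold pipeline: isolated single
  eggs found by Canny edge detection and contour filling set the reference
  egg (size, gray value, ellipse shape); the image is then binarized at
  many gray levels (default 30–230 step 10), blobs are morphology-filtered
  at each level with small aggregates split into `round(area / ref_area)`
  eggs, and the pooled detections are clustered across levels, keeping
  locations seen at enough distinct thresholds.

A deterministic **simulator** generates the validation data: videos of
sinusoidal virtual worms moving straight at constant speed in random
directions, still plates of worms with analytically known arc length
(numeric quadrature of the generating curve), egg plates with touching
clusters and debris, and time-lapse pairs with a known number of movers —
each with a ground-truth manifest, so every engine is testable against
known truth. Batch processing, 3×4 tile assembly into well mosaics,
TSV reports and file-based manual corrections round out the workflow, and
`inst/cli/wormvision.R` exposes everything as a command-line tool.

## Worked example

```r
library(wormvision)

# Lifespan: a simulated well with 7 moving and 7 still worms
pair <- render_lifespan_pair(n_moving = 7, n_still = 7, seed = 42,
                             canvas = c(720, 1280))
count_moving_worms(pair$img1, pair$img2)
#> <moving_worm_result> 7 moving (7 flagged ROI + 0 recovered), 14 candidate ROI(s)

# Daily counts -> monotone series -> survival summary
counts <- stepwise_decrease_filter(c(48, 50, 47, 41, 30, 31, 18, 7, 0))
counts
#> [1] 50 50 47 41 31 31 18  7  0
survival_summary(counts, days = 0:8)
#> <survival_series> days 0..8, 50 -> 0 worms
#>   mean lifespan: 5.50 days

# Locomotion: five virtual worms at 1 px/frame, 7 fps, 20 um/px
cfg <- sim_video_config(rep(1, 5), seed = 7, frame_size = c(240, 320),
                        n_frames = 70)
v <- render_worm_video(cfg)
track_video(v, tracker_params(fps = 7, scale = 20))$summary
#> <velocity_summary> 5 track(s) (+0 excluded), mean 140.0 um/s, sd 1.2

# Eggs: 30 true eggs, 30% in touching clusters, 8 debris objects
ep <- render_egg_plate(30, cluster_fraction = 0.3, debris_count = 8,
                       seed = 42)
count_eggs(ep$image)
#> <egg_count_result> 30 egg(s) (38 raw cluster(s) before the occurrence filter)
```

The locomotion mean is exactly what the kinematics predict: 1 px/frame ×
7 frames/s × 20 µm/px = 140 µm/s. The worked survival series says half the
cohort was dead by day 5–6 and the death-weighted mean lifespan is 5.5
days of adulthood.

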