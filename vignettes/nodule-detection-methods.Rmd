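---
title: "Ant-colony lung-nodule detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ant-colony lung-nodule detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Lung nodules appear in a CT slice as small, roughly circular bright blobs a
few pixels across, embedded in darker parenchyma and surrounded by
confusable bright *line* structures (lung-field edges, vessel walls).
Detecting them is a chain of stages, and `noduleant` implements the whole
chain:

1. **edge detection** — seven interchangeable detectors: Otsu thresholding,
   watershed, seeded region growing, ant colony optimization (ACO), and
   three ACO variants (refined, logical, variant);
2. **candidate generation** — clusters of edge pixels become nodule
   candidates; thin elongated clusters are rejected as lines ("black
   circular neighbourhood" analysis);
3. **intensity filtering** — candidates whose surrounding region in the
   *original* image is not bright enough are dropped;
4. **clustering** — surviving candidates are grouped into benign and
   malignant clusters by GA-refined k-means (primary) or single-linkage
   hierarchical clustering (comparison);
5. **evaluation** — recall ratio, sensitivity, specificity, accuracy and
   precision against ground truth, at object and pixel level.

Because no public dataset accompanies the method, the package ships a
seeded phantom generator (`generate_phantom()`, `standard_suite()`) that
renders CT-like slices with exact ground truth; every stage is tested
against those phantoms.

## The ACO edge model

Ants walk on the pixel lattice.  Pixel `j` carries pheromone `tau(j)`
(initialized at `tau0`) and a static heuristic attractiveness `eta(j)`,
the normalized local intensity variation: the largest absolute difference
across the four pixel pairs straddling `j` (vertical, horizontal, two
diagonals), divided by the image-wide maximum.  From its current pixel an
ant moves to one of the 8-neighbours it has not yet visited, with
probability proportional to

    tau(j)^alpha * eta(j)^beta

(uniform among admissible neighbours when every weight is zero; an ant
with no admissible neighbour respawns at a fresh random pixel).  After
each of `n_iterations` construction rounds the field evaporates,
`tau <- (1 - rho) * tau`, and every visited pixel receives `rho * eta(j)`.
The accumulated field is quantized to 256 bins and binarized at its Otsu
threshold, reusing the same histogram-splitting code as the Otsu detector.

Defaults (all exposed in `aco_params()`):

| parameter       | default          | meaning                                  |
|-----------------|------------------|------------------------------------------|
| `n_ants`        | `round(sqrt(HW))`| one ant per ~`sqrt(H*W)` pixels          |
| `n_iterations`  | 10               | construction/evaporation rounds          |
| `steps_per_ant` | 40               | moves per ant per round                  |
| `alpha`         | 1.0              | pheromone exponent                       |
| `beta`          | 2.0              | heuristic exponent                       |
| `rho`           | 0.1              | evaporation rate, strictly in (0, 1)     |
| `tau0`          | 0.1              | initial pheromone, > 0                   |

These are the standard values of the ACO image-edge literature; the
published description of this detector family leaves the transition and
deposit rules unstated, so the scheme above is a faithful member of the
genus rather than a verbatim reconstruction, and every constant is a
visible knob.  Determinism is part of the contract: a single random
stream (seeded by `seed`) drives spawn positions and moves in a documented
order — iterations outermost, ants in index order, moves in step order —
so equal seeds give bitwise-equal pheromone fields.

### The variants

* **Refined ACO** (`refined_aco()`): feed the binarized output back in as
  a grayscale image (`TRUE -> 1.0`) and re-run, stopping when the Hamming
  fraction between consecutive rounds drops to `tol` (default 0.01) or
  after `max_rounds` (default 5).  Round `r` is seeded with
  `seed + r - 1`, so a one-round run equals plain `aco_edges()` and each
  round is independently reproducible.  The pheromone field is restarted
  each round; carrying it across rounds would let the first round's noise
  anchor later rounds, which is the opposite of what refinement is for.
* **Logical ACO** (`logical_aco()`): pixelwise XOR of the final and
  pre-final refined rounds — the set of pixels still changing when
  iteration stopped.  A single-round run has no pre-final map, and the
  operation refuses it rather than XOR-ing with an implicit blank.
* **Variant ACO** (`variant_aco()`): run ACO on the *Otsu edge map* of
  the image instead of on the raw image.  The binary input has zero
  heuristic attractiveness away from structure, so the stray deposits
  that plain ACO accumulates over low-level intensity noise never happen
  — this is the mechanism behind its lower false-positive count, which
  the acceptance suite verifies as a property (variant FP total ≤ plain
  ACO FP total on the fixed phantom suite).

## From edges to candidates

`find_components()` partitions edge pixels into 4- or 8-connected
components (default 8: diagonal bridges merge, reducing spurious splits).
A component is rejected as a *line* when its bounding-box fill ratio
`area / (extent_major * extent_minor)` falls below `fill_ratio_min` or its
bounding-box aspect exceeds `aspect_max`: one-pixel lung-edge lines have
extreme aspect or sparse boxes, compact blobs have neither.  Survivors
become candidates with

* equivalent diameter `2 * sqrt(area / pi)`, rejected above `d_max`
  (default 5 px — the method's "up to 5 units" size limit, with units read
  as pixels; re-scan it for other image resolutions);
* centre = pixel-rounded centroid (ties toward the smaller index), or the
  bounding-box centre under `center_policy = "bbox"`;
* shape class spherical/elliptical by bounding-box aspect against
  `ecc_threshold` (default 1.5).

## Intensity filtering

For each candidate, `build_feature_matrix()` measures the mean of the
*original* raster over a disk around the candidate centre (pixels whose
centre lies within the radius; the radius is the candidate's equivalent
radius under the default policy, or a fixed value).  Candidates whose
mean exceeds `intensity_threshold` (default 0.5 of the normalized range)
survive and carry `(mean_intensity, size, shape[, age])` into clustering.
With `center_search_radius > 0` the disk is placed at the best position
within that distance of the candidate centre — see the calibration notes
below for why the pipeline uses this.

## Clustering

Feature columns are standardized to zero mean and unit spread (constant
columns stay at 0) because pixel counts and `[0,1]` intensities are
incommensurate; unstandardized distances would be size-dominated.

* `kmeans_init()` runs Lloyd iterations from `k` distinct seeded random
  points, re-seeding an emptied cluster with the farthest point.
* `ga_refine()` encodes the `k` concatenated centres as a real-valued
  chromosome with fitness `1 / (1 + SSE)` — the standard GA-clustering
  choice, monotone in clustering quality (the method's own fitness is
  deferred to an inaccessible companion reference, so this is a documented
  stand-in).  The population starts at the k-means chromosome plus
  gaussian perturbations; generations apply size-2 tournament selection,
  single-point crossover anywhere on the gene vector, per-gene gaussian
  mutation (scale 0.1 x column spread), and elitism.  Elitism makes the
  best fitness non-decreasing, so the GA can never return a worse SSE
  than its k-means initializer — both facts are asserted in the tests.
* `hierarchical_cluster()` is single-linkage agglomeration (via
  `stats::hclust`), the comparison method.
* `label_malignancy()` names the cluster with the larger mean size
  malignant (ties broken by mean intensity), reflecting that malignant
  nodules run larger and brighter than benign ones.

## Evaluation

Object mode matches candidates to true nodules greedily by ascending
centre distance, one-to-one, within each truth's own radius by default
(so matching scales with nodule size).  TP/FP/FN follow; there is no
object-level negative class, so specificity is undefined there and
object-mode accuracy is the Jaccard-style `tp / (tp + fp + fn)`.  Pixel
mode tallies the full per-pixel contingency (detected candidate pixels vs
the truth mask) and supplies the TN that specificity and the conventional
accuracy need.  The *recall ratio* is detected candidates / true nodules;
over-detection pushes it above 1, which is why it is reported separately
from sensitivity.  Zero denominators yield `NA`, never a division.

## The phantom generator

`phantom_spec()` defaults describe the regime the candidate detector
targets: 256 x 256 slices, background 0.2, six non-overlapping nodules of
3-5 px diameter (30% elliptical at 2:1 axis ratio, area-preserving),
contrast 0.5, three one-pixel bright polylines standing in for lung edges
and vessels, gaussian noise sigma 0.02, half the nodules malignant.
Malignant nodules draw from the upper half of the diameter range at +10%
contrast, benign from the lower half, so the generator's labels are
recoverable from size/intensity — which is what the clustering stage
claims to exploit.  Nodules are placed by rejection sampling with 5 px of
clearance between edge *bands* (not just the nodules themselves) and
lines are kept 6 px clear of nodule centres, so each ground-truth object
maps to its own edge component.  Rendering is anti-aliased by 4 x 4
subpixel coverage; the truth mask is coverage >= 0.5.

What the phantoms deliberately do **not** emulate: anatomy (lung lobes,
rib shadows), Hounsfield-unit physics, irregular nodule shapes, textured
parenchyma, and overlapping structures.  Tests passing on phantoms
therefore demonstrate the chain's correctness and its behaviour under
controlled contrast/noise, not clinical performance.

## Numerical choices and degenerate inputs

* Intensities quantize to 256 bins by `round(v * 255)`; the pheromone
  field quantizes min-max over its own range, which makes binarization
  invariant under positive affine rescalings of the field.
* Otsu on a single-occupied-bin histogram has no split: the bin is
  returned with a warning, and the detectors then produce empty edge maps
  (constant image -> no edges).
* The Otsu argmax breaks ties toward the smaller threshold.
* Watershed floods the (optionally 3 x 3 mean-smoothed) central-difference
  gradient magnitude from its regional minima (8-connected plateaus with
  no lower neighbour), through 4-neighbours in (height, insertion-order)
  priority; pixels reached by two basins are dams.  4-connected flooding
  guarantees dams 4-separate basins.  Gradients below `gradient_floor`
  (default 0.02) count as flat, so residual noise on flat terrain does
  not spawn a basin per dimple — without this, any noisy flat background
  oversegments into thousands of basins regardless of smoothing.
* Region growing admits a FIFO frontier pixel when it is within
  `tolerance` of the running region mean, each pixel tested once; the
  boundary convention treats out-of-image neighbours as outside the
  region (a region filling the raster has the raster border as its edge),
  while the threshold detectors replicate the border (only genuine
  intensity transitions become edges).
* Rounding of candidate centres sends exact halves to the smaller index.

## Pipeline calibration for the phantom regime

The standalone module defaults describe the published rules on clean
inputs.  The pipeline (`pipeline_config()`) overrides four of them, all
for one reason: the ACO edge response is not a one-pixel contour but a
band ~2 px wider than the underlying structure (any symmetric
local-variation heuristic lights both sides of a step), and because
deposits evaporate, the binarized band is often a *partial, ragged ring*.

* `d_max = 8` px: a 5 px nodule's edge component, band included, reaches
  equivalent diameter ~7; the 5 px limit applies to the nodule, not to
  the detector's response to it.
* `fill_ratio_min = 0.3`: ragged partial rings fill their bounding box
  more sparsely than solid blobs; genuine lines are still caught by the
  aspect test and, decisively, by the intensity filter.
* `center_policy = "bbox"`: the centroid of an open arc is pulled toward
  the arc; the bounding-box centre estimates the underlying blob centre
  with much less bias (a property test demonstrates this on a half-ring).
* intensity probe: fixed radius 1.5 px with `center_search_radius = 2`
  and threshold 0.5.  The band-inflated equivalent radius would dilute a
  true nodule's core with background; a small core probe placed at the
  best position within 2 px separates cleanly, because a bright disk
  always presents a fully-covered probe somewhere near the candidate
  (mean ~ background + contrast) while a one-pixel line covers at most
  ~`2/(pi*r)` of any probe disk (mean ~ background + 0.4 x contrast).

These settings were fixed once, from the geometry above, and are recorded
in every run manifest.

## Problem sizes

The test-suite checks run at sizes chosen to keep the whole suite fast
while still exercising the defaults: oracle comparisons on 1,000 random
histograms, 200 random 64 x 64 rasters, and 100 point sets; GA contracts
on 20 two-cloud datasets (n = 100 each); and the end-to-end properties on
the fixed 10-phantom suite at the full default spec (256 x 256, six
nodules, three lines).  `scripts/acceptance.R` re-runs the seven-method
comparison and clustering from scratch on a freshly seeded suite.

## Known limitations

* The ACO parameterization is a canonical reconstruction; anyone matching
  the original implementation's pixel-level output will need its exact
  transition and deposit constants, which are not public.
* The candidate-size unit ("5 units") is taken as pixels; at other
  resolutions `d_max` must be re-scanned.
* Hierarchical clustering and the GA share the same feature space; with
  fewer than `k` distinct feature rows the pipeline skips clustering and
  says so rather than fabricating clusters.
* Object-level specificity does not exist (no negative objects); pixel
  mode is the defensible reconstruction used for the comparison table.
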