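---
title: "Estimating corn-ear consumption from instance masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating corn-ear consumption from instance masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CobQuant)
```

## The problem

Feeding-preference experiments offer wild animals a pair of corn ears side by
side and photograph the stand at intervals. The measurement of interest is how
much of each ear has been eaten, expressed as a percentage of the visible ear
area, and which of the two ears was eaten more. Manual scoring of thousands of
community-contributed photographs is slow and observer-dependent, so the
measurement is automated on top of instance segmentation: a model (or an
annotator) delineates each corn ear and each exposed bare-cob region with a
per-instance pixel mask, and the consumption of an ear is a pure pixel ratio

$$ C \;=\; 100 \cdot \frac{\sum_{\text{bare parts}} |\text{mask}|}
                         {|\text{whole ear}|} \quad (\%) $$

CobQuant implements everything downstream of (and around) the segmentation
model: annotation I/O, grouping of part instances to physical ears, the ratio
itself, left-versus-right verdicts, and a full evaluation suite — plus a
synthetic scene generator that makes the whole pipeline testable without the
original photographs or a trained network.

## Labeling approaches

Two labeling schemes for the same scene are supported, mirroring how such
datasets are annotated in practice:

* **Approach 1** — classes `whole_corn` and `bare_cob`. Each bare part is
  assigned to the ear whose whole-corn mask overlaps the largest fraction of
  the bare mask (at least the assignment threshold, default 0.5). We use mask
  overlap rather than raw bounding-box containment: boxes of side-by-side
  ears frequently intersect, while mask overlap is strictly more specific and
  reduces to the box rule when boxes are disjoint.
* **Approach 2** — classes `corn_kernel` and `bare_cob`; the whole ear is not
  a class but the union of its parts. Parts are clustered into ears by single
  linkage on a box-overlap graph (boxes dilated by a 5-pixel margin), and
  $C = 100\,\Sigma|\text{bare}| / (\Sigma|\text{bare}| + \Sigma|\text{kernel}|)$.

On ground-truth masks, where kernel and bare regions exactly partition each
whole ear, the two approaches agree ear for ear; the package tests assert
this identity.

Degenerate inputs are handled explicitly: a bare part overlapping no ear above
threshold is reported (never silently dropped); bare detections with no whole
ear at all are a grouping error that feeds the outlier logic; overlapping bare
detections are unioned, not double-counted, and the Approach-1 numerator is
clipped to the whole-ear mask so protruding noise cannot push $C$ above 100.

## Coordinates and rasterization

All pixel geometry uses one convention: 0-based (row, col) indices, half-open
bounding boxes, and polygons as $(x, y)$ vertex lists in pixel units (the VIA
annotation tool's order) with the center of pixel $(r, c)$ at
$(c + 0.5,\; r + 0.5)$. A pixel belongs to a polygon's mask iff its center
lies inside under the even-odd rule; centers exactly on an edge are resolved
by half-open scanline intervals, so abutting polygons never double-claim a
pixel. The scanline implementation is checked against a brute-force per-pixel
point-in-polygon oracle on random polygons.

Masks written back to VIA JSON are traced along pixel *edges* (not through
pixel centers), which makes the polygon → mask → polygon round trip lossless
for hole-free components — the property that lets a simulated dataset pass
through disk and still reproduce its truth table exactly. Components with
interior holes lose the holes with a warning; the generator is designed so
this never happens to its own output (consumed regions always touch the ear
outline, as real bite marks do).

Images of arbitrary resolution can be passed through the square-resize
convention used by fixed-input segmentation networks: the long side is scaled
to 1024 by bilinear interpolation and the short side zero-padded
symmetrically. Whether such a pipeline pads symmetrically or bottom-right is
not standardized; we chose symmetric padding and return the exact geometry
(scale and offsets) so external coordinates can be mapped either way. Masks
travel through the same geometry with nearest-neighbor sampling so labels
stay binary.

## The synthetic scene generator

The generator is the package's statistical stand-in for the study data: one
or two conical ears per frame (tapered polygon, blunted ends), kernel texture
as multiplicative noise plus a faint grid on a fixed-hue yellow base, bare
cob in a pale red-brown, backgrounds plain/textured/cluttered with optional
distractor shapes, image sizes drawn from 640×480, 1280×760 and 2048×1536
(the range reported for community-science photographs; the 4080×3072 extreme
is excluded from defaults to keep test runtimes reasonable). Ear length is
drawn as 38–55% of the short image side — a realism judgment recorded here,
not a measured value. Per-ear bare fractions are uniform on $[0, 1]$ by
default, or stratified over the pre-screening categories
`0-5% / 5-95% / 95-100%` by largest-remainder allocation; stratified draws
keep a safety margin inside the category bounds so pixel rounding can never
flip a realized category.

Two properties make the generator an oracle rather than a fixture:

* the bare-pixel budget of an ear is exactly `round(f × area)`, so the true
  consumption of every ear is exact by construction, and
* kernel and bare masks partition the whole-ear mask, so both labeling
  approaches see identical geometry.

Consumption patterns are either `top_down` (pixels consumed from the tip
downward, the typical squirrel pattern) or `patchy` (1–4 blobs grown from
seeds on the ear outline — guaranteeing several bare instances per ear, which
is what exercises the grouping logic). Everything is deterministic given the
seed; augmentation (flips, 90° rotations, Gaussian blur, per-channel color
multipliers) transforms masks and image by the identical pixel permutation,
so all downstream ratios are bit-identical under the geometric ops.

What the generator does **not** emulate: real lighting, occlusion by the
feeding stand, animals in frame, camera noise, and the irregular texture of
real kernels. Passing tests therefore demonstrate the correctness of the
estimation and evaluation machinery, not the accuracy of any particular
segmentation model on real photographs.

## The built-in color backend

To run the pipeline end to end without a GPU-trained network, a classical
backend classifies pixels by HSV ranges (kernel hue 35–75°, bare 0–32°, with
saturation/value floors separating the background), cleans each class map by
morphological opening and closing (disc radius 1), and promotes connected
components of at least 50 pixels to detections. Approach-1 whole-ear
instances are the components of the kernel ∪ bare map, mirroring how
Approach 2's classes sum to a whole ear. Scores are component areas
normalized by the largest component of the class — a deterministic ranking,
required because average precision needs an ordering. For that reason the
`--min-score` threshold (default 0.5) applies only to *external* detections,
whose scores are genuine model confidences; thresholding area ranks would
delete the small bare patch of a lightly consumed ear.

The default palette is deliberately separable so the backend is near-perfect
on clean scenes; the palette is a generator parameter, so stress tests can
degrade separability on purpose.

## Evaluation suite

* **Matching** is greedy: predictions in descending score order each claim
  the unclaimed same-class ground-truth instance of highest IoU, if that IoU
  reaches the threshold.
* **Weighted mean IoU** per class: within an image, matched IoUs are averaged
  weighted by ground-truth instance area (missed instances contribute 0),
  then images are averaged unweighted. Area weighting is our reading of
  "weighted" (large instances dominate, consistent with whole-ear IoU being
  much higher than bare-cob IoU in this kind of data); `weight = "uniform"`
  is available.
* **AP / mAP**: all-point interpolated area under the PR walk, thresholds
  0.50–0.95 in 0.05 steps; the default aggregation is per-image AP averaged
  over thresholds and images, with a pooled-dataset mode also provided (which
  of the two a given report means is often unstated; both are one flag
  apart). The pooled PR curve's area equals the pooled AP by construction,
  and the per-image implementation is tested against a brute-force oracle.
* **Consumption R²**: coefficient of determination of the least-squares fit
  of predicted on true consumption. Ears whose ground truth contains a class
  the prediction missed entirely (an undetected ear, or bare cob present in
  truth with no predicted bare instance) are *outliers*: flagged with a
  reason, retained in outputs, excluded from the fit. A constant prediction
  vector is defined to have R² = 0.
* **Left-right verdicts**: `left`/`right`/`equal` with a configurable
  tolerance defaulting to 0 — strict comparison, under which a 99%-vs-98%
  pair is classified toward the 99% side — summarized as a 3×3 confusion
  matrix against ground-truth verdicts.
* **Ablation harness**: stratified subsamples at increasing sizes, several
  repeats, a pluggable quality model standing in for training (default:
  ground-truth masks eroded, jittered and thinned with severity
  $4/\sqrt{n}$, so quality rises with sample size and small samples produce
  the occasional total miss), metrics aggregated as mean ± sd with two-sided
  Welch t-tests between consecutive sizes. Welch rather than pooled-variance
  is chosen because repeat-level variances visibly differ across sizes in
  this kind of experiment. The harness's contract — not the stand-in — is
  the tested content; GPU training is out of scope.

## Numerical choices and problem sizes

Left/right is decided by the horizontal centers of ear boxes; a vertical tie
breaks top-most-first with a logged notice. Empty∩empty IoU is 0 (matched
pairs always have nonempty ground truth). Tie-breaks in bare-pixel selection
are deterministic (row, then column), making every artifact byte-reproducible
from its seed. The package's own acceptance benchmark uses 50 scenes
(100 ears) per run and completes in about a minute; unit tests use 96×128 to
320×240 scenes so the full suite stays fast.

## Worked example

```{r example, eval = FALSE}
ds <- generateDataset(8, seed = 42, imageSizes = list(c(480L, 640L)))
sets <- runBackend(ds, backendConfig("color_cc"), approachUsed = 1)
report <- evaluateDataset(sets, ds)
report
```

The same workflow is available from a shell via the `inst/cli/cobquant.R`
wrapper (`simulate`, `segment`, `estimate`, `evaluate` subcommands), and
`scripts/acceptance.R` reruns the 50-scene benchmark from scratch.

## Known limitations

Synthetic scenes are far easier than real photographs; the color backend is a
desk-scale stand-in, not a replacement for a trained segmentation model, and
its accuracy claims apply to the synthetic palette only. Multi-label pixels
(an ear in front of another ear) are out of scope, as are weight- or
volume-based consumption, 3-D modeling, and linking the same ear across days.
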