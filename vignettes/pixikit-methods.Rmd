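---
title: "pixikit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pixikit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pixikit)
```

pixikit is a headless toolkit for the common loop of quantitative
bioimage analysis: import images, outline the objects in them, measure
the objects, train a classifier on a labeled subset, let the model label
the rest, correct its mistakes, and resume training. This vignette
documents the models and conventions behind each step — the choices a
user must know to interpret the numbers — and what the synthetic test
fixtures do and do not demonstrate.

## The project store and staged edits

A `Project` holds four entity collections — images, annotation objects,
kinds and categories — in id-keyed tables. A *kind* is a class of
measurable entities: the built-in `"Image"` kind for whole images, plus
user-registered object kinds (`"cells"`, `"glands"`, ...). Each kind owns
its categories, including a reserved, undeletable `"Unknown"` category
that houses unlabeled items; the classifier treats `"Unknown"` as "no
label yet", so an explicit unlabeled pool always exists. Every image and
object also carries a *partition* (`train`, `validation`, `inference`,
`unassigned`) describing its role in model development. Partitions apply
to objects as well as images: nothing in the data model distinguishes
them, and object-level classification needs the same bookkeeping.

Mutating operations (`addImages()`, `assignItems()`,
`registerCategory()`, ...) do not modify the committed state. They record
per-entity *field diffs* (or whole added entities) in a change set;
reading through the default `"staged"` view merges those diffs on the
fly. `commitProject()` folds the change set into the committed state and
clears it; `revertProject()` discards it, restoring the last committed
state exactly — a single-level commit/revert, not an undo history.
Storing diffs rather than entity copies keeps a round of model
predictions over thousands of items cheap to stage and cheap to revert.

A *split* selects items for measuring or training: a kind, optionally
narrowed by categories and/or partitions, with empty filters meaning
"all". `selectSplit()` returns ids in sorted order so that everything
downstream (measurement tables, training batches, exports) is
reproducible; adding a filter can only ever shrink the result.

Coordinates are 0-based and half-open throughout, x rightwards and
y downwards, matching the COCO convention so boxes survive export
unchanged. Pixel `(row r, col c)` spans `[c, c+1) x [r, r+1)` with its
center at `(c + 0.5, r + 0.5)`.

## Annotation operators

All operators act on one z-slice at a time and produce full-extent
binary masks; `maskToAnnotation()` crops a mask to its tight bounding
box, and re-inflating the crop is lossless by construction.

**Geometric shapes.** A pixel is foreground when its *center* lies
inside the shape; polygons use the even-odd rule. The pixel-center test
is unambiguous and makes a square polygon coincide exactly with the
rectangle of the same corners.

**SLIC quick-select.** `computeSuperpixels()` implements SLIC with
deterministic grid initialization (no RNG), compactness 10 and 5
refinement iterations by default. Cluster centers start on a regular
grid of spacing $S = \sqrt{N/k}$; each iteration assigns every pixel to
the nearest center within a $2S$ window under
$D = \sqrt{d_c^2 + m^2 (d_s/S)^2}$ and recomputes the centers. The color
distance $d_c$ is Euclidean over channels *rescaled to [0, 100]*: the
conventional compactness magnitudes assume Lab-range colors, and pixel
intensities here are [0, 1], so without rescaling any usable $m$ would
make the partition purely spatial. When the grid must be enlarged to
reach $k$ seeds, it grows in x first — a fixed, documented tie-break. A
final pass merges stray connected components into an adjacent label so
labels are spatially connected. `quickSelect()` then returns the union
of the superpixels under the seed points, never a partial superpixel.

**Flood fill (color tool).** 4-connected region growing from the seed;
a pixel joins when the Euclidean color distance (over channels) to the
*seed* color is at most the tolerance. The result always contains the
seed and is 4-connected by construction.

**Threshold tool.** Inside a user box, pixels whose channel-mean
intensity is below the threshold are selected (the dark-object
convention); an explicit `polarity = "above"` switch covers the common
fluorescence case of bright objects. Multichannel images are reduced by
the mean over channels, the simplest reduction consistent with the
grayscale description.

**Corrections.** `combineMasks()` is plain set algebra — `add` is union,
`subtract` is difference — so any tool's output can refine any other's.

## Measurements

Intensity statistics are computed per channel, for whole images or for
the pixels under an object's mask on the annotation's z-plane (the
plane the object was drawn on; other planes do not contribute). The
seven statistics are total, mean, median, standard deviation, MAD, and
the lower and upper quartiles:

* **MAD** is the median absolute deviation from the median,
  $\mathrm{MAD} = \mathrm{median}_i\,|x_i - \mathrm{median}(x)|$.
* **Quartiles** use the nearest-rank convention: the value at rank
  $\lceil 0.25\,n \rceil$ (resp. $\lceil 0.75\,n \rceil$) of the sorted
  pixel list. Nearest rank keeps the reported quartile a value an actual
  pixel attains, which interpolation would not; with interpolation-free
  ranks, "the intensity of the pixel for which 25% have lower values" is
  met up to the discreteness of the list.
* **Standard deviation** is the population form (divide by $n$): the
  pixels of an object are the whole population of interest, not a
  sample.

Object geometry comes in two layers. `primitiveGeometry()` counts
pixels: area is the foreground count; perimeter is the number of
*inner-boundary* pixels — foreground pixels with at least one background
(or out-of-extent) pixel among their 8 neighbors, i.e. the pixels a
3×3-box erosion removes; bounding-box area is the tight-box
width × height. Counting boundary against the full 8-neighborhood means
a diagonal pinch counts as boundary, which keeps the perimeter of
checkerboard-like irregular shapes from being undercounted.
`derivedGeometry()` then evaluates the closed forms

$$\mathrm{Extent} = A/A_{\mathrm{bbox}},\quad
\mathrm{EquivalentDiameter} = 2\sqrt{A/\pi},\quad
\mathrm{PED} = P/\pi,$$
$$S = \frac{P_{\mathrm{EQPC}}}{P} = \frac{2\sqrt{\pi A}}{P},\qquad
C = 1/S,$$

accepting non-integer inputs so that closed-form identities are exact:
for the analytic circle ($A = \pi r^2$, $P = 2\pi r$) sphericity and
compactness are exactly 1 at machine precision. A *rasterized* circle's
pixel perimeter is not $2\pi r$, so sphericity of rasterized disks is
only approximately 1 — which is why the exactness checks use analytic
inputs and why pixel-level claims (e.g. the plus-sign's compactness
exceeding 1) are made on fixture masks with enumerated ground truth
(area 45, perimeter 32, giving $C \approx 1.346$).

Geometry requires a mask and is therefore refused for the `"Image"`
kind; intensity measurements work for both levels. Results are cached
under a content hash of the underlying pixels/mask, so re-measuring is
free and any change to the data automatically invalidates the entry.
Split summaries report total, median and population standard deviation
per measurement (and channel), and are invariant to item order.

`plotSeries()` returns plot-ready numbers without rendering: histograms
use equal-width half-open bins `[lo, hi)` over the observed range with
the final bin closed (so counts always sum to n); scatter returns one
point per item with optional min-max-scaled size mapping; swarm returns
per-group value lists with an optional overlay of median, standard
deviation and the two quartiles, computed with the same conventions as
the intensity statistics.

## The classifier and the human-in-the-loop cycle

Two architectures are built in. `simple_cnn` is a small fully
convolutional stack — two blocks of (3×3 valid convolution, ReLU, 2×2
max-pool), 8 then 16 filters, global average pooling, and a dense
softmax layer — deliberately small enough to train in seconds on a CPU
at desk scale. `transfer_head` keeps the same stack as a *frozen*
feature extractor and trains only the final dense layer; the backbone
here is a seeded, randomly initialized frozen stack, which exercises the
frozen-backbone contract (backbone weights are bit-identical before and
after training) without requiring any pretrained download. Any frozen
feature extractor can stand in its place.

Items are standardized before entering the network: bilinear resize to
the configured input extent (pixel-center aligned), channel adaptation
(channel-mean to go down to 1, replication to go up from 1), and
per-item min-max to [0, 1]. Object items use their masked bbox crop on
their annotation plane, background zeroed.

Training is plain SGD with momentum 0.9 and a fixed learning rate,
minimizing categorical cross-entropy (additional losses can be
registered). The labeled pool is split into train/validation by
stratified sampling — per-class counts within one item of the target
fraction, falling back to a random split with a warning when a class has
a single item. One config seed drives everything random: the split, the
weight initialization and the per-epoch batch shuffle (keyed on the
*global* epoch number). Consequently `fit(a)` followed by `fit(b)` is
bit-identical to `fit(a + b)`: the momentum buffers live inside
`TrainingState` and are carried across calls, so resuming continues the
same trajectory rather than re-initializing. This is the property the
human-in-the-loop cycle relies on: `hitlRound()` fits on the currently
labeled items, predicts the `"Unknown"` pool, and *stages* the predicted
labels for review; corrections are ordinary `assignItems()` calls, and
the next round resumes training on the expanded labeled set.

`evaluateClassifier()` reports the confusion matrix (rows = truth),
per-class precision/recall/F1, accuracy (trace over total) and macro-F1
(the unweighted mean of per-class F1). Macro-F1 is the headline number
in the tests because it is insensitive to class imbalance; per-class
values are always available alongside.

## Synthetic fixtures: what they show and what they do not

`generateShapeScene()` renders disks, rectangles and plus-signs with
exact rasterized masks and closed-form geometry, optionally under
clipped additive Gaussian noise — enough to validate every measurement
formula and every selection operator against enumerable ground truth.
`generateClassDataset()` makes two-class image sets where classes differ
in mean intensity (0.3 vs 0.7 by default) and sinusoidal texture
frequency (2 vs 6 cycles, amplitude 0.15) under noise sd 0.1; with these
defaults even a fixed mean-intensity threshold at 0.5 separates the
classes, so the Bayes error is essentially zero. The classifier
recovery tests (macro-F1 ≥ 0.9 on held-out data within 30 epochs, three
seeds of three, with 50 images per class) therefore demonstrate that the
training loop *works* — gradients, resume, evaluation — not that the
architecture handles hard biological variation. Real data have
correlated noise, uneven illumination, morphology variation and class
overlap that these fixtures deliberately lack (no point-spread function,
no cell-shape simulation); results on them say nothing about absolute
accuracy on microscopy images. `generateHyperstack()` writes seeded
16-bit multi-page TIFFs in the channel-fastest page order the reader
expects, for exercising the declared-channel import path.

Test and acceptance problem sizes are deliberately desk-scale — images
of 32×32 for classification, scenes up to 64×64, 100–200 random masks
per property test, 15 epochs per training run — chosen so the whole
suite runs in well under a minute while still exercising every code
path at sizes where brute-force oracles are feasible.

## Interchange formats

**COCO.** Masks are traced to polygons at pixel-corner resolution: every
exposed pixel side contributes a directed edge (interior kept to the
right), and edges are chained into closed loops, preferring the
rightmost turn at pinch vertices so touching boundaries stay separate.
Holes appear as additional loops; import rasterizes all loops of an
annotation with even-odd semantics. Because polygons live on the corner
grid, export → import reproduces masks exactly for simple shapes
(round-trip IoU ≥ 0.99 is the documented contract). Entity ids are
strings internally; export numbers them deterministically in sorted-id
order and keeps the originals in `file_name` / `source_id`.

**Mask exports.** Three modes: labeled-instance (one 8-bit PNG per
image, pixel value = instance index in sorted-id order, 0 background,
at most 255 instances, overlaps resolved later-id-wins with a warning),
binary-instance (one PNG per object), binary-semantic (one PNG per
image × category, the union of that category's objects).

**Project archives.** `saveProject()` writes a Zarr v2 directory store
authored by the package: JSON `.zgroup`/`.zarray`/`.zattrs` metadata and
one uncompressed C-order chunk per array (float64 pixels, uint8 masks),
entity metadata in attributes, schema version `"1"` checked on load.
Doubles round-trip bit-exactly, and the store is readable by any Zarr
implementation (the test suite reads it back with the Python `zarr`
library as an independent check). Only committed state is saved; saving
with pending edits is refused rather than silently committing.

**Models.** `exportModel()` writes `model.json` — layers with shapes,
activations and trainable/frozen flags, class names, config, history,
and a weight manifest — plus one little-endian float64 shard per
parameter, optimizer momentum buffers included so an imported model
resumes exactly. Import validates every shard's byte length against the
declared shape and fails loudly on mismatch.

**Image reading.** PNG and JPEG decode to z = 1 with 1 or 3 channels
(alpha dropped); multi-page TIFFs are factored by the user-declared
channel count, pages interpreted channel-fastest within z; intensities
are scaled to [0, 1] by source bit depth, losslessly for depths up to
16. DICOM support is deliberately narrow: uncompressed single-frame
grayscale, explicit or implicit VR little endian, with rescale
slope/intercept applied and the result normalized by the stored bit
depth; encapsulated (compressed) transfer syntaxes are rejected with an
explicit unsupported-format error.

## The segmentation contract

Deep pretrained segmenters are out of scope, but the *contract* their
results must satisfy is not: `runSegmenter()` turns any registered
mask-producing function into staged `AnnotationObject`s of a chosen
kind, indistinguishable from hand-drawn annotations — editable with the
mask tools, measurable, and available to the classifier. The built-in
`"reference"` segmenter (global threshold on channel-mean intensity +
4-connected components) is a classical baseline that exists to exercise
this contract end to end.

## Known limitations

* Single-level commit/revert; no undo history or concurrent editing.
* SLIC is plain R and sized for interactive slices, not whole-slide
  images; the same holds for the classifier.
* COCO polygon semantics are even-odd across loops; overlapping
  *disjoint* polygons meant as a union (rather than holes) would XOR.
* Labeled-instance PNG export is 8-bit (≤ 255 instances per image).
* DICOM reading covers the uncompressed grayscale single-frame case
  only; no multi-frame, color or compressed syntaxes.
* Quartiles are nearest-rank by design; tools that interpolate will
  disagree by up to one inter-pixel gap on small objects.
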