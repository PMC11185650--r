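#' @import methods
NULL

PARTITIONS <- c("train", "validation", "inference", "unassigned")

#' ImageItem: a multichannel, optionally z-stacked raster
#'
#' Pixel data are stored as a 4-axis array ordered (z, channel, y, x) with
#' intensities normalized to [0, 1]. Each image belongs to the built-in
#' "Image" kind, carries a category assignment (the reserved "Unknown"
#' category when unlabeled) and a partition (train / validation / inference /
#' unassigned), plus per-channel display metadata (visibility flag and
#' display color).
#'
#' @slot id character identifier, unique within a project.
#' @slot name display name (typically the source file name).
#' @slot pixels 4-d numeric array (z, channel, y, x), values in [0, 1].
#' @slot bitDepth integer bit depth of the source data (8 or 16 typically).
#' @slot kindId identifier of the owning kind (the built-in "Image" kind).
#' @slot categoryId identifier of the assigned category.
#' @slot partition one of "train", "validation", "inference", "unassigned".
#' @slot channelVisible logical vector, one flag per channel.
#' @slot channelColor character vector of display colors, one per channel.
#' @exportClass ImageItem
setClass("ImageItem", representation(
  id = "character", name = "character", pixels = "array",
  bitDepth = "integer", kindId = "character", categoryId = "character",
  partition = "character", channelVisible = "logical",
  channelColor = "character"
))

setValidity("ImageItem", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 4L)
    msg <- c(msg, "pixels must be a 4-d array (z, channel, y, x)")
  else {
    if (any(d < 1L)) {
      msg <- c(msg, "all four pixel axes must have length >= 1")
    } else {
      rng <- range(object@pixels)
      if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1)
        msg <- c(msg, "intensities must lie in [0, 1] and contain no NA")
    }
    if (length(object@channelVisible) != d[2])
      msg <- c(msg, "channelVisible length must equal the channel axis length")
    if (length(object@channelColor) != d[2])
      msg <- c(msg, "channelColor length must equal the channel axis length")
  }
  if (!object@partition %in% PARTITIONS)
    msg <- c(msg, sprintf("partition must be one of %s",
                          paste(PARTITIONS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Kind: a class of measurable entities (whole images or an object type)
#'
#' @slot id character identifier.
#' @slot name display name; the built-in kind is named "Image".
#' @slot categoryIds identifiers of the categories owned by this kind.
#' @slot unknownCategoryId id of the reserved, undeletable "Unknown" category.
#' @exportClass Kind
setClass("Kind", representation(
  id = "character", name = "character", categoryIds = "character",
  unknownCategoryId = "character"
))

#' Category: a user-defined label within a kind
#'
#' @slot id character identifier.
#' @slot name label text; "Unknown" is reserved for the unlabeled pool.
#' @slot color RGB triple, integer values in [0, 255].
#' @slot kindId identifier of the owning kind.
#' @exportClass Category
setClass("Category", representation(
  id = "character", name = "character", color = "numeric",
  kindId = "character"
))

setValidity("Category", function(object) {
  if (length(object@color) != 3L || any(object@color < 0 | object@color > 255))
    "color must be an RGB triple with values in [0, 255]" else TRUE
})

#' AnnotationObject: a per-object binary mask cropped to a tight bounding box
#'
#' The bounding box is 0-based and half-open, (x, y, width, height) with x
#' increasing rightwards and y downwards (the COCO convention). The mask is a
#' logical matrix of shape (height, width) with at least one foreground
#' pixel, tight against every border of the box.
#'
#' @slot id character identifier.
#' @slot imageId id of the image the object lies in.
#' @slot kindId id of the object kind (e.g. "cells").
#' @slot categoryId id of the assigned category.
#' @slot bbox numeric (x, y, width, height), 0-based, half-open.
#' @slot mask logical matrix (height x width).
#' @slot zIndex 0-based z-plane the annotation was drawn on.
#' @slot partition one of "train", "validation", "inference", "unassigned".
#' @exportClass AnnotationObject
setClass("AnnotationObject", representation(
  id = "character", imageId = "character", kindId = "character",
  categoryId = "character", bbox = "numeric", mask = "matrix",
  zIndex = "integer", partition = "character"
))

setValidity("AnnotationObject", function(object) {
  msg <- character()
  b <- object@bbox
  m <- object@mask
  if (length(b) != 4L || any(b[3:4] < 1))
    msg <- c(msg, "bbox must be (x, y, width, height) with positive extents")
  if (!is.logical(m)) msg <- c(msg, "mask must be logical")
  if (length(b) == 4L && (nrow(m) != b[4] || ncol(m) != b[3]))
    msg <- c(msg, "mask shape must equal (bbox height, bbox width)")
  if (!any(m)) msg <- c(msg, "mask must have at least one foreground pixel")
  else {
    if (!any(m[1, ]) || !any(m[nrow(m), ]) || !any(m[, 1]) || !any(m[, ncol(m)]))
      msg <- c(msg, "bbox must be tight: every mask border row/column touched")
  }
  if (!object@partition %in% PARTITIONS)
    msg <- c(msg, "invalid partition")
  if (length(msg)) msg else TRUE
})

#' Split: a selection of images or objects by kind, categories and partitions
#'
#' An empty category or partition filter means "all". Used to scope
#' measurements and classifier training, mirroring how a user first picks the
#' kind being measured, then optionally narrows by category and/or partition.
#'
#' @slot kindId identifier of the kind selected.
#' @slot categoryIds category filter; empty = all categories of the kind.
#' @slot partitions partition filter; empty = all partitions.
#' @exportClass Split
setClass("Split", representation(
  kindId = "character", categoryIds = "character", partitions = "character"
))

#' Split constructor
#'
#' @param kindId kind to select.
#' @param categoryIds optional category filter (ids); default all.
#' @param partitions optional partition filter; default all.
#' @return A [Split-class] object.
#' @export
Split <- function(kindId, categoryIds = character(), partitions = character()) {
  if (length(partitions) && !all(partitions %in% PARTITIONS))
    stop("unknown partition: ", paste(setdiff(partitions, PARTITIONS),
                                      collapse = ", "))
  new("Split", kindId = kindId, categoryIds = as.character(categoryIds),
      partitions = as.character(partitions))
}

emptyStage <- function() {
  list(images = list(added = list(), diffs = list()),
       annotations = list(added = list(), diffs = list()),
       kinds = list(added = list(), diffs = list()),
       categories = list(added = list(), diffs = list()))
}

#' Project: the in-memory store of images, kinds, categories and annotations
#'
#' Edits are staged: mutating operations record per-entity field diffs (or
#' whole added entities) in a change set rather than touching the committed
#' collections. Reading through the default "staged" view reflects those
#' changes; \code{commitProject()} folds them into the committed state and
#' \code{revertProject()} discards them, restoring the last committed state
#' exactly.
#'
#' @slot name project name.
#' @slot images committed images, a named list of [ImageItem-class].
#' @slot annotations committed [AnnotationObject-class]s, named by id.
#' @slot kinds committed [Kind-class]s, named by id.
#' @slot categories committed [Category-class]s, named by id.
#' @slot staged the pending change set (added entities + field diffs).
#' @slot counter id-generation counter.
#' @exportClass Project
setClass("Project", representation(
  name = "character", images = "list", annotations = "list",
  kinds = "list", categories = "list", staged = "list", counter = "integer"
))

#' ShapeSpec: parameters of a geometric annotation shape
#'
#' @slot kind "rectangle", "ellipse" or "polygon".
#' @slot parameters rectangle: (x, y, width, height); ellipse: (center_x,
#'   center_y, radius_x, radius_y); polygon: a two-column matrix of vertices
#'   (x, y) in pixel coordinates.
#' @exportClass ShapeSpec
setClass("ShapeSpec", representation(kind = "character", parameters = "ANY"))

setValidity("ShapeSpec", function(object) {
  k <- object@kind
  p <- object@parameters
  if (!k %in% c("rectangle", "ellipse", "polygon"))
    return("kind must be rectangle, ellipse or polygon")
  if (k == "polygon") {
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L)
      return("polygon parameters must be a >= 3 x 2 vertex matrix")
  } else {
    if (length(p) != 4L) return("rectangle/ellipse need 4 parameters")
    if (any(p[3:4] <= 0)) return("extents/radii must be positive")
  }
  TRUE
})

#' ShapeSpec constructor
#'
#' @param kind "rectangle", "ellipse" or "polygon".
#' @param ... for rectangle: \code{x, y, width, height}; for ellipse:
#'   \code{cx, cy, rx, ry}; for polygon: \code{vertices} (n x 2 matrix).
#' @return A [ShapeSpec-class].
#' @export
ShapeSpec <- function(kind, ...) {
  a <- list(...)
  p <- switch(kind,
    rectangle = c(a$x, a$y, a$width, a$height),
    ellipse = c(a$cx, a$cy, a$rx, a$ry),
    polygon = a$vertices,
    stop("unknown shape kind: ", kind))
  new("ShapeSpec", kind = kind, parameters = p)
}

#' SuperpixelMap: a SLIC partition of an image slice
#'
#' @slot labels integer matrix, one superpixel label per pixel (a partition:
#'   every pixel belongs to exactly one nonempty label).
#' @slot nSegmentsRequested the requested number of segments.
#' @slot compactness the SLIC compactness used.
#' @exportClass SuperpixelMap
setClass("SuperpixelMap", representation(
  labels = "matrix", nSegmentsRequested = "integer", compactness = "numeric"
))

#' ClassifierConfig: training hyperparameters
#'
#' @slot architecture "simple_cnn" or "transfer_head".
#' @slot inputExtent (height, width, channels) the model consumes.
#' @slot lossName currently "categorical_crossentropy".
#' @slot learningRate positive SGD learning rate.
#' @slot epochs default number of epochs per fit call.
#' @slot batchSize minibatch size.
#' @slot trainFraction fraction of labeled items used for training, in (0,1).
#' @slot seed integer seed driving split, weight init and batch shuffling.
#' @exportClass ClassifierConfig
setClass("ClassifierConfig", representation(
  architecture = "character", inputExtent = "integer", lossName = "character",
  learningRate = "numeric", epochs = "integer", batchSize = "integer",
  trainFraction = "numeric", seed = "integer"
))

setValidity("ClassifierConfig", function(object) {
  msg <- character()
  if (!object@architecture %in% c("simple_cnn", "transfer_head"))
    msg <- c(msg, "architecture must be simple_cnn or transfer_head")
  if (length(object@inputExtent) != 3L || any(object@inputExtent < 1L))
    msg <- c(msg, "inputExtent must be (height, width, channels), all >= 1")
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    msg <- c(msg, "trainFraction must be strictly between 0 and 1")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be positive")
  if (length(msg)) msg else TRUE
})

#' ClassifierConfig constructor
#'
#' @param architecture "simple_cnn" (default) or "transfer_head".
#' @param inputExtent integer (height, width, channels).
#' @param lossName loss identifier; "categorical_crossentropy".
#' @param learningRate SGD learning rate.
#' @param epochs default epochs per fit call.
#' @param batchSize minibatch size.
#' @param trainFraction train share of the labeled pool, in (0,1).
#' @param seed integer seed.
#' @return A [ClassifierConfig-class].
#' @export
ClassifierConfig <- function(architecture = "simple_cnn",
                             inputExtent = c(32L, 32L, 1L),
                             lossName = "categorical_crossentropy",
                             learningRate = 0.05, epochs = 10L,
                             batchSize = 16L, trainFraction = 0.8,
                             seed = 1L) {
  new("ClassifierConfig", architecture = architecture,
      inputExtent = as.integer(inputExtent), lossName = lossName,
      learningRate = learningRate, epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), trainFraction = trainFraction,
      seed = as.integer(seed))
}

#' TrainingState: weights, optimizer state and epoch history
#'
#' Holds everything needed to resume training where it previously stopped:
#' the parameter arrays, the SGD momentum buffers, the per-epoch history and
#' the (fixed) class-name order.
#'
#' @slot layers architecture description (list of layer specs).
#' @slot weights named list of parameter arrays.
#' @slot optimizerState momentum buffers, same shapes as weights.
#' @slot epochsCompleted number of epochs trained so far.
#' @slot history data.frame with one row per epoch (losses, accuracies).
#' @slot classNames ordered category names; fixed once training starts.
#' @slot config the [ClassifierConfig-class] used to build the model.
#' @exportClass TrainingState
setClass("TrainingState", representation(
  layers = "list", weights = "list", optimizerState = "list",
  epochsCompleted = "integer", history = "data.frame",
  classNames = "character", config = "ClassifierConfig"
))

setValidity("TrainingState", function(object) {
  if (nrow(object@history) != object@epochsCompleted)
    "history length must equal epochsCompleted" else TRUE
})

#' EvaluationReport: confusion matrix and derived classification metrics
#'
#' @slot confusionMatrix class x class counts; rows = truth, cols = predicted.
#' @slot perClass data.frame with precision, recall and F1 per class.
#' @slot accuracy trace / total.
#' @slot macroF1 unweighted mean of per-class F1 scores.
#' @exportClass EvaluationReport
setClass("EvaluationReport", representation(
  confusionMatrix = "matrix", perClass = "data.frame",
  accuracy = "numeric", macroF1 = "numeric"
))

#' MeasurementTable: per-item measurement rows plus split summaries
#'
#' @slot rows data.frame keyed by (item id, measurement name, channel) with
#'   item metadata columns (kind, category, partition) and the value.
#' @slot summaries data.frame keyed by (measurement, channel) holding the
#'   split-wise total, median and (population) standard deviation.
#' @slot split the [Split-class] the table was computed over.
#' @exportClass MeasurementTable
setClass("MeasurementTable", representation(
  rows = "data.frame", summaries = "data.frame", split = "Split"
))

#' SceneSpec: a synthetic shape scene with known ground truth
#'
#' @slot extent (height, width) of the rendered image.
#' @slot objects list of object specs: each a list with \code{shape}
#'   ("disk", "rectangle" or "plus"), shape parameters, \code{intensity}
#'   and optionally a per-channel intensity \code{profile}.
#' @slot background background intensity in [0, 1].
#' @slot noiseSigma additive Gaussian noise sd (clipped to [0, 1]).
#' @slot seed integer seed; generation is a pure function of (spec, seed).
#' @exportClass SceneSpec
setClass("SceneSpec", representation(
  extent = "integer", objects = "list", background = "numeric",
  noiseSigma = "numeric", seed = "integer"
))

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (length(object@extent) != 2L || any(object@extent < 1L))
    msg <- c(msg, "extent must be (height, width), both >= 1")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@background < 0 || object@background > 1)
    msg <- c(msg, "background intensity must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' SceneSpec constructor
#'
#' @param extent integer (height, width).
#' @param objects list of object specs (see [SceneSpec-class]).
#' @param background background intensity.
#' @param noiseSigma Gaussian noise sd.
#' @param seed integer seed.
#' @return A [SceneSpec-class].
#' @export
SceneSpec <- function(extent, objects, background = 0, noiseSigma = 0,
                      seed = 1L) {
  new("SceneSpec", extent = as.integer(extent), objects = objects,
      background = background, noiseSigma = noiseSigma,
      seed = as.integer(seed))
}

setMethod("show", "Project", function(object) {
  st <- object@staged
  n_staged <- sum(vapply(st, function(s) length(s$added) + length(s$diffs),
                         integer(1)))
  cat("Project:", object@name, "\n",
      " images:      ", length(object@images), "committed\n",
      " annotations: ", length(object@annotations), "committed\n",
      " kinds:       ", length(object@kinds), "\n",
      " categories:  ", length(object@categories), "\n",
      " staged edits:", n_staged, "\n")
})

setMethod("show", "ImageItem", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageItem '%s' (%s): z=%d c=%d %dx%d, %d-bit, partition=%s\n",
              object@name, object@id, d[1], d[2], d[3], d[4],
              object@bitDepth, object@partition))
})

setMethod("show", "AnnotationObject", function(object) {
  b <- object@bbox
  cat(sprintf(
    "AnnotationObject '%s': image=%s bbox=(%g,%g,%g,%g) area=%d z=%d\n",
    object@id, object@imageId, b[1], b[2], b[3], b[4],
    sum(object@mask), object@zIndex))
})

setMethod("show", "TrainingState", function(object) {
  cat(sprintf(
    "TrainingState: %s, %d classes, %d epochs completed\n",
    object@config@architecture, length(object@classNames),
    object@epochsCompleted))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: accuracy %.4f, macro-F1 %.4f\n",
              object@accuracy, object@macroF1))
  print(object@confusionMatrix)
})

setMethod("show", "MeasurementTable", function(object) {
  cat(sprintf("MeasurementTable: %d rows, %d summary entries\n",
              nrow(object@rows), nrow(object@summaries)))
})
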