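# Pluggable segmentation interface: a segmenter is any function taking an
# ImageItem and returning a list of full-size binary masks. Results become
# ordinary AnnotationObjects, editable with the annotator tools and usable
# by the classifier and measurements, exactly like hand-drawn annotations.

.segmenterRegistry <- new.env(parent = emptyenv())

#' Register a segmentation model
#'
#' @param name model name used in [runSegmenter()].
#' @param fn function(image, ...) returning a list of logical full-extent
#'   masks (one per detected object).
#' @export
registerSegmenter <- function(name, fn) {
  .segmenterRegistry[[name]] <- fn
  invisible(name)
}

#' List registered segmenters
#'
#' @return Character vector of registered segmenter names.
#' @export
listSegmenters <- function() sort(ls(.segmenterRegistry))

# 4-connected component labeling of a binary mask.
labelComponents <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nextLab <- 0L
  for (s in which(mask & lab == 0L)) {
    if (lab[s] != 0L) next
    nextLab <- nextLab + 1L
    frontier <- s
    lab[s] <- nextLab
    while (length(frontier)) {
      nxt <- integer()
      for (off in c(-1L, 1L, -h, h)) {
        nb <- frontier + off
        ok <- nb >= 1L & nb <= h * w
        if (any(abs(off) == 1L))
          ok <- ok & ((nb - 1L) %/% h == (frontier - 1L) %/% h)
        nb <- nb[ok]
        nb <- nb[mask[nb] & lab[nb] == 0L]
        if (length(nb)) {
          lab[nb] <- nextLab
          nxt <- c(nxt, nb)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

# Classical reference segmenter: global threshold on the channel-mean
# intensity followed by 4-connected component labeling. Exists to exercise
# the segmentation-result data contract without any pretrained network.
referenceSegmenterFn <- function(image, z = 0L, threshold = NULL,
                                 polarity = c("above", "below"),
                                 minArea = 1L) {
  polarity <- match.arg(polarity)
  sl <- imageSlice(image, z)
  mean_int <- apply(sl, c(2, 3), mean)
  if (is.null(threshold)) threshold <- mean(range(mean_int))
  fg <- if (polarity == "above") mean_int > threshold else mean_int < threshold
  lab <- labelComponents(fg)
  k <- max(lab)
  masks <- list()
  for (i in seq_len(k)) {
    m <- lab == i
    if (sum(m) >= minArea) masks[[length(masks) + 1L]] <- m
  }
  masks
}

#' Run a segmenter and stage its results as annotation objects
#'
#' Applies a registered segmentation model to the given images; every
#' detected object becomes a staged [AnnotationObject-class] of the given
#' kind (with its "Unknown" category), indistinguishable from a manually
#' drawn annotation — editable, measurable and classifiable.
#'
#' @param project a [Project-class].
#' @param model registered segmenter name (the built-in classical model is
#'   "reference").
#' @param imageIds images to segment (default: all).
#' @param kindId object kind for the results (registered if missing).
#' @param ... passed to the segmenter function.
#' @param view project view to read.
#' @return The updated project with segmentation results staged.
#' @export
runSegmenter <- function(project, model = "reference", imageIds = NULL,
                         kindId = "cells", ..., view = "staged") {
  fn <- .segmenterRegistry[[model]]
  if (is.null(fn)) stop("unregistered segmenter: ", model)
  if (!kindId %in% names(projectKinds(project, view)))
    project <- registerKind(project, kindId)
  if (is.null(imageIds))
    imageIds <- sort(names(projectImages(project, view)))
  for (id in imageIds) {
    img <- projectImages(project, view)[[id]]
    masks <- fn(img, ...)
    for (m in masks) {
      ann <- maskToAnnotation(m, imageId = id, kindId = kindId)
      project <- addAnnotations(project, ann)
    }
  }
  project
}
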