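# Synthetic fixtures: scenes of simple shapes with exact ground-truth masks
# and closed-form geometry, class-separable labeled image sets, and
# hyperstack TIFFs. All generators are pure functions of (spec, seed).

shapeMask <- function(obj, extent) {
  switch(obj$shape,
    disk = rasterizeShape(ShapeSpec("ellipse", cx = obj$cx, cy = obj$cy,
                                    rx = obj$r, ry = obj$r), extent),
    rectangle = rasterizeShape(ShapeSpec("rectangle", x = obj$x, y = obj$y,
                                         width = obj$width,
                                         height = obj$height), extent),
    plus = {
      L <- obj$length %||% 9; W <- obj$width %||% 3
      h <- rasterizeShape(ShapeSpec("rectangle", x = obj$cx - L / 2,
                                    y = obj$cy - W / 2, width = L,
                                    height = W), extent)
      v <- rasterizeShape(ShapeSpec("rectangle", x = obj$cx - W / 2,
                                    y = obj$cy - L / 2, width = W,
                                    height = L), extent)
      h | v
    },
    stop("unknown fixture shape: ", obj$shape))
}

shapeAnalyticGeometry <- function(obj) {
  prim <- switch(obj$shape,
    disk = list(area = pi * obj$r^2, perimeter = 2 * pi * obj$r,
                bbox_area = (2 * obj$r)^2),
    rectangle = list(area = obj$width * obj$height,
                     perimeter = 2 * (obj$width + obj$height),
                     bbox_area = obj$width * obj$height),
    plus = {
      L <- obj$length %||% 9; W <- obj$width %||% 3
      list(area = 2 * L * W - W^2, perimeter = 4 * L, bbox_area = L^2)
    })
  derivedGeometry(prim$area, prim$perimeter, prim$bbox_area)
}

#' Generate a shape scene with known ground truth
#'
#' Renders the spec's objects (disks, rectangles, plus-signs) onto a
#' background, optionally adding clipped Gaussian noise, and returns the
#' image together with the exact per-object masks (as
#' [AnnotationObject-class]s) and both the analytic (continuous) and
#' rasterized (pixel-count) geometry of every object.
#'
#' @param spec a [SceneSpec-class].
#' @param disjoint error if any two object masks overlap.
#' @return List with \code{image} ([ImageItem-class]), \code{annotations},
#'   \code{analytic} and \code{rasterized} geometry lists.
#' @export
generateShapeScene <- function(spec, disjoint = FALSE) {
  validObject(spec)
  ext <- spec@extent
  masks <- lapply(spec@objects, shapeMask, extent = ext)
  if (disjoint && length(masks) > 1L) {
    acc <- matrix(FALSE, ext[1], ext[2])
    for (m in masks) {
      if (any(acc & m)) stop("objects overlap but disjointness was requested")
      acc <- acc | m
    }
  }
  nch <- max(c(1L, vapply(spec@objects, function(o)
    length(o$profile %||% o$intensity), integer(1))))
  px <- array(spec@background, c(1L, nch, ext[1], ext[2]))
  for (i in seq_along(spec@objects)) {
    prof <- spec@objects[[i]]$profile %||%
      rep(spec@objects[[i]]$intensity, nch)
    prof <- rep_len(prof, nch)
    for (ch in seq_len(nch)) {
      plane <- px[1L, ch, , ]
      plane[masks[[i]]] <- prof[ch]
      px[1L, ch, , ] <- plane
    }
  }
  if (spec@noiseSigma > 0) {
    noise <- withLocalSeed(spec@seed,
      array(stats::rnorm(length(px), sd = spec@noiseSigma), dim = dim(px)))
    px <- pmin(pmax(px + noise, 0), 1)
  }
  image <- ImageItem(px, name = sprintf("scene-%d", spec@seed),
                     id = sprintf("scene-%d", spec@seed))
  annotations <- lapply(seq_along(masks), function(i)
    maskToAnnotation(masks[[i]], imageId = image@id, kindId = "object",
                     categoryId = NA_character_, zIndex = 0L,
                     id = sprintf("scene-%d-obj-%03d", spec@seed, i)))
  list(image = image, annotations = annotations,
       analytic = lapply(spec@objects, shapeAnalyticGeometry),
       rasterized = lapply(masks, maskGeometry))
}

#' Generate a class-separable labeled image set
#'
#' Each class is defined by a mean intensity and a texture frequency: an
#' image is the class mean plus a sinusoidal grating at the class frequency
#' (random phase) plus clipped Gaussian noise. The defaults (means 0.3 vs
#' 0.7, noise sd 0.1) keep the Bayes error low, so even a per-image
#' mean-intensity threshold separates the classes.
#'
#' @param nPerClass images per class (>= 1).
#' @param classSpecs list of per-class specs: list(mean=, freq=), optionally
#'   named (names become the labels).
#' @param noiseSigma Gaussian noise sd.
#' @param extent image (height, width), default 32 x 32.
#' @param seed integer seed; the dataset is a pure function of it.
#' @param amplitude grating amplitude (default 0.15).
#' @return List with \code{items} (list of [ImageItem-class]) and
#'   \code{labels} (character vector).
#' @export
generateClassDataset <- function(nPerClass,
                                 classSpecs = list(
                                   A = list(mean = 0.3, freq = 2),
                                   B = list(mean = 0.7, freq = 6)),
                                 noiseSigma = 0.1, extent = c(32L, 32L),
                                 seed = 1L, amplitude = 0.15) {
  if (nPerClass < 1L) stop("nPerClass must be >= 1")
  if (length(classSpecs) < 2L) stop("need at least 2 classes")
  labelsAll <- names(classSpecs)
  if (is.null(labelsAll))
    labelsAll <- paste0("class", seq_along(classSpecs))
  sig <- vapply(classSpecs, function(s) paste(s$mean, s$freq), character(1))
  if (anyDuplicated(sig))
    warning("identical class specs: the classes are not separable")
  h <- extent[1]; w <- extent[2]
  xg <- matrix(rep(seq_len(w), each = h), h, w)
  yg <- matrix(rep(seq_len(h), times = w), h, w)
  items <- list()
  labels <- character()
  withLocalSeed(seed, {
    for (ci in seq_along(classSpecs)) {
      cs <- classSpecs[[ci]]
      for (i in seq_len(nPerClass)) {
        phase <- stats::runif(1, 0, 2 * pi)
        img <- cs$mean +
          amplitude * sin(2 * pi * cs$freq * (xg + yg) / w + phase) +
          stats::rnorm(h * w, sd = noiseSigma)
        img <- pmin(pmax(img, 0), 1)
        id <- sprintf("%s-%03d", labelsAll[ci], i)
        items[[length(items) + 1L]] <-
          ImageItem(matrix(img, h, w), name = id, id = id)
        labels <- c(labels, labelsAll[ci])
      }
    }
  })
  list(items = items, labels = labels)
}

#' Write a synthetic hyperstack TIFF
#'
#' Generates z x channels pages of seeded 16-bit noise and writes them
#' channel-fastest (channel varying within z), the page order
#' [readImageFile()] expects; reading the file back with the same declared
#' channel count round-trips to shape (z, channels, height, width).
#'
#' @param z number of z planes.
#' @param channels number of channels.
#' @param extent (height, width) per page.
#' @param seed integer seed.
#' @param path output TIFF path.
#' @return Invisibly, \code{path}.
#' @export
generateHyperstack <- function(z, channels, extent = c(16L, 16L), seed = 1L,
                               path) {
  if (z < 1L || channels < 1L) stop("z and channels must be >= 1")
  pages <- withLocalSeed(seed, {
    lapply(seq_len(z * channels), function(i) {
      m <- matrix(stats::runif(extent[1] * extent[2]), extent[1], extent[2])
      round(m * 65535) / 65535
    })
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
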