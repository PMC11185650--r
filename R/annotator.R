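#' Extract one z-slice of an image as a (channel, y, x) array
#'
#' @param image an [ImageItem-class].
#' @param z 0-based z index.
#' @param visibleOnly keep only channels flagged visible.
#' @return A 3-d numeric array (channel, y, x).
#' @export
imageSlice <- function(image, z = 0L, visibleOnly = FALSE) {
  d <- dim(image@pixels)
  if (z < 0 || z >= d[1]) stop("z index out of range")
  sl <- image@pixels[z + 1L, , , , drop = FALSE]
  dim(sl) <- d[2:4]
  if (visibleOnly) {
    keep <- which(image@channelVisible)
    if (!length(keep)) keep <- seq_len(d[2])
    sl <- sl[keep, , , drop = FALSE]
  }
  sl
}

#' Rasterize a geometric shape to a full-image binary mask
#'
#' A pixel is foreground when its center lies inside the shape; polygons use
#' the even-odd rule. Coordinates are 0-based with x rightwards and y
#' downwards; pixel (row r, col c) has its center at (c + 0.5, r + 0.5).
#'
#' @param shape a [ShapeSpec-class].
#' @param extent integer (height, width) of the image.
#' @return Logical matrix (height x width).
#' @export
rasterizeShape <- function(shape, extent) {
  validObject(shape)
  h <- as.integer(extent[1]); w <- as.integer(extent[2])
  cx <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)  # pixel-center x
  cy <- matrix(rep(seq_len(h) - 0.5, times = w), h, w) # pixel-center y
  p <- shape@parameters
  mask <- switch(shape@kind,
    rectangle = cx >= p[1] & cx < p[1] + p[3] & cy >= p[2] & cy < p[2] + p[4],
    ellipse = ((cx - p[1]) / p[3])^2 + ((cy - p[2]) / p[4])^2 <= 1,
    polygon = pointInPolygonEvenOdd(cx, cy, p))
  if (!any(mask)) stop("empty annotation: no pixel center lies in the shape")
  mask
}

# Even-odd crossing test, vectorized over pixel centers for each edge.
pointInPolygonEvenOdd <- function(px, py, vertices) {
  n <- nrow(vertices)
  inside <- matrix(FALSE, nrow(px), ncol(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    if (yi != yj) {
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside
}

#' Compute SLIC superpixels on an image slice
#'
#' Deterministic SLIC: cluster centers start on a regular grid of spacing
#' \eqn{S = \sqrt{N/k}} and are refined for a fixed number of iterations,
#' assigning each pixel to the nearest center within a 2S window under the
#' combined distance \eqn{D = \sqrt{d_c^2 + m^2 (d_s/S)^2}}, where the color
#' distance \eqn{d_c} is Euclidean over channels rescaled to [0, 100] (the
#' magnitude the compactness constant conventionally assumes for Lab-range
#' colors) and \eqn{d_s} is the spatial Euclidean distance. A final pass
#' enforces label connectivity by merging stray components into an adjacent
#' label.
#'
#' @param slicePixels (channel, y, x) array, intensities in [0, 1].
#' @param nSegments requested number of superpixels (1 .. pixel count).
#' @param compactness positive compactness constant (default 10).
#' @param iterations refinement iterations (default 5).
#' @return A [SuperpixelMap-class].
#' @export
computeSuperpixels <- function(slicePixels, nSegments, compactness = 10,
                               iterations = 5L) {
  d <- dim(slicePixels)
  if (length(d) != 3L) stop("slicePixels must be (channel, y, x)")
  nc <- d[1]; h <- d[2]; w <- d[3]
  npix <- h * w
  if (nSegments < 1 || nSegments > npix)
    stop("nSegments must be between 1 and the pixel count")
  # feature matrix: rows = pixels (column-major over y within x), cols = channels
  feat <- matrix(aperm(slicePixels, c(2, 3, 1)), nrow = npix, ncol = nc) * 100
  ys <- rep(seq_len(h), times = w)
  xs <- rep(seq_len(w), each = h)
  S <- sqrt(npix / nSegments)
  gx <- max(1L, round(w / S)); gy <- max(1L, round(h / S))
  while (gx * gy < nSegments) { if (gx / w <= gy / h) gx <- gx + 1L else gy <- gy + 1L }
  cyc <- (seq_len(gy) - 0.5) * h / gy
  cxc <- (seq_len(gx) - 0.5) * w / gx
  centers <- cbind(y = rep(cyc, times = gx), x = rep(cxc, each = gy))
  k <- nrow(centers)
  cfeat <- matrix(0, k, nc)
  for (i in seq_len(k)) {
    py <- pmin(h, pmax(1L, round(centers[i, 1])))
    px <- pmin(w, pmax(1L, round(centers[i, 2])))
    cfeat[i, ] <- feat[(px - 1L) * h + py, ]
  }
  labels <- integer(npix)
  for (it in seq_len(iterations)) {
    best <- rep(Inf, npix)
    labels <- integer(npix)
    for (i in seq_len(k)) {
      y0 <- max(1L, floor(centers[i, 1] - 2 * S))
      y1 <- min(h, ceiling(centers[i, 1] + 2 * S))
      x0 <- max(1L, floor(centers[i, 2] - 2 * S))
      x1 <- min(w, ceiling(centers[i, 2] + 2 * S))
      idx <- as.vector(outer((y0:y1), (x0:x1 - 1L) * h, `+`))
      dc2 <- rowSums((feat[idx, , drop = FALSE] -
                      matrix(cfeat[i, ], length(idx), nc, byrow = TRUE))^2)
      ds2 <- (ys[idx] - centers[i, 1])^2 + (xs[idx] - centers[i, 2])^2
      dist <- dc2 + compactness^2 * ds2 / S^2
      upd <- dist < best[idx]
      sel <- idx[upd]
      best[sel] <- dist[upd]
      labels[sel] <- i
    }
    # any pixel outside every window: nearest center by space
    orphan <- which(labels == 0L)
    if (length(orphan)) {
      for (p in orphan) {
        ds2 <- (ys[p] - centers[, 1])^2 + (xs[p] - centers[, 2])^2
        labels[p] <- which.min(ds2)
      }
    }
    for (i in seq_len(k)) {
      members <- labels == i
      if (!any(members)) next
      centers[i, 1] <- mean(ys[members])
      centers[i, 2] <- mean(xs[members])
      cfeat[i, ] <- colMeans(feat[members, , drop = FALSE])
    }
  }
  lab <- matrix(labels, h, w)
  lab <- enforceConnectivity(lab)
  new("SuperpixelMap", labels = lab,
      nSegmentsRequested = as.integer(nSegments),
      compactness = compactness)
}

# Merge connected components that are not the largest of their label into a
# neighboring label, then relabel 1..K densely.
enforceConnectivity <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  comp <- matrix(0L, h, w)
  ncomp <- 0L
  compLabel <- integer()
  compSize <- integer()
  for (start in which(comp == 0L)) {
    if (comp[start] != 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    comp[start] <- ncomp
    sz <- 0L
    lv <- lab[start]
    while (length(queue)) {
      cur <- queue
      queue <- integer()
      sz <- sz + length(cur)
      for (off in c(-1L, 1L, -h, h)) {
        nb <- cur + off
        ok <- nb >= 1L & nb <= h * w
        if (any(abs(off) == 1L)) {
          # stay within the same column for vertical moves
          ok <- ok & ((nb - 1L) %/% h == (cur - 1L) %/% h)
        }
        nb <- nb[ok]
        nb <- nb[comp[nb] == 0L & lab[nb] == lv]
        if (length(nb)) {
          comp[nb] <- ncomp
          queue <- c(queue, unique(nb))
        }
      }
      queue <- unique(queue)
    }
    compLabel[ncomp] <- lv
    compSize[ncomp] <- sz
  }
  # keep the largest component per label; merge others into an adjacent label
  keep <- integer(max(lab))
  for (lv in seq_len(max(lab))) {
    comps <- which(compLabel == lv)
    if (length(comps)) keep[lv] <- comps[which.max(compSize[comps])]
  }
  for (ci in seq_len(ncomp)) {
    if (ci == keep[compLabel[ci]]) next
    cells <- which(comp == ci)
    nbLab <- integer()
    for (off in c(-1L, 1L, -h, h)) {
      nb <- cells + off
      ok <- nb >= 1L & nb <= h * w
      if (any(abs(off) == 1L)) ok <- ok & ((nb - 1L) %/% h == (cells - 1L) %/% h)
      nb <- nb[ok]
      nb <- nb[comp[nb] != ci]
      nbLab <- c(nbLab, lab[nb])
    }
    newLab <- if (length(nbLab)) as.integer(names(which.max(table(nbLab))))
              else compLabel[ci]
    lab[cells] <- newLab
  }
  dense <- match(lab, sort(unique(as.vector(lab))))
  matrix(as.integer(dense), h, w)
}

#' Quick-select: union of the superpixels containing each seed
#'
#' @param superpixels a [SuperpixelMap-class].
#' @param seeds matrix or list of (row, col) pixel coordinates (1-based).
#' @return Logical mask, the union of the seeds' whole superpixels.
#' @export
quickSelect <- function(superpixels, seeds) {
  lab <- superpixels@labels
  seeds <- seedMatrix(seeds)
  h <- nrow(lab); w <- ncol(lab)
  if (any(seeds[, 1] < 1 | seeds[, 1] > h | seeds[, 2] < 1 | seeds[, 2] > w))
    stop("seed outside image extent")
  picked <- unique(lab[cbind(seeds[, 1], seeds[, 2])])
  matrix(lab %in% picked, h, w)
}

seedMatrix <- function(seeds) {
  if (is.list(seeds)) seeds <- do.call(rbind, seeds)
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 2)
  seeds
}

#' Flood-fill selection from a seed pixel
#'
#' Grows the 4-connected region of pixels reachable from the seed whose
#' Euclidean color distance (over channels, [0, 1] intensities) to the seed
#' color is at most \code{tolerance}.
#'
#' @param slicePixels (channel, y, x) array.
#' @param seed (row, col) 1-based pixel coordinate.
#' @param tolerance nonnegative color distance threshold.
#' @return Logical mask; always 4-connected and containing the seed.
#' @export
floodFillSelect <- function(slicePixels, seed, tolerance) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  d <- dim(slicePixels)
  nc <- d[1]; h <- d[2]; w <- d[3]
  if (seed[1] < 1 || seed[1] > h || seed[2] < 1 || seed[2] > w)
    stop("seed outside image extent")
  feat <- matrix(aperm(slicePixels, c(2, 3, 1)), nrow = h * w, ncol = nc)
  s <- (seed[2] - 1L) * h + seed[1]
  dist <- sqrt(rowSums((feat - matrix(feat[s, ], h * w, nc, byrow = TRUE))^2))
  eligible <- dist <= tolerance + 1e-12
  visited <- logical(h * w)
  visited[s] <- TRUE
  frontier <- s
  while (length(frontier)) {
    nxt <- integer()
    for (off in c(-1L, 1L, -h, h)) {
      nb <- frontier + off
      ok <- nb >= 1L & nb <= h * w
      if (any(abs(off) == 1L))
        ok <- ok & ((nb - 1L) %/% h == (frontier - 1L) %/% h)
      nb <- nb[ok]
      nb <- nb[eligible[nb] & !visited[nb]]
      if (length(nb)) {
        visited[nb] <- TRUE
        nxt <- c(nxt, nb)
      }
    }
    frontier <- unique(nxt)
  }
  matrix(visited, h, w)
}

#' Threshold selection inside a bounding box
#'
#' Selects the pixels inside the box whose channel-mean intensity (over
#' visible channels) is strictly below (or above) the threshold.
#'
#' @param slicePixels (channel, y, x) array.
#' @param bbox (x, y, width, height), 0-based half-open, inside the extent.
#' @param threshold intensity threshold in [0, 1].
#' @param polarity "below" (default, dark objects) or "above".
#' @return Logical full-extent mask; foreground restricted to the box.
#' @export
thresholdSelect <- function(slicePixels, bbox, threshold,
                            polarity = c("below", "above")) {
  polarity <- match.arg(polarity)
  d <- dim(slicePixels)
  h <- d[2]; w <- d[3]
  if (bbox[3] < 1 || bbox[4] < 1) stop("degenerate bbox")
  if (bbox[1] < 0 || bbox[2] < 0 || bbox[1] + bbox[3] > w ||
      bbox[2] + bbox[4] > h) stop("bbox outside image extent")
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  mean_int <- apply(slicePixels, c(2, 3), mean)
  mask <- matrix(FALSE, h, w)
  rows <- (bbox[2] + 1L):(bbox[2] + bbox[4])
  cols <- (bbox[1] + 1L):(bbox[1] + bbox[3])
  sub <- mean_int[rows, cols, drop = FALSE]
  mask[rows, cols] <- if (polarity == "below") sub < threshold else sub > threshold
  mask
}

#' Combine two masks by adding or subtracting a region
#'
#' @param base logical mask.
#' @param edit logical mask of the same extent.
#' @param mode "add" (set union) or "subtract" (base minus edit).
#' @return Logical mask.
#' @export
combineMasks <- function(base, edit, mode = c("add", "subtract")) {
  mode <- match.arg(mode)
  if (!identical(dim(base), dim(edit))) stop("mask extent mismatch")
  if (mode == "add") base | edit else base & !edit
}

#' Crop a full-size mask into an annotation object
#'
#' Computes the tight bounding box of the mask, crops it, and wraps the
#' result in an [AnnotationObject-class] (0-based half-open bbox).
#'
#' @param mask logical full-image mask with at least one foreground pixel.
#' @param imageId,kindId,categoryId entity references.
#' @param zIndex 0-based z plane the mask was drawn on.
#' @param id optional id (autogenerated on [addAnnotations()] when `NA`).
#' @param partition partition assignment.
#' @return An [AnnotationObject-class].
#' @export
maskToAnnotation <- function(mask, imageId, kindId,
                             categoryId = NA_character_, zIndex = 0L,
                             id = NA_character_, partition = "unassigned") {
  if (!any(mask)) stop("empty mask")
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  r0 <- min(rows); r1 <- max(rows)
  c0 <- min(cols); c1 <- max(cols)
  cropped <- mask[r0:r1, c0:c1, drop = FALSE]
  new("AnnotationObject", id = id, imageId = imageId, kindId = kindId,
      categoryId = categoryId,
      bbox = c(c0 - 1, r0 - 1, c1 - c0 + 1, r1 - r0 + 1),
      mask = cropped, zIndex = as.integer(zIndex), partition = partition)
}

#' Re-inflate an annotation's cropped mask to full image size
#'
#' @param annotation an [AnnotationObject-class].
#' @param extent integer (height, width) of the image.
#' @return Logical full-extent mask.
#' @export
annotationFullMask <- function(annotation, extent) {
  m <- matrix(FALSE, extent[1], extent[2])
  b <- annotation@bbox
  m[(b[2] + 1):(b[2] + b[4]), (b[1] + 1):(b[1] + b[3])] <- annotation@mask
  m
}
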