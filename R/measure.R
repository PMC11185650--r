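MEASUREMENT_NAMES <- c(
  "area", "perimeter", "bbox_area", "extent", "equivalent_diameter", "ped",
  "sphericity", "compactness",
  "intensity_total", "intensity_mean", "intensity_median", "intensity_std",
  "intensity_mad", "intensity_lower_quartile", "intensity_upper_quartile")

GEOMETRY_NAMES <- MEASUREMENT_NAMES[1:8]
INTENSITY_NAMES <- MEASUREMENT_NAMES[9:15]

#' Measurement name registry
#'
#' @return Character vector of the stable measurement identifiers.
#' @export
measurementNames <- function() MEASUREMENT_NAMES

# Nearest-rank quartile: the intensity value of the pixel at rank
# ceiling(p * n) of the sorted list, so the value is always attained by an
# actual pixel.
nearestRankQuantile <- function(sorted, p) {
  n <- length(sorted)
  sorted[max(1L, ceiling(p * n))]
}

#' Per-channel intensity statistics
#'
#' Computes total, mean, median, (population) standard deviation, MAD,
#' lower quartile and upper quartile for each channel. The MAD is the
#' median absolute deviation from the median,
#' \eqn{MAD = median(|x_i - median(x)|)}; the quartiles use the
#' nearest-rank convention so each reported quartile is the intensity of an
#' actual pixel.
#'
#' @param values a numeric vector (one channel) or list of numeric vectors
#'   (one per channel).
#' @return data.frame with one row per channel and columns
#'   \code{channel, total, mean, median, std, mad, lower_quartile,
#'   upper_quartile}.
#' @export
intensityStats <- function(values) {
  if (!is.list(values)) values <- list(values)
  rows <- lapply(seq_along(values), function(ch) {
    x <- values[[ch]]
    if (!length(x)) stop("empty channel ", ch)
    s <- sort(x)
    med <- stats::median(x)
    data.frame(
      channel = ch - 1L,
      total = sum(x),
      mean = mean(x),
      median = med,
      std = sqrt(mean((x - mean(x))^2)),
      mad = stats::median(abs(x - med)),
      lower_quartile = nearestRankQuantile(s, 0.25),
      upper_quartile = nearestRankQuantile(s, 0.75))
  })
  do.call(rbind, rows)
}

#' Primitive geometry of a binary mask
#'
#' Area is the foreground pixel count. Perimeter is the number of foreground
#' pixels on the inner boundary: pixels with at least one background (or
#' out-of-extent) pixel among their 8 neighbors, i.e. the pixels removed by
#' an erosion with the 3x3 box. Bounding-box area is the tight-box
#' width x height.
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @return List with \code{area}, \code{perimeter}, \code{bbox_area}.
#' @export
primitiveGeometry <- function(mask) {
  if (!any(mask)) stop("empty mask")
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  interior <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    interior <- interior & pad[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]
  }
  rows <- which(rowSums(mask) > 0); cols <- which(colSums(mask) > 0)
  list(area = sum(mask),
       perimeter = sum(mask & !interior),
       bbox_area = (max(rows) - min(rows) + 1L) * (max(cols) - min(cols) + 1L))
}

#' Derived geometric measurements
#'
#' Evaluates the closed-form shape descriptors from primitive area \eqn{A},
#' perimeter \eqn{P} and bounding-box area: extent \eqn{A / A_{bbox}},
#' equivalent diameter \eqn{2\sqrt{A/\pi}}, perimeter-equivalent diameter
#' \eqn{P/\pi}, sphericity \eqn{S = 2\sqrt{\pi A}/P} (the perimeter of the
#' equal-area circle over the real perimeter; 1 for a circle) and
#' compactness \eqn{C = 1/S}. Inputs may be analytic (non-integer), so
#' closed-form identities hold exactly.
#'
#' @param area positive area.
#' @param perimeter positive perimeter.
#' @param bboxArea bounding-box area, at least \code{area}.
#' @return List with all eight geometry fields.
#' @export
derivedGeometry <- function(area, perimeter, bboxArea) {
  if (area <= 0 || perimeter <= 0) stop("area and perimeter must be positive")
  if (bboxArea < area) stop("bbox_area must be >= area")
  s <- 2 * sqrt(pi * area) / perimeter
  list(area = area, perimeter = perimeter, bbox_area = bboxArea,
       extent = area / bboxArea,
       equivalent_diameter = 2 * sqrt(area / pi),
       ped = perimeter / pi,
       sphericity = s,
       compactness = 1 / s)
}

#' Full geometry record of a mask
#'
#' @param mask logical matrix.
#' @return List combining [primitiveGeometry()] and [derivedGeometry()].
#' @export
maskGeometry <- function(mask) {
  p <- primitiveGeometry(mask)
  derivedGeometry(p$area, p$perimeter, p$bbox_area)
}

# -- measurement cache -------------------------------------------------------
# Values are cached by a content hash of the underlying pixels/mask, so a
# cached entry can only be reused while the underlying data are unchanged.
.measureCache <- new.env(parent = emptyenv())

cacheFetch <- function(key, compute) {
  if (!is.null(.measureCache[[key]])) {
    .measureCache[["__hits__"]] <- (.measureCache[["__hits__"]] %||% 0L) + 1L
    return(.measureCache[[key]])
  }
  val <- compute()
  .measureCache[[key]] <- val
  val
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inspect or clear the measurement cache
#'
#' @return \code{measureCacheHits} returns the number of cache hits since
#'   the last reset; \code{clearMeasureCache} empties the cache.
#' @export
measureCacheHits <- function() .measureCache[["__hits__"]] %||% 0L

#' @rdname measureCacheHits
#' @export
clearMeasureCache <- function() {
  rm(list = ls(.measureCache), envir = .measureCache)
  invisible(NULL)
}

itemGeometry <- function(ann) {
  key <- paste0("geom:", rlang::hash(ann@mask))
  cacheFetch(key, function() maskGeometry(ann@mask))
}

itemIntensity <- function(values, tag) {
  key <- paste0("int:", tag)
  cacheFetch(key, function() intensityStats(values))
}

#' Measure a split of images or objects
#'
#' Intensity measurements are available for both images and objects (object
#' intensities are taken per channel within the mask, on the annotation's
#' z-plane); geometry measurements require a mask and therefore cannot be
#' requested for the "Image" kind. Returns per-item rows plus split-wise
#' summaries (total, median, population std per measurement/channel).
#'
#' @param project a [Project-class].
#' @param split a [Split-class].
#' @param measurements character vector of measurement names
#'   (see [measurementNames()]).
#' @param view project view to read ("staged" default).
#' @return A [MeasurementTable-class].
#' @export
measureSplit <- function(project, split, measurements, view = "staged") {
  unknown <- setdiff(measurements, MEASUREMENT_NAMES)
  if (length(unknown))
    stop("unknown measurements: ", paste(unknown, collapse = ", "))
  wantGeom <- intersect(measurements, GEOMETRY_NAMES)
  wantInt <- intersect(measurements, INTENSITY_NAMES)
  isImageKind <- split@kindId == IMAGE_KIND_ID
  if (isImageKind && length(wantGeom))
    stop("geometry measurements require an object mask and cannot be ",
         "computed for the \"Image\" kind")
  ids <- selectSplit(project, split, view)
  cats <- projectCategories(project, view)
  rows <- list()
  for (id in ids) {
    if (isImageKind) {
      item <- projectImages(project, view)[[id]]
      meta <- list(kind = item@kindId,
                   category = cats[[item@categoryId]]@name,
                   partition = item@partition)
      nc <- dim(item@pixels)[2]
      vals <- lapply(seq_len(nc), function(ch) as.vector(item@pixels[, ch, , ]))
      istats <- itemIntensity(vals, rlang::hash(item@pixels))
    } else {
      item <- projectAnnotations(project, view)[[id]]
      meta <- list(kind = item@kindId,
                   category = cats[[item@categoryId]]@name,
                   partition = item@partition)
      if (length(wantGeom)) {
        g <- itemGeometry(item)
        for (m in wantGeom)
          rows[[length(rows) + 1L]] <- data.frame(
            item_id = id, kind = meta$kind, category = meta$category,
            partition = meta$partition, measurement = m, channel = NA_integer_,
            value = g[[m]])
      }
      if (length(wantInt)) {
        img <- projectImages(project, view)[[item@imageId]]
        full <- annotationFullMask(item, dim(img@pixels)[3:4])
        nc <- dim(img@pixels)[2]
        vals <- lapply(seq_len(nc), function(ch) {
          plane <- img@pixels[item@zIndex + 1L, ch, , ]
          plane[full]
        })
        istats <- itemIntensity(
          vals, rlang::hash(list(img@pixels, item@mask, item@bbox,
                                 item@zIndex)))
      }
    }
    if (length(wantInt)) {
      for (m in wantInt) {
        col <- sub("intensity_", "", m)
        for (r in seq_len(nrow(istats)))
          rows[[length(rows) + 1L]] <- data.frame(
            item_id = id, kind = meta$kind, category = meta$category,
            partition = meta$partition, measurement = m,
            channel = istats$channel[r], value = istats[[col]][r])
      }
    }
    if (!isImageKind) next
  }
  rowsDf <- if (length(rows)) do.call(rbind, rows)
            else data.frame(item_id = character(), kind = character(),
                            category = character(), partition = character(),
                            measurement = character(), channel = integer(),
                            value = numeric())
  summaries <- summarizeRows(rowsDf)
  new("MeasurementTable", rows = rowsDf, summaries = summaries, split = split)
}

summarizeRows <- function(rowsDf) {
  if (!nrow(rowsDf))
    return(data.frame(measurement = character(), channel = integer(),
                      total = numeric(), median = numeric(), std = numeric()))
  keys <- unique(rowsDf[, c("measurement", "channel")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    m <- keys$measurement[i]; ch <- keys$channel[i]
    sel <- rowsDf$measurement == m &
      (is.na(ch) & is.na(rowsDf$channel) |
         (!is.na(ch) & !is.na(rowsDf$channel) & rowsDf$channel == ch))
    v <- rowsDf$value[sel]
    data.frame(measurement = m, channel = ch, total = sum(v),
               median = stats::median(v), std = sqrt(mean((v - mean(v))^2)))
  })
  do.call(rbind, out)
}

#' Plot-ready data series from a measurement table
#'
#' Computes the numeric series behind the three supported plot kinds without
#' rendering anything: histogram (bin edges and counts; half-open bins, the
#' last bin closed), scatter (point tuples with optional size/color
#' mappings) and swarm (per-group value lists with an optional statistics
#' overlay: median, std, lower and upper quartile per the intensity-stats
#' convention).
#'
#' @param table a [MeasurementTable-class].
#' @param kind "histogram", "scatter" or "swarm".
#' @param x measurement name for histogram / scatter x.
#' @param y measurement name for scatter y / swarm values.
#' @param bins histogram bin count (>= 1).
#' @param size optional measurement mapped to point size (scatter, swarm).
#' @param groupBy swarm grouping column: "category" or "partition".
#' @param overlay logical; include the swarm statistics overlay.
#' @param channel channel selector for per-channel measurements (default
#'   first available).
#' @return A list of numeric series; structure depends on \code{kind}.
#' @export
plotSeries <- function(table, kind = c("histogram", "scatter", "swarm"),
                       x = NULL, y = NULL, bins = 10L, size = NULL,
                       groupBy = "category", overlay = FALSE,
                       channel = NULL) {
  kind <- match.arg(kind)
  rowsDf <- table@rows
  pull <- function(m) {
    if (is.null(m) || !m %in% rowsDf$measurement)
      stop("unknown measurement: ", if (is.null(m)) "<missing>" else m)
    sel <- rowsDf$measurement == m
    if (!is.null(channel)) sel <- sel & rowsDf$channel %in% channel
    rowsDf[sel, , drop = FALSE]
  }
  if (kind == "histogram") {
    if (bins < 1) stop("bin count must be >= 1")
    v <- pull(x)$value
    lo <- min(v); hi <- max(v)
    if (hi == lo) hi <- lo + 1
    edges <- seq(lo, hi, length.out = bins + 1L)
    idx <- pmin(floor((v - lo) / (hi - lo) * bins) + 1L, bins)
    counts <- tabulate(idx, nbins = bins)
    return(list(kind = "histogram", edges = edges, counts = counts))
  }
  if (kind == "scatter") {
    dx <- pull(x); dy <- pull(y)
    pts <- merge(dx[, c("item_id", "value")], dy[, c("item_id", "value")],
                 by = "item_id", suffixes = c(".x", ".y"))
    pts <- pts[order(pts$item_id), ]
    out <- list(kind = "scatter", item_id = pts$item_id,
                x = pts$value.x, y = pts$value.y)
    if (!is.null(size)) {
      ds <- pull(size)
      sv <- ds$value[match(pts$item_id, ds$item_id)]
      rng <- range(sv)
      out$size <- if (rng[2] > rng[1]) (sv - rng[1]) / (rng[2] - rng[1]) + 0.5
                  else rep(1, length(sv))
    }
    return(out)
  }
  dy <- pull(y)
  groups <- split(dy$value, dy[[groupBy]])
  out <- list(kind = "swarm", groups = groups)
  if (overlay) {
    out$overlay <- lapply(groups, function(v) {
      s <- sort(v)
      list(median = stats::median(v), std = sqrt(mean((v - mean(v))^2)),
           lower_quartile = nearestRankQuantile(s, 0.25),
           upper_quartile = nearestRankQuantile(s, 0.75))
    })
  }
  out
}
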