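# COCO interchange: masks are traced to polygons at pixel-corner resolution
# (outer contours plus hole contours; even-odd semantics on import), so a
# mask -> polygon -> mask round trip is exact for simple shapes.

# Trace all boundary loops of a mask as closed polygons on the pixel-corner
# grid (0-based corner coordinates, x rightwards, y downwards). Each
# foreground pixel contributes one directed edge per exposed side, oriented
# so the object interior lies to the right; loops are recovered by following
# edges, preferring the rightmost turn at pinch vertices.
traceMaskPolygons <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- function(dr, dc) pad[2:(h + 1L) + dr, 2:(w + 1L) + dc]
  exposedN <- mask & !core(-1L, 0L)
  exposedS <- mask & !core(1L, 0L)
  exposedW <- mask & !core(0L, -1L)
  exposedE <- mask & !core(0L, 1L)
  edges <- list()
  addEdges <- function(which, fx, fy, tx, ty) {
    idx <- which(which, arr.ind = TRUE)
    if (!nrow(idx)) return()
    r <- idx[, 1] - 1L; cl <- idx[, 2] - 1L
    edges[[length(edges) + 1L]] <<- cbind(fx(cl, r), fy(cl, r),
                                          tx(cl, r), ty(cl, r))
  }
  # oriented: interior on the right of travel (y grows downwards)
  addEdges(exposedN, function(c, r) c,       function(c, r) r,
                     function(c, r) c + 1L,  function(c, r) r)
  addEdges(exposedE, function(c, r) c + 1L,  function(c, r) r,
                     function(c, r) c + 1L,  function(c, r) r + 1L)
  addEdges(exposedS, function(c, r) c + 1L,  function(c, r) r + 1L,
                     function(c, r) c,       function(c, r) r + 1L)
  addEdges(exposedW, function(c, r) c,       function(c, r) r + 1L,
                     function(c, r) c,       function(c, r) r)
  E <- do.call(rbind, edges)
  keyOf <- function(x, y) x * (h + 1L) + y + 1L
  fromKey <- keyOf(E[, 1], E[, 2])
  used <- logical(nrow(E))
  outgoing <- split(seq_len(nrow(E)), fromKey)
  loops <- list()
  dirOf <- function(i) c(E[i, 3] - E[i, 1], E[i, 4] - E[i, 2])
  for (startEdge in seq_len(nrow(E))) {
    if (used[startEdge]) next
    loop <- list()
    cur <- startEdge
    repeat {
      used[cur] <- TRUE
      loop[[length(loop) + 1L]] <- E[cur, 1:2]
      nextKey <- as.character(keyOf(E[cur, 3], E[cur, 4]))
      cands <- outgoing[[nextKey]]
      cands <- cands[!used[cands]]
      if (!length(cands)) break
      if (length(cands) == 1L) {
        cur <- cands
      } else {
        d <- dirOf(cur)
        # rightmost turn first (clockwise of d in y-down coords), then
        # straight, then left
        pref <- list(c(-d[2], d[1]), d, c(d[2], -d[1]))
        pick <- NA_integer_
        for (p in pref) {
          hit <- cands[vapply(cands, function(i)
            all(dirOf(i) == p), logical(1))]
          if (length(hit)) { pick <- hit[1]; break }
        }
        cur <- if (is.na(pick)) cands[1] else pick
      }
    }
    loops[[length(loops) + 1L]] <- do.call(rbind, loop)
  }
  loops
}

# Rasterize COCO polygons (list of flat [x1,y1,x2,y2,...] vectors) with
# even-odd semantics across loops.
cocoPolygonsToMask <- function(polys, height, width) {
  mask <- matrix(FALSE, height, width)
  for (p in polys) {
    v <- matrix(p, ncol = 2, byrow = TRUE)
    mask <- xor(mask, rasterizeShape(ShapeSpec("polygon", vertices = v),
                                     c(height, width)))
  }
  mask
}

#' Export a project's annotations as a COCO document
#'
#' Entities are ordered and numbered deterministically (sorted by string
#' id); the original string ids are kept in \code{file_name} (images) and a
#' \code{source_id} field (annotations). Polygons are traced from the masks
#' at pixel-corner resolution, holes appearing as additional loops.
#'
#' @param project a [Project-class].
#' @param splits optional list of [Split-class] restricting the exported
#'   annotations; default: all annotations.
#' @param view project view to read (default "committed").
#' @return The COCO document as a nested list (images, annotations,
#'   categories).
#' @export
exportCoco <- function(project, splits = NULL, view = "committed") {
  anns <- projectAnnotations(project, view)
  if (!is.null(splits)) {
    ids <- sort(unique(unlist(lapply(splits, selectSplit,
                                     project = project, view = view))))
    anns <- anns[intersect(names(anns), ids)]
  }
  images <- projectImages(project, view)
  kinds <- projectKinds(project, view)
  cats <- projectCategories(project, view)
  imgIds <- sort(names(images))
  catIds <- sort(names(cats))
  annIds <- sort(names(anns))
  imgNum <- stats::setNames(seq_along(imgIds), imgIds)
  catNum <- stats::setNames(seq_along(catIds), catIds)
  imagesOut <- lapply(imgIds, function(id) {
    d <- dim(images[[id]]@pixels)
    list(id = unname(imgNum[id]), file_name = images[[id]]@name,
         width = d[4], height = d[3])
  })
  categoriesOut <- lapply(catIds, function(id) {
    list(id = unname(catNum[id]), name = cats[[id]]@name,
         supercategory = kinds[[cats[[id]]@kindId]]@name)
  })
  annotationsOut <- lapply(seq_along(annIds), function(i) {
    a <- anns[[annIds[i]]]
    img <- images[[a@imageId]]
    full <- annotationFullMask(a, dim(img@pixels)[3:4])
    loops <- traceMaskPolygons(full)
    seg <- lapply(loops, function(m) as.numeric(t(m)))
    list(id = i, source_id = a@id, image_id = unname(imgNum[a@imageId]),
         category_id = unname(catNum[a@categoryId]),
         bbox = as.numeric(a@bbox), segmentation = seg,
         area = sum(a@mask), iscrowd = 0L)
  })
  list(images = imagesOut, annotations = annotationsOut,
       categories = categoriesOut)
}

#' Write a COCO document to a JSON file
#'
#' @param doc a COCO document list as produced by [exportCoco()].
#' @param path output path.
#' @export
writeCocoJson <- function(doc, path) {
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' Read a COCO JSON file
#'
#' @param path input path.
#' @return The COCO document as a nested list.
#' @export
readCocoJson <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Import COCO annotations into a project
#'
#' Images are matched by \code{file_name} against the project's image
#' names. Missing kinds (from category supercategories) and categories are
#' registered on the fly; polygons are rasterized back to masks (even-odd
#' rule) and added as staged annotation objects.
#'
#' @param doc a COCO document list.
#' @param project a [Project-class] already containing the images.
#' @param view project view used to resolve images.
#' @return The updated project with imported annotations staged.
#' @export
importCoco <- function(doc, project, view = "staged") {
  if (is.null(doc$images) || is.null(doc$annotations) ||
      is.null(doc$categories))
    stop("malformed COCO document: images/annotations/categories required")
  images <- projectImages(project, view)
  byName <- list()
  for (id in names(images)) byName[[images[[id]]@name]] <- id
  imgById <- list()
  for (im in doc$images) {
    pid <- byName[[im$file_name]]
    if (is.null(pid))
      stop("COCO image not present in project: ", im$file_name)
    imgById[[as.character(im$id)]] <- pid
  }
  catById <- list()
  for (ct in doc$categories) {
    kindName <- ct$supercategory %||% "Image"
    if (!kindName %in% names(projectKinds(project)))
      project <- registerKind(project, kindName)
    cat <- tryCatch(findCategory(project, kindName, ct$name),
                    error = function(e) NULL)
    if (is.null(cat)) {
      project <- registerCategory(project, kindName, ct$name)
      cat <- findCategory(project, kindName, ct$name)
    }
    catById[[as.character(ct$id)]] <- cat
  }
  for (an in doc$annotations) {
    pid <- imgById[[as.character(an$image_id)]]
    if (is.null(pid))
      stop("annotation references missing image id: ", an$image_id)
    cat <- catById[[as.character(an$category_id)]]
    if (is.null(cat))
      stop("annotation references missing category id: ", an$category_id)
    img <- images[[pid]]
    d <- dim(img@pixels)
    polys <- lapply(an$segmentation, function(s) as.numeric(unlist(s)))
    mask <- cocoPolygonsToMask(polys, d[3], d[4])
    if (!any(mask)) stop("COCO annotation rasterized to an empty mask")
    ann <- maskToAnnotation(mask, imageId = pid, kindId = cat@kindId,
                            categoryId = cat@id, zIndex = 0L)
    project <- addAnnotations(project, ann)
  }
  project
}
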