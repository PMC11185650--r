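#' Export annotation masks as PNG files
#'
#' Three modes: \code{labeled_instance} writes one image per source image
#' with pixel value = instance index (1..n, 0 background; 8-bit, so at most
#' 255 instances per image); \code{binary_instance} writes one binary image
#' per object; \code{binary_semantic} writes one binary image per (source
#' image, category), the union of that category's objects. Instance indices
#' follow sorted annotation id order; overlapping instances in labeled mode
#' are resolved by draw order (later id wins) with a warning.
#'
#' @param project a [Project-class].
#' @param split a [Split-class] selecting the objects.
#' @param mode "labeled_instance", "binary_instance" or "binary_semantic".
#' @param dir output directory (created if needed).
#' @param view project view to read (default "committed").
#' @return Invisibly, a data.frame manifest of the written files.
#' @export
exportMasks <- function(project, split, mode = c("labeled_instance",
                                                 "binary_instance",
                                                 "binary_semantic"),
                        dir, view = "committed") {
  mode <- match.arg(mode)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- selectSplit(project, split, view)
  if (!length(ids)) stop("split selects no objects")
  anns <- projectAnnotations(project, view)[ids]
  images <- projectImages(project, view)
  cats <- projectCategories(project, view)
  manifest <- list()
  record <- function(file, imageId, annId = NA, category = NA, instance = NA)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = file, image_id = imageId, annotation_id = annId,
      category = category, instance = instance)
  byImage <- split(names(anns),
                   vapply(anns, slot, character(1), "imageId"))
  if (mode == "labeled_instance") {
    for (imgId in sort(names(byImage))) {
      img <- images[[imgId]]
      ext <- dim(img@pixels)[3:4]
      lab <- matrix(0L, ext[1], ext[2])
      annIds <- sort(byImage[[imgId]])
      if (length(annIds) > 255L)
        stop("more than 255 instances in one image; 8-bit labeled export")
      overlapped <- FALSE
      for (k in seq_along(annIds)) {
        m <- annotationFullMask(anns[[annIds[k]]], ext)
        if (any(lab[m] != 0L)) overlapped <- TRUE
        lab[m] <- k
        record(file.path(dir, paste0(img@name, "_labeled.png")), imgId,
               annIds[k], instance = k)
      }
      if (overlapped)
        warning("overlapping instances in image ", img@name,
                "; later instance wins")
      png::writePNG(lab / 255, file.path(dir, paste0(img@name,
                                                     "_labeled.png")))
    }
  } else if (mode == "binary_instance") {
    for (annId in sort(names(anns))) {
      a <- anns[[annId]]
      img <- images[[a@imageId]]
      ext <- dim(img@pixels)[3:4]
      m <- annotationFullMask(a, ext)
      file <- file.path(dir, paste0(annId, "_mask.png"))
      png::writePNG(m * 1, file)
      record(file, a@imageId, annId)
    }
  } else {
    for (imgId in sort(names(byImage))) {
      img <- images[[imgId]]
      ext <- dim(img@pixels)[3:4]
      annIds <- byImage[[imgId]]
      catIds <- sort(unique(vapply(anns[annIds], slot, character(1),
                                   "categoryId")))
      for (catId in catIds) {
        m <- matrix(FALSE, ext[1], ext[2])
        for (annId in annIds) {
          if (anns[[annId]]@categoryId != catId) next
          m <- m | annotationFullMask(anns[[annId]], ext)
        }
        file <- file.path(dir, paste0(img@name, "_",
                                      cats[[catId]]@name, "_semantic.png"))
        png::writePNG(m * 1, file)
        record(file, imgId, category = cats[[catId]]@name)
      }
    }
  }
  invisible(do.call(rbind, manifest))
}
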