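# Project archives are written as a self-contained Zarr v2 directory store:
# each group is a directory with a .zgroup marker and JSON attributes in
# .zattrs; each array is a directory with a .zarray descriptor and a single
# uncompressed C-order chunk. Doubles round-trip bit-exactly.

ARCHIVE_SCHEMA_VERSION <- "1"

zarrWriteJson <- function(x, path) {
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
}

zarrWriteGroup <- function(dir, attrs = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  zarrWriteJson(list(zarr_format = 2L), file.path(dir, ".zgroup"))
  if (!is.null(attrs)) zarrWriteJson(attrs, file.path(dir, ".zattrs"))
}

zarrWriteArray <- function(dir, arr, dtype = c("f8", "u1"), attrs = NULL) {
  dtype <- match.arg(dtype)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  shape <- dim(arr)
  if (is.null(shape)) shape <- length(arr)
  meta <- list(zarr_format = 2L, shape = as.list(as.integer(shape)),
               chunks = as.list(as.integer(shape)),
               dtype = if (dtype == "f8") "<f8" else "|u1",
               compressor = NULL, fill_value = 0L, filters = NULL,
               order = "C")
  zarrWriteJson(meta, file.path(dir, ".zarray"))
  if (!is.null(attrs)) zarrWriteJson(attrs, file.path(dir, ".zattrs"))
  # C order: last axis fastest -> reverse axes before flattening column-major
  cOrd <- if (length(shape) > 1L) aperm(arr, rev(seq_along(shape))) else arr
  chunk <- file.path(dir, paste(rep("0", length(shape)), collapse = "."))
  con <- file(chunk, "wb")
  on.exit(close(con))
  if (dtype == "f8")
    writeBin(as.numeric(cOrd), con, size = 8L, endian = "little")
  else
    writeBin(as.raw(as.integer(cOrd)), con)
  invisible(dir)
}

zarrReadJson <- function(path) jsonlite::fromJSON(path, simplifyVector = TRUE)

zarrReadArray <- function(dir) {
  meta <- zarrReadJson(file.path(dir, ".zarray"))
  shape <- as.integer(unlist(meta$shape))
  chunk <- file.path(dir, paste(rep("0", length(shape)), collapse = "."))
  n <- prod(shape)
  if (identical(meta$dtype, "<f8")) {
    vals <- readBin(chunk, "numeric", n = n, size = 8L, endian = "little")
  } else if (identical(meta$dtype, "|u1")) {
    vals <- as.integer(readBin(chunk, "raw", n = n))
  } else stop("unsupported zarr dtype: ", meta$dtype)
  if (length(shape) > 1L) {
    arr <- array(vals, dim = rev(shape))
    aperm(arr, rev(seq_along(shape)))
  } else vals
}

catTable <- function(cats) {
  lapply(unname(cats), function(cc)
    list(id = cc@id, name = cc@name, color = as.numeric(cc@color),
         kind = cc@kindId))
}

kindTable <- function(kinds) {
  lapply(unname(kinds), function(k)
    list(id = k@id, name = k@name,
         category_ids = as.list(k@categoryIds),
         unknown_category_id = k@unknownCategoryId))
}

#' Save a committed project as a Zarr archive
#'
#' Writes the project (pixels, masks, assignments, kinds, categories) into a
#' Zarr v2 directory store; [loadProject()] reproduces every committed
#' entity bit-exactly. The project must have no staged changes.
#'
#' @param project a committed [Project-class].
#' @param path archive directory (created; conventionally ".zarr").
#' @return Invisibly, \code{path}.
#' @export
saveProject <- function(project, path) {
  if (hasStagedChanges(project))
    stop("project has staged changes; commit or revert before saving")
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  zarrWriteGroup(path, attrs = list(
    name = project@name, schema_version = ARCHIVE_SCHEMA_VERSION,
    counter = project@counter))
  zarrWriteGroup(file.path(path, "kinds"),
                 attrs = list(table = kindTable(project@kinds)))
  zarrWriteGroup(file.path(path, "categories"),
                 attrs = list(table = catTable(project@categories)))
  zarrWriteGroup(file.path(path, "images"))
  for (id in names(project@images)) {
    img <- project@images[[id]]
    zarrWriteArray(file.path(path, "images", id), img@pixels, "f8",
                   attrs = list(
                     id = id, name = img@name, bit_depth = img@bitDepth,
                     kind = img@kindId, category = img@categoryId,
                     partition = img@partition,
                     channel_visible = as.logical(img@channelVisible),
                     channel_color = as.character(img@channelColor)))
  }
  zarrWriteGroup(file.path(path, "annotations"))
  for (id in names(project@annotations)) {
    a <- project@annotations[[id]]
    zarrWriteArray(file.path(path, "annotations", id), a@mask * 1L, "u1",
                   attrs = list(
                     id = id, image_id = a@imageId, kind = a@kindId,
                     category = a@categoryId, bbox = as.numeric(a@bbox),
                     z_index = a@zIndex, partition = a@partition))
  }
  invisible(path)
}

#' Load a project from a Zarr archive
#'
#' @param path archive directory written by [saveProject()].
#' @return The reconstructed [Project-class] (fully committed).
#' @export
loadProject <- function(path) {
  attrsPath <- file.path(path, ".zattrs")
  if (!file.exists(attrsPath)) stop("not a project archive: ", path)
  at <- zarrReadJson(attrsPath)
  if (!identical(as.character(at$schema_version), ARCHIVE_SCHEMA_VERSION))
    stop("unsupported archive schema version '", at$schema_version,
         "' (this build reads version ", ARCHIVE_SCHEMA_VERSION, ")")
  kt <- zarrReadJson(file.path(path, "kinds", ".zattrs"))$table
  ct <- zarrReadJson(file.path(path, "categories", ".zattrs"))$table
  asRows <- function(tbl) {
    if (is.data.frame(tbl)) lapply(seq_len(nrow(tbl)), function(i)
      lapply(tbl, function(col) if (is.list(col)) col[[i]] else col[i]))
    else tbl
  }
  kinds <- list()
  for (k in asRows(kt)) {
    kinds[[k$id]] <- new("Kind", id = k$id, name = k$name,
                         categoryIds = as.character(unlist(k$category_ids)),
                         unknownCategoryId = k$unknown_category_id)
  }
  cats <- list()
  for (cc in asRows(ct)) {
    cats[[cc$id]] <- new("Category", id = cc$id, name = cc$name,
                         color = as.numeric(unlist(cc$color)),
                         kindId = cc$kind)
  }
  images <- list()
  for (id in sort(list.dirs(file.path(path, "images"), recursive = FALSE,
                            full.names = FALSE))) {
    d <- file.path(path, "images", id)
    a <- zarrReadJson(file.path(d, ".zattrs"))
    images[[id]] <- new("ImageItem", id = a$id, name = a$name,
                        pixels = zarrReadArray(d),
                        bitDepth = as.integer(a$bit_depth), kindId = a$kind,
                        categoryId = a$category, partition = a$partition,
                        channelVisible = as.logical(unlist(a$channel_visible)),
                        channelColor = as.character(unlist(a$channel_color)))
  }
  annotations <- list()
  for (id in sort(list.dirs(file.path(path, "annotations"),
                            recursive = FALSE, full.names = FALSE))) {
    d <- file.path(path, "annotations", id)
    a <- zarrReadJson(file.path(d, ".zattrs"))
    m <- zarrReadArray(d)
    annotations[[id]] <- new("AnnotationObject", id = a$id,
                             imageId = a$image_id, kindId = a$kind,
                             categoryId = a$category,
                             bbox = as.numeric(unlist(a$bbox)),
                             mask = m == 1L,
                             zIndex = as.integer(a$z_index),
                             partition = a$partition)
  }
  new("Project", name = at$name, images = images, annotations = annotations,
      kinds = kinds, categories = cats, staged = emptyStage(),
      counter = as.integer(at$counter))
}
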