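#' Create an image item
#'
#' Wraps a pixel array into an [ImageItem-class]. The array may be supplied
#' as (y, x), (channel, y, x) or the full (z, channel, y, x); missing leading
#' axes are added with length 1.
#'
#' @param pixels numeric array with intensities in [0, 1].
#' @param name display name.
#' @param id optional identifier; autogenerated on [addImages()] when `NA`.
#' @param bitDepth source bit depth (default 8).
#' @param categoryId optional category id; defaults to the "Unknown"
#'   category of the "Image" kind when added to a project.
#' @param partition partition assignment (default "unassigned").
#' @param channelColor optional per-channel display colors.
#' @param channelVisible optional per-channel visibility flags.
#' @return An [ImageItem-class].
#' @export
ImageItem <- function(pixels, name = "image", id = NA_character_,
                      bitDepth = 8L, categoryId = NA_character_,
                      partition = "unassigned", channelColor = NULL,
                      channelVisible = NULL) {
  d <- dim(pixels)
  if (is.null(d)) d <- c(1L, 1L, 1L, length(pixels))
  if (length(d) == 2L) d <- c(1L, 1L, d)
  if (length(d) == 3L) d <- c(1L, d)
  if (length(d) != 4L) stop("pixels must have 2 to 4 axes")
  pixels <- array(as.numeric(pixels), dim = d)
  nc <- d[2]
  if (is.null(channelColor))
    channelColor <- defaultChannelColors(nc)
  if (is.null(channelVisible)) channelVisible <- rep(TRUE, nc)
  obj <- new("ImageItem", id = id, name = name, pixels = pixels,
             bitDepth = as.integer(bitDepth), kindId = "Image",
             categoryId = categoryId, partition = partition,
             channelVisible = channelVisible, channelColor = channelColor)
  obj
}

defaultChannelColors <- function(n) {
  base <- c("#FF0000", "#00FF00", "#0000FF", "#FF00FF", "#FFFF00", "#00FFFF")
  if (n == 1L) return("#FFFFFF")
  rep_len(base, n)
}

IMAGE_KIND_ID <- "Image"

#' Create an empty project
#'
#' The new project contains the built-in "Image" kind with its reserved
#' "Unknown" category, no images and an empty change set.
#'
#' @param name nonempty project name.
#' @return A [Project-class].
#' @export
createProject <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("project name must be a nonempty string")
  unknown <- new("Category", id = "Image/Unknown", name = "Unknown",
                 color = c(128, 128, 128), kindId = IMAGE_KIND_ID)
  kind <- new("Kind", id = IMAGE_KIND_ID, name = "Image",
              categoryIds = unknown@id, unknownCategoryId = unknown@id)
  new("Project", name = name, images = list(), annotations = list(),
      kinds = stats::setNames(list(kind), kind@id),
      categories = stats::setNames(list(unknown), unknown@id),
      staged = emptyStage(), counter = 0L)
}

nextId <- function(project, prefix) {
  project@counter <- project@counter + 1L
  list(project = project, id = sprintf("%s-%06d", prefix, project@counter))
}

applyDiff <- function(entity, diff) {
  for (field in names(diff)) slot(entity, field) <- diff[[field]]
  entity
}

collectionView <- function(project, coll, view = c("staged", "committed")) {
  view <- match.arg(view)
  committed <- slot(project, coll)
  if (view == "committed") return(committed)
  st <- project@staged[[coll]]
  merged <- committed
  for (id in names(st$diffs))
    merged[[id]] <- applyDiff(merged[[id]], st$diffs[[id]])
  c(merged, st$added)
}

#' Project collection accessors
#'
#' Read a project collection through either the staged view (committed state
#' plus pending edits; the default) or the committed view.
#'
#' @param project a [Project-class].
#' @param view "staged" (default) or "committed".
#' @return A named list of entities.
#' @export
projectImages <- function(project, view = "staged")
  collectionView(project, "images", view)

#' @rdname projectImages
#' @export
projectAnnotations <- function(project, view = "staged")
  collectionView(project, "annotations", view)

#' @rdname projectImages
#' @export
projectKinds <- function(project, view = "staged")
  collectionView(project, "kinds", view)

#' @rdname projectImages
#' @export
projectCategories <- function(project, view = "staged")
  collectionView(project, "categories", view)

stageAdd <- function(project, coll, entity) {
  project@staged[[coll]]$added[[entity@id]] <- entity
  project
}

stageDiff <- function(project, coll, id, diff) {
  st <- project@staged[[coll]]
  if (id %in% names(st$added)) {
    st$added[[id]] <- applyDiff(st$added[[id]], diff)
  } else {
    old <- st$diffs[[id]]
    if (is.null(old)) old <- list()
    old[names(diff)] <- diff
    st$diffs[[id]] <- old
  }
  project@staged[[coll]] <- st
  project
}

#' Add images to a project (staged)
#'
#' Items are appended with partition "unassigned" and the "Unknown" category
#' of the "Image" kind unless the item already carries an assignment. The
#' addition is staged, not committed.
#'
#' @param project a [Project-class].
#' @param items an [ImageItem-class] or list of them.
#' @return The updated project.
#' @export
addImages <- function(project, items) {
  if (is(items, "ImageItem")) items <- list(items)
  existing <- names(projectImages(project))
  for (item in items) {
    if (is.na(item@id)) {
      gen <- nextId(project, "img")
      project <- gen$project
      item@id <- gen$id
    }
    if (item@id %in% existing)
      stop("duplicate image id: ", item@id)
    if (is.na(item@categoryId))
      item@categoryId <- projectKinds(project)[[IMAGE_KIND_ID]]@unknownCategoryId
    validObject(item)
    project <- stageAdd(project, "images", item)
    existing <- c(existing, item@id)
  }
  project
}

#' Register an object kind (staged)
#'
#' Creates a kind together with its reserved "Unknown" category.
#'
#' @param project a [Project-class].
#' @param name unique kind name (also used as its id).
#' @return The updated project.
#' @export
registerKind <- function(project, name) {
  kinds <- projectKinds(project)
  if (name %in% vapply(kinds, slot, character(1), "name"))
    stop("kind already exists: ", name)
  unknown <- new("Category", id = paste0(name, "/Unknown"), name = "Unknown",
                 color = c(128, 128, 128), kindId = name)
  kind <- new("Kind", id = name, name = name, categoryIds = unknown@id,
              unknownCategoryId = unknown@id)
  project <- stageAdd(project, "kinds", kind)
  stageAdd(project, "categories", unknown)
}

#' Register a category under a kind (staged)
#'
#' @param project a [Project-class].
#' @param kindId owning kind id.
#' @param name category name, unique within the kind.
#' @param color RGB triple in [0, 255].
#' @return The updated project; look the new id up with [findCategory()].
#' @export
registerCategory <- function(project, kindId, name, color = c(255, 0, 0)) {
  kinds <- projectKinds(project)
  if (!kindId %in% names(kinds)) stop("unknown kind: ", kindId)
  kind <- kinds[[kindId]]
  cats <- projectCategories(project)
  owned <- cats[kind@categoryIds]
  if (name %in% vapply(owned, slot, character(1), "name"))
    stop("duplicate category name within kind: ", name)
  gen <- nextId(project, "cat")
  project <- gen$project
  cat <- new("Category", id = gen$id, name = name, color = as.numeric(color),
             kindId = kindId)
  project <- stageAdd(project, "categories", cat)
  stageDiff(project, "kinds", kindId,
            list(categoryIds = c(kind@categoryIds, cat@id)))
}

#' Look up a category by name within a kind
#'
#' @param project a [Project-class].
#' @param kindId kind id.
#' @param name category name.
#' @param view "staged" or "committed".
#' @return The [Category-class], or an error if absent.
#' @export
findCategory <- function(project, kindId, name, view = "staged") {
  kind <- projectKinds(project, view)[[kindId]]
  if (is.null(kind)) stop("unknown kind: ", kindId)
  cats <- projectCategories(project, view)[kind@categoryIds]
  hit <- Filter(function(cc) cc@name == name, cats)
  if (!length(hit)) stop("no category named '", name, "' under kind ", kindId)
  hit[[1]]
}

#' Add annotation objects to a project (staged)
#'
#' Each annotation must reference an existing image, kind and category, and
#' its bounding box must lie fully inside the image extent.
#'
#' @param project a [Project-class].
#' @param annotations an [AnnotationObject-class] or list of them.
#' @return The updated project.
#' @export
addAnnotations <- function(project, annotations) {
  if (is(annotations, "AnnotationObject")) annotations <- list(annotations)
  images <- projectImages(project)
  kinds <- projectKinds(project)
  cats <- projectCategories(project)
  existing <- names(projectAnnotations(project))
  for (ann in annotations) {
    if (is.na(ann@id)) {
      gen <- nextId(project, "ann")
      project <- gen$project
      ann@id <- gen$id
    }
    if (ann@id %in% existing) stop("duplicate annotation id: ", ann@id)
    img <- images[[ann@imageId]]
    if (is.null(img)) stop("annotation references missing image: ", ann@imageId)
    kind <- kinds[[ann@kindId]]
    if (is.null(kind)) stop("annotation references missing kind: ", ann@kindId)
    if (is.na(ann@categoryId)) ann@categoryId <- kind@unknownCategoryId
    cat <- cats[[ann@categoryId]]
    if (is.null(cat))
      stop("annotation references missing category: ", ann@categoryId)
    if (cat@kindId != ann@kindId)
      stop("category ", cat@id, " does not belong to kind ", ann@kindId)
    d <- dim(img@pixels)
    b <- ann@bbox
    if (b[1] < 0 || b[2] < 0 || b[1] + b[3] > d[4] || b[2] + b[4] > d[3])
      stop("bbox outside image extent for annotation ", ann@id)
    validObject(ann)
    project <- stageAdd(project, "annotations", ann)
    existing <- c(existing, ann@id)
  }
  project
}

itemCollection <- function(project, id, view = "staged") {
  if (id %in% names(projectImages(project, view))) "images"
  else if (id %in% names(projectAnnotations(project, view))) "annotations"
  else NA_character_
}

#' Assign a category and/or partition to images or annotations (staged)
#'
#' Reassignment overwrites any prior staged value; the category (if given)
#' must belong to each item's kind.
#'
#' @param project a [Project-class].
#' @param itemIds ids of images and/or annotations.
#' @param categoryId optional category id to assign.
#' @param partition optional partition to assign.
#' @return The updated project.
#' @export
assignItems <- function(project, itemIds, categoryId = NULL,
                        partition = NULL) {
  if (!is.null(partition) && !partition %in% PARTITIONS)
    stop("unknown partition: ", partition)
  cats <- projectCategories(project)
  if (!is.null(categoryId) && is.null(cats[[categoryId]]))
    stop("unknown category: ", categoryId)
  for (id in itemIds) {
    coll <- itemCollection(project, id)
    if (is.na(coll)) stop("no image or annotation with id: ", id)
    item <- collectionView(project, coll)[[id]]
    diff <- list()
    if (!is.null(categoryId)) {
      if (cats[[categoryId]]@kindId != item@kindId)
        stop("category ", categoryId, " belongs to kind ",
             cats[[categoryId]]@kindId, ", not ", item@kindId)
      diff$categoryId <- categoryId
    }
    if (!is.null(partition)) diff$partition <- partition
    if (length(diff)) project <- stageDiff(project, coll, id, diff)
  }
  project
}

#' Select items by kind, category and partition
#'
#' Returns the ids of all items of the split's kind matching every given
#' filter, in deterministic (sorted id) order. Empty filters mean "all".
#'
#' @param project a [Project-class].
#' @param split a [Split-class].
#' @param view "staged" (default) or "committed".
#' @return Character vector of item ids (possibly empty).
#' @export
selectSplit <- function(project, split, view = "staged") {
  kinds <- projectKinds(project, view)
  if (!split@kindId %in% names(kinds)) stop("unknown kind: ", split@kindId)
  cats <- projectCategories(project, view)
  if (length(split@categoryIds)) {
    missing <- setdiff(split@categoryIds, names(cats))
    if (length(missing)) stop("unknown categories: ",
                              paste(missing, collapse = ", "))
  }
  items <- if (split@kindId == IMAGE_KIND_ID) projectImages(project, view)
           else Filter(function(a) a@kindId == split@kindId,
                       projectAnnotations(project, view))
  keep <- vapply(items, function(it) {
    (!length(split@categoryIds) || it@categoryId %in% split@categoryIds) &&
      (!length(split@partitions) || it@partition %in% split@partitions)
  }, logical(1))
  sort(names(items)[keep])
}

#' Commit or revert staged changes
#'
#' \code{commitProject} folds the staged change set into the committed state
#' and clears it; \code{revertProject} discards the change set, restoring
#' the last committed state exactly.
#'
#' @param project a [Project-class].
#' @return The updated project.
#' @export
commitProject <- function(project) {
  for (coll in names(project@staged)) {
    slot(project, coll) <- collectionView(project, coll, "staged")
  }
  project@staged <- emptyStage()
  project
}

#' @rdname commitProject
#' @export
revertProject <- function(project) {
  project@staged <- emptyStage()
  project
}

#' Check whether a project has uncommitted changes
#'
#' @param project a [Project-class].
#' @return TRUE if the change set is nonempty.
#' @export
hasStagedChanges <- function(project) {
  any(vapply(project@staged,
             function(s) length(s$added) + length(s$diffs) > 0, logical(1)))
}
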