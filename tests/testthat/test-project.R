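test_that("a new project holds the built-in Image kind and Unknown category", {
  p <- createProject("demo")
  expect_length(projectKinds(p), 1L)
  expect_length(projectCategories(p), 1L)
  expect_length(projectImages(p), 0L)
  expect_false(hasStagedChanges(p))
  expect_identical(projectKinds(p)[["Image"]]@name, "Image")
  expect_identical(projectCategories(p)[[1]]@name, "Unknown")
  expect_error(createProject(""), "nonempty")
  # commit of an empty change set is the identity
  expect_equal(commitProject(p), p)
})

test_that("added images are staged, not committed, and revert restores", {
  p <- createProject("demo")
  imgs <- lapply(1:3, function(i)
    ImageItem(matrix(stats::runif(64), 8, 8), name = paste0("im", i)))
  p2 <- addImages(p, imgs)
  expect_length(projectImages(p2, "staged"), 3L)
  expect_length(projectImages(p2, "committed"), 0L)
  # defaults: Unknown category, unassigned partition
  img <- projectImages(p2)[[1]]
  expect_identical(img@categoryId, "Image/Unknown")
  expect_identical(img@partition, "unassigned")
  p3 <- revertProject(p2)
  expect_length(projectImages(p3, "staged"), 0L)
  expect_length(projectImages(p3, "committed"), 0L)
  # invalid items are rejected
  expect_error(addImages(p, ImageItem(array(0.5, c(1, 8, 8))[, 0, , drop = FALSE])),
               "axes|axis")
  p4 <- commitProject(p2)
  expect_error(addImages(p4, projectImages(p4)[[1]]), "duplicate")
})

test_that("category registration is unique per kind and staged", {
  p <- createProject("demo")
  p <- registerCategory(p, "Image", "mitotic", c(255, 0, 0))
  cat <- findCategory(p, "Image", "mitotic")
  expect_identical(cat@kindId, "Image")
  expect_true(cat@id %in% projectKinds(p)[["Image"]]@categoryIds)
  expect_error(registerCategory(p, "Image", "mitotic"), "duplicate")
  expect_error(registerCategory(p, "nope", "x"), "unknown kind")
  # before commit the kind's committed view is unchanged
  expect_false(cat@id %in% projectKinds(p, "committed")[["Image"]]@categoryIds)
})

test_that("assignment stages category/partition and validates the kind", {
  cp <- classProject(nPerClass = 3, labelFirst = 0)
  p <- cp$project
  ids <- cp$ids
  p <- assignItems(p, ids[1:2], categoryId = cp$catId[["A"]],
                   partition = "validation")
  staged <- projectImages(p)[[ids[1]]]
  expect_identical(staged@categoryId, cp$catId[["A"]])
  expect_identical(staged@partition, "validation")
  expect_identical(projectImages(p, "committed")[[ids[1]]]@categoryId,
                   "Image/Unknown")
  # reassignment overwrites the staged value; back to Unknown restores
  p <- assignItems(p, ids[1:2], categoryId = "Image/Unknown")
  expect_identical(projectImages(p)[[ids[1]]]@categoryId, "Image/Unknown")
  # kind mismatch: an object category cannot label an image
  p2 <- registerKind(p, "cells")
  p2 <- registerCategory(p2, "cells", "round", c(1, 2, 3))
  expect_error(assignItems(p2, ids[1], categoryId =
                             findCategory(p2, "cells", "round")@id),
               "belongs to kind")
  expect_error(assignItems(p, "ghost", partition = "train"),
               "no image or annotation")
})

test_that("commit folds staged edits and clears the change set", {
  cp <- classProject(nPerClass = 2, labelFirst = 0)
  p <- assignItems(cp$project, cp$ids[1], categoryId = cp$catId[["B"]],
                   partition = "train")
  stagedView <- projectImages(p)[[cp$ids[1]]]
  p2 <- commitProject(p)
  expect_false(hasStagedChanges(p2))
  expect_equal(projectImages(p2, "committed")[[cp$ids[1]]], stagedView)
  # revert leaves the committed state untouched
  p3 <- assignItems(p2, cp$ids[1], partition = "inference")
  p3 <- revertProject(p3)
  expect_equal(projectImages(p3, "committed")[[cp$ids[1]]], stagedView)
  expect_equal(p3, p2)
})

test_that("selectSplit filters by kind, category and partition", {
  sp <- sceneProject()
  p <- sp$project
  blob <- findCategory(p, "object", "blob")@id
  allObj <- selectSplit(p, Split("object"))
  expect_length(allObj, 3L)
  expect_identical(allObj, sort(allObj))
  expect_identical(selectSplit(p, Split("object", categoryIds = blob)),
                   allObj)
  expect_identical(selectSplit(p, Split("Image", partitions = "validation")),
                   character(0))
  expect_error(selectSplit(p, Split("ghost")), "unknown kind")
  expect_error(selectSplit(p, Split("object", categoryIds = "ghost")),
               "unknown categories")
})

test_that("filters only ever narrow a split (monotone restriction)", {
  cp <- classProject(nPerClass = 5)
  p <- assignItems(cp$project, cp$ids[1:4], partition = "train")
  p <- commitProject(p)
  full <- selectSplit(p, Split("Image"))
  for (cats in list(character(), cp$catId[["A"]], cp$catId)) {
    for (parts in list(character(), "train", c("train", "validation"))) {
      sub <- selectSplit(p, Split("Image", categoryIds = cats,
                                  partitions = parts))
      expect_true(all(sub %in% full))
    }
  }
  expect_identical(full, sort(names(projectImages(p))))
})

test_that("referential integrity holds after committed operations", {
  sp <- sceneProject()
  p <- sp$project
  anns <- projectAnnotations(p, "committed")
  imgs <- names(projectImages(p, "committed"))
  kinds <- names(projectKinds(p, "committed"))
  cats <- names(projectCategories(p, "committed"))
  for (a in anns) {
    expect_true(a@imageId %in% imgs)
    expect_true(a@kindId %in% kinds)
    expect_true(a@categoryId %in% cats)
  }
  # annotations referencing missing entities are rejected
  orphan <- sp$scene$annotations[[1]]
  orphan@id <- "orphan"
  orphan@imageId <- "ghost"
  expect_error(addAnnotations(p, orphan), "missing image")
})
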