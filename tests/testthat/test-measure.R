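test_that("intensity statistics follow the printed MAD/quartile definitions", {
  s <- intensityStats(c(1, 2, 3, 4, 100))
  expect_equal(s$median, 3)
  expect_equal(s$mad, 1)  # deviations {2,1,0,1,97}, median 1
  expect_equal(s$lower_quartile, 2)
  expect_equal(s$upper_quartile, 4)
  # constant list
  sc <- intensityStats(rep(0.4, 7))
  expect_equal(sc$total, 2.8)
  expect_equal(sc$std, 0)
  expect_equal(sc$mad, 0)
  expect_equal(sc$lower_quartile, 0.4)
  expect_equal(sc$upper_quartile, 0.4)
  # nearest-rank quartiles on 1..100
  s100 <- intensityStats(1:100)
  expect_equal(s100$lower_quartile, 25)
  expect_equal(s100$upper_quartile, 75)
  expect_equal(s100$median, 50.5)
  # per-channel lists
  s2 <- intensityStats(list(c(0, 1), c(1, 1)))
  expect_equal(s2$channel, c(0L, 1L))
  expect_equal(s2$total, c(1, 2))
  expect_error(intensityStats(list(numeric())), "empty channel")
})

test_that("intensity statistics match a sort-based oracle on random lists", {
  withr::with_seed(11, {
    for (i in 1:100) {
      x <- stats::runif(sample(1:60, 1))
      got <- intensityStats(x)
      want <- oracleIntensity(x)
      expect_equal(got$total, want$total)
      expect_equal(got$mean, want$mean)
      expect_equal(got$median, want$median)
      expect_equal(got$std, want$std)
      expect_equal(got$mad, want$mad)
      expect_equal(got$lower_quartile, want$lower_quartile)
      expect_equal(got$upper_quartile, want$upper_quartile)
    }
  })
})

test_that("primitive geometry matches hand-enumerated reference masks", {
  one <- primitiveGeometry(matrix(TRUE, 1, 1))
  expect_equal(one, list(area = 1L, perimeter = 1L, bbox_area = 1L))
  sq <- primitiveGeometry(matrix(TRUE, 4, 4))
  expect_equal(sq$area, 16L)
  expect_equal(sq$perimeter, 12L)  # interior is the 2x2 core
  expect_equal(sq$bbox_area, 16L)
  plus <- generateShapeScene(SceneSpec(c(11, 11), list(
    list(shape = "plus", cx = 5.5, cy = 5.5, length = 9, width = 3,
         intensity = 1))))
  g <- plus$rasterized[[1]]
  expect_equal(g$area, 45)
  expect_equal(g$perimeter, 32)
  expect_equal(g$bbox_area, 81)
  expect_error(primitiveGeometry(matrix(FALSE, 3, 3)), "empty")
})

test_that("primitive geometry equals a per-pixel double-loop oracle", {
  withr::with_seed(23, {
    for (i in 1:200) {
      h <- sample(2:28, 1); w <- sample(2:28, 1)
      m <- randomBlobMask(h, w)
      got <- primitiveGeometry(m)
      want <- oracleGeometry(m)
      expect_identical(got$area, as.integer(want$area))
      expect_identical(got$perimeter, as.integer(want$perimeter))
      expect_identical(as.numeric(got$bbox_area), as.numeric(want$bbox_area))
    }
    # a few at the full 64x64 extent
    for (i in 1:5) {
      m <- randomBlobMask(64, 64)
      expect_identical(primitiveGeometry(m)[c("area", "perimeter")],
                       oracleGeometry(m)[c("area", "perimeter")])
    }
  })
})

test_that("derived geometry evaluates the closed-form descriptors", {
  # analytic circle r = 2: sphericity and compactness exactly 1
  dg <- derivedGeometry(4 * pi, 4 * pi, 16)
  expect_equal(dg$sphericity, 1)
  expect_equal(dg$compactness, 1)
  expect_equal(dg$equivalent_diameter, 4)
  expect_equal(dg$ped, 4)
  expect_equal(dg$extent, pi / 4)
  d2 <- derivedGeometry(100, 40, 100)
  expect_equal(d2$extent, 1)
  expect_equal(d2$equivalent_diameter, 11.2838, tolerance = 1e-4)
  expect_equal(d2$ped, 12.7324, tolerance = 1e-4)
  expect_equal(d2$sphericity, 0.8862, tolerance = 1e-4)
  # compactness x sphericity = 1 for arbitrary inputs
  withr::with_seed(2, {
    for (i in 1:20) {
      a <- stats::runif(1, 1, 500); pr <- stats::runif(1, 1, 200)
      g <- derivedGeometry(a, pr, a * stats::runif(1, 1, 3))
      expect_equal(g$compactness * g$sphericity, 1)
      expect_true(g$extent > 0 && g$extent <= 1)
    }
  })
  expect_error(derivedGeometry(0, 10, 10), "positive")
  expect_error(derivedGeometry(10, 10, 5), ">= area")
})

test_that("measureSplit produces per-item rows and split summaries", {
  sp <- sceneProject()
  tab <- measureSplit(sp$project, Split("object"),
                      c("area", "intensity_mean"))
  areas <- tab@rows$value[tab@rows$measurement == "area"]
  expect_setequal(areas, c(112, 80, 45))
  s <- tab@summaries[tab@summaries$measurement == "area", ]
  expect_equal(s$total, 237)
  expect_equal(s$median, 80)
  # object intensities are the pixels under the mask only (noise-free scene)
  mi <- tab@rows[tab@rows$measurement == "intensity_mean", ]
  expect_setequal(round(mi$value, 6), c(0.9, 0.7, 0.5))
  # empty split: empty table, no error
  p2 <- registerKind(sp$project, "empty")
  expect_identical(nrow(measureSplit(p2, Split("empty"), "area")@rows), 0L)
  # geometry on the Image kind is refused
  expect_error(measureSplit(sp$project, Split("Image"), "area"),
               "cannot be")
  expect_error(measureSplit(sp$project, Split("object"), "no_such"),
               "unknown measurements")
  # image-level intensity works per channel
  ti <- measureSplit(sp$project, Split("Image"), "intensity_total")
  expect_identical(nrow(ti@rows), 1L)
  img <- projectImages(sp$project)[[1]]
  expect_equal(ti@rows$value, sum(img@pixels))
})

test_that("split summaries are invariant under item order", {
  sp <- sceneProject()
  tab <- measureSplit(sp$project, Split("object"), "area")
  # rebuild the project with annotations added in reverse order
  sc <- sp$scene
  p <- createProject("scene")
  p <- addImages(p, sc$image)
  p <- registerKind(p, "object")
  p <- registerCategory(p, "object", "blob", c(0, 0, 255))
  p <- commitProject(p)
  blob <- findCategory(p, "object", "blob")@id
  anns <- rev(lapply(sc$annotations, function(a) { a@categoryId <- blob; a }))
  p <- commitProject(addAnnotations(p, anns))
  tab2 <- measureSplit(p, Split("object"), "area")
  expect_equal(tab@summaries, tab2@summaries)
})

test_that("measurements are cached until the underlying mask changes", {
  sp <- sceneProject()
  clearMeasureCache()
  invisible(measureSplit(sp$project, Split("object"), "area"))
  expect_identical(measureCacheHits(), 0L)
  invisible(measureSplit(sp$project, Split("object"), "area"))
  expect_identical(measureCacheHits(), 3L)  # one hit per cached object
  # a changed mask misses the cache and recomputes
  p <- sp$project
  a <- projectAnnotations(p)[[1]]
  ext <- dim(projectImages(p)[[a@imageId]]@pixels)[3:4]
  full <- annotationFullMask(a, ext)
  full[min(which(rowSums(full) > 0)), ] <- FALSE  # shave the top row
  ann2 <- maskToAnnotation(full, a@imageId, a@kindId, a@categoryId,
                           id = "changed")
  p <- commitProject(addAnnotations(p, ann2))
  before <- measureCacheHits()
  tab <- measureSplit(p, Split(a@kindId), "area")
  expect_identical(measureCacheHits(), before + 3L)  # 3 old hits, 1 miss
  expect_setequal(tab@rows$value[tab@rows$item_id == "changed"], sum(full))
})

test_that("plot series compute histogram, scatter and swarm data", {
  rows <- data.frame(item_id = sprintf("i%02d", 1:3), kind = "object",
                     category = "blob", partition = "unassigned",
                     measurement = "area", channel = NA_integer_,
                     value = c(10, 20, 30))
  tab <- new("MeasurementTable", rows = rows,
             summaries = pixikit:::summarizeRows(rows),
             split = Split("object"))
  h <- plotSeries(tab, "histogram", x = "area", bins = 2)
  expect_equal(h$edges, c(10, 20, 30))
  expect_equal(h$counts, c(1, 2))  # half-open bins, last bin closed
  expect_error(plotSeries(tab, "histogram", x = "area", bins = 0), ">= 1")
  expect_error(plotSeries(tab, "histogram", x = "nope"), "unknown")
  # swarm overlay reuses the intensity-stats conventions
  rows100 <- data.frame(item_id = sprintf("i%03d", 1:100), kind = "k",
                        category = "g", partition = "unassigned",
                        measurement = "v", channel = NA_integer_,
                        value = 1:100)
  tab100 <- new("MeasurementTable", rows = rows100,
                summaries = pixikit:::summarizeRows(rows100),
                split = Split("object"))
  sw <- plotSeries(tab100, "swarm", y = "v", overlay = TRUE)
  expect_equal(sw$overlay$g$median, 50.5)
  expect_equal(sw$overlay$g$lower_quartile, 25)
  expect_equal(sw$overlay$g$upper_quartile, 75)
  # scatter: one point per row, sizes monotone in the size measurement
  sc <- plotSeries(tab, "scatter", x = "area", y = "area", size = "area")
  expect_length(sc$x, 3L)
  expect_true(all(diff(sc$size[order(sc$x)]) >= 0))
})
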