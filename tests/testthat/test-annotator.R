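test_that("shape rasterization follows the pixel-center rule", {
  m <- rasterizeShape(ShapeSpec("rectangle", x = 2, y = 3, width = 4,
                                height = 5), c(20, 20))
  expect_identical(sum(m), 20L)
  ann <- maskToAnnotation(m, "img", "Image")
  expect_equal(ann@bbox, c(2, 3, 4, 5))
  # square polygon coincides with the rectangle of the same corners
  pg <- rasterizeShape(ShapeSpec("polygon",
                                 vertices = rbind(c(0, 0), c(0, 4),
                                                  c(4, 4), c(4, 0))),
                       c(20, 20))
  rc <- rasterizeShape(ShapeSpec("rectangle", x = 0, y = 0, width = 4,
                                 height = 4), c(20, 20))
  expect_identical(pg, rc)
  expect_error(rasterizeShape(ShapeSpec("ellipse", cx = 100, cy = 100,
                                        rx = 2, ry = 2), c(20, 20)),
               "empty annotation")
  expect_error(ShapeSpec("polygon", vertices = rbind(c(0, 0), c(1, 1))),
               "3")
})

test_that("SLIC partitions the slice into compact homogeneous segments", {
  u <- array(0.5, c(1, 30, 30))
  sp <- computeSuperpixels(u, 9)
  areas <- table(sp@labels)
  expect_length(areas, 9L)
  expect_identical(sum(areas), 900L)          # a partition: every pixel once
  expect_true(all(areas <= 2 * mean(areas)))  # area balance within 2x mean
  expect_true(all(areas > 0))
  # n_segments = 1: one label covering everything
  sp1 <- computeSuperpixels(u, 1)
  expect_identical(unique(as.vector(sp1@labels)), 1L)
  # two solid color halves, k = 2: labels are color-pure
  halves <- array(0, c(1, 30, 30)); halves[1, , 16:30] <- 1
  sp2 <- computeSuperpixels(halves, 2)
  for (lv in unique(as.vector(sp2@labels)))
    expect_equal(stats::var(halves[1, , ][sp2@labels == lv]), 0)
  # determinism
  expect_identical(computeSuperpixels(u, 9)@labels, sp@labels)
  expect_error(computeSuperpixels(u, 0), "between")
  expect_error(computeSuperpixels(u, 1000), "between")
})

test_that("quick-select returns unions of whole superpixels", {
  img <- array(stats::runif(3 * 24 * 24), c(3, 24, 24))
  sp <- computeSuperpixels(img, 6)
  m1 <- quickSelect(sp, rbind(c(5, 5)))
  expect_identical(m1, sp@labels == sp@labels[5, 5])
  # second seed in the same superpixel changes nothing
  inSame <- which(sp@labels == sp@labels[5, 5], arr.ind = TRUE)
  m2 <- quickSelect(sp, rbind(c(5, 5), inSame[nrow(inSame), ]))
  expect_identical(m2, m1)
  # seeds covering all labels select everything
  seeds <- do.call(rbind, lapply(sort(unique(as.vector(sp@labels))),
                                 function(lv)
                                   which(sp@labels == lv, arr.ind = TRUE)[1, ]))
  expect_true(all(quickSelect(sp, seeds)))
  # every result is a union of whole superpixels
  m3 <- quickSelect(sp, rbind(c(1, 1), c(20, 20)))
  for (lv in unique(as.vector(sp@labels[m3])))
    expect_true(all(m3[sp@labels == lv]))
  expect_error(quickSelect(sp, rbind(c(0, 5))), "outside")
})

test_that("flood fill grows an exact 4-connected tolerance region", {
  # constant image, tolerance 0: everything is reachable
  expect_true(all(floodFillSelect(array(0.5, c(1, 6, 6)), c(3, 3), 0)))
  # isolated uniform disk on contrasting background: exactly the disk
  sc <- generateShapeScene(SceneSpec(c(20, 20), list(
    list(shape = "disk", cx = 10, cy = 10, r = 5, intensity = 0.9)),
    background = 0.1))
  sl <- imageSlice(sc$image, 0)
  disk <- annotationFullMask(sc$annotations[[1]], c(20, 20))
  expect_identical(floodFillSelect(sl, c(10, 10), 0.3), disk)
  # unique seed color at tolerance 0: a single pixel
  img <- array(0, c(1, 5, 5)); img[1, 3, 3] <- 0.7
  m <- floodFillSelect(img, c(3, 3), 0)
  expect_identical(sum(m), 1L)
  expect_true(m[3, 3])
  # result contains the seed and is 4-connected
  m2 <- floodFillSelect(sl, c(10, 10), 0.3)
  lab <- pixikit:::labelComponents(m2)
  expect_identical(max(lab), 1L)
  expect_error(floodFillSelect(sl, c(25, 3), 0.1), "outside")
  expect_error(floodFillSelect(sl, c(3, 3), -1), ">= 0")
})

test_that("threshold tool selects by channel-mean intensity inside the box", {
  img <- array(0.8, c(1, 10, 10)); img[1, 3:4, 3:5] <- 0.2
  sel <- thresholdSelect(img, c(0, 0, 10, 10), 0.5, "below")
  expect_identical(sum(sel), 6L)
  expect_true(all(which(sel, arr.ind = TRUE)[, 1] %in% 3:4))
  expect_identical(sum(thresholdSelect(img, c(2, 2, 4, 4), 1, "below")), 16L)
  expect_identical(sum(thresholdSelect(img, c(2, 2, 4, 4), 0, "below")), 0L)
  # polarity switch selects the complement inside the box
  above <- thresholdSelect(img, c(0, 0, 10, 10), 0.5, "above")
  expect_identical(sum(above), 94L)
  # restricted to the bbox by construction
  sel2 <- thresholdSelect(img, c(5, 5, 3, 3), 1, "below")
  expect_true(all(which(sel2, arr.ind = TRUE)[, 1] %in% 6:8))
  expect_error(thresholdSelect(img, c(0, 0, 0, 3), 0.5), "degenerate")
  expect_error(thresholdSelect(img, c(8, 8, 5, 5), 0.5), "outside")
})

test_that("mask combination is set union / difference", {
  withr::with_seed(4, {
    for (i in 1:10) {
      m <- matrix(stats::runif(100) > 0.5, 10, 10)
      e <- matrix(stats::runif(100) > 0.5, 10, 10)
      expect_identical(combineMasks(m, m, "add"), m)
      expect_false(any(combineMasks(m, m, "subtract")))
      back <- combineMasks(combineMasks(m, e, "add"), e, "subtract")
      expect_true(all(back[m & !e]))   # contains m \ e
      expect_true(all(!back | m))      # subset of m
    }
  })
  expect_error(combineMasks(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)),
               "mismatch")
})

test_that("mask-to-annotation crops tightly and round-trips losslessly", {
  full <- matrix(FALSE, 30, 30)
  full[13:17, 11:14] <- TRUE  # 5x4 blob at (x=10, y=12)
  ann <- maskToAnnotation(full, "img", "obj")
  expect_equal(ann@bbox, c(10, 12, 4, 5))
  expect_identical(dim(ann@mask), c(5L, 4L))
  expect_identical(annotationFullMask(ann, c(30, 30)), full)
  expect_error(maskToAnnotation(matrix(FALSE, 5, 5), "img", "obj"), "empty")
  # blob touching the border still satisfies every invariant
  edge <- matrix(FALSE, 10, 10); edge[1:3, 8:10] <- TRUE
  annE <- maskToAnnotation(edge, "img", "obj")
  expect_true(validObject(annE))
  expect_equal(annE@bbox, c(7, 0, 3, 3))
  # any selection-operator output round-trips through an annotation
  sc <- generateShapeScene(SceneSpec(c(20, 20), list(
    list(shape = "disk", cx = 10, cy = 10, r = 5, intensity = 0.9)),
    background = 0.1))
  m <- floodFillSelect(imageSlice(sc$image, 0), c(10, 10), 0.3)
  expect_identical(annotationFullMask(maskToAnnotation(m, "i", "k"),
                                      c(20, 20)), m)
})
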