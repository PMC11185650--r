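# Shared fixtures and independent brute-force oracles. Oracles are written
# as naive per-element loops so they share no code path with the package.

# per-pixel double-loop geometry oracle (area, inner-boundary perimeter
# with 8-neighbor background test, tight bounding box)
oracleGeometry <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  area <- 0L; per <- 0L
  rmin <- Inf; rmax <- -Inf; cmin <- Inf; cmax <- -Inf
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!mask[r, c]) next
    area <- area + 1L
    rmin <- min(rmin, r); rmax <- max(rmax, r)
    cmin <- min(cmin, c); cmax <- max(cmax, c)
    boundary <- FALSE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1L || rr > h || cc < 1L || cc > w || !mask[rr, cc])
        boundary <- TRUE
    }
    if (boundary) per <- per + 1L
  }
  list(area = area, perimeter = per,
       bbox_area = (rmax - rmin + 1) * (cmax - cmin + 1))
}

# sort-based intensity oracle following the printed definitions directly
oracleIntensity <- function(x) {
  s <- sort(x); n <- length(s)
  med <- if (n %% 2L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
  devs <- sort(abs(x - med))
  madv <- if (n %% 2L) devs[(n + 1L) / 2L]
          else (devs[n / 2L] + devs[n / 2L + 1L]) / 2
  mu <- sum(x) / n
  list(total = sum(x), mean = mu, median = med,
       std = sqrt(sum((x - mu)^2) / n), mad = madv,
       lower_quartile = s[max(1L, ceiling(0.25 * n))],
       upper_quartile = s[max(1L, ceiling(0.75 * n))])
}

# brute-force confusion-matrix metrics
oracleEvaluate <- function(predicted, truth, classes) {
  k <- length(classes)
  cm <- matrix(0L, k, k, dimnames = list(classes, classes))
  for (i in seq_along(truth))
    cm[truth[i], predicted[i]] <- cm[truth[i], predicted[i]] + 1L
  prec <- rec <- f1 <- numeric(k)
  for (ci in seq_len(k)) {
    tp <- cm[ci, ci]; fp <- sum(cm[, ci]) - tp; fn <- sum(cm[ci, ]) - tp
    prec[ci] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[ci] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[ci] <- if (prec[ci] + rec[ci] > 0)
      2 * prec[ci] * rec[ci] / (prec[ci] + rec[ci]) else 0
  }
  list(cm = cm, precision = prec, recall = rec, f1 = f1,
       accuracy = sum(diag(cm)) / sum(cm), macroF1 = mean(f1))
}

randomBlobMask <- function(h, w) {
  m <- matrix(stats::runif(h * w) > 0.55, h, w)
  if (!any(m)) m[sample(h * w, 1L)] <- TRUE
  m
}

# a committed project holding a rendered scene with categorized objects
sceneProject <- function(extent = c(40, 50), seed = 5L) {
  sc <- generateShapeScene(SceneSpec(extent, list(
    list(shape = "disk", cx = 12, cy = 12, r = 6, intensity = 0.9),
    list(shape = "rectangle", x = 30, y = 20, width = 8, height = 10,
         intensity = 0.7),
    list(shape = "plus", cx = 25.5, cy = 30.5, length = 9, width = 3,
         intensity = 0.5)), background = 0.1, seed = seed))
  p <- createProject("scene")
  p <- addImages(p, sc$image)
  p <- registerKind(p, "object")
  p <- registerCategory(p, "object", "blob", c(0, 0, 255))
  p <- commitProject(p)
  blob <- findCategory(p, "object", "blob")@id
  anns <- lapply(sc$annotations, function(a) { a@categoryId <- blob; a })
  p <- commitProject(addAnnotations(p, anns))
  list(project = p, scene = sc)
}

# a committed project with the labeled two-class dataset
classProject <- function(nPerClass = 50, seed = 7L, labelFirst = nPerClass) {
  ds <- generateClassDataset(nPerClass, seed = seed)
  p <- createProject("classes")
  p <- registerCategory(p, "Image", "A", c(255, 0, 0))
  p <- registerCategory(p, "Image", "B", c(0, 255, 0))
  p <- addImages(p, ds$items)
  p <- commitProject(p)
  ids <- sort(names(projectImages(p)))
  itemIds <- vapply(ds$items, slot, character(1), "id")
  labels <- ds$labels[match(ids, itemIds)]
  catId <- c(A = findCategory(p, "Image", "A")@id,
             B = findCategory(p, "Image", "B")@id)
  for (cls in c("A", "B")) {
    lab <- ids[labels == cls]
    if (labelFirst > 0)
      p <- assignItems(p, lab[seq_len(min(labelFirst, length(lab)))],
                       categoryId = catId[[cls]])
  }
  p <- commitProject(p)
  list(project = p, ids = ids, labels = labels, catId = catId)
}
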