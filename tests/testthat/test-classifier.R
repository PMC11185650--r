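test_that("model building is deterministic and shapes the output layer", {
  cfg <- ClassifierConfig(inputExtent = c(28, 28, 1), seed = 3L)
  st <- buildModel(cfg, paste0("c", 1:10))
  head <- st@weights[["head.W"]]
  expect_identical(ncol(head), 10L)
  st2 <- buildModel(cfg, paste0("c", 1:10))
  expect_identical(st@weights, st2@weights)
  expect_identical(st@epochsCompleted, 0L)
  expect_error(buildModel(cfg, "one"), "at least 2")
  expect_error(buildModel(ClassifierConfig(lossName = "nope"), c("a", "b")),
               "unregistered loss")
  # transfer head: only the final dense layer is trainable
  tcfg <- ClassifierConfig(architecture = "transfer_head", seed = 3L)
  ts <- buildModel(tcfg, c("a", "b"))
  trainable <- pixikit:::trainableParams(ts@layers)
  expect_setequal(trainable, c("head.W", "head.b"))
  expect_true(parameterCount(ts, trainableOnly = TRUE) <
                parameterCount(ts))
})

test_that("bilinear input resize agrees with an independent implementation", {
  withr::with_seed(1, {
    m <- matrix(stats::runif(12 * 17), 12, 17)
    up <- pixikit:::bilinearResize(m, 30, 41)
    down <- pixikit:::bilinearResize(m, 5, 7)
    expect_equal(up, EBImage::resize(m, w = 30, h = 41, filter = "bilinear"),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(down, EBImage::resize(m, w = 5, h = 7, filter = "bilinear"),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_identical(pixikit:::bilinearResize(m, 12, 17), m)
  })
})

test_that("train/validation split is stratified, disjoint and seeded", {
  ids <- sprintf("i%03d", 1:100)
  labels <- rep(c("A", "B"), each = 50)
  sp <- splitTrainVal(ids, labels, 0.8, seed = 5L)
  expect_length(sp$train, 80L)
  expect_length(sp$val, 20L)
  expect_length(intersect(sp$train, sp$val), 0L)
  perClass <- table(labels[match(sp$train, ids)])
  expect_true(all(abs(perClass - 40) <= 1))
  expect_identical(splitTrainVal(ids, labels, 0.8, seed = 5L), sp)
  expect_false(identical(splitTrainVal(ids, labels, 0.8, seed = 6L), sp))
  expect_error(splitTrainVal(ids, labels, 1.0, seed = 1L), "between")
  expect_warning(splitTrainVal(c("a", "b", "c"), c("A", "A", "B"), 0.5, 1L),
                 "stratified")
})

test_that("fitting resumes with carried optimizer state", {
  cp <- classProject(nPerClass = 15, seed = 31L)
  cfg <- ClassifierConfig(seed = 9L)
  stA <- buildModel(cfg, c("A", "B"))
  stA <- fitClassifier(stA, cp$project, cp$ids, additionalEpochs = 5)
  expect_identical(stA@epochsCompleted, 5L)
  expect_identical(nrow(stA@history), 5L)
  stA <- fitClassifier(stA, cp$project, cp$ids, additionalEpochs = 5)
  expect_identical(stA@epochsCompleted, 10L)
  expect_identical(stA@history$epoch, 1:10)
  # resume is equivalent to training straight through (same seeds, same data)
  stB <- buildModel(cfg, c("A", "B"))
  stB <- fitClassifier(stB, cp$project, cp$ids, additionalEpochs = 10)
  expect_equal(stA@weights, stB@weights)
  expect_equal(stA@history, stB@history)
  # the resumed epoch starts near the previous stop, not from scratch
  fresh <- buildModel(cfg, c("A", "B"))
  fresh <- fitClassifier(fresh, cp$project, cp$ids, additionalEpochs = 1)
  resumedLoss <- stA@history$train_loss[6]
  stoppedLoss <- stA@history$train_loss[5]
  freshLoss <- fresh@history$train_loss[1]
  expect_lt(abs(resumedLoss - stoppedLoss), abs(freshLoss - stoppedLoss))
})

test_that("unlabeled or foreign labels are rejected at fit time", {
  cp <- classProject(nPerClass = 4, labelFirst = 2)
  cfg <- ClassifierConfig(seed = 1L)
  st <- buildModel(cfg, c("A", "B"))
  expect_error(fitClassifier(st, cp$project, cp$ids), "Unknown")
  p <- registerCategory(cp$project, "Image", "C", c(9, 9, 9))
  cid <- findCategory(p, "Image", "C")@id
  p <- commitProject(assignItems(p, cp$ids, categoryId = cid))
  expect_error(fitClassifier(st, p, cp$ids), "class names")
})

test_that("frozen backbone parameters never change during training", {
  cp <- classProject(nPerClass = 10, seed = 13L)
  cfg <- ClassifierConfig(architecture = "transfer_head", seed = 2L,
                          learningRate = 0.1)
  st <- buildModel(cfg, c("A", "B"))
  frozenBefore <- st@weights[c("conv1.W", "conv1.b", "conv2.W", "conv2.b")]
  st <- fitClassifier(st, cp$project, cp$ids, additionalEpochs = 3)
  frozenAfter <- st@weights[c("conv1.W", "conv1.b", "conv2.W", "conv2.b")]
  expect_identical(frozenBefore, frozenAfter)
  expect_false(identical(st@weights[["head.W"]],
                         buildModel(cfg, c("A", "B"))@weights[["head.W"]]))
})

test_that("prediction returns valid softmax probabilities deterministically", {
  cp <- classProject(nPerClass = 10, seed = 17L)
  cfg <- ClassifierConfig(seed = 4L)
  st <- buildModel(cfg, c("A", "B"))
  expect_error(predictClassifier(st, cp$project, cp$ids), "not been trained")
  st <- fitClassifier(st, cp$project, cp$ids, additionalEpochs = 3)
  pred <- predictClassifier(st, cp$project, cp$ids[c(1, 2, 1)])
  expect_equal(rowSums(pred$probabilities), rep(1, 3), tolerance = 1e-6)
  expect_true(all(pred$probabilities >= 0))
  # duplicated item: identical probabilities both times
  expect_identical(pred$probabilities[1, ], pred$probabilities[3, ])
  expect_identical(pred$categories,
                   st@classNames[max.col(pred$probabilities)])
})

test_that("evaluation metrics match closed forms and a brute-force oracle", {
  # perfect predictions
  r <- evaluateClassifier(c("a", "b", "a"), c("a", "b", "a"))
  expect_identical(diag(r@confusionMatrix), c(a = 2L, b = 1L))
  expect_equal(r@accuracy, 1)
  expect_equal(r@perClass$f1, c(1, 1))
  # all-one-class prediction over balanced truth
  r2 <- evaluateClassifier(rep("a", 10), rep(c("a", "b"), 5), c("a", "b"))
  expect_equal(r2@accuracy, 0.5)
  expect_equal(r2@perClass$recall[r2@perClass$class == "b"], 0)
  # printed 2x2 table: TP=8 FP=2 FN=2 TN=8
  truth <- c(rep("pos", 10), rep("neg", 10))
  pred <- c(rep("pos", 8), rep("neg", 2), rep("pos", 2), rep("neg", 8))
  r3 <- evaluateClassifier(pred, truth, c("pos", "neg"))
  pc <- r3@perClass[r3@perClass$class == "pos", ]
  expect_equal(pc$precision, 0.8)
  expect_equal(pc$recall, 0.8)
  expect_equal(pc$f1, 0.8)
  # row sums equal ground-truth counts; random-pair oracle agreement
  withr::with_seed(7, {
    for (i in 1:20) {
      classes <- c("x", "y", "z")
      tr <- sample(classes, 30, replace = TRUE)
      pr <- sample(classes, 30, replace = TRUE)
      got <- evaluateClassifier(pr, tr, classes)
      want <- oracleEvaluate(pr, tr, classes)
      expect_equal(unname(rowSums(got@confusionMatrix)),
                   unname(as.numeric(table(factor(tr, classes)))))
      expect_equal(unname(got@confusionMatrix), unname(want$cm))
      expect_equal(got@perClass$f1, want$f1)
      expect_equal(got@accuracy, want$accuracy)
      expect_equal(got@macroF1, want$macroF1)
    }
  })
  expect_error(evaluateClassifier(character(), character()), "nonempty")
})

test_that("a human-in-the-loop round stages predictions for review", {
  cp <- classProject(nPerClass = 12, labelFirst = 8, seed = 19L)
  cfg <- ClassifierConfig(seed = 6L, epochs = 5L)
  st <- buildModel(cfg, c("A", "B"))
  r <- hitlRound(cp$project, st)
  expect_s4_class(r$report, "EvaluationReport")
  expect_identical(r$state@epochsCompleted, 5L)
  # the 8 unlabeled items now carry staged (uncommitted) predicted labels
  staged <- projectImages(r$project, "staged")
  committed <- projectImages(r$project, "committed")
  unl <- names(committed)[vapply(committed, function(i)
    i@categoryId == "Image/Unknown", logical(1))]
  expect_length(unl, 8L)
  stagedCats <- vapply(staged[unl], slot, character(1), "categoryId")
  expect_true(all(stagedCats != "Image/Unknown"))
  # with no unlabeled pool the round is fit + evaluate only
  cp2 <- classProject(nPerClass = 6, seed = 23L)
  r2 <- hitlRound(cp2$project, buildModel(cfg, c("A", "B")))
  expect_equal(r2$project, cp2$project)
  # degenerate corrections: everything one class -> next fit errors
  pAll <- commitProject(assignItems(cp2$project, cp2$ids,
                                    categoryId = cp2$catId[["A"]]))
  expect_error(hitlRound(pAll, r2$state), "2 classes")
})
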