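#' Build an untrained classifier
#'
#' \code{simple_cnn} is a small convolutional stack (two 3x3 conv blocks
#' with ReLU and 2x2 max-pooling) ending in global average pooling and a
#' dense softmax layer. \code{transfer_head} uses the same stack as a
#' frozen feature extractor (weights fixed at their seeded initialization,
#' standing in for any registered frozen backbone) and trains only the final
#' dense layer. Weight initialization is a pure function of the config seed.
#'
#' @param config a [ClassifierConfig-class].
#' @param classNames ordered category names (>= 2); fixes the class order
#'   for training, prediction and the confusion matrix.
#' @return A [TrainingState-class] with zero epochs completed.
#' @export
buildModel <- function(config, classNames) {
  validObject(config)
  nClasses <- length(classNames)
  if (nClasses < 2L) stop("need at least 2 classes")
  lossFunction(config@lossName)  # fail early on unregistered loss
  layers <- simpleCnnLayers(config@inputExtent, nClasses,
                            frozenBackbone = config@architecture == "transfer_head")
  weights <- initWeights(layers, config@seed)
  new("TrainingState", layers = layers, weights = weights,
      optimizerState = list(), epochsCompleted = 0L,
      history = data.frame(epoch = integer(), train_loss = numeric(),
                           train_accuracy = numeric(), val_loss = numeric(),
                           val_accuracy = numeric()),
      classNames = classNames, config = config)
}

#' Parameter count of a model
#'
#' @param state a [TrainingState-class].
#' @param trainableOnly count only trainable parameters.
#' @return Integer parameter count.
#' @export
parameterCount <- function(state, trainableOnly = FALSE) {
  nm <- names(state@weights)
  if (trainableOnly) nm <- intersect(nm, trainableParams(state@layers))
  sum(vapply(nm, function(p) length(state@weights[[p]]), integer(1)))
}

#' Stratified train/validation split
#'
#' Splits labeled item ids into disjoint train and validation sets,
#' stratified by label where possible (per-class counts balanced within one
#' item of the ideal fraction) and deterministic for a fixed seed. A class
#' with a single item cannot be stratified; the split falls back to plain
#' random sampling with a warning.
#'
#' @param itemIds labeled item ids.
#' @param labels label per item (same length).
#' @param trainFraction fraction assigned to training, in (0, 1).
#' @param seed integer seed.
#' @return List with \code{train} and \code{val} id vectors.
#' @export
splitTrainVal <- function(itemIds, labels, trainFraction, seed) {
  n <- length(itemIds)
  if (n < 2L) stop("need at least 2 labeled items")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be strictly between 0 and 1")
  nTrain <- round(trainFraction * n)
  nTrain <- min(max(nTrain, 1L), n - 1L)
  counts <- table(labels)
  withLocalSeed(seed, {
    if (any(counts < 2L)) {
      warning("a class with a single item cannot be stratified; ",
              "falling back to a random split")
      train <- sort(sample(itemIds, nTrain))
    } else {
      train <- character()
      classes <- names(counts)
      perClass <- floor(trainFraction * counts)
      perClass <- pmax(perClass, 1L)
      remainder <- nTrain - sum(perClass)
      # distribute the remainder over classes in a fixed order
      if (remainder > 0) {
        extra <- rep_len(seq_along(classes), remainder)
        for (i in extra)
          perClass[i] <- min(perClass[i] + 1L, counts[i] - 1L)
      }
      for (ci in seq_along(classes)) {
        ids <- itemIds[labels == classes[ci]]
        train <- c(train, sample(ids, perClass[ci]))
      }
      train <- sort(train)
    }
    list(train = train, val = sort(setdiff(itemIds, train)))
  })
}

# Bilinear resize of a matrix to (outH, outW); pixel centers are aligned so
# that the source and target grids span the same [0, 1]^2 extent.
bilinearResize <- function(m, outH, outW) {
  inH <- nrow(m); inW <- ncol(m)
  if (inH == outH && inW == outW) return(m)
  ys <- ((seq_len(outH) - 0.5) * inH / outH) - 0.5
  xs <- ((seq_len(outW) - 0.5) * inW / outW) - 0.5
  y0 <- pmin(pmax(floor(ys), 0), inH - 1); y1 <- pmin(y0 + 1, inH - 1)
  x0 <- pmin(pmax(floor(xs), 0), inW - 1); x1 <- pmin(x0 + 1, inW - 1)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  a <- m[y0 + 1, x0 + 1, drop = FALSE] * ((1 - wy) %o% (1 - wx))
  b <- m[y1 + 1, x0 + 1, drop = FALSE] * (wy %o% (1 - wx))
  cc <- m[y0 + 1, x1 + 1, drop = FALSE] * ((1 - wy) %o% wx)
  dd <- m[y1 + 1, x1 + 1, drop = FALSE] * (wy %o% wx)
  a + b + cc + dd
}

# Standardize one item (image or object crop) to (H, W, C) per the config:
# bilinear resize, channel adaptation, per-item min-max to [0, 1].
itemTensor <- function(project, id, config, view = "staged") {
  ext <- config@inputExtent
  coll <- itemCollection(project, id, view)
  if (is.na(coll)) stop("no image or annotation with id: ", id)
  if (coll == "images") {
    img <- projectImages(project, view)[[id]]
    sl <- imageSlice(img, 0L)
  } else {
    ann <- projectAnnotations(project, view)[[id]]
    img <- projectImages(project, view)[[ann@imageId]]
    sl <- imageSlice(img, ann@zIndex)
    b <- ann@bbox
    sl <- sl[, (b[2] + 1):(b[2] + b[4]), (b[1] + 1):(b[1] + b[3]),
             drop = FALSE]
    for (ch in seq_len(dim(sl)[1])) sl[ch, , ][!ann@mask] <- 0
  }
  nc <- dim(sl)[1]
  if (nc != ext[3]) {
    if (ext[3] == 1L) {
      sl <- array(apply(sl, c(2, 3), mean), c(1L, dim(sl)[2:3]))
    } else if (nc == 1L) {
      sl <- array(rep(sl, each = 1),
                  c(1L, dim(sl)[2:3]))[rep(1L, ext[3]), , , drop = FALSE]
    } else stop("cannot adapt ", nc, " channels to ", ext[3])
  }
  out <- array(0, c(ext[1], ext[2], ext[3]))
  for (ch in seq_len(ext[3]))
    out[, , ch] <- bilinearResize(sl[ch, , ], ext[1], ext[2])
  rng <- range(out)
  if (rng[2] > rng[1]) out <- (out - rng[1]) / (rng[2] - rng[1])
  out
}

itemsTensor <- function(project, ids, config, view = "staged") {
  ext <- config@inputExtent
  x <- array(0, c(length(ids), ext[1], ext[2], ext[3]))
  for (i in seq_along(ids))
    x[i, , , ] <- itemTensor(project, ids[i], config, view)
  x
}

itemLabels <- function(project, ids, view = "staged") {
  cats <- projectCategories(project, view)
  vapply(ids, function(id) {
    coll <- itemCollection(project, id, view)
    item <- collectionView(project, coll, view)[[id]]
    cats[[item@categoryId]]@name
  }, character(1))
}

#' Fit (or resume fitting) a classifier on labeled items
#'
#' Every item must carry a non-"Unknown" category whose name is among the
#' model's class names. The labeled pool is split into train/validation
#' (stratified, driven by the config seed and trainFraction); training then
#' runs for \code{additionalEpochs} epochs, carrying the optimizer momentum
#' state across calls so a later call resumes rather than restarts.
#'
#' @param state a [TrainingState-class].
#' @param project a [Project-class].
#' @param itemIds labeled image or annotation ids.
#' @param additionalEpochs epochs to run now (default: config epochs).
#' @param view project view to read.
#' @return The updated [TrainingState-class].
#' @export
fitClassifier <- function(state, project, itemIds, additionalEpochs = NULL,
                          view = "staged") {
  config <- state@config
  if (is.null(additionalEpochs)) additionalEpochs <- config@epochs
  labels <- itemLabels(project, itemIds, view)
  if (any(labels == "Unknown"))
    stop("training items must be labeled with a non-\"Unknown\" category")
  bad <- setdiff(unique(labels), state@classNames)
  if (length(bad))
    stop("labels outside the model's class names: ",
         paste(bad, collapse = ", "))
  if (length(unique(labels)) < 2L)
    stop("training requires items from at least 2 classes")
  sp <- splitTrainVal(itemIds, labels, config@trainFraction, config@seed)
  xTrain <- itemsTensor(project, sp$train, config, view)
  yTrain <- match(labels[match(sp$train, itemIds)], state@classNames)
  xVal <- itemsTensor(project, sp$val, config, view)
  yVal <- match(labels[match(sp$val, itemIds)], state@classNames)
  lossFn <- lossFunction(config@lossName)
  trainable <- trainableParams(state@layers)
  weights <- state@weights
  velocity <- state@optimizerState
  hist <- state@history
  for (e in seq_len(additionalEpochs)) {
    globalEpoch <- state@epochsCompleted + e
    shuffleSeed <- (config@seed %% 100000L) * 20011L + globalEpoch
    r <- runEpoch(state@layers, weights, velocity, xTrain, yTrain, lossFn,
                  config@learningRate, config@batchSize, shuffleSeed,
                  trainable)
    weights <- r$weights
    velocity <- r$velocity
    v <- evaluateLoss(state@layers, weights, xVal, yVal, lossFn)
    hist <- rbind(hist, data.frame(
      epoch = globalEpoch, train_loss = r$loss, train_accuracy = r$accuracy,
      val_loss = v$loss, val_accuracy = v$accuracy))
  }
  state@weights <- weights
  state@optimizerState <- velocity
  state@epochsCompleted <- state@epochsCompleted + as.integer(additionalEpochs)
  state@history <- hist
  validObject(state)
  state
}

#' Predict categories for items
#'
#' @param state a trained [TrainingState-class] (>= 1 epoch).
#' @param project a [Project-class].
#' @param itemIds image or annotation ids.
#' @param view project view to read.
#' @return List with \code{itemIds}, \code{categories} (argmax class names)
#'   and \code{probabilities} (items x classes matrix, rows sum to 1).
#' @export
predictClassifier <- function(state, project, itemIds, view = "staged") {
  if (state@epochsCompleted < 1L) stop("model has not been trained yet")
  x <- itemsTensor(project, itemIds, state@config, view)
  probs <- networkForward(state@layers, state@weights, x)$probs
  colnames(probs) <- state@classNames
  list(itemIds = itemIds,
       categories = state@classNames[max.col(probs, ties.method = "first")],
       probabilities = probs)
}

#' Evaluate predictions against ground truth
#'
#' Builds the class-by-class confusion matrix (rows = truth, columns =
#' predicted) and per-class precision, recall and F1 (harmonic mean of
#' precision and recall), plus accuracy (trace / total) and macro-F1
#' (unweighted mean of per-class F1; classes absent from both truth and
#' prediction contribute an F1 of 0 only if listed in \code{classNames}).
#'
#' @param predicted predicted class names.
#' @param truth ground-truth class names, same length.
#' @param classNames optional fixed class order; default: union of observed.
#' @return An [EvaluationReport-class].
#' @export
evaluateClassifier <- function(predicted, truth, classNames = NULL) {
  if (!length(predicted) || length(predicted) != length(truth))
    stop("predicted and truth must be nonempty and the same length")
  if (is.null(classNames))
    classNames <- sort(unique(c(predicted, truth)))
  cm <- table(factor(truth, levels = classNames),
              factor(predicted, levels = classNames))
  cm <- matrix(as.integer(cm), nrow = length(classNames),
               dimnames = list(truth = classNames, predicted = classNames))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  perClass <- data.frame(class = classNames, precision = precision,
                         recall = recall, f1 = f1, row.names = NULL)
  new("EvaluationReport", confusionMatrix = cm, perClass = perClass,
      accuracy = sum(tp) / sum(cm), macroF1 = mean(f1))
}

#' One human-in-the-loop round
#'
#' Fits the model on the currently labeled items of a kind, predicts
#' categories for the unlabeled ("Unknown") pool and stages those predicted
#' labels on the project for review — corrections are ordinary
#' [assignItems()] calls, after which the next round resumes training on the
#' expanded labeled set. The returned report evaluates the model on its
#' internal validation split.
#'
#' @param project a [Project-class].
#' @param state a [TrainingState-class].
#' @param kindId the kind being classified (default "Image").
#' @param additionalEpochs epochs this round (default: config epochs).
#' @param view project view to read.
#' @return List with \code{project} (predictions staged), \code{state} and
#'   \code{report}.
#' @export
hitlRound <- function(project, state, kindId = IMAGE_KIND_ID,
                      additionalEpochs = NULL, view = "staged") {
  allIds <- selectSplit(project, Split(kindId), view)
  labels <- itemLabels(project, allIds, view)
  labeled <- allIds[labels != "Unknown"]
  unlabeled <- allIds[labels == "Unknown"]
  state <- fitClassifier(state, project, labeled, additionalEpochs, view)
  sp <- splitTrainVal(labeled, labels[labels != "Unknown"],
                      state@config@trainFraction, state@config@seed)
  valPred <- predictClassifier(state, project, sp$val, view)
  report <- evaluateClassifier(valPred$categories,
                               itemLabels(project, sp$val, view),
                               state@classNames)
  if (length(unlabeled)) {
    pred <- predictClassifier(state, project, unlabeled, view)
    cats <- projectCategories(project, view)
    byName <- stats::setNames(
      names(cats),
      vapply(cats, function(cc)
        paste0(cc@kindId, "\r", cc@name), character(1)))
    for (i in seq_along(unlabeled)) {
      cid <- byName[[paste0(kindId, "\r", pred$categories[i])]]
      project <- assignItems(project, unlabeled[i], categoryId = cid)
    }
  }
  list(project = project, state = state, report = report)
}
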