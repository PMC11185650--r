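# Minimal dense/convolutional network engine with explicit backpropagation
# and an SGD-with-momentum optimizer whose state lives in TrainingState, so
# training can resume exactly where it stopped. Batches are arrays
# (n, height, width, channel); convolutions are 3x3 "valid", computed via
# im2col so the inner loop is a matrix product.

withLocalSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

im2col3x3 <- function(x) {
  d <- dim(x)
  n <- d[1]; h <- d[2]; w <- d[3]; cc <- d[4]
  oh <- h - 2L; ow <- w - 2L
  P <- matrix(0, n * oh * ow, 9L * cc)
  blk <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    sl <- x[, dy + seq_len(oh), dx + seq_len(ow), , drop = FALSE]
    dim(sl) <- c(n * oh * ow, cc)
    P[, blk * cc + seq_len(cc)] <- sl
    blk <- blk + 1L
  }
  P
}

flattenKernel <- function(W) {
  d <- dim(W)  # (3, 3, Cin, F)
  cc <- d[3]; f <- d[4]
  wm <- matrix(0, 9L * cc, f)
  blk <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    wm[blk * cc + seq_len(cc), ] <- W[dy + 1L, dx + 1L, , ]
    blk <- blk + 1L
  }
  wm
}

unflattenKernel <- function(wm, cc, f) {
  W <- array(0, c(3L, 3L, cc, f))
  blk <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    W[dy + 1L, dx + 1L, , ] <- wm[blk * cc + seq_len(cc), , drop = FALSE]
    blk <- blk + 1L
  }
  W
}

convForward <- function(x, W, b) {
  d <- dim(x)
  n <- d[1]; oh <- d[2] - 2L; ow <- d[3] - 2L
  f <- dim(W)[4]
  P <- im2col3x3(x)
  Y <- P %*% flattenKernel(W)
  Y <- sweep(Y, 2L, b, `+`)
  dim(Y) <- c(n, oh, ow, f)
  list(out = Y, cache = list(P = P, xdim = d, W = W))
}

convBackward <- function(grad, cache) {
  d <- cache$xdim
  n <- d[1]; cc <- d[4]
  oh <- d[2] - 2L; ow <- d[3] - 2L
  f <- dim(cache$W)[4]
  gf <- grad
  dim(gf) <- c(n * oh * ow, f)
  dWm <- crossprod(cache$P, gf)
  db <- colSums(gf)
  dP <- gf %*% t(flattenKernel(cache$W))
  dx <- array(0, d)
  blk <- 0L
  for (dxo in 0:2) for (dyo in 0:2) {
    sl <- dP[, blk * cc + seq_len(cc), drop = FALSE]
    dim(sl) <- c(n, oh, ow, cc)
    dx[, dyo + seq_len(oh), dxo + seq_len(ow), ] <-
      dx[, dyo + seq_len(oh), dxo + seq_len(ow), , drop = FALSE] + sl
    blk <- blk + 1L
  }
  list(dx = dx, dW = unflattenKernel(dWm, cc, f), db = db)
}

reluForward <- function(x) list(out = pmax(x, 0), cache = x > 0)
reluBackward <- function(grad, cache) grad * cache

poolForward <- function(x) {
  d <- dim(x)
  h2 <- d[2] %/% 2L * 2L; w2 <- d[3] %/% 2L * 2L
  xc <- x[, seq_len(h2), seq_len(w2), , drop = FALSE]
  a <- xc[, seq(1L, h2, 2L), seq(1L, w2, 2L), , drop = FALSE]
  b <- xc[, seq(2L, h2, 2L), seq(1L, w2, 2L), , drop = FALSE]
  cc <- xc[, seq(1L, h2, 2L), seq(2L, w2, 2L), , drop = FALSE]
  dd <- xc[, seq(2L, h2, 2L), seq(2L, w2, 2L), , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  list(out = out,
       cache = list(a = a, b = b, cc = cc, dd = dd, out = out,
                    cdim = dim(xc), xdim = d))
}

poolBackward <- function(grad, cache) {
  m1 <- cache$a == cache$out
  m2 <- (cache$b == cache$out) & !m1
  m3 <- (cache$cc == cache$out) & !(m1 | m2)
  m4 <- !(m1 | m2 | m3)
  cd <- cache$cdim
  dxc <- array(0, cd)
  h2 <- cd[2]; w2 <- cd[3]
  dxc[, seq(1L, h2, 2L), seq(1L, w2, 2L), ] <- grad * m1
  dxc[, seq(2L, h2, 2L), seq(1L, w2, 2L), ] <- grad * m2
  dxc[, seq(1L, h2, 2L), seq(2L, w2, 2L), ] <- grad * m3
  dxc[, seq(2L, h2, 2L), seq(2L, w2, 2L), ] <- grad * m4
  if (identical(cd, cache$xdim)) return(dxc)
  dx <- array(0, cache$xdim)
  dx[, seq_len(cd[2]), seq_len(cd[3]), ] <- dxc
  dx
}

gapForward <- function(x) {
  d <- dim(x)
  n <- d[1]; cc <- d[4]
  out <- matrix(0, n, cc)
  for (ch in seq_len(cc)) {
    sl <- x[, , , ch, drop = FALSE]
    dim(sl) <- c(n, d[2] * d[3])
    out[, ch] <- rowMeans(sl)
  }
  list(out = out, cache = d)
}

gapBackward <- function(grad, d) {
  dx <- array(0, d)
  scale <- d[2] * d[3]
  for (ch in seq_len(d[4]))
    dx[, , , ch] <- array(grad[, ch] / scale, c(d[1], d[2], d[3]))
  dx
}

denseForward <- function(x, W, b) {
  list(out = sweep(x %*% W, 2L, b, `+`), cache = list(x = x, W = W))
}

denseBackward <- function(grad, cache) {
  list(dx = grad %*% t(cache$W), dW = crossprod(cache$x, grad),
       db = colSums(grad))
}

softmaxProbs <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# loss registry; categorical cross-entropy is built in
.lossRegistry <- new.env(parent = emptyenv())
.lossRegistry[["categorical_crossentropy"]] <- function(probs, yIdx) {
  n <- nrow(probs)
  p <- probs[cbind(seq_len(n), yIdx)]
  loss <- -mean(log(pmax(p, 1e-12)))
  grad <- probs
  grad[cbind(seq_len(n), yIdx)] <- grad[cbind(seq_len(n), yIdx)] - 1
  list(loss = loss, grad = grad / n)
}

#' Register a classification loss
#'
#' @param name loss identifier usable in [ClassifierConfig()].
#' @param fn function(probs, yIdx) returning list(loss, grad) where grad is
#'   the gradient w.r.t. the softmax probabilities' logits input convention
#'   used by the built-in loss.
#' @export
registerLoss <- function(name, fn) {
  .lossRegistry[[name]] <- fn
  invisible(name)
}

lossFunction <- function(name) {
  fn <- .lossRegistry[[name]]
  if (is.null(fn)) stop("unregistered loss: ", name)
  fn
}

# architecture description ---------------------------------------------------

simpleCnnLayers <- function(inputExtent, nClasses, frozenBackbone = FALSE) {
  cc <- inputExtent[3]
  list(
    list(type = "conv", name = "conv1", filters = 8L, inChannels = cc,
         trainable = !frozenBackbone),
    list(type = "relu", name = "relu1"),
    list(type = "pool", name = "pool1"),
    list(type = "conv", name = "conv2", filters = 16L, inChannels = 8L,
         trainable = !frozenBackbone),
    list(type = "relu", name = "relu2"),
    list(type = "pool", name = "pool2"),
    list(type = "gap", name = "gap"),
    list(type = "dense", name = "head", units = nClasses, inUnits = 16L,
         trainable = TRUE),
    list(type = "softmax", name = "softmax"))
}

initWeights <- function(layers, seed) {
  withLocalSeed(seed, {
    weights <- list()
    for (ly in layers) {
      if (ly$type == "conv") {
        fanIn <- 9L * ly$inChannels
        weights[[paste0(ly$name, ".W")]] <-
          array(stats::rnorm(9L * ly$inChannels * ly$filters,
                             sd = sqrt(2 / fanIn)),
                c(3L, 3L, ly$inChannels, ly$filters))
        weights[[paste0(ly$name, ".b")]] <- numeric(ly$filters)
      } else if (ly$type == "dense") {
        weights[[paste0(ly$name, ".W")]] <-
          matrix(stats::rnorm(ly$inUnits * ly$units,
                              sd = sqrt(2 / ly$inUnits)),
                 ly$inUnits, ly$units)
        weights[[paste0(ly$name, ".b")]] <- numeric(ly$units)
      }
    }
    weights
  })
}

trainableParams <- function(layers) {
  out <- character()
  for (ly in layers)
    if (isTRUE(ly$trainable))
      out <- c(out, paste0(ly$name, ".W"), paste0(ly$name, ".b"))
  out
}

networkForward <- function(layers, weights, x, wantCache = FALSE) {
  caches <- vector("list", length(layers))
  cur <- x
  probs <- NULL
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    r <- switch(ly$type,
      conv = convForward(cur, weights[[paste0(ly$name, ".W")]],
                         weights[[paste0(ly$name, ".b")]]),
      relu = reluForward(cur),
      pool = poolForward(cur),
      gap = gapForward(cur),
      dense = denseForward(cur, weights[[paste0(ly$name, ".W")]],
                           weights[[paste0(ly$name, ".b")]]),
      softmax = list(out = softmaxProbs(cur), cache = NULL))
    cur <- r$out
    if (wantCache) caches[[i]] <- r$cache
  }
  list(probs = cur, caches = caches)
}

networkBackward <- function(layers, gradLogits, caches) {
  grads <- list()
  grad <- gradLogits
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    if (ly$type == "softmax") next  # fused with the loss gradient
    if (ly$type == "conv") {
      r <- convBackward(grad, caches[[i]])
      grads[[paste0(ly$name, ".W")]] <- r$dW
      grads[[paste0(ly$name, ".b")]] <- r$db
      grad <- r$dx
    } else if (ly$type == "relu") {
      grad <- reluBackward(grad, caches[[i]])
    } else if (ly$type == "pool") {
      grad <- poolBackward(grad, caches[[i]])
    } else if (ly$type == "gap") {
      grad <- gapBackward(grad, caches[[i]])
    } else if (ly$type == "dense") {
      r <- denseBackward(grad, caches[[i]])
      grads[[paste0(ly$name, ".W")]] <- r$dW
      grads[[paste0(ly$name, ".b")]] <- r$db
      grad <- r$dx
    }
  }
  grads
}

sgdMomentumStep <- function(weights, velocity, grads, trainable, lr,
                            momentum = 0.9) {
  for (p in trainable) {
    if (is.null(grads[[p]])) next
    v <- velocity[[p]]
    if (is.null(v)) v <- grads[[p]] * 0
    v <- momentum * v - lr * grads[[p]]
    velocity[[p]] <- v
    weights[[p]] <- weights[[p]] + v
  }
  list(weights = weights, velocity = velocity)
}

runEpoch <- function(layers, weights, velocity, x, yIdx, lossFn, lr,
                     batchSize, shuffleSeed, trainable) {
  n <- dim(x)[1]
  ord <- withLocalSeed(shuffleSeed, sample.int(n))
  totalLoss <- 0
  correct <- 0L
  for (start in seq(1L, n, by = batchSize)) {
    idx <- ord[start:min(start + batchSize - 1L, n)]
    xb <- x[idx, , , , drop = FALSE]
    yb <- yIdx[idx]
    fwd <- networkForward(layers, weights, xb, wantCache = TRUE)
    l <- lossFn(fwd$probs, yb)
    totalLoss <- totalLoss + l$loss * length(idx)
    correct <- correct + sum(max.col(fwd$probs) == yb)
    grads <- networkBackward(layers, l$grad, fwd$caches)
    st <- sgdMomentumStep(weights, velocity, grads, trainable, lr)
    weights <- st$weights
    velocity <- st$velocity
  }
  list(weights = weights, velocity = velocity,
       loss = totalLoss / n, accuracy = correct / n)
}

evaluateLoss <- function(layers, weights, x, yIdx, lossFn) {
  fwd <- networkForward(layers, weights, x)
  l <- lossFn(fwd$probs, yIdx)
  list(loss = l$loss, accuracy = mean(max.col(fwd$probs) == yIdx))
}
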