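#' Export a model to a portable directory
#'
#' Writes \code{model.json} — a structured description of the architecture
#' (layer list with shapes, activations and trainable/frozen flags), the
#' class names, the config, the epoch history and a weight manifest — plus
#' one little-endian float64 binary shard per parameter array (optimizer
#' momentum buffers included, so an imported model resumes training
#' exactly).
#'
#' @param state a [TrainingState-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
exportModel <- function(state, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  shard <- 0L
  writeShard <- function(name, arr, role) {
    shard <<- shard + 1L
    file <- sprintf("weights_%03d.bin", shard)
    con <- file(file.path(dir, file), "wb")
    on.exit(close(con))
    writeBin(as.numeric(arr), con, size = 8L, endian = "little")
    shape <- dim(arr)
    if (is.null(shape)) shape <- length(arr)
    manifest[[length(manifest) + 1L]] <<- list(
      name = name, role = role, shape = as.list(as.integer(shape)),
      dtype = "<f8", file = file,
      byte_length = 8L * length(arr))
  }
  for (nm in names(state@weights))
    writeShard(nm, state@weights[[nm]], "weight")
  for (nm in names(state@optimizerState))
    writeShard(nm, state@optimizerState[[nm]], "optimizer")
  cfg <- state@config
  desc <- list(
    format = "pixikit-model", format_version = "1",
    layers = lapply(state@layers, function(ly) {
      out <- list(type = ly$type, name = ly$name)
      if (!is.null(ly$filters)) out$filters <- ly$filters
      if (!is.null(ly$inChannels)) out$in_channels <- ly$inChannels
      if (!is.null(ly$units)) out$units <- ly$units
      if (!is.null(ly$inUnits)) out$in_units <- ly$inUnits
      if (ly$type %in% c("conv", "dense"))
        out$trainable <- isTRUE(ly$trainable)
      if (ly$type == "relu") out$activation <- "relu"
      if (ly$type == "softmax") out$activation <- "softmax"
      out
    }),
    class_names = as.list(state@classNames),
    epochs_completed = state@epochsCompleted,
    history = state@history,
    config = list(architecture = cfg@architecture,
                  input_extent = as.list(cfg@inputExtent),
                  loss_name = cfg@lossName, learning_rate = cfg@learningRate,
                  epochs = cfg@epochs, batch_size = cfg@batchSize,
                  train_fraction = cfg@trainFraction, seed = cfg@seed),
    weights_manifest = manifest)
  writeLines(jsonlite::toJSON(desc, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns"),
             file.path(dir, "model.json"))
  invisible(dir)
}

#' Import a model exported with exportModel
#'
#' Every shard's byte length is validated against the declared shape; a
#' mismatch (e.g. a tampered or truncated shard) raises a shape-mismatch
#' error. The reconstructed model's predictions equal the exported model's.
#'
#' @param dir directory written by [exportModel()].
#' @return A [TrainingState-class].
#' @export
importModel <- function(dir) {
  descPath <- file.path(dir, "model.json")
  if (!file.exists(descPath)) stop("no model.json in ", dir)
  desc <- jsonlite::fromJSON(descPath, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  if (!identical(desc$format, "pixikit-model"))
    stop("not a pixikit model directory")
  cfgL <- desc$config
  config <- ClassifierConfig(
    architecture = cfgL$architecture,
    inputExtent = as.integer(unlist(cfgL$input_extent)),
    lossName = cfgL$loss_name, learningRate = cfgL$learning_rate,
    epochs = cfgL$epochs, batchSize = cfgL$batch_size,
    trainFraction = cfgL$train_fraction, seed = cfgL$seed)
  layersDf <- desc$layers
  layers <- lapply(seq_len(nrow(layersDf)), function(i) {
    row <- as.list(layersDf[i, ])
    ly <- list(type = row$type, name = row$name)
    if (!is.na(row$filters %||% NA)) ly$filters <- as.integer(row$filters)
    if (!is.na(row$in_channels %||% NA))
      ly$inChannels <- as.integer(row$in_channels)
    if (!is.na(row$units %||% NA)) ly$units <- as.integer(row$units)
    if (!is.na(row$in_units %||% NA)) ly$inUnits <- as.integer(row$in_units)
    if (!is.null(row$trainable) && !is.na(row$trainable))
      ly$trainable <- as.logical(row$trainable)
    ly
  })
  mf <- desc$weights_manifest
  weights <- list()
  optimizer <- list()
  for (i in seq_len(nrow(mf))) {
    shape <- as.integer(unlist(mf$shape[[i]]))
    file <- file.path(dir, mf$file[i])
    if (!file.exists(file)) stop("missing weight shard: ", mf$file[i])
    actual <- file.info(file)$size
    if (actual != 8 * prod(shape) || actual != mf$byte_length[i])
      stop("shape mismatch: shard ", mf$file[i], " holds ", actual,
           " bytes but the description declares ",
           8 * prod(shape), " (shape ", paste(shape, collapse = "x"), ")")
    vals <- readBin(file, "numeric", n = prod(shape), size = 8L,
                    endian = "little")
    arr <- if (length(shape) > 1L) array(vals, shape) else vals
    if (mf$role[i] == "weight") weights[[mf$name[i]]] <- arr
    else optimizer[[mf$name[i]]] <- arr
  }
  hist <- desc$history
  if (is.null(hist) || !length(hist))
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       train_accuracy = numeric(), val_loss = numeric(),
                       val_accuracy = numeric())
  new("TrainingState", layers = layers, weights = weights,
      optimizerState = optimizer,
      epochsCompleted = as.integer(desc$epochs_completed),
      history = as.data.frame(hist),
      classNames = as.character(unlist(desc$class_names)), config = config)
}
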