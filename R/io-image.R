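#' Read a raster image file into an ImageItem
#'
#' Supports PNG, JPEG, multi-page ("hyperstack") TIFF and uncompressed
#' single-frame grayscale DICOM. TIFF page stacks are factored by the
#' declared channel count: pages are interpreted channel-fastest (channel
#' varying within z), so a 12-page file with 3 declared channels yields a
#' (z = 4, channel = 3) stack. PNG/JPEG give z = 1 with 1 (gray) or 3 (RGB)
#' channels (alpha is dropped). Intensities are scaled to [0, 1] by the
#' source bit depth, losslessly for bit depths up to 16.
#'
#' @param path file path.
#' @param declaredChannels channel count used to factor TIFF page stacks
#'   (default 1: every page is its own z-plane).
#' @param name item name (default: the file's base name).
#' @return An [ImageItem-class] with pixels ordered (z, channel, y, x).
#' @export
readImageFile <- function(path, declaredChannels = NULL, name = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) return(readPngItem(path, name))
  if (ext %in% c("jpg", "jpeg")) return(readJpegItem(path, name))
  if (ext %in% c("tif", "tiff"))
    return(readTiffItem(path, declaredChannels, name))
  if (ext %in% c("dcm", "dicom") || isDicom(path))
    return(readDicomItem(path, name))
  stop("unsupported image format: ", path)
}

dropAlpha <- function(a) {
  if (length(dim(a)) == 3L && dim(a)[3] %in% c(2L, 4L))
    a <- a[, , -dim(a)[3], drop = FALSE]
  a
}

toZCYX <- function(a) {
  # (y, x) or (y, x, c) -> (1, c, y, x)
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  aperm(array(a, dim = c(dim(a), 1L)), c(4L, 3L, 1L, 2L))
}

readPngItem <- function(path, name) {
  a <- png::readPNG(path, info = TRUE)
  info <- attr(a, "info")
  bits <- if (!is.null(info$bit.depth)) as.integer(info$bit.depth) else 8L
  a <- dropAlpha(a)
  ImageItem(toZCYX(a), name = name, bitDepth = bits)
}

readJpegItem <- function(path, name) {
  a <- jpeg::readJPEG(path)
  ImageItem(toZCYX(a), name = name, bitDepth = 8L)
}

readTiffItem <- function(path, declaredChannels, name) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- 8L
  pageDim <- dim(pages[[1]])
  if (length(pageDim) == 3L && pageDim[3] > 1L) {
    # RGB(A) pages: channels live inside the page
    if (!is.null(declaredChannels) && declaredChannels != pageDim[3])
      stop("declaredChannels conflicts with the per-page channel count")
    planes <- lapply(pages, dropAlpha)
    nc <- dim(planes[[1]])[3]
    z <- length(planes)
    px <- array(0, c(z, nc, pageDim[1], pageDim[2]))
    for (zi in seq_len(z)) for (ch in seq_len(nc))
      px[zi, ch, , ] <- planes[[zi]][, , ch]
  } else {
    d <- if (is.null(declaredChannels)) 1L else as.integer(declaredChannels)
    n <- length(pages)
    if (n %% d != 0L)
      stop("TIFF page count (", n, ") is not divisible by the declared ",
           "channel count (", d, ")")
    z <- n %/% d
    px <- array(0, c(z, d, pageDim[1], pageDim[2]))
    for (zi in seq_len(z)) for (ch in seq_len(d)) {
      pg <- pages[[(zi - 1L) * d + ch]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1]
      px[zi, ch, , ] <- pg
    }
  }
  ImageItem(px, name = name, bitDepth = as.integer(bits[1]))
}

# -- DICOM (uncompressed, single-frame grayscale) ----------------------------

isDicom <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 132L)
  length(hdr) == 132L && rawToChar(hdr[129:132]) == "DICM"
}

readUint <- function(raw) sum(as.numeric(raw) * 256^(seq_along(raw) - 1L))

SUPPORTED_TS <- c(implicit = "1.2.840.10008.1.2",
                  explicit = "1.2.840.10008.1.2.1")

readDicomItem <- function(path, name) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  pos <- 1L
  explicitVR <- TRUE
  if (length(bytes) >= 132L && rawToChar(bytes[129:132]) == "DICM") {
    pos <- 133L
  }
  fields <- list(samplesPerPixel = 1L, bitsAllocated = 16L, bitsStored = NA,
                 pixelRepresentation = 0L, slope = 1, intercept = 0,
                 rows = NA, cols = NA, pixelData = NULL, ts = NA_character_)
  metaExplicit <- TRUE
  longVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= length(bytes)) {
    group <- readUint(bytes[pos:(pos + 1L)])
    elem <- readUint(bytes[(pos + 2L):(pos + 3L)])
    pos <- pos + 4L
    useExplicit <- if (group == 0x0002) TRUE else explicitVR
    if (useExplicit) {
      vr <- rawToChar(bytes[pos:(pos + 1L)])
      if (vr %in% longVRs) {
        len <- readUint(bytes[(pos + 4L):(pos + 7L)])
        pos <- pos + 8L
      } else {
        len <- readUint(bytes[(pos + 2L):(pos + 3L)])
        pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- readUint(bytes[pos:(pos + 3L)])
      pos <- pos + 4L
    }
    if (len == 0xFFFFFFFF)
      stop("unsupported-format: encapsulated (compressed) DICOM pixel data")
    val <- bytes[pos:(pos + len - 1L)]
    pos <- pos + len
    key <- sprintf("%04x,%04x", group, elem)
    if (key == "0002,0010") {
      ts <- trimws(rawToChar(val[val != as.raw(0)]))
      if (!ts %in% SUPPORTED_TS)
        stop("unsupported-format: compressed or non-little-endian DICOM ",
             "transfer syntax ", ts)
      explicitVR <- ts == SUPPORTED_TS[["explicit"]]
      fields$ts <- ts
    } else if (key == "0028,0002") fields$samplesPerPixel <- readUint(val)
    else if (key == "0028,0010") fields$rows <- readUint(val)
    else if (key == "0028,0011") fields$cols <- readUint(val)
    else if (key == "0028,0100") fields$bitsAllocated <- readUint(val)
    else if (key == "0028,0101") fields$bitsStored <- readUint(val)
    else if (key == "0028,0103") fields$pixelRepresentation <- readUint(val)
    else if (key == "0028,1052") fields$intercept <- as.numeric(rawToChar(val))
    else if (key == "0028,1053") fields$slope <- as.numeric(rawToChar(val))
    else if (key == "7fe0,0010") { fields$pixelData <- val; break }
  }
  if (is.null(fields$pixelData)) stop("DICOM file has no pixel data")
  if (fields$samplesPerPixel != 1L)
    stop("only single-sample (grayscale) DICOM is supported")
  if (is.na(fields$bitsStored)) fields$bitsStored <- fields$bitsAllocated
  nbytes <- fields$bitsAllocated %/% 8L
  expected <- fields$rows * fields$cols * nbytes
  if (length(fields$pixelData) < expected)
    stop("DICOM pixel data shorter than Rows x Columns")
  raw <- fields$pixelData[seq_len(expected)]
  vals <- readBin(raw, "integer", n = fields$rows * fields$cols,
                  size = nbytes, signed = fields$pixelRepresentation == 1L,
                  endian = "little")
  if (nbytes == 2L && fields$pixelRepresentation == 0L)
    vals <- ifelse(vals < 0, vals + 65536, vals)
  phys <- fields$slope * vals + fields$intercept
  lo <- min(fields$intercept, fields$slope * (2^fields$bitsStored - 1) +
              fields$intercept)
  hi <- max(fields$intercept, fields$slope * (2^fields$bitsStored - 1) +
              fields$intercept)
  v01 <- (phys - lo) / (hi - lo)
  img <- matrix(v01, nrow = fields$rows, ncol = fields$cols, byrow = TRUE)
  ImageItem(toZCYX(img), name = name,
            bitDepth = as.integer(fields$bitsStored))
}
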