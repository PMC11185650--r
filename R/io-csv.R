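#' Export a measurement table to CSV
#'
#' Wide layout: one row per item (or per item/channel when per-channel
#' intensity measurements are present), columns \code{item_id, kind,
#' category, partition, channel} followed by one column per measurement in
#' registry order. Floats are serialized with 6 significant digits; row and
#' column order are deterministic, so re-exporting an unchanged table gives
#' a byte-identical file.
#'
#' @param table a [MeasurementTable-class] with at least one row.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
exportMeasurementsCsv <- function(table, path) {
  rowsDf <- table@rows
  if (!nrow(rowsDf)) stop("measurement table is empty")
  meas <- intersect(MEASUREMENT_NAMES, unique(rowsDf$measurement))
  # one row per item/channel; channel-independent (geometry) values repeat
  # across an item's channel rows
  keys <- do.call(rbind, lapply(sort(unique(rowsDf$item_id)), function(id) {
    chs <- sort(unique(rowsDf$channel[rowsDf$item_id == id &
                                        !is.na(rowsDf$channel)]))
    if (!length(chs)) chs <- NA_integer_
    data.frame(item_id = id, channel = chs)
  }))
  fmt <- function(v) {
    out <- vapply(v, function(x) {
      if (is.na(x)) return("")
      if (x == round(x) && abs(x) < 1e15)
        return(format(x, scientific = FALSE, trim = TRUE))
      format(signif(x, 6), scientific = FALSE, trim = TRUE)
    }, character(1))
    out
  }
  header <- c("item_id", "kind", "category", "partition", "channel", meas)
  lines <- paste(header, collapse = ",")
  for (i in seq_len(nrow(keys))) {
    id <- keys$item_id[i]; ch <- keys$channel[i]
    sel <- rowsDf$item_id == id &
      (is.na(rowsDf$channel) | (!is.na(ch) & rowsDf$channel %in% ch))
    sub <- rowsDf[sel, , drop = FALSE]
    vals <- vapply(meas, function(m) {
      v <- sub$value[sub$measurement == m]
      if (length(v)) v[1] else NA_real_
    }, numeric(1))
    meta <- sub[1, ]
    lines <- c(lines, paste(c(id, meta$kind, meta$category, meta$partition,
                              if (is.na(ch)) "" else ch, fmt(vals)),
                            collapse = ","))
  }
  con <- file(path, "wb")  # fixed newline convention for byte-identity
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
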