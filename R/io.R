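# File formats: 16-bit multi-page TIFF fields (page order DAPI, FITC,
# TexasRed, Cy5), 16-bit label-map TIFFs with JSON sidecars, 8-bit 0/255
# masks, CSV layouts and cell records, TSV profile matrices, GMT pathway
# sets, Newick dendrograms, SIF/GraphML networks.

#' Write a FieldImage as a 16-bit multi-page TIFF
#'
#' One page per channel in the canonical order returned by
#' [fieldChannels()] (any extra channels follow in their stored order).
#'
#' @param image A [FieldImage-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeFieldImage <- function(image, path) {
  ord <- c(intersect(fieldChannels(), channelNames(image)),
           setdiff(channelNames(image), fieldChannels()))
  pages <- lapply(image@channels[ord], function(m) round(m) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF field
#'
#' @param path TIFF file written by [writeFieldImage()].
#' @param channels Channel names to assign to the pages, in page order.
#' @param pixelSize Micrometres per pixel.
#' @param metadata Optional metadata list.
#' @return A [FieldImage-class].
#' @export
readFieldImage <- function(path, channels = fieldChannels(),
                           pixelSize = 1, metadata = list()) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stopIfNot(length(pages) == length(channels),
            "page count does not match channel names")
  chans <- lapply(pages, function(p) round(p * 65535))
  names(chans) <- channels
  FieldImage(chans, pixelSize = pixelSize, metadata = metadata)
}

#' Write a LabelMap as 16-bit TIFF plus JSON sidecar
#'
#' The sidecar `<path>.json` records the kind, the parent map and an
#' optional echo of the segmentation settings.
#'
#' @param map A [LabelMap-class] (labels must fit in 16 bits).
#' @param path Output TIFF file.
#' @param configEcho Optional list echoed into the sidecar.
#' @return `path`, invisibly.
#' @export
writeLabelMap <- function(map, path, configEcho = NULL) {
  stopIfNot(max(map@labels) <= 65535L, "more than 65535 labels")
  tiff::writeTIFF(map@labels / 65535, path, bits.per.sample = 16L)
  side <- list(kind = map@kind,
               parent = as.list(setNames(as.integer(map@parent),
                                         names(map@parent))))
  if (!is.null(configEcho)) side$config <- configEcho
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a LabelMap written by [writeLabelMap()]
#' @param path TIFF file (sidecar `<path>.json` must exist).
#' @return A [LabelMap-class].
#' @export
readLabelMap <- function(path) {
  lab <- round(tiff::readTIFF(path) * 65535)
  storage.mode(lab) <- "integer"
  side <- jsonlite::read_json(paste0(path, ".json"))
  parent <- setNames(as.integer(unlist(side$parent)), names(side$parent))
  LabelMap(lab, side$kind, parent = parent)
}

#' Write / read a binary mask as single-page 8-bit TIFF (0/255)
#'
#' @param mask Logical matrix.
#' @param path TIFF file.
#' @return `path` invisibly (write); logical matrix (read).
#' @export
writeMask <- function(mask, path) {
  tiff::writeTIFF((mask > 0) * 1.0, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  tiff::readTIFF(path) > 0.5
}

#' Write / read a plate layout CSV (columns well, treatment, replicate)
#' @param layout data.frame(well, treatment, replicate).
#' @param path CSV file.
#' @return `path` invisibly (write); data.frame (read).
#' @export
writePlateLayout <- function(layout, path) {
  write.csv(layout[c("well", "treatment", "replicate")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname writePlateLayout
#' @export
readPlateLayout <- function(path) {
  lay <- read.csv(path, stringsAsFactors = FALSE)
  stopIfNot(all(c("well", "treatment", "replicate") %in% names(lay)),
            "layout CSV needs columns well, treatment, replicate")
  lay
}

#' Write / read per-cell records as CSV
#' @param records data.frame from [cellFeatures()] (with any identity
#'   columns added).
#' @param path CSV file.
#' @return `path` invisibly (write); data.frame (read).
#' @export
writeCellRecords <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCellRecords
#' @export
readCellRecords <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a ProfileMatrix as TSV
#'
#' Rows are treatments, columns parameters; the first column holds the
#' treatment label. Heatmap-viewer friendly.
#'
#' @param pm A [ProfileMatrix-class].
#' @param path TSV file.
#' @param controlLabel Control label to restore on read.
#' @return `path` invisibly (write); [ProfileMatrix-class] (read, with
#'   replicate counts unknown, set to 1).
#' @export
writeProfileMatrix <- function(pm, path) {
  df <- data.frame(treatment = rownames(pm@values), pm@values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfileMatrix
#' @export
readProfileMatrix <- function(path, controlLabel = "PMC") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df[[1L]]
  new("ProfileMatrix", values = vals,
      replicateN = matrix(1L, nrow(vals), ncol(vals),
                          dimnames = dimnames(vals)),
      controlLabel = controlLabel,
      qcLog = data.frame(item = character(0), reason = character(0),
                         stringsAsFactors = FALSE))
}

#' Read / write gene sets in GMT format
#'
#' Reading delegates to `fgsea::gmtPathways`.
#'
#' @param sets Named list of character vectors.
#' @param path GMT file.
#' @return Named list (read); `path` invisibly (write).
#' @export
readGmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname readGmt
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}
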