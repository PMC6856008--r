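# Accessors and show methods.

#' @describeIn FieldImage-class Channel names.
#' @param x,object A FieldImage.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname FieldImage-class
#' @export
setMethod("channelNames", "FieldImage", function(x) names(x@channels))

#' Extract one channel raster from a FieldImage
#' @param x A [FieldImage-class].
#' @param name Channel name (e.g. "DAPI").
#' @return Numeric matrix.
#' @export
getChannel <- function(x, name) {
  stopIfNot(name %in% names(x@channels),
            paste0("channel '", name, "' not present (have: ",
                   paste(names(x@channels), collapse = ", "), ")"))
  x@channels[[name]]
}

#' Pixel size of a FieldImage (micrometres per pixel)
#' @param x A [FieldImage-class].
#' @return Numeric scalar.
#' @export
pixelSize <- function(x) x@pixelSize

setMethod("show", "FieldImage", function(object) {
  d <- dim(object@channels[[1L]])
  cat("FieldImage:", d[1L], "x", d[2L], "px,",
      length(object@channels), "channel(s) [",
      paste(names(object@channels), collapse = ", "), "]\n")
  cat("  pixelSize:", object@pixelSize, "um/px\n")
  md <- object@metadata
  if (length(md))
    cat("  metadata:", paste(names(md), unlist(md), sep = "=",
                             collapse = ", "), "\n")
})

#' Label raster of a LabelMap
#' @param x A [LabelMap-class].
#' @return Integer matrix.
#' @export
labelMatrix <- function(x) x@labels

#' Kind of a LabelMap ("nucleus", "cell" or "cytoplasm")
#' @param x A [LabelMap-class].
#' @return Character scalar.
#' @export
labelKind <- function(x) x@kind

#' Parent map of a LabelMap (nucleus label -> cell label)
#' @param x A [LabelMap-class].
#' @return Named integer vector.
#' @export
parentMap <- function(x) x@parent

#' Number of labelled objects in a LabelMap
#' @param x A [LabelMap-class].
#' @return Integer.
#' @export
nObjects <- function(x) {
  m <- max(x@labels)
  if (m == 0L) 0L else length(unique(x@labels[x@labels > 0L]))
}

setMethod("show", "LabelMap", function(object) {
  cat("LabelMap(", object@kind, "): ", nrow(object@labels), " x ",
      ncol(object@labels), " px, ", nObjects(object), " object(s)\n",
      sep = "")
})

#' Profile values of a ProfileMatrix
#' @param x A [ProfileMatrix-class].
#' @return Numeric matrix (treatments x parameters, percent change).
#' @export
profileValues <- function(x) x@values

#' Replicate counts behind each ProfileMatrix entry
#' @param x A [ProfileMatrix-class].
#' @return Integer matrix.
#' @export
replicateN <- function(x) x@replicateN

#' Negative-control label of a ProfileMatrix
#' @param x A [ProfileMatrix-class].
#' @return Character scalar.
#' @export
controlLabel <- function(x) x@controlLabel

#' QC log of a ProfileMatrix (dropped wells and columns, with reasons)
#' @param x A [ProfileMatrix-class].
#' @return data.frame(item, reason).
#' @export
qcLog <- function(x) x@qcLog

setMethod("show", "ProfileMatrix", function(object) {
  cat("ProfileMatrix: ", nrow(object@values), " treatment(s) x ",
      ncol(object@values), " parameter(s), control = '",
      object@controlLabel, "'\n", sep = "")
  if (nrow(object@qcLog))
    cat("  QC: ", nrow(object@qcLog), " item(s) dropped\n", sep = "")
})

#' Group memberships of a clustering
#' @param x A [MirClustering-class].
#' @return data.frame(mir, mainGroup, group).
#' @export
memberships <- function(x) x@memberships

setMethod("show", "MirClustering", function(object) {
  tab <- table(object@memberships$group)
  cat("MirClustering: ", nrow(object@memberships), " miRs in ",
      length(tab), " group(s) [k_main = ", object@kMain, "]\n", sep = "")
  print(tab)
})

setMethod("show", "MiRGroup", function(object) {
  cat("MiRGroup ", object@groupId, " (", object@phenotype, "): ",
      length(object@members), " member(s)\n", sep = "")
})

#' Consensus genes (with supporter counts) of a ConsensusResult
#' @param x A [ConsensusResult-class].
#' @return Named integer vector, gene -> supporter count.
#' @export
consensusGenes <- function(x) x@supporters

#' Filtered genes of a ConsensusResult (consensus minus excluded)
#' @param x A [ConsensusResult-class].
#' @return Character vector.
#' @export
filteredGenes <- function(x) x@filtered

#' Excluded genes of a ConsensusResult
#' @param x A [ConsensusResult-class].
#' @return data.frame(gene, sharedWith).
#' @export
excludedGenes <- function(x) x@excluded

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult ", object@groupId, ": N = ",
      length(object@members), ", threshold = ", object@thresholdUsed,
      "; consensus ", length(object@supporters), ", excluded ",
      nrow(object@excluded), ", filtered ", length(object@filtered),
      "\n", sep = "")
})

#' Edge table of a TargetTable
#' @param x A [TargetTable-class].
#' @return data.frame(mir, gene).
#' @export
targetEdges <- function(x) x@edges

setMethod("show", "TargetTable", function(object) {
  cat("TargetTable: ", nrow(object@edges), " edge(s), ",
      length(unique(object@edges$mir)), " miR(s), ",
      length(unique(object@edges$gene)), " gene(s) [",
      object@source, "]\n", sep = "")
})
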