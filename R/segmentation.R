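# Nucleus / cell / cytoplasm segmentation. Classical operators throughout:
# Gaussian smoothing, Otsu or fixed threshold, hole filling,
# distance-transform watershed declumping, and seeded propagation of cell
# bodies from nuclei over the smoothed whole-cell (Cy5) channel.

smoothChannel <- function(ch, sigma) {
  x <- ch / 65535
  if (sigma > 0) x <- ebMat(EBImage::gblur(EBImage::Image(x),
                                               sigma = sigma))
  x
}

channelThreshold <- function(sm, cfg) {
  if (cfg@thresholdMethod == "otsu")
    EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  else cfg@fixedThreshold / 65535
}

borderLabels <- function(lab) {
  unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
}

#' Segment nuclei from the DAPI channel
#'
#' Thresholds the Gaussian-smoothed DAPI channel (Otsu by default), fills
#' holes, optionally splits touching nuclei by distance-transform
#' watershed, filters objects by area, optionally discards objects
#' touching the field border, and renumbers the surviving objects 1..K in
#' raster-scan order of their first pixel. An all-background field yields
#' an empty label map, not an error.
#'
#' @param image A [FieldImage-class] with a DAPI channel.
#' @param cfg A [SegmentationConfig-class].
#' @return A [LabelMap-class] of kind "nucleus".
#' @export
#' @examples
#' f <- generateField(sceneSpec(nCells = 8, fieldShape = c(192, 192),
#'                              noiseSd = 0))
#' nObjects(segmentNuclei(f$image, segmentationConfig()))
segmentNuclei <- function(image, cfg = segmentationConfig()) {
  dapi <- getChannel(image, "DAPI")
  sm <- smoothChannel(dapi, cfg@smoothingSigma)
  mask <- sm > channelThreshold(sm, cfg)
  if (!any(mask))
    return(LabelMap(matrix(0L, nrow(dapi), ncol(dapi)), "nucleus"))
  mask <- ebMat(EBImage::fillHull(EBImage::Image(mask))) > 0
  lab <- if (cfg@declump) {
    dm <- EBImage::distmap(EBImage::Image(mask))
    ebMat(EBImage::watershed(dm, tolerance = 1, ext = 1))
  } else {
    ebMat(EBImage::bwlabel(EBImage::Image(mask)))
  }
  storage.mode(lab) <- "integer"
  sizes <- tabulate(lab[lab > 0L])
  drop <- which(sizes < cfg@minNucleusArea | sizes > cfg@maxNucleusArea)
  if (cfg@excludeBorderObjects)
    drop <- union(drop, setdiff(borderLabels(lab), 0L))
  if (length(drop)) lab[lab %in% drop] <- 0L
  LabelMap(relabelRasterScan(lab), "nucleus")
}

#' Segment cell bodies and cytoplasm from nuclei seeds
#'
#' Grows one cell per nucleus over the Gaussian-smoothed Cy5 (whole-cell
#' dye) channel by seeded propagation, constrained to the Cy5 foreground
#' (Otsu threshold) united with the nucleus pixels, so every nucleus is
#' covered by its own cell even where it pokes past the dye foreground.
#' The cytoplasm map is the per-object set difference cell minus nucleus.
#'
#' @param image A [FieldImage-class] with a Cy5 channel.
#' @param nuclei Nucleus [LabelMap-class] (the seeds).
#' @param cfg A [SegmentationConfig-class].
#' @return List with `cells` and `cytoplasm` [LabelMap-class]s; cell
#'   labels equal their seed nucleus labels and the parent map is the
#'   identity over them.
#' @export
segmentCells <- function(image, nuclei, cfg = segmentationConfig()) {
  cy5 <- getChannel(image, "Cy5")
  stopIfNot(identical(dim(cy5), dim(nuclei@labels)),
            "nucleus map and image shapes differ")
  if (nObjects(nuclei) == 0L) {
    empty <- LabelMap(matrix(0L, nrow(cy5), ncol(cy5)), "cell")
    return(list(cells = empty,
                cytoplasm = LabelMap(empty@labels, "cytoplasm")))
  }
  sm <- smoothChannel(cy5, cfg@smoothingSigma)
  fg <- sm > channelThreshold(sm, cfg)
  mask <- fg | nuclei@labels > 0L
  cells <- ebMat(EBImage::propagate(EBImage::Image(sm),
                                        seeds = nuclei@labels,
                                        mask = mask, lambda = 1e-4))
  storage.mode(cells) <- "integer"
  present <- sort(unique(cells[cells > 0L]))
  cellMap <- LabelMap(cells, "cell",
                      parent = setNames(present, present))
  list(cells = cellMap, cytoplasm = cytoplasmMap(cellMap, nuclei))
}

#' Match objects between two label maps by intersection-over-union
#'
#' Standard segmentation evaluation: every pair of overlapping objects is
#' scored by IoU; each reference object is then matched greedily to its
#' best-IoU counterpart.
#'
#' @param ref,seg [LabelMap-class]s over the same pixel grid (reference /
#'   candidate).
#' @return data.frame(refLabel, segLabel, iou) with one row per reference
#'   object (segLabel NA when nothing overlaps).
#' @export
matchObjects <- function(ref, seg) {
  r <- ref@labels; s <- seg@labels
  stopIfNot(identical(dim(r), dim(s)), "label maps must share one shape")
  areaR <- tabulate(r[r > 0L])
  areaS <- tabulate(s[s > 0L])
  both <- which(r > 0L & s > 0L)
  out <- data.frame(refLabel = which(areaR > 0L), segLabel = NA_integer_,
                    iou = 0)
  if (length(both)) {
    key <- paste(r[both], s[both])
    cnt <- table(key)
    parts <- strsplit(names(cnt), " ", fixed = TRUE)
    rl <- as.integer(vapply(parts, `[`, "", 1L))
    sl <- as.integer(vapply(parts, `[`, "", 2L))
    inter <- as.integer(cnt)
    iou <- inter / (areaR[rl] + areaS[sl] - inter)
    for (i in seq_len(nrow(out))) {
      j <- which(rl == out$refLabel[i])
      if (length(j)) {
        best <- j[which.max(iou[j])]
        out$segLabel[i] <- sl[best]
        out$iou[i] <- iou[best]
      }
    }
  }
  out
}
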