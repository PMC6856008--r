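# S4 class definitions for the screening pipeline.

#' FieldImage: one multi-channel screening field
#'
#' Holds the 2-D intensity rasters of one microscope field, one matrix per
#' channel (16-bit range, 0-based pixel convention documented as (row, col)
#' with 1-based R indexing), the pixel size in micrometres and free-form
#' acquisition metadata (plate, well, field index).
#'
#' @slot channels Named list of numeric matrices, all of identical shape.
#' @slot pixelSize Micrometres per pixel (> 0).
#' @slot metadata Named list (plate/well/field and anything else).
#' @export
setClass("FieldImage",
  representation(channels = "list", pixelSize = "numeric", metadata = "list"),
  prototype(channels = list(), pixelSize = 1, metadata = list()))

setValidity("FieldImage", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("at least one channel required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))))
    return("channels must be named")
  if (!all(vapply(ch, is.matrix, logical(1L))))
    return("all channels must be matrices")
  d <- dim(ch[[1L]])
  if (!all(vapply(ch, function(m) identical(dim(m), d), logical(1L))))
    return("all channels must share one shape")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  rng <- range(unlist(lapply(ch, range), use.names = FALSE))
  if (rng[1L] < 0 || rng[2L] > 65535)
    return("channel intensities must lie in [0, 65535]")
  TRUE
})

#' Construct a FieldImage
#'
#' @param channels Named list of intensity matrices (identical shapes,
#'   values in the unsigned 16-bit range).
#' @param pixelSize Micrometres per pixel; default 1.
#' @param metadata Named list of acquisition metadata.
#' @return A [FieldImage-class] object.
#' @export
FieldImage <- function(channels, pixelSize = 1, metadata = list()) {
  new("FieldImage", channels = channels, pixelSize = pixelSize,
      metadata = metadata)
}

#' LabelMap: integer object labels over a field
#'
#' A raster of non-negative integer labels (0 = background, k > 0 = object
#' k) of one of three kinds: nucleus, cell or cytoplasm. For cell maps a
#' parent map records which cell each nucleus label belongs to (here always
#' the identity, one cell per seeding nucleus).
#'
#' @slot labels Integer matrix, values >= 0.
#' @slot kind One of "nucleus", "cell", "cytoplasm".
#' @slot parent Named integer vector mapping nucleus label -> cell label
#'   (possibly empty).
#' @export
setClass("LabelMap",
  representation(labels = "matrix", kind = "character", parent = "integer"),
  prototype(kind = "nucleus", parent = integer(0)))

setValidity("LabelMap", function(object) {
  if (!object@kind %in% c("nucleus", "cell", "cytoplasm"))
    return("kind must be nucleus, cell or cytoplasm")
  if (any(object@labels < 0)) return("labels must be non-negative")
  TRUE
})

#' Construct a LabelMap
#' @param labels Integer matrix of object labels (0 = background).
#' @param kind "nucleus", "cell" or "cytoplasm".
#' @param parent Optional named integer vector (nucleus label -> cell label).
#' @return A [LabelMap-class] object.
#' @export
LabelMap <- function(labels, kind = c("nucleus", "cell", "cytoplasm"),
                     parent = integer(0)) {
  kind <- match.arg(kind)
  storage.mode(labels) <- "integer"
  new("LabelMap", labels = labels, kind = kind, parent = parent)
}

#' SegmentationConfig: tunable segmentation settings
#'
#' @slot thresholdMethod "otsu" or "fixed".
#' @slot fixedThreshold Intensity threshold used when thresholdMethod is
#'   "fixed".
#' @slot minNucleusArea,maxNucleusArea Nucleus area filter in px^2
#'   (0 < min < max).
#' @slot declump Split touching nuclei by distance-transform watershed.
#' @slot smoothingSigma Gaussian pre-smoothing sigma in px.
#' @slot excludeBorderObjects Drop nuclei touching the field border.
#' @export
setClass("SegmentationConfig",
  representation(thresholdMethod = "character", fixedThreshold = "numeric",
    minNucleusArea = "numeric", maxNucleusArea = "numeric",
    declump = "logical", smoothingSigma = "numeric",
    excludeBorderObjects = "logical"))

setValidity("SegmentationConfig", function(object) {
  if (!object@thresholdMethod %in% c("otsu", "fixed"))
    return("thresholdMethod must be 'otsu' or 'fixed'")
  if (!(object@minNucleusArea > 0 &&
        object@minNucleusArea < object@maxNucleusArea))
    return("need 0 < minNucleusArea < maxNucleusArea")
  TRUE
})

#' Construct a SegmentationConfig
#'
#' Defaults follow standard practice for 10X fluorescence HCS fields:
#' Otsu threshold on a 2 px Gaussian-smoothed channel, declumping on,
#' border objects excluded.
#'
#' @param thresholdMethod "otsu" (default) or "fixed".
#' @param fixedThreshold Intensity cutoff for the "fixed" method.
#' @param minNucleusArea,maxNucleusArea Area filter in px^2.
#' @param declump Logical; split touching nuclei (default TRUE).
#' @param smoothingSigma Gaussian sigma in px (default 2).
#' @param excludeBorderObjects Logical; default TRUE.
#' @return A [SegmentationConfig-class] object.
#' @export
segmentationConfig <- function(thresholdMethod = c("otsu", "fixed"),
                               fixedThreshold = 0,
                               minNucleusArea = 20,
                               maxNucleusArea = 5000,
                               declump = TRUE,
                               smoothingSigma = 2,
                               excludeBorderObjects = TRUE) {
  new("SegmentationConfig", thresholdMethod = match.arg(thresholdMethod),
      fixedThreshold = fixedThreshold, minNucleusArea = minNucleusArea,
      maxNucleusArea = maxNucleusArea, declump = declump,
      smoothingSigma = smoothingSigma,
      excludeBorderObjects = excludeBorderObjects)
}

#' SceneSpec: parameters of one synthetic field
#'
#' Describes a synthetic screening field: how many cells, their shape
#' (mean area, eccentricity range), spatial organisation (clustering
#' strength, mesenchymal fraction), marker levels and noise. All
#' randomness derives from the single seed.
#'
#' @slot fieldShape Integer (rows, cols).
#' @slot nCells Number of cells to place (>= 0).
#' @slot mesenchymalFraction Fraction of cells drawn with the mesenchymal
#'   morphology (elongated, dispersed) in [0, 1].
#' @slot meanCellArea Mean cell area in px^2.
#' @slot eccentricityRange Per-cell eccentricity sampling interval, a
#'   sub-interval of [0, 1).
#' @slot clusteringStrength >= 0; 0 = uniform placement, larger = tighter
#'   Gaussian clusters around Poisson-placed centres.
#' @slot nuclearMarkerLevel,cytoplasmicMarkerLevel Mean FITC (Snail/Slug)
#'   intensity in nucleus / cytoplasm, in [0, 65535].
#' @slot nuclearDyeLevel,cellDyeLevel DAPI and Cy5 dye levels.
#' @slot background Constant autofluorescence added to every channel.
#' @slot noiseSd Additive Gaussian noise sd (intensity units).
#' @slot nucleusAreaRatio Nucleus:cell area ratio (default 0.25).
#' @slot boundaryJitter Relative amplitude of the cell-boundary jitter.
#' @slot areaCv Coefficient of variation of per-cell area.
#' @slot seed Integer seed.
#' @export
setClass("SceneSpec",
  representation(fieldShape = "integer", nCells = "integer",
    mesenchymalFraction = "numeric", meanCellArea = "numeric",
    eccentricityRange = "numeric", clusteringStrength = "numeric",
    nuclearMarkerLevel = "numeric", cytoplasmicMarkerLevel = "numeric",
    nuclearDyeLevel = "numeric", cellDyeLevel = "numeric",
    background = "numeric", noiseSd = "numeric",
    nucleusAreaRatio = "numeric", boundaryJitter = "numeric",
    areaCv = "numeric", seed = "integer"))

setValidity("SceneSpec", function(object) {
  if (length(object@fieldShape) != 2L || any(object@fieldShape < 16L))
    return("fieldShape must be two integers >= 16")
  if (object@nCells < 0L) return("nCells must be >= 0")
  if (object@mesenchymalFraction < 0 || object@mesenchymalFraction > 1)
    return("mesenchymalFraction must lie in [0, 1]")
  er <- object@eccentricityRange
  if (length(er) != 2L || er[1L] > er[2L] || er[1L] < 0 || er[2L] >= 1)
    return("eccentricityRange must be an interval inside [0, 1)")
  if (object@clusteringStrength < 0)
    return("clusteringStrength must be >= 0")
  lv <- c(object@nuclearMarkerLevel, object@cytoplasmicMarkerLevel,
          object@nuclearDyeLevel, object@cellDyeLevel, object@background)
  if (any(lv < 0) || any(lv > 65535))
    return("intensity levels must lie in [0, 65535]")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@nucleusAreaRatio <= 0 || object@nucleusAreaRatio >= 1)
    return("nucleusAreaRatio must lie in (0, 1)")
  if (object@boundaryJitter < 0 || object@boundaryJitter > 0.3)
    return("boundaryJitter must lie in [0, 0.3]")
  if (object@meanCellArea < 9) return("meanCellArea too small")
  TRUE
})

#' Construct a SceneSpec
#'
#' `phenotype` may be "epithelial" (round, clustered cells), "mesenchymal"
#' (elongated, dispersed) or a numeric mixture weight in [0, 1] giving the
#' fraction of mesenchymal cells. The enum presets set the eccentricity
#' range and clustering strength typical of the phenotype; any explicitly
#' supplied value overrides the preset.
#'
#' @param fieldShape Integer (rows, cols); default c(512, 512).
#' @param nCells Cells per field; default 50.
#' @param phenotype "epithelial", "mesenchymal" or numeric in [0, 1].
#' @param meanCellArea px^2; default 400.
#' @param eccentricityRange Default depends on phenotype; the generic
#'   default c(0.45, 0.65) describes an intermediate, TNF-alpha-primed
#'   epithelial morphology with headroom for planted effects either way.
#' @param clusteringStrength Default depends on phenotype (generic 1).
#' @param nuclearMarkerLevel,cytoplasmicMarkerLevel FITC means; defaults
#'   3000 / 1500 (nuclear:cytoplasmic Snail/Slug ratio 2).
#' @param nuclearDyeLevel,cellDyeLevel DAPI / Cy5 levels (30000 / 15000).
#' @param background Constant autofluorescence; default 200.
#' @param noiseSd Additive Gaussian noise sd; default 50.
#' @param nucleusAreaRatio Default 0.25.
#' @param boundaryJitter Default 0.05.
#' @param areaCv Default 0.1.
#' @param seed Integer seed; default 1.
#' @return A [SceneSpec-class] object.
#' @export
#' @examples
#' sceneSpec(nCells = 10, phenotype = "epithelial", seed = 7)
sceneSpec <- function(fieldShape = c(512L, 512L), nCells = 50,
                      phenotype = NULL, meanCellArea = 400,
                      eccentricityRange = NULL, clusteringStrength = NULL,
                      nuclearMarkerLevel = 3000,
                      cytoplasmicMarkerLevel = 1500,
                      nuclearDyeLevel = 30000, cellDyeLevel = 15000,
                      background = 200, noiseSd = 50,
                      nucleusAreaRatio = 0.25, boundaryJitter = 0.05,
                      areaCv = 0.1, seed = 1L) {
  mes <- 0
  presetEcc <- c(0.45, 0.65)
  presetClus <- 1
  if (!is.null(phenotype)) {
    if (is.character(phenotype)) {
      phenotype <- match.arg(phenotype, c("epithelial", "mesenchymal"))
      if (phenotype == "epithelial") {
        mes <- 0; presetEcc <- c(0.05, 0.25); presetClus <- 2
      } else {
        mes <- 1; presetEcc <- c(0.70, 0.92); presetClus <- 0
      }
    } else {
      mes <- as.numeric(phenotype)
    }
  }
  if (is.null(eccentricityRange)) eccentricityRange <- presetEcc
  if (is.null(clusteringStrength)) clusteringStrength <- presetClus
  new("SceneSpec", fieldShape = as.integer(fieldShape),
      nCells = as.integer(nCells), mesenchymalFraction = mes,
      meanCellArea = meanCellArea, eccentricityRange = eccentricityRange,
      clusteringStrength = clusteringStrength,
      nuclearMarkerLevel = nuclearMarkerLevel,
      cytoplasmicMarkerLevel = cytoplasmicMarkerLevel,
      nuclearDyeLevel = nuclearDyeLevel, cellDyeLevel = cellDyeLevel,
      background = background, noiseSd = noiseSd,
      nucleusAreaRatio = nucleusAreaRatio, boundaryJitter = boundaryJitter,
      areaCv = areaCv, seed = as.integer(seed))
}

#' ScreenDesign: plate layout plus planted treatment effects
#'
#' @slot layout data.frame with columns well, treatment, replicate.
#' @slot treatments Named list mapping treatment label to a named numeric
#'   vector of signed percent-change effects over (a subset of) the four
#'   classification parameters (see [clusteringParameters()]).
#' @slot fieldsPerWell Imaged fields per well (default 9).
#' @slot controlLabel Label of the negative-control treatment.
#' @export
setClass("ScreenDesign",
  representation(layout = "data.frame", treatments = "list",
    fieldsPerWell = "integer", controlLabel = "character"))

setValidity("ScreenDesign", function(object) {
  lay <- object@layout
  if (!all(c("well", "treatment", "replicate") %in% names(lay)))
    return("layout needs columns well, treatment, replicate")
  if (object@fieldsPerWell < 1L) return("fieldsPerWell must be >= 1")
  if (!object@controlLabel %in% lay$treatment)
    return("control label must appear in at least one well")
  bad <- setdiff(unique(lay$treatment), names(object@treatments))
  if (length(bad))
    return(paste0("layout treatment(s) missing from treatments: ",
                  paste(bad, collapse = ", ")))
  badp <- unlist(lapply(object@treatments, function(e)
    setdiff(names(e), clusteringParameters())))
  if (length(badp))
    return(paste0("unknown effect parameter(s): ",
                  paste(unique(badp), collapse = ", ")))
  TRUE
})

#' Construct a ScreenDesign
#'
#' Builds a one-plate layout with `replicates` wells per treatment plus
#' `controlWells` wells of the negative control, assigning well ids
#' row-major on a 96-well grid.
#'
#' @param treatments Named list of effect vectors (signed percent change on
#'   the classification parameters); the control is added automatically
#'   with a zero effect if absent.
#' @param controlLabel Negative-control label; default "PMC".
#' @param replicates Wells per treatment; default 3.
#' @param controlWells Wells of the control; default `replicates`.
#' @param fieldsPerWell Default 9.
#' @return A [ScreenDesign-class] object.
#' @export
#' @examples
#' screenDesign(list(`miR-a` = c(`count nuclei` = -40)), replicates = 2)
screenDesign <- function(treatments, controlLabel = "PMC", replicates = 3,
                         controlWells = replicates, fieldsPerWell = 9) {
  if (!controlLabel %in% names(treatments))
    treatments[[controlLabel]] <- numeric(0)
  labs <- c(controlLabel, setdiff(names(treatments), controlLabel))
  reps <- ifelse(labs == controlLabel, controlWells, replicates)
  treatment <- rep(labs, reps)
  replicate <- unlist(lapply(reps, seq_len), use.names = FALSE)
  n <- length(treatment)
  stopIfNot(n <= 96L, "design does not fit on a 96-well plate")
  wellRow <- (seq_len(n) - 1L) %/% 12L + 1L
  wellCol <- (seq_len(n) - 1L) %% 12L + 1L
  layout <- data.frame(well = sprintf("%s%02d", LETTERS[wellRow], wellCol),
                       treatment = treatment, replicate = replicate,
                       stringsAsFactors = FALSE)
  new("ScreenDesign", layout = layout, treatments = treatments,
      fieldsPerWell = as.integer(fieldsPerWell),
      controlLabel = controlLabel)
}

#' PlantedTargetSpec: synthetic target-table blueprint
#'
#' Describes a synthetic miR -> predicted-target table with planted
#' structure: per-group consensus genes guaranteed to pass the
#' max(N - 2, 4) rule, genes planted as shared between designated group
#' pairs (to exercise opposite-group exclusion), and i.i.d. background
#' edges.
#'
#' @slot groups Named list: group id -> character vector of miR labels.
#' @slot universeSize Number of genes in the universe.
#' @slot plantedConsensus Named list: group id -> planted consensus genes.
#' @slot plantedShared Named list: "A|B" -> genes planted into the
#'   consensus of both A and B.
#' @slot backgroundEdgeProb Probability of each non-planted (miR, gene)
#'   edge.
#' @slot seed Integer seed.
#' @export
setClass("PlantedTargetSpec",
  representation(groups = "list", universeSize = "integer",
    plantedConsensus = "list", plantedShared = "list",
    backgroundEdgeProb = "numeric", seed = "integer"))

setValidity("PlantedTargetSpec", function(object) {
  if (length(object@groups) == 0L) return("at least one group required")
  if (is.null(names(object@groups))) return("groups must be named")
  uni <- geneUniverse(object@universeSize)
  planted <- c(unlist(object@plantedConsensus, use.names = FALSE),
               unlist(object@plantedShared, use.names = FALSE))
  if (!all(planted %in% uni))
    return("planted genes must lie inside the universe")
  if (anyDuplicated(planted))
    return("planted consensus/shared gene sets must be disjoint")
  for (nm in names(object@plantedShared)) {
    gg <- strsplit(nm, "|", fixed = TRUE)[[1L]]
    if (length(gg) != 2L || !all(gg %in% names(object@groups)))
      return("plantedShared names must be 'groupA|groupB' over known groups")
  }
  if (!all(names(object@plantedConsensus) %in% names(object@groups)))
    return("plantedConsensus names must be known groups")
  if (object@backgroundEdgeProb < 0 || object@backgroundEdgeProb > 1)
    return("backgroundEdgeProb must lie in [0, 1]")
  TRUE
})

#' Gene universe of a synthetic target table
#' @param n Universe size.
#' @return Character vector "GENE00001"... of length n.
#' @export
geneUniverse <- function(n) sprintf("GENE%05d", seq_len(n))

#' Construct a PlantedTargetSpec
#'
#' Planted gene identities are allocated deterministically from the front
#' of the universe: first the per-group consensus blocks (in group order),
#' then the shared blocks (in pair order).
#'
#' @param groups Named list of miR label vectors.
#' @param universeSize Gene universe size.
#' @param nConsensus Named integer (or single value recycled): planted
#'   consensus genes per group.
#' @param shared Named integer: planted shared genes per "A|B" pair
#'   (default none).
#' @param backgroundEdgeProb Default 0.
#' @param seed Default 1.
#' @return A [PlantedTargetSpec-class] object.
#' @export
plantedTargetSpec <- function(groups, universeSize, nConsensus,
                              shared = integer(0),
                              backgroundEdgeProb = 0, seed = 1L) {
  if (length(nConsensus) == 1L && is.null(names(nConsensus)))
    nConsensus <- setNames(rep(nConsensus, length(groups)), names(groups))
  uni <- geneUniverse(universeSize)
  need <- sum(nConsensus) + sum(shared)
  stopIfNot(need <= universeSize,
            "universe too small to host the planted gene sets")
  cursor <- 0L
  take <- function(k) {
    out <- uni[cursor + seq_len(k)]
    cursor <<- cursor + as.integer(k)
    out
  }
  plantedConsensus <- lapply(nConsensus, take)
  plantedShared <- lapply(shared, take)
  new("PlantedTargetSpec", groups = groups,
      universeSize = as.integer(universeSize),
      plantedConsensus = plantedConsensus, plantedShared = plantedShared,
      backgroundEdgeProb = backgroundEdgeProb, seed = as.integer(seed))
}

#' TargetTable: miR -> predicted-target edges
#'
#' @slot edges data.frame with character columns mir and gene; rows unique.
#' @slot source Free-text provenance of the prediction set.
#' @export
setClass("TargetTable",
  representation(edges = "data.frame", source = "character"),
  prototype(source = "unspecified"))

setValidity("TargetTable", function(object) {
  e <- object@edges
  if (!all(c("mir", "gene") %in% names(e)))
    return("edges needs columns mir and gene")
  if (nrow(e) == 0L) return("target table is empty")
  if (any(!nzchar(e$mir)) || any(!nzchar(e$gene)))
    return("mir and gene labels must be non-empty")
  if (anyDuplicated(paste(e$mir, e$gene, sep = "\r")))
    return("edges must be unique")
  TRUE
})

#' Construct a TargetTable
#' @param edges data.frame with columns mir, gene (duplicates collapsed).
#' @param source Provenance string.
#' @return A [TargetTable-class] object.
#' @export
TargetTable <- function(edges, source = "unspecified") {
  edges <- unique(data.frame(mir = as.character(edges$mir),
                             gene = as.character(edges$gene),
                             stringsAsFactors = FALSE))
  rownames(edges) <- NULL
  new("TargetTable", edges = edges, source = source)
}

#' ProfileMatrix: percent-change-vs-control phenotypic profiles
#'
#' Rows are treatments (miRs), columns are measured parameters; values are
#' the signed percent change of the per-well medians relative to the
#' negative-control wells (PMC normalisation).
#'
#' @slot values Numeric matrix, treatments x parameters, finite values.
#' @slot replicateN Integer matrix of the same shape: wells contributing
#'   to each entry.
#' @slot controlLabel The negative-control treatment label.
#' @slot qcLog data.frame(item, reason) of dropped wells/columns.
#' @export
setClass("ProfileMatrix",
  representation(values = "matrix", replicateN = "matrix",
    controlLabel = "character", qcLog = "data.frame"),
  prototype(qcLog = data.frame(item = character(0), reason = character(0),
                               stringsAsFactors = FALSE)))

setValidity("ProfileMatrix", function(object) {
  if (any(!is.finite(object@values)))
    return("profile values must be finite")
  if (is.null(rownames(object@values)) || is.null(colnames(object@values)))
    return("values must carry treatment and parameter dimnames")
  if (!identical(dim(object@values), dim(object@replicateN)))
    return("replicateN must match values in shape")
  TRUE
})

#' MiRGroup: a clustered miR group with its phenotype call
#'
#' @slot groupId Group label (e.g. "G1a").
#' @slot members miR labels.
#' @slot meanProfile Named numeric: mean PMC per parameter over members.
#' @slot phenotype One of "pro-survival/EMT", "anti-survival/EMT",
#'   "pro-survival", "anti-survival", "unclassified".
#' @export
setClass("MiRGroup",
  representation(groupId = "character", members = "character",
    meanProfile = "numeric", phenotype = "character"))

setValidity("MiRGroup", function(object) {
  if (length(object@members) == 0L) return("group must have members")
  ok <- c("pro-survival/EMT", "anti-survival/EMT", "pro-survival",
          "anti-survival", "unclassified")
  if (!object@phenotype %in% ok)
    return("invalid phenotype label")
  TRUE
})

#' MirClustering: result of hierarchical clustering of the profile matrix
#'
#' @slot memberships data.frame(mir, mainGroup, group): main dendrogram
#'   groups plus survival-split subgroups.
#' @slot hclust The hclust tree (over z-scored profiles).
#' @slot pmc The PMC matrix the clustering ran on (rows as clustered).
#' @slot kMain Number of main groups the dendrogram was cut into.
#' @slot droppedColumns Zero-variance columns removed before clustering.
#' @export
setClass("MirClustering",
  representation(memberships = "data.frame", hclust = "ANY",
    pmc = "matrix", kMain = "integer", droppedColumns = "character"))

#' ConsensusResult: per-group consensus targets with exclusion state
#'
#' @slot groupId Group label.
#' @slot members miR labels of the group (defines N).
#' @slot thresholdUsed max(N - 2, 4).
#' @slot supporters Named integer: consensus gene -> number of distinct
#'   group miRs predicted to target it (all >= threshold).
#' @slot excluded data.frame(gene, sharedWith): consensus genes removed
#'   because an opposite-phenotype group also reached consensus on them.
#' @slot filtered Consensus genes surviving exclusion.
#' @slot absentMembers Group miRs not found in the target table (kept in N).
#' @export
setClass("ConsensusResult",
  representation(groupId = "character", members = "character",
    thresholdUsed = "integer", supporters = "integer",
    excluded = "data.frame", filtered = "character",
    absentMembers = "character"),
  prototype(excluded = data.frame(gene = character(0),
                                  sharedWith = character(0),
                                  stringsAsFactors = FALSE),
            absentMembers = character(0)))

setValidity("ConsensusResult", function(object) {
  n <- length(object@members)
  if (n < 1L) return("group must have at least one member")
  if (object@thresholdUsed != max(n - 2L, 4L))
    return("thresholdUsed must equal max(N - 2, 4)")
  cons <- names(object@supporters)
  if (!all(object@filtered %in% cons))
    return("filtered genes must be a subset of consensus genes")
  if (length(intersect(object@excluded$gene, object@filtered)))
    return("excluded and filtered gene sets must be disjoint")
  TRUE
})
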