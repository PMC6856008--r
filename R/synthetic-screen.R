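# Synthetic screen generation: one scene spec per well, derived from the
# control spec by the treatment's signed percent-change effects on the
# four classification parameters; fields generated and (optionally)
# measured one at a time so a full plate never sits in memory.

# Derive the per-well scene spec: control parameters scaled by
# (1 + effect / 100).
applyEffects <- function(baseSpec, effect) {
  spec <- baseSpec
  e <- function(p) if (p %in% names(effect)) effect[[p]] else 0
  spec@nCells <- as.integer(round(baseSpec@nCells *
                                    (1 + e("count nuclei") / 100)))
  er <- baseSpec@eccentricityRange * (1 + e("cells eccentricity") / 100)
  stopIfNot(er[2L] < 1,
            "eccentricity effect pushes the range outside [0, 1)")
  spec@eccentricityRange <- er
  spec@nuclearMarkerLevel <- baseSpec@nuclearMarkerLevel *
    (1 + e("Nuclei Median Intensity Snail/Slug") / 100)
  spec@cytoplasmicMarkerLevel <- baseSpec@cytoplasmicMarkerLevel *
    (1 + e("Cytoplasm Median Intensity Snail/Slug") / 100)
  spec
}

#' Generate (and optionally measure) a synthetic miR screen
#'
#' For every well of the design, derives the well's scene parameters from
#' the control spec and the treatment's planted effects, generates
#' `fieldsPerWell` fields, and (by default) measures the ground-truth
#' label maps with [cellFeatures()] to produce per-cell records ready for
#' [fieldSummaries()]. Per-well planted parameter values are returned as
#' the ground-truth table. With an output directory, fields are written
#' as multi-page TIFFs named `<plate>_<well>_s<field>.tif` alongside the
#' plate-layout and ground-truth CSVs.
#'
#' @param design A [ScreenDesign-class].
#' @param baseSpec The control-condition [SceneSpec-class]; its seed seeds
#'   the whole screen (each well/field derives its own stream).
#' @param measure Measure ground-truth label maps into cell records
#'   (default TRUE).
#' @param outDir Optional directory for TIFF/CSV output.
#' @param plate Plate name used in file names (default "plate1").
#' @param channels Channels measured for intensity features (default
#'   "FITC", the Snail/Slug stain — all the profile matrix needs).
#' @param expansionPx Neighbour-detection expansion (default 1).
#' @return List: `cells` (per-cell records with well/field/treatment
#'   columns; NULL unless `measure`), `truth` (per-well planted parameter
#'   values), `layout`, `design`, and `files` (written TIFF paths, if
#'   any).
#' @export
#' @examples
#' d <- screenDesign(list(`miR-a` = c(`count nuclei` = -50)),
#'                   replicates = 1, fieldsPerWell = 2)
#' scr <- generateScreen(d, sceneSpec(nCells = 20, fieldShape = c(256, 256),
#'                                    noiseSd = 0, seed = 3))
#' head(scr$truth)
generateScreen <- function(design, baseSpec, measure = TRUE,
                           outDir = NULL, plate = "plate1",
                           channels = "FITC", expansionPx = 1L) {
  validObject(design)
  lay <- design@layout
  cellsList <- vector("list", nrow(lay) * design@fieldsPerWell)
  files <- character(0)
  truth <- data.frame()
  k <- 0L
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  for (w in seq_len(nrow(lay))) {
    wellId <- lay$well[w]
    trt <- lay$treatment[w]
    if (!trt %in% names(design@treatments))
      stop("unknown treatment label: ", trt, call. = FALSE)
    eff <- design@treatments[[trt]]
    wellSpec <- applyEffects(baseSpec, eff)
    truth <- rbind(truth, data.frame(
      well = wellId, treatment = trt,
      `count nuclei` = wellSpec@nCells * design@fieldsPerWell,
      `cells eccentricity` = mean(wellSpec@eccentricityRange),
      `Nuclei Median Intensity Snail/Slug` = wellSpec@nuclearMarkerLevel,
      `Cytoplasm Median Intensity Snail/Slug` =
        wellSpec@cytoplasmicMarkerLevel,
      check.names = FALSE, stringsAsFactors = FALSE))
    for (fi in seq_len(design@fieldsPerWell)) {
      wellSpec@seed <- mixSeed(baseSpec@seed, wellId, fi)
      fld <- generateField(wellSpec)
      if (!is.null(outDir)) {
        fn <- file.path(outDir,
                        sprintf("%s_%s_s%d.tif", plate, wellId, fi))
        writeFieldImage(fld$image, fn)
        files <- c(files, fn)
      }
      k <- k + 1L
      if (measure) {
        rec <- cellFeatures(fld$image, fld$nuclei, fld$cells,
                            expansionPx = expansionPx,
                            channels = channels)
        if (nrow(rec)) {
          rec$well <- wellId
          rec$field <- fi
          rec$treatment <- trt
          cellsList[[k]] <- rec
        }
      }
    }
  }
  cells <- if (measure) do.call(rbind, cellsList[!vapply(
    cellsList, is.null, logical(1L))]) else NULL
  if (!is.null(outDir)) {
    writePlateLayout(lay, file.path(outDir, paste0(plate, "_layout.csv")))
    write.csv(truth, file.path(outDir, paste0(plate, "_truth.csv")),
              row.names = FALSE)
  }
  list(cells = cells, truth = truth, layout = lay, design = design,
       files = files)
}

#' Enumerate the fields of a screen design
#'
#' @param design A [ScreenDesign-class].
#' @return data.frame(well, field), one row per imaged field.
#' @export
screenFields <- function(design) {
  lay <- design@layout
  data.frame(well = rep(lay$well, each = design@fieldsPerWell),
             field = rep(seq_len(design@fieldsPerWell), nrow(lay)),
             stringsAsFactors = FALSE)
}
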