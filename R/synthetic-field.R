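# Synthetic field generation: rasterized jittered ellipses on a dark
# background, with ground-truth label maps. Cells are elliptical with a
# concentric elliptical nucleus (area ratio nucleusAreaRatio); epithelial
# cells are placed in Gaussian clusters around Poisson-distributed
# centres, mesenchymal cells are elongated and uniformly dispersed.

mesenchymalEccRange <- c(0.70, 0.92)

# Pixel indices (into an nr x nc matrix) of a jittered ellipse.
# a, b: semi-axes (a along orientation theta); jitter multiplies the
# radius by 1 + amp * sin(harm * phi + phase) in normalized polar angle.
rasterizeEllipse <- function(center, a, b, theta, shape, amp = 0,
                             harm = 3L, phase = 0) {
  nr <- shape[1L]; nc <- shape[2L]
  ext <- max(a, b) * (1 + amp) + 1
  r0 <- max(1L, floor(center[1L] - ext)); r1 <- min(nr, ceiling(center[1L] + ext))
  c0 <- max(1L, floor(center[2L] - ext)); c1 <- min(nc, ceiling(center[2L] + ext))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  dy <- rows - center[1L]
  dx <- cols - center[2L]
  DY <- matrix(dy, length(dy), length(dx))
  DX <- matrix(dx, length(dy), length(dx), byrow = TRUE)
  u <- (DX * cos(theta) + DY * sin(theta)) / a
  v <- (-DX * sin(theta) + DY * cos(theta)) / b
  rr <- u * u + v * v
  if (amp > 0) {
    phi <- atan2(v, u)
    scale <- 1 + amp * sin(harm * phi + phase)
    inside <- rr <= scale * scale
  } else {
    inside <- rr <= 1
  }
  w <- which(inside)
  if (length(w) == 0L) return(integer(0))
  lr <- (w - 1L) %% length(rows) + 1L
  lc <- (w - 1L) %/% length(rows) + 1L
  (cols[lc] - 1L) * nr + rows[lr]
}

# Semi-axes of an ellipse with given area and eccentricity.
ellipseAxes <- function(area, ecc) {
  ratio <- sqrt(1 - ecc^2)                    # b / a
  a <- sqrt(area / (pi * ratio))
  c(a = a, b = a * ratio)
}

#' Generate one synthetic multi-channel field with ground truth
#'
#' Places `nCells` non-overlapping jittered-ellipse cells (each with a
#' concentric elliptical nucleus) according to the scene specification and
#' renders the four channels: DAPI (nuclear dye), FITC (Snail/Slug:
#' `nuclearMarkerLevel` inside nuclei, `cytoplasmicMarkerLevel` inside
#' cytoplasm), TexasRed (background only) and Cy5 (whole-cell dye).
#' Before noise, FITC inside each compartment equals the spec mean
#' exactly. Identical spec + seed reproduces the identical scene.
#'
#' @param spec A [SceneSpec-class].
#' @param maxAttempts Placement attempts per cell before the field is
#'   declared overcrowded.
#' @return List with elements `image` ([FieldImage-class]), `nuclei` and
#'   `cells` (ground-truth [LabelMap-class]s, labels 1..nCells in
#'   placement order), and `truth` (data.frame of planted per-cell
#'   parameters: cell, row, col, area_px, eccentricity, mesenchymal).
#' @export
#' @examples
#' f <- generateField(sceneSpec(nCells = 5, fieldShape = c(128, 128)))
#' nObjects(f$nuclei)
generateField <- function(spec, maxAttempts = 200L) {
  validObject(spec)
  nr <- spec@fieldShape[1L]; nc <- spec@fieldShape[2L]
  n <- spec@nCells
  withSeed(spec@seed, {
    cellLab <- matrix(0L, nr, nc)
    nucLab <- matrix(0L, nr, nc)
    truth <- data.frame(cell = integer(0), row = numeric(0),
                        col = numeric(0), area_px = integer(0),
                        eccentricity = numeric(0), mesenchymal = logical(0))
    if (n > 0L) {
      mes <- runif(n) < spec@mesenchymalFraction
      er <- spec@eccentricityRange
      ecc <- runif(n, er[1L], er[2L])
      ecc[mes] <- runif(sum(mes), mesenchymalEccRange[1L],
                        mesenchymalEccRange[2L])
      s <- sqrt(log(1 + spec@areaCv^2))
      area <- if (s > 0)
        exp(rnorm(n, log(spec@meanCellArea) - s^2 / 2, s)) else
        rep(spec@meanCellArea, n)
      area <- pmax(area, 9)
      theta <- runif(n, 0, pi)
      harm <- sample(3:6, n, replace = TRUE)
      phase <- runif(n, 0, 2 * pi)
      nClusters <- 1L + rpois(1L, n / 12)
      margin <- max(ellipseAxes(max(area), max(ecc))[1L]) *
        (1 + spec@boundaryJitter) + 2
      stopIfNot(margin * 2 < min(nr, nc),
                "field overcrowded: cells too large for the field")
      ctrRow <- runif(nClusters, margin, nr - margin)
      ctrCol <- runif(nClusters, margin, nc - margin)
      clusterOf <- sample.int(nClusters, n, replace = TRUE)
      sdClus <- if (spec@clusteringStrength > 0)
        min(nr, nc) / (4 * spec@clusteringStrength) else Inf
      truth <- data.frame(cell = seq_len(n), row = NA_real_,
                          col = NA_real_, area_px = NA_integer_,
                          eccentricity = ecc, mesenchymal = mes)
      for (i in seq_len(n)) {
        ax <- ellipseAxes(area[i], ecc[i])
        placed <- FALSE
        for (att in seq_len(maxAttempts)) {
          if (mes[i] || is.infinite(sdClus)) {
            pos <- c(runif(1, margin, nr - margin),
                     runif(1, margin, nc - margin))
          } else {
            k <- clusterOf[i]
            pos <- c(ctrRow[k], ctrCol[k]) + rnorm(2L, 0, sdClus)
            pos <- pmin(pmax(pos, margin), c(nr, nc) - margin)
          }
          idx <- rasterizeEllipse(pos, ax[1L], ax[2L], theta[i],
                                  c(nr, nc), spec@boundaryJitter,
                                  harm[i], phase[i])
          if (length(idx) && !any(cellLab[idx] > 0L)) {
            cellLab[idx] <- i
            nax <- ax * sqrt(spec@nucleusAreaRatio)
            nidx <- rasterizeEllipse(pos, nax[1L], nax[2L], theta[i],
                                     c(nr, nc))
            nucLab[nidx] <- i
            truth$row[i] <- pos[1L]; truth$col[i] <- pos[2L]
            truth$area_px[i] <- length(idx)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("field overcrowded: could not place cell ", i, " after ",
               maxAttempts, " attempts", call. = FALSE)
      }
    }
    bg <- spec@background
    dapi <- matrix(bg, nr, nc)
    fitc <- matrix(bg, nr, nc)
    texas <- matrix(bg, nr, nc)
    cy5 <- matrix(bg, nr, nc)
    cellIdx <- which(cellLab > 0L)
    nucIdx <- which(nucLab > 0L)
    cytoIdx <- setdiff(cellIdx, nucIdx)
    dapi[nucIdx] <- spec@nuclearDyeLevel
    cy5[cellIdx] <- spec@cellDyeLevel
    fitc[nucIdx] <- spec@nuclearMarkerLevel
    fitc[cytoIdx] <- spec@cytoplasmicMarkerLevel
    channels <- list(DAPI = dapi, FITC = fitc, TexasRed = texas, Cy5 = cy5)
    if (spec@noiseSd > 0) {
      channels <- lapply(channels, function(m) {
        m <- m + rnorm(length(m), 0, spec@noiseSd)
        pmin(pmax(m, 0), 65535)
      })
    }
    channels <- lapply(channels, round)
    list(image = FieldImage(channels, metadata = list(seed = spec@seed)),
         nuclei = LabelMap(nucLab, "nucleus"),
         cells = LabelMap(cellLab, "cell",
                          parent = setNames(seq_len(max(n, 0L)),
                                            seq_len(max(n, 0L)))),
         truth = truth)
  })
}

#' Cytoplasm label map from matching cell and nucleus maps
#'
#' The cytoplasm of object k is the set difference cell_k minus nucleus_k.
#'
#' @param cells,nuclei [LabelMap-class]s of kind "cell" / "nucleus" with
#'   matching labels.
#' @return A [LabelMap-class] of kind "cytoplasm".
#' @export
cytoplasmMap <- function(cells, nuclei) {
  stopIfNot(identical(dim(cells@labels), dim(nuclei@labels)),
            "cell and nucleus maps must share one shape")
  lab <- cells@labels
  lab[nuclei@labels > 0L] <- 0L
  LabelMap(lab, "cytoplasm", parent = cells@parent)
}

#' Generate a synthetic phase-contrast-like confluence image
#'
#' Emulates the texture contrast of phase-contrast migration images:
#' a blurred-noise blob mask occupying exactly the requested fraction of
#' the field, filled with high-variance texture over a flat low-variance
#' background (mean intensity is identical, only texture differs).
#'
#' @param fraction Target occupied fraction in [0, 1].
#' @param fieldShape Integer (rows, cols); default c(256, 256).
#' @param seed Integer seed.
#' @return List: `image` (numeric matrix), `mask` (logical ground truth),
#'   `fraction` (achieved pixel fraction).
#' @export
generateConfluenceImage <- function(fraction, fieldShape = c(256L, 256L),
                                    seed = 1L) {
  stopIfNot(fraction >= 0 && fraction <= 1, "fraction must lie in [0, 1]")
  nr <- fieldShape[1L]; nc <- fieldShape[2L]
  withSeed(mixSeed(seed, "confluence"), {
    field <- matrix(rnorm(nr * nc), nr, nc)
    sm <- ebMat(EBImage::gblur(EBImage::Image(field), sigma = 8))
    mask <- if (fraction == 0) matrix(FALSE, nr, nc)
            else sm >= quantile(sm, 1 - fraction, type = 1)
    img <- 1000 + matrix(rnorm(nr * nc, 0, 15), nr, nc)
    img[mask] <- 1000 + rnorm(sum(mask), 0, 300)
    img <- pmin(pmax(img, 0), 65535)
    list(image = img, mask = mask, fraction = mean(mask))
  })
}
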