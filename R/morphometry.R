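# Per-cell morphometry: area, eccentricity, solidity, neighbour counts,
# percent intercellular contact, compartment median intensities.
#
# Conventions (fixed so results are bit-stable):
# * Eccentricity comes from the eigenvalues of the second central moments
#   of the pixel distribution, with 1/12 (the variance of a unit pixel)
#   added to both diagonal moments — the regionprops/CellProfiler ellipse.
#   A single pixel therefore has eccentricity exactly 0 and no mask
#   reaches 1.
# * Solidity is pixel count / number of pixel centres inside-or-on the
#   convex hull of the object's pixel centres (the "convex image" count).
# * Medians over an even number of pixels are the midpoint of the two
#   central order statistics.

eccFromMoments <- function(m20, m02, m11) {
  tr <- m20 + m02
  d <- sqrt((m20 - m02)^2 + 4 * m11^2)
  l1 <- (tr + d) / 2
  l2 <- (tr - d) / 2
  sqrt(pmax(0, 1 - l2 / l1))
}

# Number of integer lattice points inside or on the convex hull of the
# given pixel centres. Handles degenerate (collinear) point sets.
convexPixelCount <- function(row, col, eps = 1e-9) {
  n <- length(row)
  if (n == 1L) return(1L)
  pts <- unique(cbind(col, row))            # (x, y)
  h <- chull(pts[, 1L], pts[, 2L])
  if (length(h) < 3L) {                     # collinear set
    i <- which.max((pts[, 1L] - pts[1L, 1L])^2 +
                   (pts[, 2L] - pts[1L, 2L])^2)
    dx <- pts[i, 1L] - pts[1L, 1L]
    dy <- pts[i, 2L] - pts[1L, 2L]
    # extremes along the line
    proj <- (pts[, 1L] - pts[1L, 1L]) * dx + (pts[, 2L] - pts[1L, 2L]) * dy
    a <- pts[which.min(proj), , drop = TRUE]
    b <- pts[which.max(proj), , drop = TRUE]
    g <- abs(b[1L] - a[1L])
    g2 <- abs(b[2L] - a[2L])
    gcd <- function(p, q) if (q == 0) p else gcd(q, p %% q)
    return(as.integer(gcd(max(g, g2), min(g, g2)) + 1L))
  }
  vx <- pts[h, 1L]; vy <- pts[h, 2L]
  m <- length(h)
  cx <- seq(min(vx), max(vx))
  cy <- seq(min(vy), max(vy))
  X <- matrix(cx, length(cx), length(cy))
  Y <- matrix(cy, length(cx), length(cy), byrow = TRUE)
  jj <- c(seq_len(m)[-1L], 1L)
  orient <- sign(sum(vx * vy[jj] - vx[jj] * vy))   # +1 ccw, -1 cw
  inside <- matrix(TRUE, length(cx), length(cy))
  for (i in seq_len(m)) {
    j <- jj[i]
    cross <- (vx[j] - vx[i]) * (Y - vy[i]) - (vy[j] - vy[i]) * (X - vx[i])
    inside <- inside & (orient * cross >= -eps)
  }
  sum(inside)
}

#' Shape features of a single binary mask
#'
#' @param mask Logical (or 0/1) matrix holding one connected object.
#' @return Named numeric vector: `area` (pixel count), `eccentricity`
#'   (0 = circle), `solidity` (area / convex-hull pixel count).
#' @export
#' @examples
#' disc <- outer(1:41, 1:41, function(r, c) (r - 21)^2 + (c - 21)^2 <= 400)
#' shapeFeatures(disc)
shapeFeatures <- function(mask) {
  idx <- which(mask > 0)
  stopIfNot(length(idx) > 0L, "empty mask")
  nr <- nrow(mask)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  n <- length(idx)
  mr <- mean(row); mc <- mean(col)
  m20 <- mean((row - mr)^2) + 1 / 12
  m02 <- mean((col - mc)^2) + 1 / 12
  m11 <- mean((row - mr) * (col - mc))
  c(area = n,
    eccentricity = eccFromMoments(m20, m02, m11),
    solidity = n / convexPixelCount(row, col))
}

# Vectorized shape features for every label of a map.
shapeFeaturesByLabel <- function(lab) {
  idx <- which(lab > 0L)
  if (length(idx) == 0L)
    return(data.frame(cell_id = integer(0), area_px = integer(0),
                      eccentricity = numeric(0), solidity = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0)))
  nr <- nrow(lab)
  l <- lab[idx]
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  S <- rowsum(cbind(1, row, col, row^2, col^2, row * col), l)
  ids <- as.integer(rownames(S))
  n <- S[, 1L]
  mr <- S[, 2L] / n; mc <- S[, 3L] / n
  m20 <- S[, 4L] / n - mr^2 + 1 / 12
  m02 <- S[, 5L] / n - mc^2 + 1 / 12
  m11 <- S[, 6L] / n - mr * mc
  byLab <- split(seq_along(l), l)
  sol <- vapply(byLab, function(ii)
    n[[as.character(l[ii[1L]])]] /
      convexPixelCount(row[ii], col[ii]), numeric(1L))
  data.frame(cell_id = ids, area_px = as.integer(n),
             eccentricity = eccFromMoments(m20, m02, m11),
             solidity = as.numeric(sol[as.character(ids)]),
             centroid_row = mr, centroid_col = mc)
}

#' Neighbour counts and percent intercellular contact
#'
#' Two cells are neighbours iff, after expanding every label by
#' `expansionPx` pixels (8-connectivity, ties to the lower label), their
#' expanded masks contain an 8-adjacent pixel pair. Percent touching is
#' measured on the *un-expanded* map: 100 x (boundary pixels 8-adjacent
#' to a different cell label) / (total boundary pixels), where boundary
#' pixels are object pixels with any 8-neighbour (or field edge) outside
#' the object.
#'
#' @param cells A [LabelMap-class] of kind "cell".
#' @param expansionPx Label expansion radius for neighbour detection
#'   (default 1).
#' @return data.frame(cell_id, n_neighbors, percent_touching).
#' @export
neighborFeatures <- function(cells, expansionPx = 1L) {
  lab <- cells@labels
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L)
    return(data.frame(cell_id = integer(0), n_neighbors = integer(0),
                      percent_touching = numeric(0)))
  offs <- neighborOffsets8()
  # --- expansion (ties to lower label) ---
  cur <- lab
  for (step in seq_len(expansionPx)) {
    nb <- matrix(Inf, nrow(cur), ncol(cur))
    for (k in seq_len(nrow(offs))) {
      s <- shiftMat(cur, offs[k, 1L], offs[k, 2L], 0L)
      sel <- s > 0L
      nb[sel] <- pmin(nb[sel], s[sel])
    }
    grow <- cur == 0L & is.finite(nb)
    cur[grow] <- as.integer(nb[grow])
  }
  # --- neighbour pairs on the expanded map ---
  pairA <- integer(0); pairB <- integer(0)
  for (k in seq_len(nrow(offs))) {
    s <- shiftMat(cur, offs[k, 1L], offs[k, 2L], 0L)
    sel <- cur > 0L & s > 0L & cur != s
    if (any(sel)) {
      pairA <- c(pairA, cur[sel])
      pairB <- c(pairB, s[sel])
    }
  }
  nb <- unique(data.frame(a = pmin(pairA, pairB), b = pmax(pairA, pairB)))
  nNeigh <- setNames(integer(length(ids)), ids)
  if (nrow(nb)) {
    cnt <- table(c(nb$a, nb$b))
    nNeigh[names(cnt)] <- as.integer(cnt)
  }
  # --- percent touching on the un-expanded map ---
  anyOut <- matrix(FALSE, nrow(lab), ncol(lab))
  anyOther <- matrix(FALSE, nrow(lab), ncol(lab))
  for (k in seq_len(nrow(offs))) {
    s <- shiftMat(lab, offs[k, 1L], offs[k, 2L], -1L)
    anyOut <- anyOut | s != lab
    anyOther <- anyOther | (s > 0L & s != lab)
  }
  boundary <- lab > 0L & anyOut
  touch <- boundary & anyOther
  bCnt <- tabulate(lab[boundary], nbins = max(ids))
  tCnt <- tabulate(lab[touch], nbins = max(ids))
  pct <- ifelse(bCnt[ids] > 0L, 100 * tCnt[ids] / bCnt[ids], 0)
  data.frame(cell_id = ids, n_neighbors = as.integer(nNeigh),
             percent_touching = pct)
}

#' Per-cell median channel intensities by compartment
#'
#' Median pixel intensity of every requested channel over the nucleus and
#' cytoplasm of each object. Objects whose cytoplasm is empty (nucleus
#' fills the cell) get NA cytoplasmic medians and are flagged.
#'
#' @param image A [FieldImage-class].
#' @param nuclei,cytoplasm [LabelMap-class]s aligned with the image.
#' @param channels Channel names to measure (default: all).
#' @return data.frame with cell_id, `median_<channel>_nucleus` /
#'   `_cytoplasm` columns and a logical `cytoplasm_missing` flag.
#' @export
intensityFeatures <- function(image, nuclei, cytoplasm,
                              channels = channelNames(image)) {
  d <- dim(image@channels[[1L]])
  stopIfNot(identical(d, dim(nuclei@labels)) &&
              identical(d, dim(cytoplasm@labels)),
            "label map and image shapes differ")
  ids <- sort(unique(c(nuclei@labels[nuclei@labels > 0L],
                       cytoplasm@labels[cytoplasm@labels > 0L])))
  out <- data.frame(cell_id = ids)
  medByLabel <- function(ch, lab) {
    v <- tapply(ch[lab > 0L], lab[lab > 0L], median)
    res <- setNames(rep(NA_real_, length(ids)), ids)
    res[names(v)] <- v
    res
  }
  for (ch in channels) {
    m <- getChannel(image, ch)
    out[[paste0("median_", ch, "_nucleus")]] <-
      as.numeric(medByLabel(m, nuclei@labels))
    out[[paste0("median_", ch, "_cytoplasm")]] <-
      as.numeric(medByLabel(m, cytoplasm@labels))
  }
  cytoIds <- unique(cytoplasm@labels[cytoplasm@labels > 0L])
  out$cytoplasm_missing <- !(ids %in% cytoIds)
  out
}

#' Full per-cell feature table for one field
#'
#' Combines shape, neighbour and intensity features into one record per
#' cell (cell shape from the cell mask, intensities from nucleus and
#' cytoplasm compartments).
#'
#' @param image A [FieldImage-class].
#' @param nuclei,cells Matching [LabelMap-class]s (e.g. ground truth from
#'   [generateField()] or output of [segmentNuclei()]/[segmentCells()]).
#' @param expansionPx Neighbour-detection expansion (default 1).
#' @param channels Channels to measure intensities for (default: all).
#' @return data.frame, one row per cell: cell_id, area_px, area_um2,
#'   eccentricity, solidity, centroid, n_neighbors, percent_touching and
#'   per-channel compartment medians.
#' @export
cellFeatures <- function(image, nuclei, cells, expansionPx = 1L,
                         channels = channelNames(image)) {
  cyto <- cytoplasmMap(cells, nuclei)
  shp <- shapeFeaturesByLabel(cells@labels)
  if (nrow(shp) == 0L) return(shp)
  shp$area_um2 <- shp$area_px * image@pixelSize^2
  nbr <- neighborFeatures(cells, expansionPx)
  ints <- intensityFeatures(image, nuclei, cyto, channels)
  out <- merge(shp, nbr, by = "cell_id", all.x = TRUE)
  out <- merge(out, ints, by = "cell_id", all.x = TRUE)
  out[order(out$cell_id), , drop = FALSE]
}
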