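# Exclusion-zone migration: occupied-area quantification and the
# migration index M = (Ae/As * 100) - 100.

#' Fraction of a field occupied by cells
#'
#' Binary masks (logical, or numeric with at most the two levels 0 and
#' one positive value, e.g. 0/255) are measured exactly as the fraction
#' of nonzero pixels. Grayscale images are segmented by texture:
#' local-variance map (square window, default 15 px), Otsu threshold on
#' the normalized variance map, morphological closing — phase-contrast
#' cells differ from background in texture, not brightness. The method
#' used is recorded in attribute `method`.
#'
#' @param x Logical/binary mask or single-channel numeric matrix.
#' @param window Local-variance window in px (odd; default 15).
#' @return Occupied fraction in [0, 1], with attribute `method`
#'   ("mask" or "texture").
#' @export
occupiedArea <- function(x, window = 15L) {
  stopIfNot(length(x) > 0L && is.matrix(x), "empty or non-matrix image")
  vals <- unique(as.vector(x))
  if (is.logical(x) || length(vals) <= 2L) {
    out <- mean(x > 0)
    attr(out, "method") <- "mask"
    return(out)
  }
  w <- as.integer(window)
  if (w %% 2L == 0L) w <- w + 1L
  box <- matrix(1 / (w * w), w, w)
  xi <- EBImage::Image(x)
  m1 <- EBImage::filter2(xi, box)
  m2 <- EBImage::filter2(xi^2, box)
  v <- pmax(ebMat(m2) - ebMat(m1)^2, 0)
  vn <- v / max(v)
  thr <- EBImage::otsu(EBImage::Image(vn), range = c(0, 1))
  mask <- EBImage::closing(EBImage::Image(vn > thr),
                           EBImage::makeBrush(5L, "disc"))
  out <- mean(ebMat(mask) > 0)
  attr(out, "method") <- "texture"
  out
}

#' Migration index
#'
#' M = (Ae / As * 100) - 100, the percent growth of the occupied area
#' from seeding (As) to endpoint (Ae). Negative values (area
#' contraction) are permitted and flagged via attribute `contraction`.
#'
#' @param As Occupied area (pixels or fraction) at start; must be > 0.
#' @param Ae Occupied area at endpoint, same units as `As`.
#' @return The migration index in percent, with attribute `contraction`.
#' @export
#' @examples
#' migrationIndex(1000, 1300)   # 30
migrationIndex <- function(As, Ae) {
  stopIfNot(is.finite(As) && As > 0, "As must be > 0")
  m <- (Ae / As * 100) - 100
  attr(m, "contraction") <- m < 0
  m
}

#' Measure a start/end migration image pair
#'
#' @param start,end Masks or grayscale images (see [occupiedArea()]).
#' @param window Local-variance window for grayscale inputs.
#' @return data.frame(As, Ae, M, method).
#' @export
measureMigration <- function(start, end, window = 15L) {
  As <- occupiedArea(start, window)
  Ae <- occupiedArea(end, window)
  data.frame(As = as.numeric(As), Ae = as.numeric(Ae),
             M = as.numeric(migrationIndex(as.numeric(As),
                                           as.numeric(Ae))),
             method = attr(As, "method"), stringsAsFactors = FALSE)
}
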