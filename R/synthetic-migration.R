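# Synthetic exclusion-zone migration mask pairs: cells occupy the field
# outside a central cell-free zone; migration shrinks the zone.

#' Generate a start/end exclusion-zone mask pair
#'
#' The start mask occupies exactly `startFraction` of the field (cells
#' around a central exclusion zone); the end mask occupies
#' `growthFactor x startFraction` (the zone closes as cells migrate
#' inward). Zone radii are chosen as exact quantiles of the
#' (roughness-perturbed) pixel distance distribution, so the occupied
#' areas match their targets to within one pixel and the end/start area
#' ratio equals `growthFactor` within rasterization error (well under
#' 1%).
#'
#' @param startFraction Occupied fraction at seeding, in (0, 1].
#' @param growthFactor Ratio of end to start occupied area (>= 0);
#'   `startFraction * growthFactor` must not exceed 1.
#' @param fieldShape Integer (rows, cols); default c(512, 512).
#' @param seed Integer seed (drives the zone-edge roughness).
#' @param roughness Amplitude (px) of the angular perturbation of the
#'   zone edge; default 3.
#' @return List: `start`, `end` (logical masks), `startFraction`,
#'   `endFraction` (achieved pixel fractions).
#' @export
#' @examples
#' p <- generateMigrationPair(0.4, 1.3, c(128, 128), seed = 2)
#' measureMigration(p$start, p$end)$M   # ~30
generateMigrationPair <- function(startFraction, growthFactor,
                                  fieldShape = c(512L, 512L), seed = 1L,
                                  roughness = 3) {
  stopIfNot(startFraction > 0 && startFraction <= 1,
            "startFraction must lie in (0, 1]")
  stopIfNot(growthFactor >= 0, "growthFactor must be >= 0")
  stopIfNot(startFraction * growthFactor <= 1,
            "infeasible growth: end fraction would exceed 1")
  nr <- fieldShape[1L]; nc <- fieldShape[2L]
  withSeed(mixSeed(seed, "migration"), {
    ctr <- c((nr + 1) / 2, (nc + 1) / 2)
    DY <- matrix(seq_len(nr) - ctr[1L], nr, nc)
    DX <- matrix(seq_len(nc) - ctr[2L], nr, nc, byrow = TRUE)
    d <- sqrt(DY^2 + DX^2)
    if (roughness > 0) {
      phi <- atan2(DY, DX)
      amp <- runif(3L, 0, roughness)
      ph <- runif(3L, 0, 2 * pi)
      d <- d + amp[1L] * sin(3 * phi + ph[1L]) +
        amp[2L] * sin(5 * phi + ph[2L]) +
        amp[3L] * sin(7 * phi + ph[3L])
    }
    occupy <- function(fraction) {
      if (fraction >= 1) return(matrix(TRUE, nr, nc))
      if (fraction <= 0) return(matrix(FALSE, nr, nc))
      d > quantile(d, 1 - fraction, type = 1L)
    }
    start <- occupy(startFraction)
    end <- occupy(startFraction * growthFactor)
    list(start = start, end = end, startFraction = mean(start),
         endFraction = mean(end))
  })
}
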