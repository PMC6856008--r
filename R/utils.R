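# Internal helpers: seeded RNG scoping, label bookkeeping, raster shifts.

# Derive a child seed from a base seed and an arbitrary mix of integer /
# string stream identifiers. Keeps all randomness attributable to one
# user-visible seed without sharing streams between generators.
mixSeed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), function(p) {
    if (is.character(p)) utf8ToInt(paste(p, collapse = "|")) else as.integer(p)
  }), use.names = FALSE)
  h <- as.double(as.integer(seed) %% 2147483647L)
  for (v in parts) {
    h <- (h * 69069 + abs(as.double(v)) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr under set.seed(seed), restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Renumber positive labels 1..K in raster-scan (row-major) order of each
# object's first pixel. Matrices are column-major in R, so the scan key is
# recomputed explicitly.
relabelRasterScan <- function(lab) {
  idx <- which(lab > 0)
  if (length(idx) == 0L) {
    storage.mode(lab) <- "integer"
    return(lab)
  }
  nr <- nrow(lab)
  nc <- ncol(lab)
  l <- lab[idx]
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  key <- (as.double(row) - 1) * nc + as.double(col)
  first <- tapply(key, l, min)
  ord <- order(first)
  map <- integer(max(l))
  map[as.integer(names(first))[ord]] <- seq_along(ord)
  out <- matrix(0L, nr, nc)
  out[idx] <- map[l]
  out
}

# Strip the EBImage Image class, returning a plain matrix.
ebMat <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  class(m) <- NULL
  m
}

# Shift a matrix by (dr, dc), padding with `fill`.
shiftMat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr)
  cs <- seq_len(nc)
  rdst <- rs[rs + dr >= 1 & rs + dr <= nr]
  cdst <- cs[cs + dc >= 1 & cs + dc <= nc]
  out[rdst + dr, cdst + dc] <- m[rdst, cdst, drop = FALSE]
  out
}

# The eight (dr, dc) offsets of the 8-connected neighbourhood.
neighborOffsets8 <- function() {
  cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
        dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
}

# Normalize mature miR names for matching: case-fold and strip the species
# "hsa-" prefix. Family expansion is never implicit (see readTargetTable).
normalizeMir <- function(x) {
  sub("^hsa-", "", tolower(trimws(x)))
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
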