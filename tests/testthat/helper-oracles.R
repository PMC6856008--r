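# Independent brute-force oracles used to freeze expected values. These
# deliberately avoid the code paths of the package implementation:
# moments by explicit double loops, convex-hull membership by exhaustive
# line separation, consensus by direct enumeration, hypergeometric tails
# by direct combinatorial sums.

# --- shape oracle -----------------------------------------------------

oracleShape <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pts <- NULL
  for (r in seq_len(nr)) for (c in seq_len(nc))
    if (mask[r, c] > 0) pts <- rbind(pts, c(r, c))
  n <- nrow(pts)
  mr <- 0; mc <- 0
  for (i in seq_len(n)) { mr <- mr + pts[i, 1]; mc <- mc + pts[i, 2] }
  mr <- mr / n; mc <- mc / n
  m20 <- 0; m02 <- 0; m11 <- 0
  for (i in seq_len(n)) {
    dr <- pts[i, 1] - mr; dc <- pts[i, 2] - mc
    m20 <- m20 + dr * dr; m02 <- m02 + dc * dc; m11 <- m11 + dr * dc
  }
  m20 <- m20 / n + 1 / 12; m02 <- m02 / n + 1 / 12; m11 <- m11 / n
  tr <- m20 + m02
  disc <- sqrt((m20 - m02)^2 + 4 * m11^2)
  l1 <- (tr + disc) / 2; l2 <- (tr - disc) / 2
  ecc <- sqrt(max(0, 1 - l2 / l1))
  # hull pixel count by exhaustive line-separation membership test
  P <- cbind(pts[, 2], pts[, 1])                 # (x, y)
  inHull <- function(q) {
    if (any(P[, 1] == q[1] & P[, 2] == q[2])) return(TRUE)
    m <- nrow(P)
    if (m == 1) return(FALSE)
    for (i in seq_len(m - 1)) for (j in seq.int(i + 1, m)) {
      nx <- -(P[j, 2] - P[i, 2]); ny <- P[j, 1] - P[i, 1]
      sS <- (P[, 1] - P[i, 1]) * nx + (P[, 2] - P[i, 2]) * ny
      sq <- (q[1] - P[i, 1]) * nx + (q[2] - P[i, 2]) * ny
      if (all(sS <= 1e-9) && sq > 1e-9) return(FALSE)
      if (all(sS >= -1e-9) && sq < -1e-9) return(FALSE)
    }
    TRUE
  }
  cnt <- 0L
  for (x in seq(min(P[, 1]), max(P[, 1])))
    for (y in seq(min(P[, 2]), max(P[, 2])))
      if (inHull(c(x, y))) cnt <- cnt + 1L
  c(area = n, eccentricity = ecc, solidity = n / cnt)
}

# Random connected mask (4-connected growth) within maxDim x maxDim.
randomConnectedMask <- function(npix, maxDim = 12L) {
  m <- matrix(0L, maxDim, maxDim)
  m[sample.int(maxDim, 1L), sample.int(maxDim, 1L)] <- 1L
  placed <- 1L
  dirs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  attempts <- 0L
  while (placed < npix && attempts < 10000L) {
    attempts <- attempts + 1L
    occ <- which(m == 1L, arr.ind = TRUE)
    p <- occ[sample.int(nrow(occ), 1L), ]
    q <- p + dirs[sample.int(4L, 1L), ]
    if (all(q >= 1L) && all(q <= maxDim) && m[q[1L], q[2L]] == 0L) {
      m[q[1L], q[2L]] <- 1L
      placed <- placed + 1L
    }
  }
  m
}

# --- consensus oracle -------------------------------------------------

bruteConsensus <- function(members, edges) {
  norm <- function(x) sub("^hsa-", "", tolower(trimws(x)))
  n <- length(members)
  thr <- max(n - 2L, 4L)
  key <- norm(members)
  genes <- unique(edges$gene)
  out <- setNames(integer(0), character(0))
  for (g in genes) {
    supp <- 0L
    for (m in key)
      if (any(norm(edges$mir) == m & edges$gene == g)) supp <- supp + 1L
    if (supp >= thr) out[g] <- supp
  }
  out[order(names(out))]
}

# --- hypergeometric tail oracle ---------------------------------------

# P(X >= k), X ~ Hyper(N, K, n), by direct combinatorial summation.
hyperTailEnum <- function(k, K, n, N) {
  lo <- max(0L, k)
  hi <- min(K, n)
  if (lo > hi) return(if (k <= max(0L, n - (N - K))) 1 else 0)
  s <- 0
  for (i in seq.int(lo, hi))
    s <- s + choose(K, i) * choose(N - K, n - i)
  s / choose(N, n)
}

# Direct Benjamini-Hochberg.
bhDirect <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# --- adjusted Rand index ----------------------------------------------

ariIndex <- function(x, y) {
  tab <- table(x, y)
  a <- rowSums(tab); b <- colSums(tab); n <- sum(tab)
  sij <- sum(choose(tab, 2)); sa <- sum(choose(a, 2))
  sb <- sum(choose(b, 2)); sn <- choose(n, 2)
  expected <- sa * sb / sn
  (sij - expected) / ((sa + sb) / 2 - expected)
}

# --- small image fixtures ---------------------------------------------

# FieldImage from a list of matrices, filling absent canonical channels
# with a constant background.
makeField <- function(..., shape = NULL, background = 0) {
  ch <- list(...)
  if (is.null(shape)) shape <- dim(ch[[1L]])
  full <- setNames(lapply(fieldChannels(), function(nm)
    if (nm %in% names(ch)) ch[[nm]] else matrix(background, shape[1L],
                                                shape[2L])),
    fieldChannels())
  FieldImage(full)
}

# Disc mask helper.
discMask <- function(shape, center, radius) {
  outer(seq_len(shape[1L]), seq_len(shape[2L]), function(r, c)
    (r - center[1L])^2 + (c - center[2L])^2 <= radius^2)
}
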