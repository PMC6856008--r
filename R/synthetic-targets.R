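# Synthetic miR -> predicted-target tables with planted consensus and
# shared-decoy structure.

#' Generate a synthetic target table with planted structure
#'
#' Builds a [TargetTable-class] from a [PlantedTargetSpec-class]:
#'
#' * every planted consensus gene of a group receives edges from a random
#'   subset of the group's members of size drawn between the consensus
#'   threshold max(N - 2, 4) and N, so it passes [consensusTargets()] by
#'   construction;
#' * every planted shared gene of a pair (A, B) receives such a supporter
#'   set from *both* groups, so it reaches consensus in both and is
#'   removed from both by [excludeShared()];
#' * every remaining (miR, gene) pair is added i.i.d. with probability
#'   `backgroundEdgeProb`.
#'
#' Background edges can in principle push an unplanted gene over a
#' group's threshold; the analytic union bound on the probability of at
#' least one such false consensus gene is attached as attribute
#' `consensusFalsePositiveBound` and reported in a message.
#'
#' @param spec A [PlantedTargetSpec-class].
#' @return A [TargetTable-class] (attribute `consensusFalsePositiveBound`
#'   as above).
#' @export
#' @examples
#' sp <- plantedTargetSpec(list(A = paste0("miR-", 1:6)),
#'                         universeSize = 50, nConsensus = c(A = 3))
#' tab <- generateTargetTable(sp)
#' consensusTargets("A", paste0("miR-", 1:6), tab)
generateTargetTable <- function(spec) {
  validObject(spec)
  uni <- geneUniverse(spec@universeSize)
  thr <- vapply(spec@groups, function(m) max(length(m) - 2L, 4L),
                integer(1L))
  for (g in names(spec@plantedConsensus))
    stopIfNot(thr[[g]] <= length(spec@groups[[g]]),
              paste0("group ", g, " too small: threshold exceeds size"))
  withSeed(mixSeed(spec@seed, "targets"), {
    edges <- list()
    plantSupporters <- function(group, gene) {
      m <- spec@groups[[group]]
      ks <- seq.int(thr[[group]], length(m))
      k <- if (length(ks) == 1L) ks else sample(ks, 1L)
      data.frame(mir = sample(m, k), gene = gene,
                 stringsAsFactors = FALSE)
    }
    for (g in names(spec@plantedConsensus))
      for (gene in spec@plantedConsensus[[g]])
        edges[[length(edges) + 1L]] <- plantSupporters(g, gene)
    for (nm in names(spec@plantedShared)) {
      pair <- strsplit(nm, "|", fixed = TRUE)[[1L]]
      for (gene in spec@plantedShared[[nm]]) {
        edges[[length(edges) + 1L]] <- plantSupporters(pair[1L], gene)
        edges[[length(edges) + 1L]] <- plantSupporters(pair[2L], gene)
      }
    }
    planted <- do.call(rbind, c(edges, list(
      data.frame(mir = character(0), gene = character(0)))))
    p <- spec@backgroundEdgeProb
    if (p > 0) {
      mirs <- unique(unlist(spec@groups, use.names = FALSE))
      full <- expand.grid(mir = mirs, gene = uni,
                          KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
      pk <- paste(planted$mir, planted$gene, sep = "\r")
      cand <- full[!(paste(full$mir, full$gene, sep = "\r") %in% pk), ,
                   drop = FALSE]
      bg <- cand[runif(nrow(cand)) < p, , drop = FALSE]
      planted <- rbind(planted, bg)
    }
    stopIfNot(nrow(planted) > 0L,
              "spec yields no edges (no planted genes, zero background)")
    tab <- TargetTable(planted, source = "synthetic")
    # union bound on a background-born false consensus gene per group
    nPlanted <- length(unlist(spec@plantedConsensus)) +
      length(unlist(spec@plantedShared))
    bound <- sum(vapply(names(spec@groups), function(g) {
      n <- length(spec@groups[[g]])
      (spec@universeSize - nPlanted) *
        stats::pbinom(thr[[g]] - 1L, n, p, lower.tail = FALSE)
    }, numeric(1L)))
    attr(tab, "consensusFalsePositiveBound") <- bound
    message(sprintf(
      "background false-consensus probability bound: %.3g", bound))
    tab
  })
}
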