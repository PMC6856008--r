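# Pathway over-representation: one-sided hypergeometric upper tail, the
# conservative EASE variant (overlap reduced by one), and
# Benjamini-Hochberg adjustment across the tested pathways.

#' Hypergeometric upper-tail enrichment p-value
#'
#' P(X >= overlap) for X ~ Hypergeometric(universe, pathway, query).
#'
#' @param overlap Genes in both the query and the pathway.
#' @param pathwaySize Pathway genes inside the universe.
#' @param querySize Query genes inside the universe.
#' @param universeSize Total genes in the universe.
#' @param ease Use the EASE convention (overlap reduced by 1, floor 0),
#'   the conservative "modified Fisher exact" score; default FALSE.
#' @return p-value in [0, 1].
#' @export
#' @examples
#' hyperP(4, 5, 5, 20)            # 76 / 15504
#' hyperP(4, 5, 5, 20, ease = TRUE)   # 1126 / 15504
hyperP <- function(overlap, pathwaySize, querySize, universeSize,
                   ease = FALSE) {
  k <- if (ease) pmax(overlap - 1, 0) else overlap
  phyper(k - 1, pathwaySize, universeSize - pathwaySize, querySize,
         lower.tail = FALSE)
}

#' Pathway enrichment of a filtered target set
#'
#' Tests every pathway for over-representation of `genes` in `universe`
#' by the one-sided hypergeometric upper tail, also reporting the EASE
#' variant and Benjamini-Hochberg adjusted p-values (adjustment over the
#' plain p-values, across all tested pathways). Pathways are intersected
#' with the universe before testing; results are sorted by adjusted p,
#' ties by pathway name.
#'
#' @param genes Query gene set (must lie inside the universe).
#' @param pathways Named list of gene sets (e.g. from [readGmt()]).
#' @param universe Background gene universe.
#' @return data.frame: pathway, universeSize, pathwaySize, querySize,
#'   overlap, pValue, easeP, adjP, genes (overlap, "/"-separated).
#' @export
enrichPathways <- function(genes, pathways, universe) {
  stopIfNot(length(universe) > 0L, "empty universe")
  stopIfNot(length(pathways) > 0L, "empty pathway collection")
  universe <- unique(universe)
  genes <- unique(genes)
  out <- setdiff(genes, universe)
  stopIfNot(length(out) == 0L,
            paste0("query genes outside the universe: ",
                   paste(head(out, 5L), collapse = ", ")))
  n <- length(universe)
  q <- length(genes)
  rows <- lapply(names(pathways), function(nm) {
    pw <- intersect(unique(pathways[[nm]]), universe)
    ov <- intersect(genes, pw)
    data.frame(pathway = nm, universeSize = n, pathwaySize = length(pw),
               querySize = q, overlap = length(ov),
               pValue = hyperP(length(ov), length(pw), q, n),
               easeP = hyperP(length(ov), length(pw), q, n, ease = TRUE),
               genes = paste(sort(ov), collapse = "/"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$adjP <- p.adjust(res$pValue, method = "BH")
  res <- res[order(res$adjP, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  res[c("pathway", "universeSize", "pathwaySize", "querySize", "overlap",
        "pValue", "easeP", "adjP", "genes")]
}

#' Assign genes to the pathways that contain them
#'
#' @param genes Gene set.
#' @param pathways Named list of gene sets.
#' @return data.frame(gene, pathway), one row per membership (genes in
#'   several pathways carry several rows; unassigned genes none).
#' @export
assignPathways <- function(genes, pathways) {
  rows <- lapply(names(pathways), function(nm) {
    g <- intersect(genes, pathways[[nm]])
    if (length(g)) data.frame(gene = g, pathway = nm,
                              stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(data.frame(gene = character(0),
                                                pathway = character(0)))))
  rownames(out) <- NULL
  out
}
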