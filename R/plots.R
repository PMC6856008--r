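# Visualisation helpers.

#' Clustered heatmap of a profile matrix
#'
#' Draws the PMC profile matrix with the package's clustering (rows
#' ordered by the dendrogram). Requires the suggested package pheatmap.
#'
#' @param clustering A [MirClustering-class].
#' @param filename Optional file to save to (passed to pheatmap).
#' @param ... Further arguments to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plotProfileHeatmap <- function(clustering, filename = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plotProfileHeatmap requires the 'pheatmap' package",
         call. = FALSE)
  ann <- data.frame(group = clustering@memberships$group,
                    row.names = clustering@memberships$mir)
  p <- pheatmap::pheatmap(
    clustering@pmc,
    cluster_rows = clustering@hclust,
    cluster_cols = FALSE, annotation_row = ann, filename = filename, ...)
  invisible(p)
}
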