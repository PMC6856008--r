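# Regulatory-network assembly and export: miR -> gene (predicted
# targeting) and gene -> pathway (membership) edges, with per-gene
# supporter counts, exported as SIF and GraphML.

#' Build the miR-target-pathway regulatory network of one group
#'
#' Nodes are the group's miRs, its filtered consensus targets and the
#' pathways containing them; edges are miR -> gene predicted-targeting
#' edges (restricted to group members and filtered genes) and
#' gene -> pathway memberships. Genes assigned to several pathways carry
#' all their membership edges; filtered genes belonging to no supplied
#' pathway are dropped with a warning (the network is the
#' pathway-restricted view). Gene nodes carry their consensus supporter
#' count as vertex attribute `supporterCount`.
#'
#' @param result A [ConsensusResult-class] (post-exclusion).
#' @param table The [TargetTable-class] the consensus was computed from.
#' @param pathways Named list of pathway gene sets.
#' @return An `igraph` graph with vertex attributes `type` ("mir",
#'   "gene", "pathway") and `supporterCount` (genes only, NA elsewhere),
#'   and edge attribute `interaction` ("targets" / "member_of"). Empty
#'   filtered set yields an empty graph with a warning.
#' @export
buildNetwork <- function(result, table, pathways) {
  genes <- result@filtered
  if (length(genes) == 0L) {
    warning("empty filtered target set: returning an empty network",
            call. = FALSE)
    return(igraph::make_empty_graph(directed = TRUE))
  }
  memb <- assignPathways(genes, pathways)
  unassigned <- setdiff(genes, memb$gene)
  if (length(unassigned))
    warning(length(unassigned), " filtered gene(s) in no supplied ",
            "pathway dropped from the network", call. = FALSE)
  genes <- intersect(genes, memb$gene)
  if (length(genes) == 0L) {
    warning("no filtered target maps to a supplied pathway",
            call. = FALSE)
    return(igraph::make_empty_graph(directed = TRUE))
  }
  edges <- table@edges
  key <- normalizeMir(result@members)
  mirEdges <- edges[normalizeMir(edges$mir) %in% key &
                      edges$gene %in% genes, , drop = FALSE]
  memb <- memb[memb$gene %in% genes, , drop = FALSE]
  edgeDf <- rbind(
    data.frame(from = mirEdges$mir, to = mirEdges$gene,
               interaction = "targets", stringsAsFactors = FALSE),
    data.frame(from = memb$gene, to = memb$pathway,
               interaction = "member_of", stringsAsFactors = FALSE))
  vertices <- data.frame(
    name = c(unique(mirEdges$mir), genes, unique(memb$pathway)),
    type = c(rep("mir", length(unique(mirEdges$mir))),
             rep("gene", length(genes)),
             rep("pathway", length(unique(memb$pathway)))),
    stringsAsFactors = FALSE)
  vertices$supporterCount <- ifelse(
    vertices$type == "gene",
    as.integer(result@supporters[vertices$name]), NA_integer_)
  igraph::graph_from_data_frame(edgeDf, directed = TRUE,
                                vertices = vertices)
}

#' Export a regulatory network in SIF format
#'
#' One line per edge: `source <TAB> interaction <TAB> target`.
#'
#' @param graph igraph network from [buildNetwork()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeNetworkSif <- function(graph, path) {
  if (igraph::ecount(graph) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  el <- igraph::as_edgelist(graph)
  inter <- igraph::edge_attr(graph, "interaction")
  if (is.null(inter)) inter <- rep("interacts", nrow(el))
  writeLines(paste(el[, 1L], inter, el[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Export / import a regulatory network as GraphML
#'
#' @param graph igraph network.
#' @param path GraphML file.
#' @return `path` invisibly (write); igraph graph (read).
#' @export
writeNetworkGraphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname writeNetworkGraphml
#' @export
readNetworkGraphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
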