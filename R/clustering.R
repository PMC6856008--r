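# Hierarchical clustering of miR profiles and survival/EMT phenotype
# classification of the resulting groups.

#' Hierarchical clustering of miR phenotypic profiles
#'
#' Columns are z-scored across miRs (zero-variance columns dropped with a
#' warning), pairwise distance is 1 - uncentered Pearson correlation
#' between rows (the Cluster3 default similarity; configurable to centered
#' Pearson or Euclidean), the agglomeration is average linkage, and
#' the dendrogram is cut into `kMain` main groups, labelled G1..Gk in
#' dendrogram leaf order. Optionally, any main group whose members
#' disagree in the sign of their "count nuclei" percent change beyond the
#' tolerance band (|PMC| > `splitTol`) is split into a positive ("a") and
#' a negative ("b") survival subgroup; in-band members go by their raw
#' sign (ties to "a").
#'
#' @param pm A [ProfileMatrix-class] (its control row is dropped before
#'   clustering) or a plain numeric matrix (rows = miRs).
#' @param kMain Number of main groups to cut (required; must not exceed
#'   the number of rows).
#' @param metric "uncentered" (1 - uncentered correlation, i.e. cosine,
#'   default: it keeps the sign of a profile informative, which centred
#'   Pearson discards for uniformly up/down profiles after z-scoring),
#'   "correlation" (1 - Pearson) or "euclidean".
#' @param linkage Agglomeration method for [stats::hclust()]; default
#'   "average".
#' @param survivalSplit Apply the count-nuclei sign split (default TRUE).
#' @param splitTol Tolerance band, in percent points (default 10).
#' @return A [MirClustering-class].
#' @export
clusterMirs <- function(pm, kMain,
                        metric = c("uncentered", "correlation",
                                   "euclidean"),
                        linkage = "average", survivalSplit = TRUE,
                        splitTol = 10) {
  metric <- match.arg(metric)
  mat <- if (is(pm, "ProfileMatrix")) {
    v <- pm@values
    v[setdiff(rownames(v), pm@controlLabel), , drop = FALSE]
  } else as.matrix(pm)
  stopIfNot(nrow(mat) >= 2L, "need at least 2 miR rows to cluster")
  stopIfNot(!anyNA(mat),
            "missing values present; rows with missing values are not accepted")
  stopIfNot(kMain >= 1L && kMain <= nrow(mat),
            "kMain must lie between 1 and the number of rows")
  sds <- apply(mat, 2L, sd)
  dropped <- colnames(mat)[sds == 0]
  if (length(dropped))
    warning("zero-variance column(s) dropped before clustering: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  z <- scale(mat[, sds > 0, drop = FALSE])
  stopIfNot(ncol(z) >= 2L, "need >= 2 informative parameters")
  d <- switch(metric,
    correlation = as.dist(1 - cor(t(z))),
    uncentered = {
      nrm <- sqrt(rowSums(z^2))
      as.dist(1 - (z %*% t(z)) / outer(nrm, nrm))
    },
    euclidean = stats::dist(z))
  hc <- hclust(d, method = linkage)
  cut <- cutree(hc, k = kMain)
  # relabel main groups G1..Gk in dendrogram leaf order
  leafOrder <- rownames(mat)[hc$order]
  firstSeen <- unique(cut[leafOrder])
  mainId <- setNames(paste0("G", seq_along(firstSeen)), firstSeen)
  main <- mainId[as.character(cut)]
  group <- main
  if (survivalSplit && "count nuclei" %in% colnames(mat)) {
    cn <- mat[, "count nuclei"]
    for (g in unique(main)) {
      sel <- main == g
      strong <- cn[sel][abs(cn[sel]) > splitTol]
      if (length(unique(sign(strong))) == 2L) {
        group[sel] <- paste0(g, ifelse(cn[sel] >= 0, "a", "b"))
      }
    }
  }
  memberships <- data.frame(mir = rownames(mat), mainGroup = unname(main),
                            group = unname(group),
                            stringsAsFactors = FALSE)
  new("MirClustering", memberships = memberships, hclust = hc,
      pmc = mat, kMain = as.integer(kMain), droppedColumns = dropped)
}

#' Mean PMC profiles of the clustered groups
#'
#' @param clustering A [MirClustering-class].
#' @param params Parameters to average; default all clustered columns.
#' @return Matrix groups x parameters of member-mean percent changes.
#' @export
groupMeanProfiles <- function(clustering,
                              params = colnames(clustering@pmc)) {
  m <- clustering@memberships
  groups <- unique(m$group)
  out <- t(vapply(groups, function(g)
    colMeans(clustering@pmc[m$mir[m$group == g], params, drop = FALSE]),
    numeric(length(params))))
  rownames(out) <- groups
  out
}

#' Classify a miR group's survival/EMT phenotype
#'
#' The survival direction is the sign of the group-mean "count nuclei"
#' percent change where its magnitude exceeds `tau` (otherwise the group
#' is unclassified). The EMT direction is the sign of the mean of the
#' "cells eccentricity" and "Nuclei Median Intensity Snail/Slug" percent
#' changes where that mean's magnitude exceeds `tau`. Because cell
#' density itself confounds EMT readouts (sparse wells look mesenchymal,
#' dense wells epithelial), the EMT label is attached only when the EMT
#' direction is *opposite* the density expectation — anti-survival groups
#' are expected to drift pro-EMT and pro-survival groups anti-EMT; a
#' group matching that expectation is labelled by survival alone.
#'
#' @param meanProfile Named numeric vector containing the four
#'   classification parameters (see [clusteringParameters()]).
#' @param tau Threshold in percent points (default 10).
#' @return One of "pro-survival/EMT", "anti-survival/EMT",
#'   "pro-survival", "anti-survival", "unclassified".
#' @export
#' @examples
#' classifyGroup(c(`count nuclei` = -40, `cells eccentricity` = -20,
#'                 `Nuclei Median Intensity Snail/Slug` = -30,
#'                 `Cytoplasm Median Intensity Snail/Slug` = -10))
classifyGroup <- function(meanProfile, tau = 10) {
  need <- clusteringParameters()
  missing <- setdiff(need, names(meanProfile))
  stopIfNot(length(missing) == 0L,
            paste0("missing classification parameter(s): ",
                   paste(missing, collapse = ", ")))
  s <- meanProfile[["count nuclei"]]
  survival <- if (abs(s) > tau) sign(s) else 0
  if (survival == 0) return("unclassified")
  e <- mean(c(meanProfile[["cells eccentricity"]],
              meanProfile[["Nuclei Median Intensity Snail/Slug"]]))
  emt <- if (abs(e) > tau) sign(e) else 0
  densityExpectation <- -survival     # sparse -> pro-EMT, dense -> anti
  surLab <- if (survival > 0) "pro-survival" else "anti-survival"
  if (emt != 0 && emt != densityExpectation)
    paste0(surLab, "/EMT") else surLab
}

#' Classify all groups of a clustering
#'
#' @param clustering A [MirClustering-class] whose matrix contains the
#'   four classification parameters.
#' @param tau Threshold in percent points (default 10).
#' @return Named list of [MiRGroup-class] objects.
#' @export
classifyGroups <- function(clustering, tau = 10) {
  mp <- groupMeanProfiles(clustering)
  m <- clustering@memberships
  out <- lapply(rownames(mp), function(g) {
    prof <- setNames(as.numeric(mp[g, ]), colnames(mp))
    new("MiRGroup", groupId = g, members = m$mir[m$group == g],
        meanProfile = prof,
        phenotype = classifyGroup(prof, tau = tau))
  })
  setNames(out, rownames(mp))
}

#' Export a clustering dendrogram as a Newick string
#'
#' @param clustering A [MirClustering-class] (or plain hclust).
#' @param path Optional file to write to.
#' @return The Newick string, invisibly if written to file.
#' @export
dendrogramNewick <- function(clustering, path = NULL) {
  hc <- if (is(clustering, "MirClustering")) clustering@hclust
        else clustering
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
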