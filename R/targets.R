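# Group-consensus target identification: reading predicted-target tables,
# the max(N - 2, 4) consensus rule, and opposite-group exclusion.

#' Read a miR -> predicted-target table
#'
#' Two dialects: `simple_tsv` is a headered two-column TSV (mir, gene);
#' `targetscan_predicted_targets` reads the miR-family and gene-symbol
#' columns of a TargetScan "Predicted Targets" flat file and expands each
#' family row to its member miRs via an explicit family-membership table
#' (columns family, mir) — families absent from the membership table are
#' dropped with a warning, never guessed. Duplicate edges are collapsed;
#' rows with an empty miR or gene field are rejected and counted in the
#' malformed-row report (attribute `malformedRows` and a message).
#'
#' @param path Input file.
#' @param dialect "simple_tsv" or "targetscan_predicted_targets".
#' @param familyTable data.frame(family, mir); required for the
#'   TargetScan dialect.
#' @return A [TargetTable-class].
#' @export
readTargetTable <- function(path,
                            dialect = c("simple_tsv",
                                        "targetscan_predicted_targets"),
                            familyTable = NULL) {
  dialect <- match.arg(dialect)
  stopIfNot(file.exists(path), paste0("file not found: ", path))
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopIfNot(nrow(raw) > 0L, "target table is empty")
  if (dialect == "simple_tsv") {
    stopIfNot(all(c("mir", "gene") %in% names(raw)),
              "simple_tsv requires header columns 'mir' and 'gene'")
    edges <- data.frame(mir = trimws(as.character(raw$mir)),
                        gene = trimws(as.character(raw$gene)),
                        stringsAsFactors = FALSE)
  } else {
    stopIfNot(!is.null(familyTable) &&
                all(c("family", "mir") %in% names(familyTable)),
              "TargetScan dialect requires a familyTable(family, mir)")
    famCol <- grep("^mir[ _]?family$", names(raw), ignore.case = TRUE,
                   value = TRUE)
    geneCol <- grep("^gene[ _]?symbol$", names(raw), ignore.case = TRUE,
                    value = TRUE)
    stopIfNot(length(famCol) == 1L && length(geneCol) == 1L,
              "TargetScan file must carry miR family and Gene Symbol columns")
    fam <- trimws(as.character(raw[[famCol]]))
    gene <- trimws(as.character(raw[[geneCol]]))
    known <- fam %in% familyTable$family
    if (!all(known))
      warning(sum(!known), " row(s) with families absent from the ",
              "membership table dropped", call. = FALSE)
    idx <- which(known & nzchar(gene))
    expanded <- lapply(idx, function(i) {
      data.frame(mir = familyTable$mir[familyTable$family == fam[i]],
                 gene = gene[i], stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, c(expanded,
                              list(data.frame(mir = character(0),
                                              gene = character(0)))))
  }
  malformed <- !nzchar(edges$mir) | !nzchar(edges$gene) |
    is.na(edges$mir) | is.na(edges$gene)
  if (any(malformed))
    message(sum(malformed), " malformed row(s) rejected")
  edges <- edges[!malformed, , drop = FALSE]
  stopIfNot(nrow(edges) > 0L, "no valid rows in target table")
  tab <- TargetTable(edges, source = paste0(dialect, ":", basename(path)))
  attr(tab, "malformedRows") <- sum(malformed)
  tab
}

#' Write a TargetTable as simple_tsv
#' @param table A [TargetTable-class].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
writeTargetTable <- function(table, path) {
  write.table(table@edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Consensus targets of one miR group
#'
#' A gene is a consensus target of a group of N miRs iff at least
#' max(N - 2, 4) distinct group members are predicted to target it. miR
#' matching is case-insensitive on the canonical "miR-" form with the
#' "hsa-" prefix stripped. Members absent from the table are reported
#' (slot `absentMembers`) but still count towards N.
#'
#' @param groupId Group label.
#' @param members Character vector of the group's miR labels.
#' @param table A [TargetTable-class].
#' @return A [ConsensusResult-class] (pre-exclusion: `filtered` equals
#'   the consensus set).
#' @export
consensusTargets <- function(groupId, members, table) {
  n <- length(members)
  stopIfNot(n >= 1L, "group must have at least one member")
  thr <- max(n - 2L, 4L)
  key <- normalizeMir(members)
  stopIfNot(!anyDuplicated(key), "duplicate members after normalization")
  edges <- table@edges
  emir <- normalizeMir(edges$mir)
  present <- key %in% emir
  hit <- edges[emir %in% key, , drop = FALSE]
  supp <- setNames(integer(0), character(0))
  if (nrow(hit)) {
    u <- unique(data.frame(mir = normalizeMir(hit$mir), gene = hit$gene,
                           stringsAsFactors = FALSE))
    counts <- tapply(u$mir, u$gene, length)
    supp <- setNames(as.integer(counts), names(counts))
    supp <- supp[supp >= thr]
    supp <- supp[order(names(supp))]
  }
  new("ConsensusResult", groupId = groupId, members = members,
      thresholdUsed = as.integer(thr), supporters = supp,
      filtered = names(supp),
      absentMembers = members[!present])
}

#' Exclude consensus targets shared between opposite-phenotype groups
#'
#' For each pair (A, B) of groups with opposite phenotypic effects, every
#' gene present in both groups' consensus sets is moved to the excluded
#' set of *both* results; the filtered set becomes consensus minus
#' excluded.
#'
#' @param results Named list of [ConsensusResult-class] objects.
#' @param oppositePairs List of length-2 character vectors (group id
#'   pairs), e.g. `list(c("G1a", "G2"), c("G1b", "G3"))`.
#' @return The updated named list of [ConsensusResult-class] objects.
#' @export
excludeShared <- function(results, oppositePairs) {
  for (pair in oppositePairs) {
    stopIfNot(length(pair) == 2L && all(pair %in% names(results)),
              "each pair must name two known groups")
    stopIfNot(pair[1L] != pair[2L], "a group cannot be paired with itself")
    a <- results[[pair[1L]]]
    b <- results[[pair[2L]]]
    shared <- intersect(names(a@supporters), names(b@supporters))
    if (length(shared)) {
      addEx <- function(res, other) {
        newly <- setdiff(shared, res@excluded$gene)
        res@excluded <- rbind(res@excluded,
                              data.frame(gene = newly, sharedWith = other,
                                         stringsAsFactors = FALSE))
        res@filtered <- setdiff(names(res@supporters), res@excluded$gene)
        res
      }
      results[[pair[1L]]] <- addEx(a, pair[2L])
      results[[pair[2L]]] <- addEx(b, pair[1L])
    }
  }
  results
}

#' Write a ConsensusResult as TSV
#'
#' One row per consensus gene: gene, supporter count, status
#' (filtered/excluded) and the opposing group that caused an exclusion.
#'
#' @param result A [ConsensusResult-class].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
writeConsensusResult <- function(result, path) {
  genes <- names(result@supporters)
  status <- ifelse(genes %in% result@filtered, "filtered", "excluded")
  sharedWith <- result@excluded$sharedWith[
    match(genes, result@excluded$gene)]
  df <- data.frame(group = result@groupId, gene = genes,
                   supporters = as.integer(result@supporters),
                   threshold = result@thresholdUsed, status = status,
                   sharedWith = ifelse(is.na(sharedWith), "", sharedWith),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
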