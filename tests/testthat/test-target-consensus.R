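writeTsv <- function(df) {
  p <- tempfile(fileext = ".tsv")
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

test_that("simple_tsv parsing collapses duplicates and reports bad rows", {
  p <- writeTsv(data.frame(mir = c("miR-1", "miR-2", "miR-2", "miR-4",
                                   "miR-3", ""),
                           gene = c("A", "B", "B", "C", "", "D")))
  expect_message(tab <- readTargetTable(p), "2 malformed")
  expect_equal(nrow(targetEdges(tab)), 3L)
  expect_equal(attr(tab, "malformedRows"), 2L)
  expect_error(readTargetTable(writeTsv(data.frame(x = 1, y = 2))),
               "mir")
  expect_error(readTargetTable(tempfile(), "simple_tsv"), "not found")
})

test_that("the TargetScan dialect expands families via the membership table", {
  p <- writeTsv(data.frame(`miR family` = c("miR-29-3p", "miR-200bc"),
                           `Gene Symbol` = c("AKT2", "ZEB1"),
                           check.names = FALSE))
  fam <- data.frame(family = c("miR-29-3p", "miR-29-3p", "miR-200bc"),
                    mir = c("hsa-miR-29a-3p", "hsa-miR-29b-3p",
                            "hsa-miR-200b-3p"))
  tab <- readTargetTable(p, "targetscan_predicted_targets",
                         familyTable = fam)
  e <- targetEdges(tab)
  expect_equal(nrow(e), 3L)
  expect_setequal(e$gene[e$mir %in% c("hsa-miR-29a-3p",
                                      "hsa-miR-29b-3p")], "AKT2")
  # unknown family rows are dropped with a warning, not guessed
  p2 <- writeTsv(data.frame(`miR family` = c("miR-29-3p", "miR-999"),
                            `Gene Symbol` = c("AKT2", "XYZ"),
                            check.names = FALSE))
  expect_warning(tab2 <- readTargetTable(
    p2, "targetscan_predicted_targets", familyTable = fam), "absent")
  expect_equal(nrow(targetEdges(tab2)), 2L)
})

test_that("synthetic tables round-trip losslessly through simple_tsv", {
  sp <- plantedTargetSpec(list(A = paste0("miR-", 1:6)),
                          universeSize = 60, nConsensus = c(A = 4),
                          backgroundEdgeProb = 0.02, seed = 9)
  tab <- suppressMessages(generateTargetTable(sp))
  p <- tempfile(fileext = ".tsv")
  writeTargetTable(tab, p)
  back <- readTargetTable(p)
  o <- function(e) e[order(e$mir, e$gene), ]
  expect_equal(o(targetEdges(back)), o(targetEdges(tab)),
               ignore_attr = TRUE)
})

test_that("the consensus threshold rule max(N - 2, 4) is applied", {
  mkTab <- function(hits, gene = "G1") {
    TargetTable(data.frame(mir = paste0("miR-", hits), gene = gene))
  }
  # N = 7: 5 supporters in, 4 out
  members7 <- paste0("miR-", 1:7)
  r5 <- consensusTargets("g", members7, mkTab(1:5))
  expect_equal(r5@thresholdUsed, 5L)
  expect_equal(unname(consensusGenes(r5)["G1"]), 5L)
  r4 <- consensusTargets("g", members7, mkTab(1:4))
  expect_length(consensusGenes(r4), 0L)
  # N = 4: all members required
  members4 <- paste0("miR-", 1:4)
  expect_length(consensusGenes(consensusTargets("g", members4,
                                                mkTab(1:4))), 1L)
  expect_length(consensusGenes(consensusTargets("g", members4,
                                                mkTab(1:3))), 0L)
  # N = 5, gene hit by 3 of 5: threshold max(3, 4) = 4 excludes it
  expect_length(consensusGenes(consensusTargets("g", paste0("miR-", 1:5),
                                                mkTab(1:3))), 0L)
  # matching is case-insensitive and hsa-prefix tolerant
  tab <- TargetTable(data.frame(mir = c("hsa-miR-10a", "MIR-10B",
                                        "miR-10c", "miR-10d"),
                                gene = "TP53"))
  r <- consensusTargets("g", c("miR-10a", "miR-10b", "hsa-miR-10c",
                               "miR-10d"), tab)
  expect_equal(unname(consensusGenes(r)["TP53"]), 4L)
  expect_length(r@absentMembers, 0L)
})

test_that("consensus equals brute-force enumeration on random tables", {
  set.seed(17)
  for (i in 1:25) {
    nMir <- sample(4:12, 1L)
    nGene <- sample(10:60, 1L)
    members <- paste0("miR-", seq_len(nMir))
    edges <- expand.grid(mir = members,
                         gene = sprintf("G%03d", seq_len(nGene)),
                         stringsAsFactors = FALSE)
    edges <- edges[runif(nrow(edges)) < runif(1, 0.2, 0.8), ]
    if (nrow(edges) == 0L) next
    tab <- TargetTable(edges)
    got <- consensusGenes(consensusTargets("g", members, tab))
    want <- bruteConsensus(members, targetEdges(tab))
    expect_identical(got, want)
  }
})

test_that("opposite-group exclusion removes exactly the shared targets", {
  mk <- function(id, members, genes, supp) {
    new("ConsensusResult", groupId = id, members = members,
        thresholdUsed = max(length(members) - 2L, 4L),
        supporters = setNames(supp, genes), filtered = genes,
        excluded = data.frame(gene = character(0),
                              sharedWith = character(0)),
        absentMembers = character(0))
  }
  a <- mk("A", paste0("m", 1:7), c("x", "y", "z"), c(5L, 6L, 7L))
  b <- mk("B", paste0("n", 1:6), c("y", "w"), c(4L, 4L))
  out <- excludeShared(list(A = a, B = b), list(c("A", "B")))
  expect_setequal(filteredGenes(out$A), c("x", "z"))
  expect_setequal(filteredGenes(out$B), "w")
  expect_equal(excludedGenes(out$A)$gene, "y")
  expect_equal(excludedGenes(out$A)$sharedWith, "B")
  # disjoint sets: nothing removed
  c2 <- mk("C", paste0("p", 1:6), c("q", "r"), c(4L, 5L))
  out2 <- excludeShared(list(A = a, C = c2), list(c("A", "C")))
  expect_setequal(filteredGenes(out2$A), c("x", "y", "z"))
  expect_error(excludeShared(list(A = a), list(c("A", "A"))), "itself")
  expect_error(excludeShared(list(A = a), list(c("A", "Z"))), "known")
})

test_that("hypergeometric and EASE p-values match the worked instance", {
  expect_equal(hyperP(4, 5, 5, 20), 76 / 15504, tolerance = 1e-12)
  expect_equal(hyperP(4, 5, 5, 20, ease = TRUE), 1126 / 15504,
               tolerance = 1e-12)
  expect_equal(hyperP(0, 5, 5, 20), 1)
  expect_equal(hyperP(0, 5, 5, 20, ease = TRUE), 1)
})

test_that("enrichment matches tail enumeration and direct BH", {
  set.seed(23)
  uni <- sprintf("G%03d", 1:40)
  pws <- list(p1 = uni[1:8], p2 = uni[5:20], p3 = uni[30:40],
              p4 = uni[c(1, 12, 35)])
  genes <- uni[c(1:6, 12, 35)]
  res <- enrichPathways(genes, pws, uni)
  for (i in seq_len(nrow(res))) {
    expect_equal(res$pValue[i],
                 hyperTailEnum(res$overlap[i], res$pathwaySize[i],
                               res$querySize[i], res$universeSize[i]),
                 tolerance = 1e-12)
    expect_equal(res$easeP[i],
                 hyperTailEnum(max(res$overlap[i] - 1L, 0L),
                               res$pathwaySize[i], res$querySize[i],
                               res$universeSize[i]),
                 tolerance = 1e-12)
    expect_gte(res$adjP[i], res$pValue[i])
  }
  expect_equal(sort(res$adjP), sort(bhDirect(res$pValue)),
               tolerance = 1e-12)
  expect_equal(res$adjP, sort(res$adjP))        # sorted output
  expect_error(enrichPathways(c(genes, "NOT_THERE"), pws, uni),
               "outside the universe")
  expect_error(enrichPathways(genes, list(), uni), "empty pathway")
})

test_that("increasing overlap at fixed margins never increases p", {
  for (K in c(5, 10)) for (n in c(5, 12)) {
    p <- vapply(0:min(K, n), hyperP, numeric(1L), pathwaySize = K,
                querySize = n, universeSize = 30)
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("regulatory networks carry supporters and round-trip GraphML", {
  members <- paste0("miR-", 1:7)
  edges <- rbind(expand.grid(mir = members, gene = "AKT2",
                             stringsAsFactors = FALSE),
                 expand.grid(mir = members[1:5], gene = "RELA",
                             stringsAsFactors = FALSE),
                 data.frame(mir = "miR-1", gene = "ZZZ3"))
  tab <- TargetTable(edges)
  res <- consensusTargets("G2", members, tab)
  pws <- list(`PI3K/AKT` = c("AKT2", "PIK3R3"),
              `NF-kB` = c("RELA", "AKT2"))
  net <- buildNetwork(res, tab, pws)
  vt <- igraph::V(net)
  expect_equal(unname(vt$supporterCount[vt$name == "AKT2"]), 7L)
  expect_equal(unname(vt$supporterCount[vt$name == "RELA"]), 5L)
  # gene in two pathways carries two membership edges
  gm <- igraph::as_edgelist(net)
  expect_equal(sum(gm[, 1L] == "AKT2"), 2L)
  p <- tempfile(fileext = ".graphml")
  writeNetworkGraphml(net, p)
  back <- readNetworkGraphml(p)
  expect_true(igraph::isomorphic(net, back))
  expect_setequal(igraph::V(back)$name, vt$name)
  sif <- tempfile(fileext = ".sif")
  writeNetworkSif(net, sif)
  lines <- readLines(sif)
  expect_equal(length(lines), igraph::ecount(net))
  expect_true(any(grepl("member_of", lines)))
  # genes in no supplied pathway are dropped with a warning
  expect_warning(net2 <- buildNetwork(res, tab, pws["PI3K/AKT"]),
                 "dropped")
  expect_false("RELA" %in% igraph::V(net2)$name)
  # empty filtered set
  resEmpty <- res
  resEmpty@filtered <- character(0)
  expect_warning(e <- buildNetwork(resEmpty, tab, pws), "empty")
  expect_equal(igraph::vcount(e), 0L)
})
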