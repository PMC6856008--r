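test_that("field generation is deterministic and honours the empty case", {
  spec <- sceneSpec(nCells = 12, fieldShape = c(192L, 192L), seed = 7)
  a <- generateField(spec)
  b <- generateField(spec)
  expect_identical(a$image@channels, b$image@channels)
  expect_identical(a$nuclei@labels, b$nuclei@labels)
  expect_identical(a$cells@labels, b$cells@labels)

  e <- generateField(sceneSpec(nCells = 0, fieldShape = c(64L, 64L),
                               noiseSd = 25, seed = 1))
  expect_equal(nObjects(e$nuclei), 0L)
  expect_equal(nObjects(e$cells), 0L)
  expect_gt(sd(getChannel(e$image, "DAPI")), 0)   # pure noise
})

test_that("epithelial fields carry low-eccentricity clustered cells", {
  spec <- sceneSpec(nCells = 50, phenotype = "epithelial",
                    eccentricityRange = c(0, 0.2),
                    fieldShape = c(512L, 512L), noiseSd = 0, seed = 1)
  f <- generateField(spec)
  shp <- hcsmiR:::shapeFeaturesByLabel(f$cells@labels)
  expect_lt(mean(shp$eccentricity), 0.3)
})

test_that("ground-truth morphometry matches the planted parameters", {
  spec <- sceneSpec(nCells = 60, fieldShape = c(512L, 512L),
                    meanCellArea = 380, noiseSd = 0, seed = 3)
  f <- generateField(spec)
  shp <- hcsmiR:::shapeFeaturesByLabel(f$cells@labels)
  expect_equal(mean(shp$area_px), 380, tolerance = 0.10)
  expect_equal(mean(shp$eccentricity), mean(spec@eccentricityRange),
               tolerance = 0.10)
  feats <- intensityFeatures(f$image, f$nuclei,
                             cytoplasmMap(f$cells, f$nuclei), "FITC")
  expect_equal(unique(feats$median_FITC_nucleus),
               spec@nuclearMarkerLevel)
  expect_equal(unique(feats$median_FITC_cytoplasm),
               spec@cytoplasmicMarkerLevel)
})

test_that("overcrowded fields are rejected", {
  expect_error(generateField(sceneSpec(nCells = 500,
                                       fieldShape = c(96L, 96L),
                                       meanCellArea = 400, seed = 1)),
               "overcrowded")
})

test_that("screens plant per-well effects and emit the right field count", {
  d <- screenDesign(list(`miR-a` = c(`count nuclei` = -50),
                         `miR-b` = c(`count nuclei` = 25)),
                    replicates = 3, fieldsPerWell = 9)
  expect_equal(nrow(screenFields(d)), 81L)       # (2 x 3 + 3 control) x 9
  dir <- tempfile("screen")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  dSmall <- screenDesign(list(`miR-a` = c(`count nuclei` = -50)),
                         replicates = 2, fieldsPerWell = 2)
  base <- sceneSpec(nCells = 8, fieldShape = c(128L, 128L),
                    clusteringStrength = 0, noiseSd = 0, seed = 4)
  scr <- generateScreen(dSmall, base, measure = FALSE, outDir = dir)
  expect_length(scr$files, 8L)                   # (1 x 2 + 2 control) x 2
  expect_true(all(file.exists(scr$files)))
  # planted count: -50% of 8 cells -> 4 per field
  expect_equal(scr$truth[["count nuclei"]][scr$truth$treatment == "miR-a"],
               rep(4 * 2, 2))
  # reproducibility of the emitted records
  scr2 <- generateScreen(dSmall, base)
  scr3 <- generateScreen(dSmall, base)
  expect_identical(scr2$cells, scr3$cells)
})

test_that("unknown treatment labels are named in the error", {
  d <- screenDesign(list(`miR-a` = c(`count nuclei` = -50)),
                    replicates = 1, fieldsPerWell = 1)
  d@layout$treatment[2L] <- "miR-ghost"
  expect_error(generateScreen(d, sceneSpec(nCells = 4,
                                           fieldShape = c(96L, 96L))),
               "miR-ghost")
})

test_that("synthetic target tables recover exactly the planted structure", {
  groups <- list(A = paste0("miR-", 1:7), B = paste0("miR-", 11:16))
  sp <- plantedTargetSpec(groups, universeSize = 400,
                          nConsensus = c(A = 6, B = 5),
                          shared = c(`A|B` = 3),
                          backgroundEdgeProb = 0, seed = 5)
  tab <- suppressMessages(generateTargetTable(sp))
  res <- list(A = consensusTargets("A", groups$A, tab),
              B = consensusTargets("B", groups$B, tab))
  expect_setequal(names(consensusGenes(res$A)),
                  c(sp@plantedConsensus$A, sp@plantedShared$`A|B`))
  expect_setequal(names(consensusGenes(res$B)),
                  c(sp@plantedConsensus$B, sp@plantedShared$`A|B`))
  ex <- excludeShared(res, list(c("A", "B")))
  expect_setequal(excludedGenes(ex$A)$gene, sp@plantedShared$`A|B`)
  expect_setequal(excludedGenes(ex$B)$gene, sp@plantedShared$`A|B`)
  expect_setequal(filteredGenes(ex$A), sp@plantedConsensus$A)
  expect_setequal(filteredGenes(ex$B), sp@plantedConsensus$B)
  # determinism
  tab2 <- suppressMessages(generateTargetTable(sp))
  expect_identical(targetEdges(tab), targetEdges(tab2))
})

test_that("planted spec validation rejects an overfull universe", {
  expect_error(plantedTargetSpec(list(A = paste0("m", 1:6)),
                                 universeSize = 4, nConsensus = c(A = 5)),
               "universe too small")
})

test_that("migration pairs hit the planted growth factor", {
  for (g in c(1, 1.3, 2)) {
    p <- generateMigrationPair(0.35, g, c(256L, 256L), seed = 11)
    m <- measureMigration(p$start, p$end)
    expect_equal(m$M, 100 * (g - 1), tolerance = 0.011,
                 label = paste("growth", g))
  }
  expect_error(generateMigrationPair(0.6, 2, c(128L, 128L)),
               "infeasible growth")
})

test_that("confluence images encode the planted occupied fraction", {
  ci <- generateConfluenceImage(0.30, c(256L, 256L), seed = 6)
  expect_equal(ci$fraction, 0.30, tolerance = 0.01)
  expect_equal(as.numeric(occupiedArea(ci$image)), 0.30, tolerance = 0.02 / 0.30)
})
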