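mkRecords <- function(wells, fields, areas) {
  data.frame(well = wells, field = fields, cell_id = seq_along(wells),
             area_um2 = areas, eccentricity = 0.5,
             median_FITC_nucleus = 3000, median_FITC_cytoplasm = 1500,
             stringsAsFactors = FALSE)
}

test_that("field summaries take per-field medians and counts", {
  rec <- mkRecords(rep("A01", 3L), rep(1L, 3L), c(100, 200, 300))
  fs <- fieldSummaries(rec)
  expect_equal(fs[["cell area"]], 200)
  expect_equal(fs[["count nuclei"]], 3L)
  # empty field listed via enumeration
  fs2 <- fieldSummaries(rec, fields = data.frame(well = "A01",
                                                 field = 1:2))
  expect_equal(fs2[["count nuclei"]], c(3L, 0L))
  expect_true(is.na(fs2[["cell area"]][2L]))
  # 9 fields, order preserved
  rec9 <- mkRecords(rep("A01", 9L), 1:9, seq(10, 90, 10))
  fs9 <- fieldSummaries(rec9)
  expect_equal(fs9$field, 1:9)
  expect_equal(nrow(fs9), 9L)
})

test_that("well aggregation is a median of field medians, counts summed", {
  rec <- mkRecords(rep("A01", 3L), 1:3, c(10, 20, 30))
  fs <- fieldSummaries(rec)
  wv <- aggregateWells(fs, minCellsQc = 1)
  expect_equal(wv[["cell area"]], 20)
  expect_equal(wv[["count nuclei"]], 3)
  counts <- fieldSummaries(mkRecords(rep("B02", 180L),
                                     rep(1:3, c(50, 60, 70)),
                                     rep(1, 180L)))
  expect_equal(aggregateWells(counts, minCellsQc = 1)[["count nuclei"]],
               180)
  # QC flagging
  low <- aggregateWells(fs, minCellsQc = 50)
  expect_false(low$qc_pass)
  expect_match(low$qc_reason, "< 50")
})

test_that("percent change vs control follows the PMC formula", {
  wv <- data.frame(well = c("A01", "A02", "A03"),
                   `cell area` = c(100, 120, 80),
                   qc_pass = TRUE, qc_reason = "",
                   check.names = FALSE, stringsAsFactors = FALSE)
  wv[["count nuclei"]] <- c(100, 100, 100)
  lay <- data.frame(well = c("A01", "A02", "A03"),
                    treatment = c("PMC", "up", "down"), replicate = 1L)
  pm <- percentChangeMatrix(wv, lay, "PMC")
  v <- profileValues(pm)
  expect_equal(v["up", "cell area"], 20)
  expect_equal(v["down", "cell area"], -20)
  expect_equal(v["PMC", "cell area"], 0)
  expect_equal(v[, "count nuclei"], c(PMC = 0, up = 0, down = 0))
})

test_that("failing wells and zero-reference columns are dropped and logged", {
  wv <- data.frame(well = c("A01", "A02", "A03"),
                   `cell area` = c(100, 150, 500),
                   zero = c(0, 0, 5),
                   qc_pass = c(TRUE, TRUE, FALSE),
                   qc_reason = c("", "", "total cells 3 < 50"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  lay <- data.frame(well = c("A01", "A02", "A03"),
                    treatment = c("PMC", "t1", "t1"), replicate = c(1L, 1L, 2L))
  expect_warning(pm <- percentChangeMatrix(wv, lay, "PMC"), "zero")
  expect_false("zero" %in% colnames(profileValues(pm)))
  expect_equal(profileValues(pm)["t1", "cell area"], 50)  # A03 excluded
  lg <- qcLog(pm)
  expect_true(any(grepl("A03", lg$item)))
  expect_true(any(grepl("zero", lg$item)))
})

test_that("the matrix is invariant to well processing order", {
  set.seed(9)
  wells <- sprintf("A%02d", 1:6)
  rec <- do.call(rbind, lapply(1:6, function(w)
    mkRecords(rep(wells[w], 20L), rep(1:2, 10L), runif(20, 80, 120))))
  lay <- data.frame(well = wells,
                    treatment = rep(c("PMC", "t1", "t2"), each = 2L),
                    replicate = rep(1:2, 3L))
  run <- function(r) {
    fs <- fieldSummaries(r)
    percentChangeMatrix(aggregateWells(fs, minCellsQc = 1), lay, "PMC")
  }
  a <- run(rec)
  b <- run(rec[sample.int(nrow(rec)), ])
  expect_equal(profileValues(a), profileValues(b))
})

test_that("a control-only mini-screen yields an all-zero profile", {
  d <- screenDesign(list(), controlWells = 2, fieldsPerWell = 2)
  scr <- generateScreen(d, sceneSpec(nCells = 12, fieldShape = c(160L, 160L),
                                     noiseSd = 0, seed = 21))
  fs <- fieldSummaries(scr$cells, fields = screenFields(d))
  pm <- suppressWarnings(
    percentChangeMatrix(aggregateWells(fs, minCellsQc = 1),
                        scr$layout, "PMC"))
  expect_true(all(abs(profileValues(pm)) < 1e-9))
})

test_that("profile matrices round-trip through TSV", {
  v <- matrix(c(-20.5, 10.25, 0, 5), 2, 2,
              dimnames = list(c("miR-a", "miR-b"),
                              c("count nuclei", "cells eccentricity")))
  pm <- new("ProfileMatrix", values = v,
            replicateN = matrix(3L, 2, 2, dimnames = dimnames(v)),
            controlLabel = "PMC",
            qcLog = data.frame(item = character(0),
                               reason = character(0)))
  path <- tempfile(fileext = ".tsv")
  writeProfileMatrix(pm, path)
  back <- readProfileMatrix(path)
  expect_equal(profileValues(back), v)
})
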