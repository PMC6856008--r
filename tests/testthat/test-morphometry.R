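test_that("shape features agree with the brute-force oracle on small masks", {
  set.seed(42)
  for (i in 1:30) {
    mask <- randomConnectedMask(sample(3:40, 1L))
    got <- shapeFeatures(mask)
    want <- oracleShape(mask)
    expect_equal(got[["area"]], want[["area"]])
    expect_equal(got[["eccentricity"]], want[["eccentricity"]],
                 tolerance = 1e-12)
    expect_equal(got[["solidity"]], want[["solidity"]], tolerance = 1e-12)
  }
})

test_that("canonical shapes have the expected features", {
  disc <- discMask(c(51, 51), c(26, 26), 20)
  fd <- shapeFeatures(disc)
  expect_lt(fd[["eccentricity"]], 0.05)
  expect_gte(fd[["solidity"]], 0.98)

  ell <- outer(1:61, 1:61, function(r, c)
    ((c - 31) / 20)^2 + ((r - 31) / 10)^2 <= 1)
  expect_equal(shapeFeatures(ell)[["eccentricity"]], sqrt(0.75),
               tolerance = 0.02 / sqrt(0.75))

  plus <- matrix(0, 9, 9)
  plus[4:6, 2:8] <- 1
  plus[2:8, 4:6] <- 1
  fp <- shapeFeatures(plus)
  expect_lt(fp[["solidity"]], 1)
  expect_equal(fp[["solidity"]], oracleShape(plus)[["solidity"]],
               tolerance = 1e-12)

  expect_equal(unname(shapeFeatures(matrix(c(0, 1, 0, 0), 2))),
               c(1, 0, 1))                       # single pixel
  expect_error(shapeFeatures(matrix(0, 3, 3)), "empty mask")
})

test_that("eccentricity is stable under rotation of a rasterized ellipse", {
  angs <- seq(0, pi, length.out = 13)
  eccs <- vapply(angs, function(th) {
    m <- matrix(0L, 81, 81)
    idx <- hcsmiR:::rasterizeEllipse(c(41, 41), 20, 10, th, c(81, 81))
    m[idx] <- 1L
    shapeFeatures(m)[["eccentricity"]]
  }, numeric(1L))
  expect_lt(max(eccs) - min(eccs), 0.03)
})

test_that("neighbour counts and percent touching match the fixtures", {
  lab <- matrix(0L, 20, 40)
  lab[6:15, 6:15] <- 1L     # three 10x10 squares in a row, abutting
  lab[6:15, 16:25] <- 2L
  lab[6:15, 26:35] <- 3L
  nf <- neighborFeatures(LabelMap(lab, "cell"))
  expect_equal(nf$n_neighbors, c(1L, 2L, 1L))
  # two abutting squares: 10 of 36 boundary pixels touch the other
  lab2 <- matrix(0L, 20, 30)
  lab2[6:15, 6:15] <- 1L
  lab2[6:15, 16:25] <- 2L
  nf2 <- neighborFeatures(LabelMap(lab2, "cell"))
  expect_equal(nf2$percent_touching, rep(100 * 10 / 36, 2L))
  expect_equal(nf2$n_neighbors, c(1L, 1L))
  # isolated cell
  lab3 <- matrix(0L, 20, 20)
  lab3[8:12, 8:12] <- 1L
  nf3 <- neighborFeatures(LabelMap(lab3, "cell"))
  expect_equal(nf3$n_neighbors, 0L)
  expect_equal(nf3$percent_touching, 0)
})

test_that("expansion bridges small gaps for neighbour detection only", {
  lab <- matrix(0L, 20, 25)
  lab[6:15, 4:10] <- 1L
  lab[6:15, 12:18] <- 2L    # 1-px gap
  nf1 <- neighborFeatures(LabelMap(lab, "cell"), expansionPx = 1L)
  expect_equal(nf1$n_neighbors, c(1L, 1L))
  expect_equal(nf1$percent_touching, c(0, 0))   # un-expanded boundaries
  nf0 <- neighborFeatures(LabelMap(lab, "cell"), expansionPx = 0L)
  expect_equal(nf0$n_neighbors, c(0L, 0L))
})

test_that("compartment medians follow the even-count convention", {
  nuc <- matrix(0L, 8, 8); nuc[3:4, 3:4] <- 1L
  cyt <- matrix(0L, 8, 8); cyt[5, 3:6] <- 1L
  fitc <- matrix(0, 8, 8)
  fitc[nuc > 0] <- 500
  fitc[5, 3:6] <- c(10, 20, 30, 40)
  img <- makeField(FITC = fitc)
  f <- intensityFeatures(img, LabelMap(nuc, "nucleus"),
                         LabelMap(cyt, "cytoplasm"), channels = "FITC")
  expect_equal(f$median_FITC_nucleus, 500)
  expect_equal(f$median_FITC_cytoplasm, 25)
  expect_false(f$cytoplasm_missing)
})

test_that("empty cytoplasm is reported missing, shape mismatch errors", {
  nuc <- matrix(0L, 6, 6); nuc[3:4, 3:4] <- 1L
  cyt <- matrix(0L, 6, 6)                       # nucleus fills the cell
  img <- makeField(FITC = matrix(100, 6, 6))
  f <- intensityFeatures(img, LabelMap(nuc, "nucleus"),
                         LabelMap(cyt, "cytoplasm"), channels = "FITC")
  expect_true(f$cytoplasm_missing)
  expect_true(is.na(f$median_FITC_cytoplasm))
  expect_error(intensityFeatures(img, LabelMap(matrix(0L, 3, 3), "nucleus"),
                                 LabelMap(cyt, "cytoplasm")),
               "shapes differ")
})

test_that("planted nuclear:cytoplasmic intensity ratio is recovered", {
  spec <- sceneSpec(nCells = 40, fieldShape = c(384L, 384L),
                    nuclearMarkerLevel = 3000,
                    cytoplasmicMarkerLevel = 1000, noiseSd = 20, seed = 8)
  f <- generateField(spec)
  feats <- cellFeatures(f$image, f$nuclei, f$cells, channels = "FITC")
  ratio <- median(feats$median_FITC_nucleus / feats$median_FITC_cytoplasm)
  expect_equal(ratio, 3, tolerance = 0.05)
})

test_that("area scales with pixel size, shape descriptors do not", {
  f <- generateField(sceneSpec(nCells = 10, fieldShape = c(256L, 256L),
                               noiseSd = 0, seed = 2))
  img2 <- f$image
  img2@pixelSize <- 2
  a <- cellFeatures(f$image, f$nuclei, f$cells, channels = "FITC")
  b <- cellFeatures(img2, f$nuclei, f$cells, channels = "FITC")
  expect_equal(b$area_um2, 4 * a$area_um2)
  expect_equal(b$eccentricity, a$eccentricity)
  expect_equal(b$solidity, a$solidity)
  expect_equal(b$percent_touching, a$percent_touching)
})
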