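test_that("QC applies the stated thresholds with strict boundaries", {
  # marker 1: MAF exactly 0.05 (nine 0s, one 1 in ten genotypes) -> kept;
  # marker 2: common, clean -> kept
  m <- toyMarkers(cbind(c(rep(0, 9), 1), rep(c(0, 2), 5)))
  qc <- qcFilter(m)
  expect_equal(qc$report$maf[1], 0.05)
  expect_equal(qc$report$status[1], "kept")

  # 25% missing -> removed for missingness (and call rate: same statistic,
  # both reasons reported when both thresholds fire)
  m2 <- toyMarkers(cbind(c(NA, 0, 2, 2, 0, 2, 0, NA), rep(c(0, 2), 4)))
  qc2 <- qcFilter(m2)
  expect_match(qc2$report$status[1], "max_missing")
  expect_match(qc2$report$status[1], "low_callrate")
  expect_equal(markerIDs(qc2$markers), "M02")

  # fully heterozygous marker: het = 1.0 > 0.95 -> removed
  m3 <- toyMarkers(cbind(rep(1, 10), rep(c(0, 2), 5)))
  expect_match(qcFilter(m3)$report$status[1], "max_het")

  # all-missing marker is removed with reason no_calls, not an error
  m4 <- toyMarkers(cbind(rep(NA_real_, 6), rep(c(0, 2), 3)))
  qc4 <- qcFilter(m4)
  expect_equal(qc4$report$status[1], "no_calls")
  expect_equal(qc4$nKept, 1L)
  expect_equal(qc4$nKept + qc4$nRemoved, 2L)
})

test_that("QC is idempotent and reports one row per input marker", {
  cfg <- oneTraitConfig(nGenotypes = 60, nMarkers = 120, missingRate = 0.15,
    seed = 61)
  cfg$mafRange <- c(0.02, 0.5)
  mk <- simulateMarkers(cfg)
  once <- qcFilter(mk)
  twice <- qcFilter(once$markers)
  expect_identical(as.matrix(twice$markers), as.matrix(once$markers))
  expect_equal(nrow(once$report), 120)
})

test_that("mean imputation fills missing calls with the marker mean", {
  m <- toyMarkers(cbind(c(0, 2, NA), c(1, 1, 1)))
  imp <- as.matrix(imputeMean(m))
  expect_equal(imp[3, 1], 1.0)
  expect_equal(imp[, 2], c(G01 = 1, G02 = 1, G03 = 1))

  m2 <- toyMarkers(cbind(c(1, 1, NA, NA), c(0, 2, 0, 2)))
  expect_equal(as.matrix(imputeMean(m2))[3:4, 1], c(G03 = 1, G04 = 1))

  # complete input passes through unchanged
  m3 <- toyMarkers(cbind(c(0, 1, 2), c(2, 2, 0)))
  expect_equal(unname(as.matrix(imputeMean(m3))), unname(as.matrix(m3)))

  expect_error(imputeMean(toyMarkers(cbind(rep(NA_real_, 3), c(0, 1, 2)))),
    "qcFilter")
})

test_that("GRM matches the hand-computed standardized cross-product", {
  # 2 genotypes x 2 markers [[0,2],[2,0]]: centered +-1, sample SD sqrt(2),
  # standardized +-1/sqrt(2), G = XX'/2 = [[0.5,-0.5],[-0.5,0.5]]
  m <- toyMarkers(rbind(c(0, 2), c(2, 0)))
  G <- as.matrix(computeGRM(m))
  expect_equal(unname(G), rbind(c(0.5, -0.5), c(-0.5, 0.5)),
    tolerance = 1e-12)

  # duplicated genotype rows give identical GRM rows and G[i,i] = G[i,j]
  m2 <- toyMarkers(rbind(c(0, 2, 1, 0), c(0, 2, 1, 0), c(2, 0, 0, 2)))
  G2 <- as.matrix(computeGRM(m2))
  expect_equal(G2[1, ], G2[2, ], tolerance = 1e-12,
    ignore_attr = TRUE)
  expect_equal(G2[1, 1], G2[1, 2], tolerance = 1e-12)

  expect_error(computeGRM(toyMarkers(cbind(c(1, 1, 1), c(0, 2, 1)))),
    "zero-variance")
})

test_that("GRM is symmetric PSD, column-order invariant, with unit mean diagonal", {
  cfg <- oneTraitConfig(nGenotypes = 10, nMarkers = 50, seed = 71)
  cfg$mafRange <- c(0.3, 0.5)
  mk <- simulateMarkers(cfg)
  G <- as.matrix(computeGRM(mk))
  expect_true(isSymmetric(G))
  expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
    -1e-8)

  perm <- sample(50)
  mPerm <- MarkerMatrix(as.matrix(mk)[, perm])
  expect_equal(as.matrix(computeGRM(mPerm)), G, tolerance = 1e-12)

  cfgBig <- oneTraitConfig(nGenotypes = 50, nMarkers = 5000, seed = 72)
  cfgBig$mafRange <- c(0.2, 0.5)
  Gbig <- as.matrix(computeGRM(simulateMarkers(cfgBig)))
  expect_gt(mean(diag(Gbig)), 0.95)
  expect_lt(mean(diag(Gbig)), 1.05)
})

test_that("marker and GRM text round-trips preserve values", {
  cfg <- oneTraitConfig(nGenotypes = 12, nMarkers = 20, missingRate = 0.1,
    seed = 81)
  cfg$mafRange <- c(0.3, 0.5)
  mk <- simulateMarkers(cfg)
  f <- tempfile(fileext = ".csv")
  writeMarkerCSV(mk, f)
  back <- readMarkerCSV(f)
  expect_equal(as.matrix(back), as.matrix(mk))

  # PLINK .raw-style: leading FID/IID/PAT/MAT/SEX/PHENOTYPE tolerated
  raw <- tempfile(fileext = ".raw")
  m <- as.matrix(mk)
  df <- data.frame(FID = rownames(m), IID = rownames(m), PAT = 0, MAT = 0,
    SEX = 0, PHENOTYPE = -9, m, check.names = FALSE)
  write.table(df, raw, row.names = FALSE, quote = FALSE)
  backRaw <- readPlinkRaw(raw)
  expect_equal(as.matrix(backRaw), m)

  g <- tempfile(fileext = ".csv")
  G <- computeGRM(imputeMean(mk))
  writeGRMcsv(G, g)
  expect_equal(as.matrix(readGRMcsv(g)), as.matrix(G), tolerance = 1e-12)
})
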