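# helper: simulate a response directly from the kernel generative model
simFromKernels <- function(ks, varComp, seed) {
  set.seed(seed)
  n <- nrow(ks@cells)
  y <- rep(0, n)
  for (lab in names(ks@kernels)) {
    K <- ks@kernels[[lab]]
    e <- eigen(K, symmetric = TRUE)
    d <- pmax(e$values, 0)
    y <- y + drop(e$vectors %*% (sqrt(d) * rnorm(n))) * sqrt(varComp[[lab]])
  }
  y + rnorm(n, 0, sqrt(varComp[["error"]]))
}

test_that("fixed-variance predictions match the closed-form mixed-model solve", {
  # 20-genotype toy, single genomic kernel, components held at truth
  grm <- simGRM(20, p = 80, seed = 201)
  cells <- cellGrid(genotypeIDs(grm), "E1")
  ks <- new("KernelSet", cells = cells,
    kernels = list(genomic = as.matrix(grm)), model = "M2")
  K <- as.matrix(grm); dimnames(K) <- NULL
  sg <- 2; se <- 1
  set.seed(202)
  e <- eigen(K, symmetric = TRUE)
  y <- 10 + drop(e$vectors %*% (sqrt(pmax(e$values, 0)) * rnorm(20))) *
    sqrt(sg) + rnorm(20, 0, sqrt(se))

  fit <- fitModel(ks, y, nIter = 300000, burnIn = 5000, thin = 5,
    fixedVarComp = c(genomic = sg, error = se), seed = 203)
  # GLS oracle: V = sg K + se I; beta = (1'V^-1 1)^-1 1'V^-1 y;
  # u = sg K V^-1 (y - beta); prediction = beta + u
  V <- sg * K + se * diag(20)
  Vi <- solve(V)
  beta <- sum(Vi %*% y) / sum(Vi)
  u <- sg * K %*% Vi %*% (y - beta)
  expect_lt(max(abs(fit@predictions - (beta + u))), 0.01 * sd(y))
})

test_that("with error variance pinned near zero the fit interpolates", {
  # single environment so the iid line kernel is the identity over cells
  # and the random effects span any observed response
  grm <- simGRM(15, seed = 204)
  cells <- cellGrid(genotypeIDs(grm), "E1")
  ks <- buildKernels(cells, grm, "M2")
  y <- simFromKernels(ks, c(env = 1, line = 1, genomic = 2, error = 0.5),
    seed = 205)
  fit <- fitModel(ks, y, nIter = 20000, burnIn = 2000, thin = 5,
    fixedVarComp = c(env = 1, line = 1, genomic = 2, error = 1e-6),
    seed = 206)
  expect_lt(max(abs(fit@predictions - y)), 0.01 * sd(y))
})

test_that("when simulated GxE is zero, M3 collapses onto M2", {
  cfg <- oneTraitConfig(nGenotypes = 60, nEnvironments = 3, nMarkers = 60,
    sigmaG2 = 4, sigmaGxE2 = 0, sigmaErr2 = 1, seed = 207)
  cfg$mafRange <- c(0.25, 0.5)
  ratios <- c(); cors <- c()
  for (r in 1:20) {
    cfg$seed <- 207 + r
    dat <- simulateMET(cfg)
    grm <- computeGRM(dat$markers)
    s <- dat$signals$signals
    cells <- cellGrid(sort(unique(s$genotype)), sort(unique(s$env)))
    idx <- match(paste(cells$genotype, cells$env), paste(s$genotype, s$env))
    set.seed(300 + r)
    y <- s$value[idx] + rnorm(nrow(cells), 0, 0.5)
    f2 <- fitModel(buildKernels(cells, grm, "M2"), y, nIter = 2500,
      burnIn = 1000, thin = 2, seed = 400 + r)
    f3 <- fitModel(buildKernels(cells, grm, "M3"), y, nIter = 2500,
      burnIn = 1000, thin = 2, seed = 500 + r)
    vc <- varianceComponents(f3)
    ratios <- c(ratios, vc[["gxe"]] /
      (vc[["line"]] + vc[["genomic"]] + vc[["gxe"]]))
    cors <- c(cors, cor(f2@predictions, f3@predictions))
  }
  expect_lt(median(ratios), 0.10)
  expect_gt(median(cors), 0.99)
})

test_that("adding kernels never worsens the in-sample fit (nesting)", {
  cfg <- oneTraitConfig(nGenotypes = 30, nEnvironments = 3, nMarkers = 60,
    sigmaG2 = 3, sigmaGxE2 = 3, sigmaErr2 = 1, seed = 210)
  cfg$mafRange <- c(0.25, 0.5)
  dat <- simulateMET(cfg)
  grm <- computeGRM(dat$markers)
  s <- dat$signals$signals
  cells <- cellGrid(sort(unique(s$genotype)), sort(unique(s$env)))
  idx <- match(paste(cells$genotype, cells$env), paste(s$genotype, s$env))
  set.seed(211)
  y <- s$value[idx] + rnorm(nrow(cells), 0, 0.5)
  fitMSE <- sapply(c("M1", "M2", "M3"), function(m) {
    f <- fitModel(buildKernels(cells, grm, m), y, nIter = 3000,
      burnIn = 1000, thin = 2, seed = 212)
    mean((f@predictions - y)^2)
  })
  eps <- 0.05 * var(y)    # Monte Carlo slack
  expect_lt(fitMSE[["M2"]], fitMSE[["M1"]] + eps)
  expect_lt(fitMSE[["M3"]], fitMSE[["M2"]] + eps)
})

test_that("permuting cell order permutes predictions (exchangeability)", {
  grm <- simGRM(12, seed = 213)
  cells <- cellGrid(genotypeIDs(grm), c("E1", "E2"))
  ks <- buildKernels(cells, grm, "M3")
  y <- simFromKernels(ks, c(env = 2, line = 0.5, genomic = 2, gxe = 1,
    error = 0.3), seed = 214)
  perm <- sample(nrow(cells))
  ksP <- buildKernels(cells[perm, ], grm, "M3")
  # kernels permute exactly
  expect_equal(ksP@kernels$gxe, ks@kernels$gxe[perm, perm])
  # posterior-mean predictions agree within Monte Carlo tolerance
  vc <- c(env = 2, line = 0.5, genomic = 2, gxe = 1, error = 0.3)
  f <- fitModel(ks, y, nIter = 12000, burnIn = 2000, thin = 5,
    fixedVarComp = vc, seed = 215)
  fP <- fitModel(ksP, y[perm], nIter = 12000, burnIn = 2000, thin = 5,
    fixedVarComp = vc, seed = 216)
  expect_lt(max(abs(fP@predictions - f@predictions[perm])), 0.02 * sd(y))
})

test_that("sampler guards reject degenerate settings", {
  grm <- simGRM(6, seed = 217)
  cells <- cellGrid(genotypeIDs(grm), "E1")
  ks <- buildKernels(cells, grm, "M2")
  y <- rnorm(6)
  expect_error(fitModel(ks, y, nIter = 100, burnIn = 200), "burn-in")
  expect_error(fitModel(ks, rep(NA_real_, 6)), "at least one observed")
  badK <- ks
  badK@kernels$genomic <- diag(6); badK@kernels$genomic[1, 1] <- -5
  expect_error(fitModel(badK, y), "positive semi-definite")
})
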