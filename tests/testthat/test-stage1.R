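test_that("adjusted values equal plot means in the zero-noise limit", {
  cfg <- oneTraitConfig(nGenotypes = 20, sigmaBR2 = 0, sigmaErr2 = 1e-8,
    sigmaGxE2 = 0, seed = 91)
  dat <- simulateMET(cfg)
  fit <- fitStage1(dat$plots, "Env1", "y")
  pm <- c(tapply(dat$plots$y[dat$plots$env == "Env1"],
    dat$plots$genotype[dat$plots$env == "Env1"], mean))
  adj <- fit@mu + blups(fit)
  expect_equal(unname(adj[names(pm)]), unname(pm), tolerance = 1e-6)
  expect_true(all(varianceComponents(fit) >= 0))
})

test_that("REML estimates maximize the restricted likelihood (grid-search oracle)", {
  # small toy built directly: 4 genotypes, 2 replicates, 2 blocks per rep
  set.seed(92)
  d <- expand.grid(genotype = sprintf("G%02d", 1:4), rep = 1:2,
    stringsAsFactors = FALSE)
  d$env <- "Env1"
  d$block <- c(1, 1, 2, 2, 2, 1, 2, 1)
  gEff <- rnorm(4, 0, sqrt(2))
  bEff <- rnorm(4, 0, sqrt(0.5))
  d$y <- 30 + gEff[match(d$genotype, sprintf("G%02d", 1:4))] +
    bEff[(d$rep - 1) * 2 + d$block] + rnorm(8, 0, 1)
  fit <- fitStage1(d, "Env1", "y")
  lam <- fit@convergence$lambda

  y <- d$y
  X <- model.matrix(~ factor(d$rep))
  Z1 <- model.matrix(~ 0 + factor(d$genotype))
  Z2 <- model.matrix(~ 0 + factor(paste(d$rep, d$block)))
  # dense grid (step 1e-3) around the estimate, via the independent oracle
  g1 <- seq(max(0, lam[1] - 0.05), lam[1] + 0.05, by = 1e-3)
  g2 <- seq(max(0, lam[2] - 0.05), lam[2] + 0.05, by = 1e-3)
  vals <- outer(g1, g2, Vectorize(function(a, b) rllOracle(a, b, y, X, Z1, Z2)))
  best <- arrayInd(which.max(vals), dim(vals))
  # the returned estimate attains the grid maximum (to grid resolution)
  expect_gte(rllOracle(lam[1], lam[2], y, X, Z1, Z2), max(vals) - 1e-6)
  expect_lt(abs(g1[best[1]] - lam[1]), 2e-3)
  expect_lt(abs(g2[best[2]] - lam[2]), 2e-3)
  # and the reported restricted log-likelihood agrees with the oracle
  expect_equal(fit@logLik, rllOracle(lam[1], lam[2], y, X, Z1, Z2),
    tolerance = 1e-6)
})

test_that("REML agrees with an independent mixed-model engine", {
  skip_if_not_installed("lme4")
  cfg <- oneTraitConfig(nGenotypes = 50, nEnvironments = 2, sigmaG2 = 3,
    sigmaGxE2 = 1, sigmaBR2 = 0.8, sigmaErr2 = 2, seed = 93)
  dat <- simulateMET(cfg)
  fit <- fitStage1(dat$plots, "Env2", "y")
  d <- dat$plots[dat$plots$env == "Env2", ]
  d$blk <- paste(d$rep, d$block)
  lf <- lme4::lmer(y ~ factor(rep) + (1 | genotype) + (1 | blk), data = d,
    REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  ref <- setNames(vc$vcov, vc$grp)
  est <- varianceComponents(fit)
  expect_equal(est[["genotype"]], ref[["genotype"]], tolerance = 1e-3)
  expect_equal(est[["block"]], ref[["blk"]], tolerance = 1e-3)
  expect_equal(est[["error"]], ref[["Residual"]], tolerance = 1e-3)
  blupRef <- lme4::ranef(lf)$genotype
  expect_equal(unname(blups(fit)[rownames(blupRef)]), blupRef[[1]],
    tolerance = 1e-3)
})

test_that("variance components are recovered across many simulated environments", {
  # 50 environments with known components; mean REML estimates within 10%.
  # genetic variance enters through the per-environment (GxE) component so
  # each environment carries an independent genetic draw and the average
  # converges to the parameter rather than to one realized main-effect draw
  cfg <- oneTraitConfig(nGenotypes = 80, nEnvironments = 50, sigmaG2 = 0,
    sigmaGxE2 = 4, sigmaBR2 = 1, sigmaErr2 = 2, nBlocksPerRep = 4,
    seed = 94, envMeans = rep(30, 50))
  dat <- simulateMET(cfg)
  ests <- t(vapply(sprintf("Env%d", 1:50), function(e)
    varianceComponents(fitStage1(dat$plots, e, "y")), numeric(3)))
  means <- colMeans(ests)
  expect_lt(abs(means[["genotype"]] - 4) / 4, 0.10)
  expect_lt(abs(means[["block"]] - 1) / 1, 0.10)
  expect_lt(abs(means[["error"]] - 2) / 2, 0.10)
})

test_that("BLUPs preserve the raw-mean ranking in balanced data", {
  cfg <- oneTraitConfig(nGenotypes = 30, seed = 95, sigmaBR2 = 0)
  dat <- simulateMET(cfg)
  fit <- fitStage1(dat$plots, "Env1", "y")
  d <- dat$plots[dat$plots$env == "Env1", ]
  pm <- tapply(d$y, d$genotype, mean)
  expect_equal(cor(blups(fit)[names(pm)], pm), 1, tolerance = 1e-6)
  # shrinkage: no BLUP exceeds the largest raw-mean deviation
  expect_lte(max(abs(blups(fit))), max(abs(pm - mean(pm))) + 1e-9)
})

test_that("entry-mean heritability follows its closed form", {
  expect_equal(heritability(3, 2, 2), 0.75)
  expect_equal(heritability(5, 0, 3), 1.0)
  expect_equal(heritability(0, 5, 2), 0.0)
  expect_error(heritability(0, 0, 2), "undefined")
  expect_error(heritability(-1, 2, 2), ">= 0")
  expect_error(heritability(1, 2, 0), "r must")
  # monotone in r and in genotypic variance
  r <- sapply(1:6, function(r) heritability(2, 3, r))
  expect_true(all(diff(r) > 0))
  g <- sapply(seq(0.5, 5, 0.5), function(s) heritability(s, 3, 2))
  expect_true(all(diff(g) > 0))
})

test_that("stage-1 summary mirrors the per-environment layout", {
  cfg <- oneTraitConfig(nGenotypes = 25, nEnvironments = 2, seed = 96)
  dat <- simulateMET(cfg)
  s1 <- fitStage1All(dat$plots)
  expect_equal(nrow(s1$blups), 25 * 2)
  expect_setequal(names(s1$summary),
    c("env", "trait", "mean", "sigmaG2", "sigmaBR2", "sigmaE2", "H2", "SD",
      "nReplicates"))
  expect_true(all(s1$summary$H2 >= 0 & s1$summary$H2 <= 1))
  expect_error(fitStage1(dat$plots, "nope", "y"), "no plots")
  expect_error(fitStage1(dat$plots, "Env1", "zz"), "no trait")
})
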