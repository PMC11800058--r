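# Shared fixture builders; all data are generated in code under fixed seeds.

# small single-trait config with explicit variance components
oneTraitConfig <- function(nGenotypes = 40, nEnvironments = 3,
                           nMarkers = 150, sigmaG2 = 4, sigmaGxE2 = 2,
                           sigmaBR2 = 0.5, sigmaErr2 = 2, sigmaEnv2 = 0,
                           missingRate = 0, nBlocksPerRep = 4, seed = 101,
                           envMeans = NULL, nReplicates = 2) {
  if (is.null(envMeans)) envMeans <- seq(30, 36, length.out = nEnvironments)
  simConfig(nGenotypes = nGenotypes, nEnvironments = nEnvironments,
    nMarkers = nMarkers, missingRate = missingRate,
    nReplicates = nReplicates, nBlocksPerRep = nBlocksPerRep,
    traits = list(list(name = "y", envMeans = envMeans, sigmaG2 = sigmaG2,
      sigmaGxE2 = sigmaGxE2, sigmaBR2 = sigmaBR2, sigmaErr2 = sigmaErr2,
      sigmaEnv2 = sigmaEnv2)),
    seed = seed)
}

# MarkerMatrix from a plain matrix, adding dimnames
toyMarkers <- function(m, imputed = FALSE) {
  dimnames(m) <- list(sprintf("G%02d", seq_len(nrow(m))),
    sprintf("M%02d", seq_len(ncol(m))))
  MarkerMatrix(m, imputed = imputed)
}

# all-cells data.frame for a genotype x environment grid
cellGrid <- function(genos, envs) {
  expand.grid(genotype = genos, env = envs, KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE)
}

# independent restricted log-likelihood evaluator used as the grid-search
# oracle: generic dense formula via solve()/determinant(), a different code
# path from the package's chol()-based profiled criterion
rllOracle <- function(l1, l2, y, X, Z1, Z2) {
  n <- length(y); p <- ncol(X)
  H <- diag(n) + l1 * tcrossprod(Z1) + l2 * tcrossprod(Z2)
  Hi <- solve(H)
  XtHiX <- t(X) %*% Hi %*% X
  beta <- solve(XtHiX, t(X) %*% Hi %*% y)
  r <- y - X %*% beta
  s2 <- drop(t(r) %*% Hi %*% r) / (n - p)
  -0.5 * ((n - p) * log(s2) +
    as.numeric(determinant(H, logarithm = TRUE)$modulus) +
    as.numeric(determinant(XtHiX, logarithm = TRUE)$modulus) +
    (n - p) * (1 + log(2 * pi)))
}

# GRM from freshly simulated markers, dropping monomorphic columns that can
# arise at tiny sample sizes
simGRM <- function(n, p = 60, seed = 5, mafRange = c(0.25, 0.5)) {
  cfg <- oneTraitConfig(nGenotypes = n, nMarkers = p, seed = seed)
  cfg$mafRange <- mafRange
  m <- as.matrix(imputeMean(simulateMarkers(cfg)))
  m <- m[, apply(m, 2, sd) > 0, drop = FALSE]
  computeGRM(MarkerMatrix(m, imputed = TRUE))
}
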