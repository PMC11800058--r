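#' Default trait templates for the synthetic generator
#'
#' Two traits on the scale of a cassava advanced-yield MET: root dry matter
#' content (\code{dm}, grams per 100 g, per-environment means around 30-37,
#' entry-mean heritability ~0.83) and fresh root yield (\code{fyld}, kg per
#' plot, means around 17-30, heritability ~0.72). Variance components were
#' chosen once so that total within-environment genetic variance matches the
#' trait SDs and the entry-mean heritability at two replicates
#' H2 = sigma_g2 / (sigma_g2 + sigma_e2 / r) lands in the target range; the
#' genetic variance is split between a genotype main effect and a
#' genotype-by-environment deviation (substantial G x E for fyld, milder for
#' dm).
#'
#' @param nEnvironments number of environments; per-environment means are
#'   interpolated across the template range when different from 5.
#' @return list of trait specifications, each with \code{name},
#'   \code{envMeans}, \code{sigmaG2} (genotype main), \code{sigmaGxE2}
#'   (interaction), \code{sigmaBR2} (block-in-rep), \code{sigmaErr2} (plot
#'   error) and \code{sigmaEnv2} (random environment deviation, 0 by default:
#'   environment-level variation enters through the means).
#' @export
defaultTraits <- function(nEnvironments = 5) {
  tmpl <- list(
    dm = list(means = c(37.31, 34.04, 30.52, 33.60, 29.84),
      sigmaG2 = 4.3, sigmaGxE2 = 1.5, sigmaBR2 = 0.6, sigmaErr2 = 2.4),
    fyld = list(means = c(30.44, 21.41, 23.49, 25.74, 17.21),
      sigmaG2 = 23, sigmaGxE2 = 15, sigmaBR2 = 6, sigmaErr2 = 30)
  )
  lapply(names(tmpl), function(nm) {
    t <- tmpl[[nm]]
    means <- if (nEnvironments == 5) t$means else
      seq(min(t$means), max(t$means), length.out = nEnvironments)
    list(name = nm, envMeans = means, sigmaG2 = t$sigmaG2,
      sigmaGxE2 = t$sigmaGxE2, sigmaBR2 = t$sigmaBR2,
      sigmaErr2 = t$sigmaErr2, sigmaEnv2 = 0)
  })
}

#' Configuration for the synthetic MET generator
#'
#' Bundles everything the generator needs: population and trial dimensions,
#' marker allele-frequency range and missingness, field-design structure
#' (replicates, incomplete blocks within replicate), and per-trait variance
#' components.
#'
#' @param nGenotypes,nEnvironments,nMarkers counts (defaults emulate a 435
#'   genotype x 5 environment trial genotyped at ~3000 post-QC SNPs).
#' @param mafRange minor-allele-frequency range in (0, 0.5]; each marker's MAF
#'   is drawn uniformly from it.
#' @param missingRate i.i.d. missing-call probability in [0, 1).
#' @param nReplicates complete replications per environment.
#' @param nBlocksPerRep incomplete blocks nested within each replicate.
#' @param traits list of trait specifications as in \code{\link{defaultTraits}}.
#' @param repEffects fixed replicate effects (length nReplicates); default 0.
#' @param seed integer master seed.
#' @return object of class \code{SimConfig} (validated list).
#' @export
simConfig <- function(nGenotypes = 435, nEnvironments = 5, nMarkers = 2984,
                      mafRange = c(0.05, 0.5), missingRate = 0.03,
                      nReplicates = 2, nBlocksPerRep = 5,
                      traits = defaultTraits(nEnvironments),
                      repEffects = rep(0, nReplicates), seed = 1L) {
  cfg <- list(nGenotypes = as.integer(nGenotypes),
    nEnvironments = as.integer(nEnvironments),
    nMarkers = as.integer(nMarkers), mafRange = as.numeric(mafRange),
    missingRate = as.numeric(missingRate),
    nReplicates = as.integer(nReplicates),
    nBlocksPerRep = as.integer(nBlocksPerRep), traits = traits,
    repEffects = as.numeric(repEffects), seed = as.integer(seed))
  if (cfg$nGenotypes < 1 || cfg$nEnvironments < 1 || cfg$nMarkers < 1)
    stopf("counts must be positive")
  if (length(cfg$mafRange) != 2 || cfg$mafRange[1] <= 0 ||
      cfg$mafRange[2] > 0.5 || cfg$mafRange[1] > cfg$mafRange[2])
    stopf("mafRange must lie within (0, 0.5] with min <= max")
  if (cfg$missingRate < 0 || cfg$missingRate >= 1)
    stopf("missingRate must be in [0, 1)")
  if (cfg$nReplicates < 1) stopf("nReplicates must be positive")
  if (length(cfg$repEffects) != cfg$nReplicates)
    stopf("repEffects must have one entry per replicate")
  for (t in cfg$traits) {
    vc <- unlist(t[c("sigmaG2", "sigmaGxE2", "sigmaBR2", "sigmaErr2",
      "sigmaEnv2")])
    if (any(vc < 0)) stopf("trait '%s': variances must be >= 0", t$name)
    if (length(t$envMeans) != cfg$nEnvironments)
      stopf("trait '%s': envMeans must have one entry per environment",
        t$name)
  }
  structure(cfg, class = "SimConfig")
}

envNames <- function(n) sprintf("Env%d", seq_len(n))
genoNames <- function(n) sprintf("G%04d", seq_len(n))

#' Simulate a SNP marker matrix
#'
#' Draws, for each marker, a minor allele frequency uniformly from the
#' configured range and samples genotype classes from the Hardy-Weinberg
#' proportions (q^2, 2pq, p^2) for the 0/1/2 additive coding (0 = homozygous
#' minor). Missing calls are placed i.i.d. at the configured rate.
#'
#' @param config a \code{\link{simConfig}}.
#' @param seed optional integer overriding \code{config$seed}.
#' @return A \linkS4class{MarkerMatrix}.
#' @export
simulateMarkers <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "SimConfig"))
  n <- config$nGenotypes; p <- config$nMarkers
  withSeed(seed, {
    maf <- stats::runif(p, config$mafRange[1], config$mafRange[2])
    # per-marker HW class probabilities; coding counts the major allele
    m <- vapply(seq_len(p), function(j) {
      q <- maf[j]
      sample(c(0, 1, 2), n, replace = TRUE,
        prob = c(q^2, 2 * q * (1 - q), (1 - q)^2))
    }, numeric(n))
    if (config$missingRate > 0)
      m[stats::runif(length(m)) < config$missingRate] <- NA_real_
    dimnames(m) <- list(genoNames(n), sprintf("M%05d", seq_len(p)))
    MarkerMatrix(m)
  })
}

#' Simulate true genetic signals from markers
#'
#' Generates the ground truth the prediction models target. Genotype main
#' values arise from the GBLUP generative model: i.i.d. Gaussian effects on
#' the column-standardized markers, scaled so the main values have variance
#' \code{sigmaG2}. Genotype-by-environment deviations are drawn per
#' environment with covariance \code{sigmaGxE2 * G} within environment and
#' zero covariance across environments (the reaction-norm kernel), realized
#' as independent marker-effect draws per environment. Each cell's value is
#' the exact sum environment effect + genotype main + G x E deviation.
#'
#' @param markers a complete (no missing) \linkS4class{MarkerMatrix}; impute
#'   first if needed.
#' @param config a \code{\link{simConfig}}.
#' @param seed optional integer overriding \code{config$seed}.
#' @return object of class \code{TrueSignals}: a long data.frame
#'   (trait, env, genotype, envEffect, genoMain, gxe, value) plus the config.
#' @export
simulateEffects <- function(markers, config, seed = config$seed) {
  stopifnot(is(markers, "MarkerMatrix"), inherits(config, "SimConfig"))
  m <- as.matrix(markers)
  if (anyNA(m))
    stopf("marker matrix has missing entries; run imputeMean() first")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stopf("zero-variance marker column(s): %s — cannot standardize",
      paste(utils::head(colnames(m)[sds == 0], 5), collapse = ", "))
  X <- scale(m)                       # centered, unit sample variance
  n <- nrow(X); p <- ncol(X)
  envs <- envNames(config$nEnvironments)
  withSeed(seed, {
    out <- lapply(config$traits, function(tr) {
      b <- stats::rnorm(p, 0, sqrt(tr$sigmaG2 / p))
      gMain <- drop(X %*% b)
      envEff <- tr$envMeans +
        if (tr$sigmaEnv2 > 0)
          stats::rnorm(length(envs), 0, sqrt(tr$sigmaEnv2)) else 0
      perEnv <- lapply(seq_along(envs), function(l) {
        gxe <- if (tr$sigmaGxE2 > 0)
          drop(X %*% stats::rnorm(p, 0, sqrt(tr$sigmaGxE2 / p)))
        else numeric(n)
        data.frame(trait = tr$name, env = envs[l], genotype = rownames(X),
          envEffect = envEff[l], genoMain = gMain, gxe = gxe,
          value = envEff[l] + gMain + gxe, stringsAsFactors = FALSE)
      })
      do.call(rbind, perEnv)
    })
    structure(list(signals = do.call(rbind, out), config = config),
      class = "TrueSignals")
  })
}

#' Simulate plot-level phenotype records
#'
#' Expands the true genetic cell values into an incomplete-block field layout:
#' within each environment and replicate, genotypes are assigned at random to
#' \code{nBlocksPerRep} blocks; each plot record is cell value + fixed
#' replicate effect + block-in-rep deviation (variance \code{sigmaBR2}) +
#' plot error (variance \code{sigmaErr2}). The block layout is shared across
#' traits (one field), block and plot deviations are trait-specific.
#'
#' @param signals a \code{TrueSignals} from \code{\link{simulateEffects}}.
#' @param config a \code{\link{simConfig}}.
#' @param seed optional integer overriding \code{config$seed}.
#' @return data.frame of class \code{PlotTable}: columns env, genotype, rep,
#'   block, then one column per trait.
#' @export
simulatePlots <- function(signals, config, seed = config$seed) {
  stopifnot(inherits(signals, "TrueSignals"), inherits(config, "SimConfig"))
  if (config$nReplicates < 1) stopf("nReplicates must be positive")
  sg <- signals$signals
  envs <- unique(sg$env)
  genos <- unique(sg$genotype)
  nG <- length(genos)
  nB <- config$nBlocksPerRep
  blockSize <- ceiling(nG / nB)
  if (nB * blockSize < nG)
    stopf("blocks per rep x block size must cover all genotypes")
  traitNames <- vapply(config$traits, `[[`, "", "name")
  cellVal <- lapply(traitNames, function(tn) {
    s <- sg[sg$trait == tn, ]
    v <- matrix(NA_real_, nG, length(envs), dimnames = list(genos, envs))
    v[cbind(match(s$genotype, genos), match(s$env, envs))] <- s$value
    v
  })
  names(cellVal) <- traitNames
  withSeed(seed, {
    rows <- vector("list", length(envs) * config$nReplicates)
    k <- 0
    for (l in seq_along(envs)) {
      for (r in seq_len(config$nReplicates)) {
        blk <- rep(seq_len(nB), each = blockSize)[seq_len(nG)]
        blk <- blk[sample.int(nG)]           # randomized block assignment
        rec <- data.frame(env = envs[l], genotype = genos, rep = r,
          block = blk, stringsAsFactors = FALSE)
        for (tn in traitNames) {
          tr <- config$traits[[match(tn, traitNames)]]
          blockEff <- stats::rnorm(nB, 0, sqrt(tr$sigmaBR2))
          err <- stats::rnorm(nG, 0, sqrt(tr$sigmaErr2))
          rec[[tn]] <- cellVal[[tn]][cbind(seq_len(nG), l)] +
            config$repEffects[r] + blockEff[blk] + err
        }
        k <- k + 1
        rows[[k]] <- rec
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("PlotTable", "data.frame")
    out
  })
}

#' One-call synthetic MET dataset
#'
#' Convenience wrapper chaining \code{\link{simulateMarkers}} (plus mean
#' imputation), \code{\link{simulateEffects}} and \code{\link{simulatePlots}}
#' with substream seeds derived from the config seed.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with \code{markers} (imputed), \code{markersRaw},
#'   \code{signals}, \code{plots}.
#' @export
simulateMET <- function(config) {
  mk <- simulateMarkers(config, seed = childSeed(config$seed, 1))
  mki <- if (anyNA(as.matrix(mk))) imputeMean(mk) else mk
  # at small sample sizes a drawn marker can be monomorphic; such columns
  # carry no information and cannot be standardized, so drop them (a real
  # post-QC matrix has none: MAF 0 fails the frequency filter)
  mm <- as.matrix(mki)
  sds <- apply(mm, 2, stats::sd)
  if (any(sds == 0))
    mki <- MarkerMatrix(mm[, sds > 0, drop = FALSE],
      imputed = mki@imputed)
  sig <- simulateEffects(mki, config, seed = childSeed(config$seed, 2))
  pl <- simulatePlots(sig, config, seed = childSeed(config$seed, 3))
  list(markers = mki, markersRaw = mk, signals = sig, plots = pl)
}
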