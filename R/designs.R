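# Sparse-testing allocation designs.
#
# Construction follows the two-step recipe: (1) partition the full genotype
# list into n_env equal, disjoint base sets — the largest all-NOL allocation;
# (2) for any NOL/OL composition, drop genotypes from each environment's base
# set (subsetting first when the training-set size is below the base size),
# pool the dropped genotypes, and promote a subset of the pool to OL status:
# observed in every environment. Each environment's testing set holds every
# genotype not observed there (minus, at reduced TRS sizes, the genotypes
# discarded when the base set was subset), so its size — total minus base
# size — is the same for every composition and predictive abilities are
# comparable across designs.

#' Partition genotypes into disjoint per-environment base sets
#'
#' @param genotypeIDs character vector of unique genotype IDs; its length
#'   must be divisible by \code{nEnv}.
#' @param nEnv number of environments.
#' @param seed optional integer seed.
#' @return named list of \code{nEnv} disjoint ID sets of equal size whose
#'   union is the input.
#' @export
partitionNOL <- function(genotypeIDs, nEnv, seed = NULL) {
  n <- length(genotypeIDs)
  if (anyDuplicated(genotypeIDs)) stopf("genotype IDs must be unique")
  if (n %% nEnv != 0)
    stopf("%d genotypes are not divisible by %d environments (remainder %d)",
      n, nEnv, n %% nEnv)
  withSeed(seed, {
    shuffled <- sample(genotypeIDs)
    sets <- split(shuffled, rep(seq_len(nEnv), each = n / nEnv))
    names(sets) <- envNames(nEnv)
    sets
  })
}

#' Build a NOL/OL allocation design
#'
#' Generalizes the masking procedure to any composition: from each
#' environment's base set (subset at random to \code{trsSize} genotypes when
#' smaller than the base size), \code{nOL} genotypes are dropped, leaving
#' \code{trsSize - nOL} non-overlapping genotypes; one overlapping set of
#' size \code{nOL} is drawn from the pooled dropped genotypes and marked
#' observed in every environment. Each environment's testing set is the set
#' of genotypes unobserved there, excluding genotypes discarded during base
#' subsetting; its size is constant (total minus base size) across all
#' compositions, and it is always disjoint from the observed set.
#'
#' @param basePartition named list of disjoint equal-size base sets (from
#'   \code{\link{partitionNOL}}).
#' @param trsSize training-set size per environment.
#' @param nOL number of overlapping genotypes (0 <= nOL <= trsSize).
#' @param seed optional integer seed.
#' @return An \linkS4class{AllocationDesign}.
#' @export
buildDesign <- function(basePartition, trsSize, nOL, seed = NULL) {
  baseSize <- unique(lengths(basePartition))
  if (length(baseSize) != 1) stopf("base sets must have equal size")
  trsSize <- as.integer(trsSize); nOL <- as.integer(nOL)
  if (nOL < 0 || nOL > trsSize || trsSize > baseSize)
    stopf("need 0 <= nOL <= trsSize <= base size (%d)", baseSize)
  allIDs <- unlist(basePartition, use.names = FALSE)
  nNOL <- trsSize - nOL
  withSeed(seed, {
    dropped <- character(0)
    baseDrop <- vector("list", length(basePartition))
    names(baseDrop) <- names(basePartition)
    nolSets <- basePartition
    for (e in names(basePartition)) {
      base <- basePartition[[e]]
      sub <- if (trsSize < baseSize) sample(base, trsSize) else base
      baseDrop[[e]] <- setdiff(base, sub)
      keep <- if (nNOL > 0) sample(sub, nNOL) else character(0)
      dropped <- c(dropped, setdiff(sub, keep))
      nolSets[[e]] <- keep
    }
    if (nOL > length(dropped))
      stopf("OL size %d exceeds the dropped pool (%d)", nOL, length(dropped))
    olSet <- if (nOL > 0) sample(dropped, nOL) else character(0)
    # testing set: every genotype unobserved in the environment, excluding
    # the genotypes discarded when the base set was subset to a reduced TRS
    # size; its size is constant at (total - base size) for every design
    testing <- lapply(names(basePartition), function(e) {
      setdiff(allIDs, c(nolSets[[e]], olSet, baseDrop[[e]]))
    })
    names(testing) <- names(basePartition)
    new("AllocationDesign", trsSize = trsSize, nNOL = nNOL, nOL = nOL,
      olSet = olSet, nolSets = nolSets, testingSets = testing,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  })
}

#' Exact bookkeeping counts of an allocation design
#'
#' Counts are taken from the design's sets themselves (not from formulas):
#' observed plots = sum over environments of observed-set sizes; unique
#' observed = genotypes observed in at least one environment; unobserved =
#' the rest of \code{allIDs}.
#'
#' @param design an \linkS4class{AllocationDesign}.
#' @param allIDs the full genotype list the design was built from.
#' @return list with \code{observedPlots}, \code{uniqueObserved},
#'   \code{unobserved}, \code{perEnvTRS}.
#' @export
designCounts <- function(design, allIDs) {
  obs <- observedSets(design)
  perEnv <- lengths(obs)
  seen <- unique(unlist(obs, use.names = FALSE))
  list(observedPlots = sum(perEnv), uniqueObserved = length(seen),
    unobserved = length(setdiff(allIDs, seen)), perEnvTRS = perEnv)
}

#' Enumerate the standard allocation-design grid
#'
#' For each training-set size, the NOL count decreases in steps of 10 from
#' the full size down through 7 and then 0, the OL count making up the
#' difference; with sizes 87, 77, 67, 57, 47 this reproduces the standard
#' grid rows (87/0, 77/10, ..., 7/80, 0/87 etc.).
#'
#' @param trsSizes training-set sizes (default c(87, 77, 67, 57, 47)).
#' @return data.frame with columns trs_size, n_nol, n_ol, label ("NOL/OL").
#' @export
enumerateTable1 <- function(trsSizes = c(87, 77, 67, 57, 47)) {
  rows <- lapply(trsSizes, function(t) {
    nol <- seq(t, min(t, 7), by = -10)
    nol <- unique(c(nol[nol >= 0], 0))
    data.frame(trs_size = t, n_nol = nol, n_ol = t - nol)
  })
  out <- do.call(rbind, rows)
  out$label <- sprintf("%d/%d", out$n_nol, out$n_ol)
  out
}

#' Classify a design into cross-validation scheme CV1 or CV2
#'
#' CV1 covers the fully overlapping designs (no NOL genotypes): every
#' training genotype is observed in all environments, so every testing
#' genotype is unseen in every environment. All other compositions are CV2
#' (testing genotypes may be seen in some environments but not others).
#'
#' @param design an \linkS4class{AllocationDesign}, or a numeric NOL count.
#' @return "CV1" or "CV2".
#' @export
classifyCV <- function(design) {
  nNOL <- if (is(design, "AllocationDesign")) design@nNOL else design
  if (nNOL == 0) "CV1" else "CV2"
}

#' Serialize / read an allocation design as JSON
#' @param design an \linkS4class{AllocationDesign}.
#' @param path file path.
#' @export
writeDesignJSON <- function(design, path) {
  obj <- list(trs_size = design@trsSize, n_nol = design@nNOL,
    n_ol = design@nOL, seed = design@seed, ol_set = design@olSet,
    nol_sets = design@nolSets, testing_sets = design@testingSets)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeDesignJSON
#' @export
readDesignJSON <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  asChr <- function(x) lapply(x, as.character)
  new("AllocationDesign", trsSize = as.integer(o$trs_size),
    nNOL = as.integer(o$n_nol), nOL = as.integer(o$n_ol),
    olSet = as.character(o$ol_set), nolSets = asChr(o$nol_sets),
    testingSets = asChr(o$testing_sets),
    seed = if (is.null(o$seed)) NA_integer_ else as.integer(o$seed))
}
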