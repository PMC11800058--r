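#' @import methods
NULL

#' MarkerMatrix: genotypes x markers in additive coding
#'
#' Container for a biallelic SNP matrix in additive 0/1/2 coding (0 =
#' homozygous minor, 1 = heterozygous, 2 = homozygous major), with missing
#' calls as \code{NA}. After mean imputation entries are real-valued and the
#' \code{imputed} flag is set.
#'
#' @slot geno numeric matrix, rows = genotypes, columns = markers; dimnames
#'   carry the genotype and marker identifiers.
#' @slot imputed logical scalar; \code{TRUE} once missing entries have been
#'   replaced by marker means (entries then need not lie in \{0,1,2\}).
#' @export
setClass("MarkerMatrix",
  representation(geno = "matrix", imputed = "logical"),
  prototype(geno = matrix(numeric(0), 0, 0), imputed = FALSE)
)

setValidity("MarkerMatrix", function(object) {
  m <- object@geno
  msgs <- character(0)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msgs <- c(msgs, "geno must have genotype rownames and marker colnames")
  else {
    if (anyDuplicated(rownames(m))) msgs <- c(msgs, "duplicated genotype IDs")
    if (anyDuplicated(colnames(m))) msgs <- c(msgs, "duplicated marker IDs")
  }
  if (!is.numeric(m)) msgs <- c(msgs, "geno must be numeric")
  if (length(object@imputed) != 1L) msgs <- c(msgs, "imputed must be scalar")
  if (is.numeric(m) && !isTRUE(object@imputed)) {
    v <- m[!is.na(m)]
    if (length(v) && !all(v %in% c(0, 1, 2)))
      msgs <- c(msgs, "non-imputed entries must be in {0, 1, 2, NA}")
  }
  if (isTRUE(object@imputed) && anyNA(m))
    msgs <- c(msgs, "imputed matrix must be complete")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MarkerMatrix
#'
#' @param geno numeric matrix (genotypes x markers) with dimnames.
#' @param imputed logical; set \code{TRUE} for a post-imputation real-valued
#'   matrix.
#' @return A \linkS4class{MarkerMatrix}.
#' @export
MarkerMatrix <- function(geno, imputed = FALSE) {
  new("MarkerMatrix", geno = geno, imputed = imputed)
}

#' GRM: genomic relationship matrix
#'
#' Symmetric genotypes x genotypes relationship matrix G = XX'/p built from a
#' column-centered, column-standardized marker matrix X with p markers.
#'
#' @slot mat symmetric numeric matrix with genotype IDs as dimnames.
#' @slot nMarkers integer; the number of markers p used to build the matrix.
#' @export
setClass("GRM",
  representation(mat = "matrix", nMarkers = "integer"),
  prototype(mat = matrix(numeric(0), 0, 0), nMarkers = 0L)
)

setValidity("GRM", function(object) {
  m <- object@mat
  msgs <- character(0)
  if (nrow(m) != ncol(m)) msgs <- c(msgs, "matrix must be square")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    msgs <- c(msgs, "unique genotype IDs required as dimnames")
  if (!isTRUE(all.equal(rownames(m), colnames(m))))
    msgs <- c(msgs, "row and column IDs must agree")
  if (nrow(m) && !isSymmetric(m, tol = 1e-10))
    msgs <- c(msgs, "matrix must be symmetric")
  if (nrow(m)) {
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(sum(diag(m)), 1))
      msgs <- c(msgs, "matrix must be positive semi-definite")
  }
  if (length(msgs)) msgs else TRUE
})

#' Stage1Fit: per-environment mixed-model fit
#'
#' REML fit of the single-environment model
#' y = mu + rep (fixed) + genotype (random) + block-in-rep (random) + error,
#' holding the variance components, genotype BLUPs and the restricted
#' log-likelihood.
#'
#' @slot environment,trait identifiers of the fitted slice.
#' @slot mu fitted overall mean (intercept averaged over replicate effects).
#' @slot repEffects named fixed replicate effects (treatment contrasts).
#' @slot varComp named numeric: \code{genotype}, \code{block}, \code{error}.
#' @slot blups named numeric of genotype BLUPs (deviations from mu).
#' @slot logLik restricted log-likelihood at the optimum.
#' @slot convergence list with optimizer details.
#' @export
setClass("Stage1Fit",
  representation(environment = "character", trait = "character",
    mu = "numeric", repEffects = "numeric", varComp = "numeric",
    blups = "numeric", logLik = "numeric", convergence = "list")
)

setValidity("Stage1Fit", function(object) {
  msgs <- character(0)
  need <- c("genotype", "block", "error")
  if (!all(need %in% names(object@varComp)))
    msgs <- c(msgs, "varComp must name genotype, block and error")
  else if (any(object@varComp[need] < 0))
    msgs <- c(msgs, "variance components must be non-negative")
  if (is.null(names(object@blups))) msgs <- c(msgs, "blups must be named")
  if (length(msgs)) msgs else TRUE
})

#' AllocationDesign: sparse-testing allocation of genotypes to environments
#'
#' A training-set allocation combining non-overlapping (NOL) genotypes, each
#' observed in exactly one environment, with overlapping (OL) genotypes
#' observed in every environment. Testing sets are fixed per environment.
#'
#' @slot trsSize training-set size per environment (nNOL + nOL).
#' @slot nNOL,nOL counts of non-overlapping and overlapping genotypes.
#' @slot olSet character vector of OL genotype IDs (common to all
#'   environments).
#' @slot nolSets named list (by environment) of disjoint NOL genotype ID sets.
#' @slot testingSets named list (by environment) of genotype IDs predicted and
#'   scored in that environment.
#' @slot seed integer seed used for the random draws (NA if none).
#' @export
setClass("AllocationDesign",
  representation(trsSize = "integer", nNOL = "integer", nOL = "integer",
    olSet = "character", nolSets = "list", testingSets = "list",
    seed = "integer")
)

setValidity("AllocationDesign", function(object) {
  msgs <- character(0)
  if (object@nNOL + object@nOL != object@trsSize)
    msgs <- c(msgs, "nNOL + nOL must equal trsSize")
  if (length(object@olSet) != object@nOL)
    msgs <- c(msgs, "olSet size must equal nOL")
  nol <- unlist(object@nolSets, use.names = FALSE)
  if (anyDuplicated(nol))
    msgs <- c(msgs, "NOL sets must be pairwise disjoint")
  if (length(intersect(nol, object@olSet)))
    msgs <- c(msgs, "NOL sets must be disjoint from the OL set")
  if (any(lengths(object@nolSets) != object@nNOL))
    msgs <- c(msgs, "every NOL set must have nNOL genotypes")
  if (!identical(sort(names(object@nolSets)), sort(names(object@testingSets))))
    msgs <- c(msgs, "nolSets and testingSets must cover the same environments")
  for (e in names(object@nolSets)) {
    obs <- c(object@nolSets[[e]], object@olSet)
    if (length(intersect(obs, object@testingSets[[e]])))
      msgs <- c(msgs, sprintf("testing set overlaps observed set in %s", e))
  }
  if (length(msgs)) msgs else TRUE
})

#' KernelSet: covariance kernels over genotype-in-environment cells
#'
#' The cell-level covariance structures of one prediction model: an
#' environment block kernel and an i.i.d. line kernel (M1), plus a genomic
#' main-effect kernel (M2), plus the reaction-norm interaction kernel -- the
#' Hadamard product of the genomic and environment kernels (M3).
#'
#' @slot cells data.frame with columns \code{genotype} and \code{env}, one row
#'   per cell, unique.
#' @slot kernels named list of symmetric cells x cells matrices; names drawn
#'   from \code{env}, \code{line}, \code{genomic}, \code{gxe}.
#' @slot model one of "M1", "M2", "M3".
#' @export
setClass("KernelSet",
  representation(cells = "data.frame", kernels = "list", model = "character")
)

setValidity("KernelSet", function(object) {
  msgs <- character(0)
  if (!all(c("genotype", "env") %in% names(object@cells)))
    msgs <- c(msgs, "cells needs genotype and env columns")
  else if (anyDuplicated(object@cells[c("genotype", "env")]))
    msgs <- c(msgs, "cells must be unique")
  if (!object@model %in% c("M1", "M2", "M3"))
    msgs <- c(msgs, "model must be M1, M2 or M3")
  n <- nrow(object@cells)
  for (lab in names(object@kernels)) {
    K <- object@kernels[[lab]]
    if (!all(dim(K) == n)) {
      msgs <- c(msgs, sprintf("kernel %s has wrong dimension", lab))
      next
    }
    if (n && !isSymmetric(unname(K), tol = 1e-8))
      msgs <- c(msgs, sprintf("kernel %s must be symmetric", lab))
  }
  if ("gxe" %in% names(object@kernels) && n) {
    K <- object@kernels[["gxe"]]
    diffEnv <- outer(object@cells$env, object@cells$env, "!=")
    if (any(abs(K[diffEnv]) > 1e-12))
      msgs <- c(msgs, "gxe kernel must vanish across environments")
  }
  if (length(msgs)) msgs else TRUE
})

#' ModelFit: fitted Bayesian kernel model
#'
#' Posterior summaries from the Gibbs sampler: variance components per kernel
#' plus the error variance, and the posterior-mean prediction for every cell
#' (observed and masked).
#'
#' @slot cells data.frame with columns genotype, env, observed (logical).
#' @slot predictions numeric, one prediction per cell (same order as cells).
#' @slot mu posterior-mean intercept.
#' @slot varComp named numeric: one component per kernel plus \code{error}.
#' @slot diagnostics list: chain length, burn-in, thinning, saved draws,
#'   effective sample sizes of the variance-component chains.
#' @export
setClass("ModelFit",
  representation(cells = "data.frame", predictions = "numeric",
    mu = "numeric", varComp = "numeric", diagnostics = "list")
)

setValidity("ModelFit", function(object) {
  msgs <- character(0)
  if (length(object@predictions) != nrow(object@cells))
    msgs <- c(msgs, "one prediction per cell required")
  if (any(!is.finite(object@predictions)))
    msgs <- c(msgs, "predictions must be finite")
  if (any(object@varComp < 0))
    msgs <- c(msgs, "variance components must be non-negative")
  if (length(msgs)) msgs else TRUE
})
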