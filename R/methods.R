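# Accessors and show() methods for the S4 containers.

#' @describeIn MarkerMatrix genotype IDs
#' @param x a \linkS4class{MarkerMatrix}.
#' @export
setMethod("genotypeIDs", "MarkerMatrix", function(x) rownames(x@geno))

#' @describeIn MarkerMatrix marker IDs
#' @export
setMethod("markerIDs", "MarkerMatrix", function(x) colnames(x@geno))

#' @describeIn GRM genotype IDs
#' @param x a \linkS4class{GRM}.
#' @export
setMethod("genotypeIDs", "GRM", function(x) rownames(x@mat))

#' Coerce a MarkerMatrix to its underlying matrix
#' @param x a \linkS4class{MarkerMatrix}.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "MarkerMatrix", function(x, ...) x@geno)

#' Coerce a GRM to its underlying matrix
#' @param x a \linkS4class{GRM}.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "GRM", function(x, ...) x@mat)

#' @describeIn Stage1Fit variance components (genotype, block, error)
#' @param x a \linkS4class{Stage1Fit}.
#' @export
setMethod("varianceComponents", "Stage1Fit", function(x) x@varComp)

#' @describeIn Stage1Fit genotype BLUPs
#' @export
setMethod("blups", "Stage1Fit", function(x) x@blups)

#' @describeIn ModelFit posterior-mean variance components
#' @param x a \linkS4class{ModelFit}.
#' @export
setMethod("varianceComponents", "ModelFit", function(x) x@varComp)

#' @describeIn ModelFit per-cell predictions
#' @export
setMethod("cellPredictions", "ModelFit", function(x) {
  cbind(x@cells, prediction = x@predictions)
})

#' @describeIn AllocationDesign observed (training) sets per environment
#' @param x an \linkS4class{AllocationDesign}.
#' @export
setMethod("observedSets", "AllocationDesign", function(x) {
  lapply(x@nolSets, function(s) c(s, x@olSet))
})

#' @describeIn AllocationDesign testing sets per environment
#' @export
setMethod("testingSets", "AllocationDesign", function(x) x@testingSets)

setMethod("show", "MarkerMatrix", function(object) {
  m <- object@geno
  cat(sprintf("MarkerMatrix: %d genotypes x %d markers (%s)\n",
    nrow(m), ncol(m),
    if (object@imputed) "imputed" else
      sprintf("%.1f%% missing", 100 * mean(is.na(m)))))
})

setMethod("show", "GRM", function(object) {
  cat(sprintf("GRM: %d genotypes, built from %d markers; mean diagonal %.3f\n",
    nrow(object@mat), object@nMarkers,
    if (nrow(object@mat)) mean(diag(object@mat)) else NA_real_))
})

setMethod("show", "Stage1Fit", function(object) {
  vc <- object@varComp
  cat(sprintf("Stage1Fit [%s, %s]: mu = %.3f\n", object@environment,
    object@trait, object@mu))
  cat(sprintf("  varComp: genotype %.4g, block %.4g, error %.4g\n",
    vc["genotype"], vc["block"], vc["error"]))
  cat(sprintf("  %d genotype BLUPs; REML logLik %.3f\n",
    length(object@blups), object@logLik))
})

setMethod("show", "AllocationDesign", function(object) {
  cat(sprintf("AllocationDesign %d/%d (TRS %d per environment, %d environments)\n",
    object@nNOL, object@nOL, object@trsSize, length(object@nolSets)))
  cat(sprintf("  scheme %s; testing-set size %d per environment\n",
    classifyCV(object), length(object@testingSets[[1]])))
})

setMethod("show", "KernelSet", function(object) {
  cat(sprintf("KernelSet %s: %d cells; kernels: %s\n", object@model,
    nrow(object@cells), paste(names(object@kernels), collapse = ", ")))
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit: %d cells (%d observed), mu = %.3f\n",
    nrow(object@cells), sum(object@cells$observed), object@mu))
  vc <- object@varComp
  cat("  varComp:", paste(sprintf("%s %.4g", names(vc), vc),
    collapse = ", "), "\n")
})
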