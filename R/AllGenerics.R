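#' Genotype identifiers of an object
#' @param x a sparseMET object.
#' @return character vector of genotype IDs.
#' @export
setGeneric("genotypeIDs", function(x) standardGeneric("genotypeIDs"))

#' Marker identifiers of an object
#' @param x a sparseMET object.
#' @return character vector of marker IDs.
#' @export
setGeneric("markerIDs", function(x) standardGeneric("markerIDs"))

#' Variance components of a fitted model
#' @param x a fitted object.
#' @return named numeric vector of variance components.
#' @export
setGeneric("varianceComponents",
  function(x) standardGeneric("varianceComponents"))

#' Per-cell predictions of a fitted model
#' @param x a \linkS4class{ModelFit}.
#' @return data.frame with genotype, env, observed flag and prediction.
#' @export
setGeneric("cellPredictions", function(x) standardGeneric("cellPredictions"))

#' Genotype BLUPs of a stage-1 fit
#' @param x a \linkS4class{Stage1Fit}.
#' @return named numeric vector of BLUPs (deviations from the fitted mean).
#' @export
setGeneric("blups", function(x) standardGeneric("blups"))

#' Observed (training) genotype sets of an allocation design
#' @param x an \linkS4class{AllocationDesign}.
#' @return named list by environment: NOL set union OL set.
#' @export
setGeneric("observedSets", function(x) standardGeneric("observedSets"))

#' Testing genotype sets of an allocation design
#' @param x an \linkS4class{AllocationDesign}.
#' @return named list by environment.
#' @export
setGeneric("testingSets", function(x) standardGeneric("testingSets"))
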