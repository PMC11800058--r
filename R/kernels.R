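# Covariance kernels over genotype-in-environment cells.
#
# With Z_g and Z_E the incidence matrices connecting cells to genotypes and
# environments:
#   env     Z_E Z_E'        1 when two cells share the environment
#   line    Z_g Z_g'        1 when two cells share the genotype (iid line)
#   genomic Z_g G Z_g'      genomic relationship between the cells' genotypes
#   gxe     (Z_g G Z_g') o (Z_E Z_E')   Hadamard product: reaction-norm GxE,
#                           genomic relationship within environment, zero
#                           across environments.
# M1 uses {env, line}; M2 adds genomic; M3 adds gxe. PSD holds by
# construction: the indicator kernels are Gram matrices, the genomic kernel
# inherits PSD from G (checked when the GRM is built), and the Hadamard
# product of PSD matrices is PSD (Schur product theorem).

#' Build the covariance kernels of a prediction model
#'
#' @param cells data.frame with columns \code{genotype} and \code{env}, one
#'   row per unique genotype-in-environment cell.
#' @param grm a \linkS4class{GRM} covering every cell genotype (required for
#'   M2/M3).
#' @param model "M1" (environment + iid line), "M2" (+ genomic main effect)
#'   or "M3" (+ reaction-norm genomic-by-environment interaction).
#' @return A \linkS4class{KernelSet}.
#' @export
buildKernels <- function(cells, grm = NULL, model = c("M3", "M2", "M1")) {
  model <- match.arg(model)
  stopifnot(is.data.frame(cells), all(c("genotype", "env") %in% names(cells)))
  cells <- data.frame(genotype = as.character(cells$genotype),
    env = as.character(cells$env), stringsAsFactors = FALSE)
  if (anyDuplicated(cells)) stopf("cells must be unique")
  sameEnv <- outer(cells$env, cells$env, "==") * 1
  sameLine <- outer(cells$genotype, cells$genotype, "==") * 1
  kernels <- list(env = sameEnv, line = sameLine)
  if (model %in% c("M2", "M3")) {
    if (is.null(grm)) stopf("model %s needs a GRM", model)
    G <- as.matrix(grm)
    missing <- setdiff(unique(cells$genotype), rownames(G))
    if (length(missing))
      stopf("genotype(s) absent from the GRM: %s",
        paste(utils::head(missing, 5), collapse = ", "))
    idx <- match(cells$genotype, rownames(G))
    Kg <- G[idx, idx]
    dimnames(Kg) <- NULL
    kernels$genomic <- Kg
    if (model == "M3") kernels$gxe <- Kg * sameEnv
  }
  new("KernelSet", cells = cells, kernels = kernels, model = model)
}
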