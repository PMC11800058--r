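#' SNP quality control
#'
#' Filters markers on per-marker statistics computed from non-missing calls
#' only (computing them after imputation would bias allele frequencies toward
#' the mean): missing fraction, minor allele frequency, call rate and
#' heterozygosity fraction. A marker is removed iff (strict inequalities, so
#' boundary values are kept) missing > maxMissing, MAF < minMAF, call rate <
#' minCallRate, or heterozygosity > maxHet. Missing fraction and call rate
#' are complements of the same statistic; when both thresholds fire, both
#' reasons are reported. A marker with zero non-missing calls is removed with
#' reason \code{no_calls}, not an error.
#'
#' @param markers a \linkS4class{MarkerMatrix} with entries in \{0,1,2,NA\}.
#' @param maxMissing maximum tolerated missing fraction (default 0.20).
#' @param minMAF minimum minor allele frequency (default 0.05).
#' @param minCallRate minimum call rate (default 0.80).
#' @param maxHet maximum heterozygosity fraction (default 0.95).
#' @return list with \code{markers} (the filtered \linkS4class{MarkerMatrix})
#'   and \code{report}: a data.frame with one row per input marker (maf,
#'   missing, callRate, het, status = "kept" or semicolon-joined removal
#'   reasons from \{max_missing, min_maf, low_callrate, max_het, no_calls\}).
#' @export
qcFilter <- function(markers, maxMissing = 0.20, minMAF = 0.05,
                     minCallRate = 0.80, maxHet = 0.95) {
  stopifnot(is(markers, "MarkerMatrix"))
  if (isTRUE(markers@imputed))
    stopf("qcFilter expects raw 0/1/2 calls; run QC before imputation")
  m <- as.matrix(markers)
  nGeno <- nrow(m)
  miss <- colMeans(is.na(m))
  callRate <- 1 - miss
  nCalls <- colSums(!is.na(m))
  pMajor <- colMeans(m, na.rm = TRUE) / 2      # coding counts major allele
  maf <- pmin(pMajor, 1 - pMajor)
  het <- colMeans(m == 1, na.rm = TRUE)
  status <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    if (nCalls[j] == 0L) { status[j] <- "no_calls"; next }
    reasons <- c(
      if (miss[j] > maxMissing) "max_missing",
      if (callRate[j] < minCallRate) "low_callrate",
      if (maf[j] < minMAF) "min_maf",
      if (het[j] > maxHet) "max_het")
    status[j] <- if (length(reasons)) paste(reasons, collapse = ";") else
      "kept"
  }
  report <- data.frame(marker = colnames(m), maf = maf, missing = miss,
    callRate = callRate, het = het, status = status,
    stringsAsFactors = FALSE, row.names = NULL)
  keep <- status == "kept"
  out <- MarkerMatrix(m[, keep, drop = FALSE])
  list(markers = out, report = report, nKept = sum(keep),
    nRemoved = sum(!keep), nGenotypes = nGeno)
}

#' Mean imputation of missing marker calls
#'
#' Replaces each missing entry by the mean of its marker's non-missing calls;
#' observed calls are untouched.
#'
#' @param markers a \linkS4class{MarkerMatrix}.
#' @return an imputed \linkS4class{MarkerMatrix} (real-valued entries).
#' @export
imputeMean <- function(markers) {
  stopifnot(is(markers, "MarkerMatrix"))
  m <- as.matrix(markers)
  bad <- colSums(!is.na(m)) == 0L
  if (any(bad))
    stopf("marker(s) with no calls (%s): run qcFilter() first",
      paste(utils::head(colnames(m)[bad], 5), collapse = ", "))
  if (anyNA(m)) {
    mu <- colMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 2]]
  }
  MarkerMatrix(m, imputed = TRUE)
}

#' Genomic relationship matrix G = XX'/p
#'
#' Centers every marker column to mean zero, scales it to unit sample
#' variance (n-1 denominator), and forms G = XX'/p over the p markers. The
#' diagonal then averages to one as p grows and G is positive semi-definite
#' by construction.
#'
#' @param markers a complete \linkS4class{MarkerMatrix} (impute first).
#' @return A \linkS4class{GRM}.
#' @export
computeGRM <- function(markers) {
  stopifnot(is(markers, "MarkerMatrix"))
  m <- as.matrix(markers)
  if (anyNA(m)) stopf("marker matrix has missing entries; impute first")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stopf("zero-variance marker column(s): %s",
      paste(utils::head(colnames(m)[sds == 0], 5), collapse = ", "))
  X <- scale(m)
  G <- tcrossprod(X) / ncol(X)
  G <- (G + t(G)) / 2                       # enforce exact symmetry
  dimnames(G) <- list(rownames(m), rownames(m))
  new("GRM", mat = G, nMarkers = ncol(m))
}

# ---- plain-text I/O -------------------------------------------------------

#' Write / read a MarkerMatrix as CSV
#'
#' Rows are genotypes (first column \code{genotype}), columns are marker IDs,
#' missing calls are \code{NA}.
#' @param markers a \linkS4class{MarkerMatrix}.
#' @param path file path.
#' @export
writeMarkerCSV <- function(markers, path) {
  m <- as.matrix(markers)
  df <- data.frame(genotype = rownames(m), m, check.names = FALSE,
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMarkerCSV
#' @param imputed logical flag passed to the constructor.
#' @export
readMarkerCSV <- function(path, imputed = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  MarkerMatrix(m, imputed = imputed)
}

#' Read a PLINK .raw-style additive genotype file
#'
#' Whitespace-separated text with a header; the standard leading columns
#' (FID, IID, PAT, MAT, SEX, PHENOTYPE) are tolerated and, beyond using IID
#' (or FID when IID is absent) as the genotype ID, ignored. Remaining columns
#' are additive 0/1/2 dosages with NA for missing.
#'
#' @param path file path.
#' @return A \linkS4class{MarkerMatrix}.
#' @export
readPlinkRaw <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
    stringsAsFactors = FALSE, na.strings = c("NA", "-9"))
  meta <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
    names(df))
  id <- if ("IID" %in% names(df)) df$IID else if ("FID" %in% names(df))
    df$FID else stopf("no IID/FID column in %s", path)
  m <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(id)
  MarkerMatrix(m)
}

#' Write / read a GRM as CSV with an ID header
#' @param grm a \linkS4class{GRM}.
#' @param path file path.
#' @export
writeGRMcsv <- function(grm, path) {
  m <- as.matrix(grm)
  df <- data.frame(genotype = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGRMcsv
#' @param nMarkers marker count to record (unknown from the CSV alone).
#' @export
readGRMcsv <- function(path, nMarkers = NA_integer_) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m <- (m + t(m)) / 2
  new("GRM", mat = m, nMarkers = as.integer(nMarkers))
}
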