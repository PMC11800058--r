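# Experiment grid: predictive ability and MSE per environment under
# sparse-testing allocation designs and CV1/CV2.

#' Predictive ability (Pearson correlation)
#'
#' Pearson product-moment correlation between predicted and observed values,
#' computed within an environment's testing set.
#'
#' @param pred,obs numeric vectors of equal length (>= 3), both non-constant.
#' @return correlation in [-1, 1].
#' @export
predictiveAbility <- function(pred, obs) {
  if (length(pred) != length(obs)) stopf("pred and obs lengths differ")
  if (length(pred) < 3) stopf("need at least 3 pairs")
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0)
    stopf("correlation undefined for constant input")
  stats::cor(pred, obs)
}

#' Mean squared error
#'
#' MSE = (1/n) sum (pred_i - obs_i)^2 over the testing set.
#'
#' @param pred,obs numeric vectors of equal length (>= 1).
#' @return non-negative scalar.
#' @export
mse <- function(pred, obs) {
  if (length(pred) != length(obs)) stopf("pred and obs lengths differ")
  if (!length(pred)) stopf("need at least one pair")
  mean((pred - obs)^2)
}

#' Run the sparse-testing experiment grid
#'
#' For each replicate: draw a fresh base partition, build every allocation
#' design in the grid, and for each (design, model, trait) fit the kernel
#' model on the observed cells (adjusted phenotypes) and predict all masked
#' cells; record within-environment predictive ability and MSE over that
#' environment's fixed testing set. Replicates re-randomize both the base
#' partition and the NOL/OL assignments.
#'
#' @param blups long data.frame (env, genotype, trait, value) of stage-1
#'   adjusted phenotypes covering every (genotype, environment).
#' @param grm a \linkS4class{GRM} covering every genotype.
#' @param grid data.frame with columns trs_size, n_nol, n_ol (see
#'   \code{\link{enumerateTable1}}).
#' @param models subset of c("M1","M2","M3").
#' @param traits trait names; default: all in \code{blups}.
#' @param nReplicates number of replicate re-randomizations (default 10).
#' @param seed master seed; one substream per (replicate, design, model).
#' @param nIter,burnIn,thin,priorDf sampler settings passed to
#'   \code{\link{fitModel}}.
#' @param verbose print progress.
#' @return data.frame of class \code{EvalTable}: one row per (trait, model,
#'   trs_size, design label, environment, replicate) with columns r (predictive
#'   ability), mse, n_test, cv (CV1/CV2) and error (NA unless that fit
#'   failed, in which case the message is recorded and the run continues).
#' @export
runExperiment <- function(blups, grm, grid = enumerateTable1(),
                          models = c("M1", "M2", "M3"), traits = NULL,
                          nReplicates = 10, seed = 1L, nIter = 12000,
                          burnIn = 2000, thin = 5, priorDf = 5,
                          verbose = FALSE) {
  stopifnot(is(grm, "GRM"))
  if (is.null(traits)) traits <- unique(blups$trait)
  envs <- sort(unique(blups$env))
  genos <- sort(unique(blups$genotype))
  missingG <- setdiff(genos, genotypeIDs(grm))
  if (length(missingG))
    stopf("GRM misses genotype(s): %s",
      paste(utils::head(missingG, 5), collapse = ", "))
  cmplt <- table(blups$trait)
  if (any(cmplt != length(envs) * length(genos)))
    stopf("blups must cover every (genotype, environment) per trait")
  cells <- expand.grid(genotype = genos, env = envs,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ksets <- lapply(stats::setNames(models, models),
    function(m) buildKernels(cells, grm, m))
  respByTrait <- lapply(stats::setNames(traits, traits), function(tn) {
    b <- blups[blups$trait == tn, ]
    v <- numeric(nrow(cells))
    v[match(paste(b$genotype, b$env), paste(cells$genotype, cells$env))] <-
      b$value
    v
  })
  rows <- list()
  for (rep_i in seq_len(nReplicates)) {
    repSeed <- childSeed(seed, rep_i)
    partition <- partitionNOL(genos, length(envs), seed = repSeed)
    names(partition) <- envs
    for (d in seq_len(nrow(grid))) {
      design <- buildDesign(partition, grid$trs_size[d], grid$n_ol[d],
        seed = childSeed(repSeed, d))
      obsSets <- observedSets(design)
      isObs <- rep(FALSE, nrow(cells))
      for (e in envs) {
        sel <- cells$env == e
        isObs[sel] <- cells$genotype[sel] %in% obsSets[[e]]
      }
      label <- sprintf("%d/%d", design@nNOL, design@nOL)
      for (m in models) for (tn in traits) {
        fitSeed <- childSeed(repSeed, d * 1000L + match(m, models) * 10L +
          match(tn, traits))
        resp <- respByTrait[[tn]]
        res <- tryCatch({
          fit <- fitModel(ksets[[m]], ifelse(isObs, resp, NA_real_),
            observed = isObs, nIter = nIter, burnIn = burnIn, thin = thin,
            priorDf = priorDf, seed = fitSeed)
          pc <- fit@predictions
          lapply(envs, function(e) {
            tst <- testingSets(design)[[e]]
            idx <- which(cells$env == e & cells$genotype %in% tst)
            # a model with no information on unseen genotypes (e.g. the
            # no-marker model under a fully overlapping design) predicts a
            # constant: its predictive ability is undefined and recorded NA
            constPred <- stats::sd(pc[idx]) == 0
            data.frame(trait = tn, model = m, trs_size = design@trsSize,
              design = label, env = e, replicate = rep_i,
              r = if (constPred) NA_real_ else
                predictiveAbility(pc[idx], resp[idx]),
              mse = mse(pc[idx], resp[idx]), n_test = length(idx),
              cv = classifyCV(design),
              error = if (constPred) "constant predictions" else
                NA_character_,
              stringsAsFactors = FALSE)
          })
        }, error = function(err) {
          lapply(envs, function(e) data.frame(trait = tn, model = m,
            trs_size = design@trsSize, design = label, env = e,
            replicate = rep_i, r = NA_real_, mse = NA_real_,
            n_test = NA_integer_, cv = classifyCV(design),
            error = conditionMessage(err), stringsAsFactors = FALSE))
        })
        rows <- c(rows, res)
        if (verbose)
          message(sprintf("rep %d design %s model %s trait %s", rep_i,
            label, m, tn))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("EvalTable", "data.frame")
  out
}

#' Aggregate an EvalTable over replicates and environments
#'
#' Arithmetic means of per-environment predictive ability and MSE, first the
#' replicate-level mean across environments, then the average of the 10 (or
#' however many) replicate values — equivalently the mean over all matching
#' records.
#'
#' @param evalTable output of \code{\link{runExperiment}}.
#' @return data.frame keyed by (trait, model, trs_size, design) with mean_r,
#'   mean_mse, cv, n (records averaged).
#' @export
aggregateEval <- function(evalTable) {
  ok <- !is.na(evalTable$mse)
  et <- evalTable[ok, , drop = FALSE]
  agg <- stats::aggregate(cbind(r, mse) ~ trait + model + trs_size + design,
    data = et, FUN = function(v) mean(v, na.rm = TRUE),
    na.action = stats::na.pass)
  names(agg)[names(agg) == "r"] <- "mean_r"
  names(agg)[names(agg) == "mse"] <- "mean_mse"
  cvmap <- unique(et[c("trait", "model", "trs_size", "design", "cv")])
  agg <- merge(agg, cvmap,
    by = c("trait", "model", "trs_size", "design"), all.x = TRUE)
  cnt <- stats::aggregate(list(n = et$r),
    by = et[c("trait", "model", "trs_size", "design")], FUN = length)
  merge(agg, cnt, by = c("trait", "model", "trs_size", "design"))
}
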