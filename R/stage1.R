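# Stage 1: per-environment mixed model
#   y_ijk = mu + L_i + R_j + B_k(R_j) + e_ijk
# with genotype L and block-in-rep B random, replicate R fixed. REML is done
# by direct maximization of the restricted log-likelihood over the two
# variance ratios (genotype and block, relative to the error variance), with
# the error variance profiled out analytically. With H(lambda) =
# I + l1 Z1 Z1' + l2 Z2 Z2' and P the REML projection under H, the profiled
# criterion is
#   -2 RLL = (n-p) log(sigma2_hat) + log|H| + log|X' H^-1 X| + const,
#   sigma2_hat = y' P y / (n - p).
# Negative ratio estimates are handled by the box constraint lambda >= 0
# (boundary REML).

remlCriterion <- function(lambda, y, X, Z1, Z2) {
  n <- length(y); p <- ncol(X)
  H <- diag(n) + lambda[1] * tcrossprod(Z1) + lambda[2] * tcrossprod(Z2)
  R <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(R)) return(list(value = 1e10))
  A <- backsolve(R, cbind(X, y), transpose = TRUE)   # R'^-1 [X y]
  M <- crossprod(A)                                  # [X y]' H^-1 [X y]
  XtHX <- M[1:p, 1:p, drop = FALSE]
  XtHy <- M[1:p, p + 1]
  ytHy <- M[p + 1, p + 1]
  cXtHX <- tryCatch(chol(XtHX), error = function(e) NULL)
  if (is.null(cXtHX)) return(list(value = 1e10))
  beta <- backsolve(cXtHX, backsolve(cXtHX, XtHy, transpose = TRUE))
  yPy <- ytHy - sum(XtHy * beta)
  sigma2 <- yPy / (n - p)
  if (sigma2 <= 0) return(list(value = 1e10))
  logdetH <- 2 * sum(log(diag(R)))
  logdetXtHX <- 2 * sum(log(diag(cXtHX)))
  val <- (n - p) * log(sigma2) + logdetH + logdetXtHX +
    (n - p) * (1 + log(2 * pi))
  list(value = val, beta = beta, sigma2 = sigma2, R = R)
}

#' Fit the stage-1 per-environment mixed model
#'
#' REML fit of y = mu + replicate (fixed) + genotype (random) + block
#' nested in replicate (random) + error for one environment and one trait,
#' yielding variance components, genotype BLUPs and the restricted
#' log-likelihood. BLUPs are computed from the mixed-model equations at the
#' REML estimates; the reported adjusted phenotype for a genotype is
#' \code{mu + BLUP}.
#'
#' @param plots a plot-level phenotype data.frame with columns \code{env},
#'   \code{genotype}, \code{rep}, \code{block} and the trait column.
#' @param environment environment ID to fit.
#' @param trait name of the trait column.
#' @return A \linkS4class{Stage1Fit}.
#' @export
fitStage1 <- function(plots, environment, trait) {
  d <- plots[plots$env == environment, , drop = FALSE]
  if (!nrow(d)) stopf("no plots for environment '%s'", environment)
  if (!trait %in% names(d)) stopf("no trait column '%s'", trait)
  d <- d[is.finite(d[[trait]]), , drop = FALSE]
  geno <- factor(d$genotype)
  repf <- factor(d$rep)
  blk <- factor(paste(d$rep, d$block, sep = ":"))
  if (nlevels(geno) < 2) stopf("need >= 2 genotypes in '%s'", environment)
  y <- d[[trait]]
  X <- stats::model.matrix(~repf)
  if (qr(X)$rank < ncol(X))
    stopf("singular fixed-effects design (replicates) in '%s'", environment)
  Z1 <- stats::model.matrix(~ 0 + geno)
  Z2 <- stats::model.matrix(~ 0 + blk)
  obj <- function(l) remlCriterion(l, y, X, Z1, Z2)$value
  opt <- stats::nlminb(c(0.5, 0.1), obj, lower = c(0, 0), upper = c(1e10, 1e10),
    control = list(iter.max = 500, eval.max = 1000))
  if (!opt$convergence %in% c(0L, 1L) &&
      !grepl("relative convergence|singular convergence|X convergence|both X",
        opt$message %||% ""))
    stopf("stage-1 REML did not converge in '%s' (%d iterations): %s",
      environment, opt$iterations, opt$message)
  lam <- pmax(opt$par, 0)
  fit <- remlCriterion(lam, y, X, Z1, Z2)
  sigma2 <- fit$sigma2
  beta <- fit$beta
  # BLUP: u1 = l1 * Z1' H^-1 (y - X beta)
  resid <- y - drop(X %*% beta)
  Hinv_r <- backsolve(fit$R, backsolve(fit$R, resid, transpose = TRUE))
  u1 <- lam[1] * drop(crossprod(Z1, Hinv_r))
  names(u1) <- levels(geno)
  mu <- mean(drop(X %*% beta))
  repEff <- if (ncol(X) > 1) beta[-1] else numeric(0)
  names(repEff) <- colnames(X)[-1]
  new("Stage1Fit", environment = as.character(environment), trait = trait,
    mu = mu, repEffects = repEff,
    varComp = c(genotype = lam[1] * sigma2, block = lam[2] * sigma2,
      error = sigma2),
    blups = u1, logLik = -fit$value / 2,
    convergence = list(code = opt$convergence, iterations = opt$iterations,
      message = opt$message, lambda = lam))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Entry-mean broad-sense heritability
#'
#' H2 = sigma_g2 / (sigma_g2 + sigma_e2 / r) with r replicates per
#' environment; the genotypic and error variances are the stage-1 components.
#'
#' @param sigmaG2 genotypic variance (>= 0).
#' @param sigmaE2 error variance (>= 0).
#' @param r number of replicates (>= 1).
#' @return heritability in [0, 1].
#' @export
heritability <- function(sigmaG2, sigmaE2, r) {
  if (sigmaG2 < 0 || sigmaE2 < 0) stopf("variances must be >= 0")
  if (r < 1) stopf("r must be >= 1")
  if (sigmaG2 == 0 && sigmaE2 == 0)
    stopf("heritability undefined when both variances are zero")
  sigmaG2 / (sigmaG2 + sigmaE2 / r)
}

#' Stage-1 analysis of all environments and traits
#'
#' Runs \code{\link{fitStage1}} per (environment, trait) and assembles the
#' adjusted phenotypes (mu + BLUP) together with a per-environment summary of
#' mean, variance components, entry-mean heritability and SD of the adjusted
#' values.
#'
#' @param plots plot-level phenotype data.frame.
#' @param traits trait column names; default: every column beyond
#'   env/genotype/rep/block.
#' @return list with \code{blups} (long data.frame env, genotype, trait,
#'   value), \code{summary} (per environment x trait), \code{fits} (list of
#'   \linkS4class{Stage1Fit}).
#' @export
fitStage1All <- function(plots, traits = NULL) {
  if (is.null(traits))
    traits <- setdiff(names(plots), c("env", "genotype", "rep", "block"))
  envs <- unique(plots$env)
  fits <- list(); rowsB <- list(); rowsS <- list()
  for (tn in traits) for (e in envs) {
    f <- fitStage1(plots, e, tn)
    fits[[paste(e, tn, sep = ".")]] <- f
    adj <- f@mu + f@blups
    rowsB[[length(rowsB) + 1]] <- data.frame(env = e,
      genotype = names(adj), trait = tn, value = unname(adj),
      stringsAsFactors = FALSE)
    r <- length(unique(plots$rep[plots$env == e]))
    vc <- f@varComp
    rowsS[[length(rowsS) + 1]] <- data.frame(env = e, trait = tn,
      mean = f@mu, sigmaG2 = unname(vc["genotype"]),
      sigmaBR2 = unname(vc["block"]), sigmaE2 = unname(vc["error"]),
      H2 = heritability(vc[["genotype"]], vc[["error"]], r),
      SD = stats::sd(adj), nReplicates = r, stringsAsFactors = FALSE)
  }
  blups <- do.call(rbind, rowsB)
  class(blups) <- c("EnvBLUPs", "data.frame")
  list(blups = blups, summary = do.call(rbind, rowsS), fits = fits)
}
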