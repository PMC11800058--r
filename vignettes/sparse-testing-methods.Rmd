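---
title: "Sparse-testing designs and genomic prediction for multi-environment trials"
author: "sparseMET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-testing designs and genomic prediction for multi-environment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparseMET)
```

## The problem

Multi-environment trials (METs) in plant breeding phenotype every candidate
genotype in every environment, which is the dominant cost of a breeding
cycle. *Sparse testing* allocates each genotype to only a subset of
environments and predicts the unobserved genotype-in-environment cells from
genome-wide markers, trading plots for predictions. The design question is
how to split the per-environment training set between *non-overlapping*
(NOL) genotypes — each tested in exactly one environment, maximizing the
diversity of sampled haplotypes — and *overlapping* (OL) genotypes tested in
all environments, which connect the environments. sparseMET implements the
whole loop: synthetic MET generation, marker QC and genomic relationships,
two-stage mixed-model analysis, three prediction models, allocation-design
construction, and cross-validated evaluation.

The package emulates a cassava advanced-yield MET: 435 genotypes in five
site-by-year environments, two replications in an alpha-lattice layout,
two traits (root dry matter content `dm` and fresh root yield `fyld`),
and roughly 3,000 post-QC SNPs.

## Stage 1: per-environment mixed model

Within each environment the plot model is

$$y_{ijk} = \mu + L_i + R_j + B_{k(j)} + e_{ijk},$$

with genotype $L_i \sim N(0, \sigma_L^2)$ and block-within-replicate
$B_{k(j)} \sim N(0, \sigma_{BR}^2)$ random, replicate $R_j$ fixed, and
$e_{ijk} \sim N(0, \sigma_e^2)$. `fitStage1()` maximizes the restricted
likelihood directly: with $H(\lambda) = I + \lambda_1 Z_1 Z_1' + \lambda_2
Z_2 Z_2'$ the error variance is profiled out analytically and a bounded
quasi-Newton search runs over the two variance ratios, so estimates are
exactly checkable against a dense grid search of the same criterion (the
test suite does this) and against lme4. Negative component estimates are
handled by the box constraint $\lambda \ge 0$ — standard boundary REML.
Genotype BLUPs come from the mixed-model equations at the optimum, and the
adjusted phenotype passed to stage 2 is $\hat\mu + \text{BLUP}$.

Entry-mean broad-sense heritability is
$H^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2 / r)$ with $r$ replicates
(`heritability()`), taking $\sigma_g^2$ as the stage-1 genotype component.

## Stage 2: three prediction models

Responses are the stage-1 adjusted phenotypes $y_{il}$, one per
genotype-in-environment cell. No precision weighting is applied — the
stage-1 design is balanced, so the adjusted values carry near-equal
information. All models share an intercept and Gaussian error:

* **M1 (E + L):** random environment effect plus an i.i.d. genotype (line)
  effect. No markers: unseen genotypes can only be predicted through their
  own phenotypes in other environments.
* **M2 (E + L + G):** adds the genomic value $g_i = \sum_m x_{im} b_m$ with
  i.i.d. marker effects, equivalently $g \sim N(0, G\sigma_g^2)$ with
  $G = XX'/p$ the genomic relationship matrix from the column-centered,
  column-standardized marker matrix. G lets information flow between
  relatives, but a genotype's genomic value is the same in every
  environment.
* **M3 (E + L + G + G×E):** the reaction-norm interaction, with covariance
  $(Z_g G Z_g') \circ (Z_E Z_E')$ — the Hadamard (cell-wise) product of the
  genomic kernel and the same-environment indicator. The interaction is
  genomically structured within an environment and vanishes across
  environments.

`buildKernels()` materializes these cell-level kernels; positive
semi-definiteness follows by construction (Gram matrices, a PSD $G$ checked
when the GRM is built, and the Schur product theorem for the Hadamard term).

### Fitting

`fitModel()` is a Gibbs sampler with one variance component per kernel and
scaled-inverse-$\chi^2$ priors (default df 5, prior modes set by splitting
the sample variance of the observed response equally across terms plus
error — weakly informative once a few hundred cells are observed). Each
kernel is eigendecomposed once on the observed cells and its random effect
sampled in the eigenbasis, where the conditional posterior of a whole block
is Gaussian with diagonal precision: a sweep costs $O(n \, r_k)$ per kernel.
Masked cells are predicted through their kernel covariances with the
observed cells, $\hat u = K_{\text{all,obs}} K_{\text{obs,obs}}^{+}
\bar u_{\text{obs}}$, evaluated at posterior means (the prediction is linear
in the sampled quantities). Default chain settings are 12,000 iterations,
2,000 burn-in, thinning 5; the experiment driver exposes all of them, and
the package's own experiments use shorter chains (800–2,500 iterations)
because the posterior for a few hundred cells mixes within a few hundred
sweeps — block updates in an orthogonal basis have low autocorrelation
(effective sample sizes are reported in the fit diagnostics).

Eigenvalues below $10^{-8}$ of the largest are truncated; a kernel whose
smallest eigenvalue is below $-10^{-6}$ of the largest magnitude is rejected
as non-PSD. With the error variance pinned near zero the fit interpolates
the observations, and with all variances fixed the posterior mean equals the
closed-form GLS/BLUP solve — both are test oracles.

## Allocation designs

`partitionNOL()` splits the genotype list into $n_{env}$ equal disjoint base
sets (87 at trial scale) — the all-NOL design in which all 435 genotypes are
observed exactly once. `buildDesign()` generalizes: from each environment's
base set (randomly subset for reduced training-set sizes), $n_{OL}$
genotypes are dropped; one OL set of that size is drawn from the pooled
dropped genotypes and observed in *every* environment. The grid
`enumerateTable1()` steps the NOL count down by 10 from the full size
through 7 and then 0, for training sizes 87…47 (40 designs). Fully
overlapping designs realize the CV1 scheme (testing genotypes unseen
anywhere); all others are CV2 (`classifyCV()`).

Each environment's testing set contains every genotype unobserved there,
excluding genotypes discarded during base subsetting, so its size is
constant — total minus base size, 348 at trial scale — for every
composition. This is the only definition that is simultaneously constant in
size and disjoint from every observed set once OL genotypes exist; a
"complement of the base partition" definition would place OL genotypes from
other environments' base sets inside their own training *and* testing sets.
Genotypes masked but not promoted to OL status remain eligible for testing
in their own environment: the cell is unobserved, which is what prediction
is scored on.

## Evaluation

`runExperiment()` runs the full grid: each replicate redraws the base
partition and all NOL/OL assignments; each (design, model, trait) fit
predicts all masked cells; predictive ability (Pearson correlation,
`predictiveAbility()`) and MSE (`mse()`) are computed within each
environment over its testing set and averaged over environments and
replicates (`aggregateEval()`) — means of per-environment metrics, not
pooled-cell metrics. A model that predicts a constant for a testing set
(M1 under CV1 has no information on unseen genotypes) gets an undefined
correlation, recorded as `NA` with a note; its MSE is still valid. Any fit
failure is recorded per record and the grid continues.

## The synthetic generator

`simConfig()`/`simulateMET()` generate data *from the model class being
tested*, so parameter recovery is well-posed: marker genotypes from
Hardy–Weinberg proportions at MAFs uniform in a configurable range (missing
calls i.i.d.); genotype main values $Xb$ with i.i.d. Gaussian marker
effects scaled to variance $\sigma_g^2$; G×E deviations drawn per
environment with covariance $\sigma_{gE}^2 G$ within and zero across
environments (the M3 kernel, realized as independent marker-effect draws per
environment); plot records add fixed replicate effects, block-in-rep
deviations and plot error under a randomized incomplete-block layout within
replicate. A resolvable alpha design is not constructed — the analysis model
only uses block-within-replicate nesting. Cell values decompose exactly into
stored components, and every entry point is seed-reproducible.

Default trait templates put the two traits on the cassava scale:
per-environment means 29.8–37.3 (`dm`) and 17.2–30.4 (`fyld`). Plot-level
block and error variances are rarely reported for such trials, so they were
chosen once to land entry-mean heritability in the ranges typical for these
traits (dm ≈ 0.80–0.87, fyld ≈ 0.61–0.78 at $r = 2$): dm
$\sigma_g^2 = 4.3, \sigma_{gE}^2 = 1.5, \sigma_{BR}^2 = 0.6,
\sigma_e^2 = 2.4$; fyld $\sigma_g^2 = 23, \sigma_{gE}^2 = 15,
\sigma_{BR}^2 = 6, \sigma_e^2 = 30$. Environment-level variation enters
through the fixed per-environment means (the random environment variance
defaults to 0). What the generator does *not* emulate: linkage
disequilibrium blocks, QTL architecture, population structure, spatial
field trends, or non-Gaussian error — so passing tests demonstrate internal
consistency of the machinery under its own assumptions, not robustness to
the ways real data violate them.

Monomorphic simulated markers (likely at small sample sizes) are dropped
before effect simulation: they carry no information and cannot be
standardized; a real post-QC matrix has none.

## Marker QC conventions

`qcFilter()` removes a marker iff missing fraction > 0.20, MAF < 0.05, call
rate < 0.80, or heterozygosity > 0.95 — strict inequalities, so boundary
values (e.g. MAF exactly 0.05) are kept. Statistics are computed on
non-missing calls *before* imputation, since mean imputation biases
frequencies toward the mean. Missing fraction and call rate are complements
of one statistic; both reasons are reported when both thresholds fire. Mean
imputation (`imputeMean()`) then fills remaining gaps. The GRM standardizes
by the per-column sample standard deviation ($n-1$), not the
$\sqrt{2p(1-p)}$ expected-heterozygosity scaling; the two differ by a
near-constant factor absorbed by the variance components.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at reduced scale,
chosen as the smallest sizes at which each property is informative:
grid-search REML equivalence on toys of a few genotypes; the closed-form
BLUP oracle on 20 genotypes; variance-component recovery of the M3
generative model at 200 genotypes × 5 environments over 6 replicates
(median relative error within 25%; markers are simulated at $p = 50$ so the
realized relationship matrix has enough off-diagonal structure to separate
the genomic kernel from the i.i.d. line kernel — with thousands of
independent markers on unrelated individuals the two kernels converge and
the split, though not their sum, is weakly identified); and the qualitative
sparse-testing trends at 100 genotypes × 5 environments, 3 designs per
training-set size, 10 replicates, asserted by one-sided sign tests at
$\alpha = 0.05$. The environment variance is excluded from recovery
comparisons: five environment levels cannot estimate a variance to within
25%.

Known limitations: stage 1 fits no spatial or row–column terms;
stage-2 responses are unweighted adjusted means; marker-effect models
(Bayes A/B/LASSO) and environmental-covariate reaction norms are out of
scope; training-set optimization (e.g. CD-mean) is not implemented — designs
are random draws by construction.

## A worked example

```{r, eval = FALSE}
cfg <- simConfig(nGenotypes = 100, nEnvironments = 5, nMarkers = 500,
  seed = 11)
dat <- simulateMET(cfg)
qc <- qcFilter(dat$markersRaw)
grm <- computeGRM(imputeMean(qc$markers))
s1 <- fitStage1All(dat$plots)
s1$summary[s1$summary$trait == "dm", c("env", "mean", "H2", "SD")]

grid <- enumerateTable1(c(20, 16, 12))
et <- runExperiment(s1$blups, grm, grid, nReplicates = 10, seed = 12,
  nIter = 2000, burnIn = 500)
aggregateEval(et)
```

The full pipeline, driven by a YAML config with a single master seed, is
`runPipeline()`; a command-line wrapper is installed under
`inst/scripts/run_pipeline.R`.
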