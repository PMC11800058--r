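# Seed handling: every stochastic entry point accepts `seed`; when given, the
# global RNG state is saved, the seed applied, and the state restored on exit,
# so seeded calls are pure functions of their arguments.

withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  seed <- as.integer(seed)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic substream seeds below 2^31 (Lehmer-style mixing); keeps one
# master seed spawning per-stage / per-replicate streams.
childSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + as.numeric(k) * 8191 +
    1) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# crude effective sample size from the empirical autocorrelation, truncated at
# the first non-positive lag (Geyer initial positive sequence, simplified)
essChain <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(as.numeric(n))
  rho <- stats::acf(x, lag.max = min(n - 1, 100), plot = FALSE)$acf[-1]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(rho))
}
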