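# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# Restores the caller's .Random.seed so seeded simulation calls do not
# perturb the session stream. seed = NULL leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive n reproducible sub-seeds from a master seed, each usable as set.seed
# input. Every stochastic stage of a pipeline gets its own explicit sub-seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Round half away from zero (display convention for the Ofm index:
# -3.33 -> -3, 18.6 -> 19, 2.5 -> 3, -2.5 -> -3).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Lower median: sorted value at position ceiling(n/2). For even n this is the
# conservative (lower) of the two central order statistics.
lower_median <- function(x) {
  n <- length(x)
  if (n == 0L) {
    return(NA_real_)
  }
  sort(x)[ceiling(n / 2)]
}

# Construct names are stored ASCII-safe ("5ORID-DR"); accept the Greek-letter
# spellings used in the literature ("5ORIΔ-ΔR") interchangeably.
canonical_construct <- function(x) {
  gsub("Δ", "D", x)
}

# Truncated-normal (>= 0) sampler by inverse CDF; sd = 0 collapses to mean.
rtnorm_pos <- function(n, mean, sd) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- numeric(n)
  fixed <- sd <= 0
  out[fixed] <- pmax(0, mean[fixed])
  if (any(!fixed)) {
    m <- mean[!fixed]
    s <- sd[!fixed]
    lo <- stats::pnorm(0, m, s)
    u <- stats::runif(sum(!fixed), min = lo, max = 1)
    out[!fixed] <- stats::qnorm(pmin(u, 1 - 1e-16), m, s)
  }
  out
}
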