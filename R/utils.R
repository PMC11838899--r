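# Internal utilities: seed handling and a left-truncated normal sampler.

# Evaluate `code` under a fixed RNG seed and restore the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Left-truncated normal draws on [lower, Inf) by inverse-CDF in the upper
# tail, which stays numerically stable even for extreme truncation points
# (the upper-tail probability is representable down to ~1e-300).
rtnorm_lower <- function(n, mean, sd, lower) {
  alpha <- (lower - mean) / sd
  pu <- stats::pnorm(alpha, lower.tail = FALSE)
  u <- stats::runif(n, 0, pu)
  u <- pmax(u, .Machine$double.xmin)  # guard qnorm(0) = -Inf
  mean + sd * stats::qnorm(u, lower.tail = FALSE)
}

# log of the truncated-normal normalizing constant P(X >= lower),
# X ~ N(mean, sd^2).
ltnorm_logconst <- function(mean, sd, lower) {
  stats::pnorm((mean - lower) / sd, log.p = TRUE)
}

# log density of a left-truncated normal.
dtnorm_lower_log <- function(x, mean, sd, lower) {
  ifelse(x < lower, -Inf,
         stats::dnorm(x, mean, sd, log = TRUE) -
           ltnorm_logconst(mean, sd, lower))
}
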