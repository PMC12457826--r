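# Internal helpers shared across modules.

# Run code under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Vectorized truncated-normal draws via the inverse-CDF method.
# lo/hi may be +-Inf and are recycled against mean/sd.
rtruncnorm_inv <- function(n, mean = 0, sd = 1, lo = -Inf, hi = Inf) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  # guard against bins with essentially no mass under the proposal
  eps <- 1e-12
  plo <- pmin(plo, 1 - eps)
  phi <- pmax(phi, plo + eps)
  u <- runif(n, plo, phi)
  q <- qnorm(u, mean, sd)
  pmin(pmax(q, lo), hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
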