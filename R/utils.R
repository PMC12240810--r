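# Internal helpers: seeding, hashing, logging, small numeric utilities.

MOD31 <- 2147483647 # 2^31 - 1, keeps every derived seed a valid 32-bit integer

#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' Every stochastic operation in the package draws its generator state from the
#' caller's seed plus a stable per-operation tag, so that independent pipeline
#' stages do not consume each other's random streams.
#'
#' @param seed Integer master seed.
#' @param tag Character tag naming the consuming operation.
#' @return An integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, tag = "") {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- string_hash(tag)
  ((abs(seed) %% 1000003) * 1009 + h) %% MOD31
}

# Polynomial rolling hash of a string into [0, 2^31 - 1). Pure double
# arithmetic; intermediate values stay below 2^53.
string_hash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% MOD31
  h
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% MOD31))
  expr
}

log_msg <- function(...) {
  message(sprintf(...))
}

# L2 norm / row-wise L2 normalization
l2_norm <- function(x) sqrt(sum(x^2))

l2_normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("cannot L2-normalize zero rows")
  m / nrm
}

# Stable log-sum-exp of a vector (supports -Inf entries)
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
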