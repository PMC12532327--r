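# Internal helpers shared across modules.

# Evaluate expr under a local RNG seed without touching the caller's stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Derive a reproducible per-stage sub-seed from one global seed; stays within
# the 32-bit integer range.
deriveSeed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Moments of a sample: mean, variance (n-1 denominator) and standardized
# skewness (population third moment); skewness of a constant sample is 0.
sampleMoments <- function(x) {
  n <- length(x)
  m <- mean(x)
  v <- stats::var(x)
  s2 <- mean((x - m)^2)
  sk <- if (s2 > 0) mean((x - m)^3) / s2^1.5 else 0
  c(mean = m, variance = v, skewness = sk)
}
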