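#' @keywords internal
"_PACKAGE"

# Deterministic seed derivation: every stage / subject / fold gets its own
# substream derived from a master seed, so stages are individually replayable.
# Mixing is a small multiplicative integer hash kept below 2^31 - 1.
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (tok in c(...)) {
    for (ch in utf8ToInt(as.character(tok))) {
      h <- (h * 31 + ch) %% m
    }
    h <- (h * 2654435761) %% m
  }
  as.integer(h)
}

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Moment-based summary used by the histogram and gradient families.
# Kurtosis is excess kurtosis (normal -> 0); zero variance yields
# skewness = kurtosis = 0 by the documented degenerate rule.
moment_stats <- function(v) {
  n <- length(v)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 <= 0) {
    return(c(mean = m, variance = 0, skewness = 0, kurtosis = 0))
  }
  m3 <- mean((v - m)^3)
  m4 <- mean((v - m)^4)
  c(mean = m, variance = m2, skewness = m3 / m2^1.5,
    kurtosis = m4 / m2^2 - 3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
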