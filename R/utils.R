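# Internal helpers shared across modules.

# Deterministic seed splitting: folds a master seed and any number of
# integer indices into a 31-bit stream so every derived seed is a valid R
# integer and every cell of a sweep gets an independent, reproducible seed.
deriveSeed <- function(master, ...) {
  idx <- c(...)
  s <- (abs(as.numeric(master)) + 1) %% 2147483647
  for (k in idx) {
    s <- (s * 69069 + abs(as.numeric(k)) + 1) %% 2147483647
  }
  as.integer(s)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# x * log(x) with the 0 * log(0) = 0 convention, elementwise.
plogp <- function(x) {
  y <- x
  pos <- x > 0
  y[pos] <- x[pos] * log(x[pos])
  y[!pos] <- 0
  y
}

# sample() without the length-1 surprise.
resample <- function(x, n = length(x)) {
  x[sample.int(length(x), n)]
}

upperTriVals <- function(w) {
  w[upper.tri(w)]
}
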