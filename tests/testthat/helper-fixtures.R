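# Fixtures and independent oracles shared across the test files. All
# fixtures are generated in code under fixed seeds.

# Random valid connectivity matrix with weights uniform on [-1, 1].
randomConnectivity <- function(N, seed, scale = 1) {
  withr::with_seed(seed, {
    w <- matrix(0, N, N)
    ut <- upper.tri(w)
    w[ut] <- runif(sum(ut), -scale, scale)
    w <- w + t(w)
    ConnectivityMatrix(w, subjectId = sprintf("rand%d", seed))
  })
}

# Two-node symmetric relay: |w| = strength above the threshold.
relayNetwork <- function(strength = 0.9, wt = 0.5) {
  m <- ConnectivityMatrix(matrix(c(0, strength, strength, 0), 2, 2), "relay")
  binarize(m, wt)
}

# Boundary-power draws conditioned on (wt, 1] via the conditional inverse
# CDF (the caller controls the RNG state).
bpTruncSample <- function(gamma, wt, n) {
  u <- runif(n)
  1 - (1 - wt) * (1 - u)^(1 / (gamma + 1))
}

# Independent transitivity oracle: 3 x triangles / connected triples via
# matrix algebra (trace(A^3) counts each triangle 6 times; each ordered
# path of length 2 is a connected triple counted twice).
transitivityOracle <- function(a) {
  a3 <- a %*% a %*% a
  deg <- rowSums(a)
  triples <- sum(deg * (deg - 1))
  if (triples == 0) return(0)
  sum(diag(a3)) / triples
}

# Independent connected-components oracle: plain BFS over the adjacency.
componentSizesOracle <- function(a) {
  n <- nrow(a)
  seen <- rep(FALSE, n)
  sizes <- integer(0)
  for (start in seq_len(n)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      size <- size + 1L
      nb <- which(a[v, ] > 0 & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# A connectivity matrix whose six upper-triangle |w| values are three
# copies of 0.1 and three of 0.3 (mean 0.2, population sd 0.1).
balancedFourNode <- function() {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[1, 3] <- w[1, 4] <- 0.1
  w[2, 3] <- w[2, 4] <- w[3, 4] <- 0.3
  ConnectivityMatrix(w + t(w), "balanced")
}
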