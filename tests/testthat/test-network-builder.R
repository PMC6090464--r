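test_that("the threshold rule uses the population sd of |w|", {
  m <- balancedFourNode() # six |w| values: three 0.1, three 0.3
  expect_equal(wt(computeThreshold(m, 0)), 0.2)
  expect_equal(wt(computeThreshold(m, 1)), 0.3)
  expect_equal(wt(computeThreshold(m, -2)), 0.0)

  # independent two-pass mean/sd oracle on a random 50-node matrix
  r <- randomConnectivity(50, seed = 3)
  v <- abs(weights(r)[upper.tri(weights(r))])
  mu <- sum(v) / length(v)
  sigma <- sqrt(sum((v - mu)^2) / length(v))
  for (n in c(-2, 0, 1.7)) {
    expect_equal(wt(computeThreshold(r, n)), mu + n * sigma,
                 tolerance = 1e-12)
  }

  flat <- ConnectivityMatrix(matrix(0.2, 3, 3) - diag(0.2, 3))
  expect_warning(ts <- computeThreshold(flat, 1), "identical")
  expect_equal(wt(ts), 0.2)
})

test_that("binarization keeps |w| strictly above the threshold, signs intact", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- -0.5
  w[1, 3] <- w[3, 1] <- 0.4
  m <- ConnectivityMatrix(w)

  net <- binarize(m, 0.4)
  expect_equal(adjacency(net)[1, 2], 1) # negative weight survives by magnitude
  expect_equal(retainedWeights(net)[1, 2], -0.5)
  expect_equal(adjacency(net)[1, 3], 0) # tie at the threshold is excluded

  net0 <- binarize(m, 0)
  expect_equal(adjacency(net0), (w != 0) * 1)
  expect_true(validObject(net0))

  # extreme thresholds bracket the possible adjacencies
  r <- randomConnectivity(12, seed = 5)
  expect_equal(sum(adjacency(binarize(r, max(abs(weights(r)))))), 0)
  expect_equal(adjacency(binarize(r, 0)),
               (weights(r) != 0) * 1)
})

test_that("largest-component fraction counts isolated nodes", {
  complete <- binarize(ConnectivityMatrix(matrix(0.9, 6, 6) - diag(0.9, 6)), 0.5)
  expect_equal(largestComponentFraction(complete), 1)

  w <- matrix(0, 6, 6)
  for (tri in list(1:3, 4:6))
    for (i in tri) for (j in tri) if (i != j) w[i, j] <- 0.9
  twoTriangles <- binarize(ConnectivityMatrix(w), 0.5)
  expect_equal(largestComponentFraction(twoTriangles), 0.5)

  edgeless <- binarize(randomConnectivity(10, seed = 1), 2)
  expect_equal(largestComponentFraction(edgeless), 0.1)
})

test_that("transitivity matches the closed forms", {
  w <- matrix(0, 3, 3)
  w[upper.tri(w)] <- 0.9
  triangle <- binarize(ConnectivityMatrix(w + t(w)), 0.5)
  expect_equal(clusteringCoefficient(triangle), 1)

  s <- matrix(0, 5, 5)
  s[1, 2:5] <- 0.9
  star <- binarize(ConnectivityMatrix(s + t(s)), 0.5)
  expect_equal(clusteringCoefficient(star), 0)

  # degree-4 ring lattice on 20 nodes: 3(k-2)/(4(k-1)) = 0.5
  N <- 20
  ring <- matrix(0, N, N)
  for (i in seq_len(N)) for (d in 1:2) {
    j <- ((i - 1 + d) %% N) + 1
    ring[i, j] <- ring[j, i] <- 0.9
  }
  rnet <- binarize(ConnectivityMatrix(ring), 0.5)
  expect_equal(clusteringCoefficient(rnet), 0.5)
  expect_true(clusteringCoefficient(rnet, type = "local-mean") >= 0)
})

test_that("topology measures agree with independent oracles on random graphs", {
  for (seed in 1:100) {
    m <- randomConnectivity(15, seed = 1000 + seed)
    net <- binarize(m, withr::with_seed(seed, runif(1, 0.2, 0.9)))
    a <- adjacency(net)
    expect_equal(clusteringCoefficient(net), transitivityOracle(a))
    sizes <- componentSizesOracle(a)
    expect_equal(largestComponentFraction(net), max(sizes) / 15)
  }
})

test_that("component fraction never grows as the threshold rises", {
  for (seed in 1:20) {
    m <- randomConnectivity(30, seed = 200 + seed)
    wts <- seq(0, max(abs(weights(m))), length.out = 12)
    lcc <- vapply(wts, function(w) largestComponentFraction(binarize(m, w)),
                  numeric(1))
    expect_true(all(diff(lcc) <= 1e-12))
  }
})

test_that("stepwise clustering changes difference and telescope", {
  d <- deltaClustering(1:5, rep(0.4, 5))
  expect_equal(d$delta_clustering, rep(0, 4))
  expect_equal(d$n, 1:4)

  d2 <- deltaClustering(c(0, 1, 2), c(0.5, 0.3, 0.3))
  expect_equal(d2$delta_clustering, c(0.2, 0))

  withr::with_seed(11, {
    cc <- runif(10)
    d3 <- deltaClustering(seq(-2, 2.5, 0.5), cc)
    expect_equal(sum(d3$delta_clustering), cc[1] - cc[10]) # telescoping
  })

  expect_error(deltaClustering(1, 0.5), "at least 2")
  expect_error(deltaClustering(c(2, 1), c(0.1, 0.2)), "increasing")
})
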