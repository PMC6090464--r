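test_that("entropy in nats handles degenerate and uniform tables", {
  expect_equal(entropyNats(c(1, 0, 0)), 0)
  expect_equal(entropyNats(rep(1 / 3, 3)), log(3))
  expect_equal(entropyNats(c(0.25, 0.25, 0.5)), 1.5 * log(2))
  expect_error(entropyNats(c(0.5, 0.6)), "sum to 1")
  expect_error(entropyNats(c(-0.1, 1.1)), "nonnegative")
})

test_that("pairwise mutual information follows the entropy identity", {
  p <- 0.25
  q <- 0.1
  prod <- outer(c(p, 1 - 2 * p, p), c(q, 1 - 2 * q, q))
  expect_equal(pairwiseMutualInformation(prod), 0, tolerance = 1e-12)

  diagJoint <- diag(c(0.25, 0.5, 0.25))
  expect_equal(pairwiseMutualInformation(diagJoint), 1.5 * log(2))

  # brute-force double-loop oracle on the hub-cancellation fixture
  w <- matrix(0, 3, 3)
  w[1, 3] <- w[3, 1] <- 0.6
  w[2, 3] <- w[3, 2] <- -0.6
  hub <- binarize(ConnectivityMatrix(w), 0.5)
  j <- enumerateExactJoint(hub, 0.2, 1, 3)
  pr <- rowSums(j)
  pc <- colSums(j)
  mOracle <- 0
  for (a in 1:3) for (b in 1:3)
    if (j[a, b] > 0)
      mOracle <- mOracle + j[a, b] * log(j[a, b] / (pr[a] * pc[b]))
  expect_equal(pairwiseMutualInformation(j), unname(mOracle),
               tolerance = 1e-12)
})

test_that("a silent network transfers zero information", {
  m <- randomConnectivity(6, seed = 9, scale = 0.3)
  net <- binarize(m, 1) # nothing survives
  expect_equal(sum(adjacency(net)), 0)
  est <- estimateNetworkMI(net, 0.1, 500, seed = 1)
  expect_identical(networkMean(est), 0)
  exa <- exactNetworkMI(net, 0.1)
  expect_identical(networkMean(exa), 0)
})

test_that("the symmetric relay reaches its analytic mutual information", {
  net <- relayNetwork(0.9, 0.5)
  exact <- exactNetworkMI(net, 0.25)
  expect_equal(pairwiseMI(exact)[1, 2], 1.5 * log(2), tolerance = 1e-12)
  # symmetry relays both directions equally
  expect_equal(pairwiseMI(exact)[2, 1], 1.5 * log(2), tolerance = 1e-12)
  expect_equal(networkMean(exact), 1.5 * log(2), tolerance = 1e-12)

  est <- estimateNetworkMI(net, 0.25, 1e4, seed = 12)
  se <- 3 * sqrt(1.5 * log(2) / 1e4) # generous 3-sigma band
  expect_lt(abs(pairwiseMI(est)[1, 2] - 1.5 * log(2)), max(se, 0.02))
})

test_that("Monte-Carlo estimates track the enumeration oracle", {
  m <- randomConnectivity(6, seed = 21)
  net <- binarize(m, wt(computeThreshold(m, 0.3)))
  p <- 0.1
  exact <- exactNetworkMI(net, p)
  est <- estimateNetworkMI(net, p, 2e4, seed = 2)
  expect_lt(abs(networkMean(est) - networkMean(exact)), 0.005)
  expect_lt(max(abs(pairwiseMI(est) - pairwiseMI(exact))), 0.02)
})

test_that("mutual information obeys nonnegativity and entropy bounds", {
  for (seed in 1:8) {
    m <- randomConnectivity(7, seed = 400 + seed)
    net <- binarize(m, wt(computeThreshold(m, 0.5)))
    p <- c(0.05, 0.1, 0.2, 0.3)[(seed %% 4) + 1]
    for (res in list(exactNetworkMI(net, p),
                     estimateNetworkMI(net, p, 500, seed = seed))) {
      mm <- pairwiseMI(res)
      expect_true(all(mm >= 0))
      hS <- entropyNats(c(p, 1 - 2 * p, p))
      if (res@nTrials == 0) # exact marginals: H(s_i) is analytic
        expect_true(all(mm <= hS + 1e-9))
      # averaging contract
      expect_equal(perNodeMI(res), colSums(mm) / (nRegions(net) - 1))
      expect_equal(networkMean(res), mean(perNodeMI(res)))
    }
  }
})

test_that("network mutual information is invariant to node relabeling", {
  m <- randomConnectivity(6, seed = 31)
  net <- binarize(m, wt(computeThreshold(m, 0)))
  perm <- c(4, 1, 6, 2, 5, 3)
  mp <- ConnectivityMatrix(weights(m)[perm, perm])
  netp <- binarize(mp, net@wt)
  expect_equal(networkMean(exactNetworkMI(netp, 0.15)),
               networkMean(exactNetworkMI(net, 0.15)), tolerance = 1e-12)
})

test_that("the adjacency-restricted averaging variant is bounded above", {
  m <- randomConnectivity(6, seed = 41)
  net <- binarize(m, wt(computeThreshold(m, 0.5)))
  all <- exactNetworkMI(net, 0.2, pairs = "all")
  adj <- exactNetworkMI(net, 0.2, pairs = "adjacent")
  expect_lte(networkMean(adj), networkMean(all) + 1e-12)
})
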