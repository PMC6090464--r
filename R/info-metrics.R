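# Mutual-information readout of the transfer model. All entropies use the
# natural logarithm (nats) and the plug-in (maximum-likelihood) estimator;
# marginals are always taken from the same joint table so that every
# pairwise mutual information is nonnegative by construction.

#' Shannon entropy of a finite probability table (nats)
#'
#' -sum p ln p with the 0 ln 0 = 0 convention.
#'
#' @param prob numeric vector, matrix or table of probabilities; must be
#'   nonnegative and sum to 1 within 1e-9.
#' @return entropy in nats.
#' @examples
#' entropyNats(c(1/3, 1/3, 1/3)) # log(3)
#' @export
entropyNats <- function(prob) {
  p <- as.numeric(prob)
  if (any(p < 0)) stop("probabilities must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9)
    stop(sprintf("probabilities must sum to 1 (got %.12g)", sum(p)))
  -sum(plogp(p))
}

#' Pairwise mutual information from a joint table (nats)
#'
#' m = H(row marginal) + H(column marginal) - H(joint). For a true
#' probability table this is nonnegative; float-level negative rounding is
#' clipped to 0.
#'
#' @param joint matrix of joint probabilities (rows = stimulus states,
#'   columns = response states).
#' @return mutual information in nats.
#' @export
pairwiseMutualInformation <- function(joint) {
  if (!is.matrix(joint)) stop("'joint' must be a matrix")
  m <- entropyNats(rowSums(joint)) + entropyNats(colSums(joint)) -
    entropyNats(joint)
  max(m, 0)
}

# Shared core: pairwise m(i,j) from per-level stimulus/response indicator
# matrices and per-configuration weights. Slev/Rlev are lists of three
# N x K numeric indicator matrices; weight is a length-K vector summing
# to 1 (1/T for Monte-Carlo trials, configuration probabilities for the
# exact variant).
pairwiseMIMatrix <- function(Slev, Rlev, weight) {
  N <- nrow(Slev[[1]])
  Ps <- vapply(Slev, function(M) as.vector(M %*% weight), numeric(N))
  Pr <- vapply(Rlev, function(M) as.vector(M %*% weight), numeric(N))
  Hs <- -rowSums(plogp(Ps))
  Hr <- -rowSums(plogp(Pr))
  Hjoint <- matrix(0, N, N)
  for (a in 1:3)
    for (b in 1:3) {
      Jab <- Slev[[a]] %*% (weight * t(Rlev[[b]]))
      Hjoint <- Hjoint - plogp(Jab)
    }
  m <- outer(Hs, rep(1, N)) + outer(rep(1, N), Hr) - Hjoint
  diag(m) <- 0
  m <- pmax(m, 0)
  m[m < 1e-12] <- 0 # snap float-cancellation residue of independent pairs
  m
}

levelIndicators <- function(M) {
  lapply(c(-1, 0, 1), function(v) (M == v) * 1)
}

miResultFromPairwise <- function(m, pairs, adjacencyMatrix) {
  N <- nrow(m)
  if (pairs == "adjacent") m <- m * adjacencyMatrix
  perNode <- colSums(m) / (N - 1)
  list(pairwise = m, perNode = perNode, networkMean = mean(perNode))
}

#' Monte-Carlo estimate of the network mutual information
#'
#' Draws `nTrials` random stimulus vectors, propagates each through the
#' network in one step, and accumulates the empirical 3 x 3 joint of
#' (s_i, r_j) for every ordered pair i != j. Pairwise mutual informations
#' are averaged per node, <m(j)> = sum_i m(i,j) / (N - 1), and over nodes,
#' m = mean_j <m(j)>. Stimulus and response marginals are estimated from
#' the same trials, so each m(i,j) is nonnegative.
#'
#' @param network a [ThresholdedNetwork-class].
#' @param p activation density in (0, 0.5).
#' @param nTrials Monte-Carlo trials (default 1000).
#' @param seed integer seed for the stimulus draws.
#' @param pairs "all" (default; the divisor N - 1 counts every ordered
#'   pair) or "adjacent" to restrict the sum to connected pairs.
#' @return a [MutualInfoResult-class].
#' @export
estimateNetworkMI <- function(network, p, nTrials = 1000, seed,
                              pairs = c("all", "adjacent")) {
  stopifnot(is(network, "ThresholdedNetwork"))
  pairs <- match.arg(pairs)
  N <- nrow(network@adjacency)
  S <- generateSignals(N, p, nTrials, seed) # validates p
  R <- ternaryResponse(network@retainedWeights, S, network@wt)
  m <- pairwiseMIMatrix(levelIndicators(S), levelIndicators(R),
                        rep(1 / nTrials, nTrials))
  res <- miResultFromPairwise(m, pairs, network@adjacency)
  new("MutualInfoResult", pairwise = res$pairwise, perNode = res$perNode,
      networkMean = res$networkMean, nTrials = as.numeric(nTrials), p = p,
      wt = network@wt, seed = as.numeric(seed))
}

#' Exact network mutual information by enumeration
#'
#' Same averaging contract as [estimateNetworkMI()] but with exact joint
#' distributions from full enumeration of the 3^N stimulus configurations;
#' deterministic, `nTrials` recorded as 0.
#'
#' @param network a [ThresholdedNetwork-class] with at most `limit` nodes.
#' @param p activation density in (0, 0.5).
#' @param pairs as in [estimateNetworkMI()].
#' @param limit enumeration cap (default 10 nodes).
#' @return a [MutualInfoResult-class].
#' @export
exactNetworkMI <- function(network, p, pairs = c("all", "adjacent"),
                           limit = 10) {
  stopifnot(is(network, "ThresholdedNetwork"))
  pairs <- match.arg(pairs)
  N <- nrow(network@adjacency)
  if (N > limit)
    stop(sprintf(
      "N = %d exceeds the enumeration limit %d; use estimateNetworkMI",
      N, limit))
  if (p <= 0 || p >= 0.5) stop("'p' must lie strictly between 0 and 0.5")
  en <- enumerateStimuli(N, p)
  R <- ternaryResponse(network@retainedWeights, en$S, network@wt)
  m <- pairwiseMIMatrix(levelIndicators(en$S), levelIndicators(R), en$probs)
  res <- miResultFromPairwise(m, pairs, network@adjacency)
  new("MutualInfoResult", pairwise = res$pairwise, perNode = res$perNode,
      networkMean = res$networkMean, nTrials = 0, p = p,
      wt = network@wt, seed = NA_real_)
}
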