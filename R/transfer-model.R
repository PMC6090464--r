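# The one-step ternary transfer model: a stimulus vector S over {-1, 0, +1}
# drives each node j through its retained connections, and the response is
# r_j = +1 if the summed input exceeds w_t, -1 below -w_t, 0 otherwise.
# There is no recurrent iteration: the response is read out after a single
# synchronous step.

# Ternary response of every column of a stimulus matrix (N x T).
# The response threshold is max(w_t, 0): the printed rule is contradictory
# for negative thresholds, which the sweep grid can reach at n = -2.
ternaryResponse <- function(retained, stimuli, wt) {
  tau <- max(wt, 0)
  d <- retained %*% stimuli
  (d > tau) - (d < -tau)
}

#' Propagate a stimulus through a thresholded network
#'
#' drive_j = sum_i a_ij w_ij s_i over all nodes i (signed weights, gated by
#' the adjacency); the ternary response applies the same threshold w_t that
#' defined the network, so a boundary drive |drive| = w_t maps to 0.
#'
#' @param network a [ThresholdedNetwork-class].
#' @param stimulus numeric vector over \{-1, 0, +1\}, one entry per node.
#' @return a [ResponseVector-class] with the states and the drives.
#' @examples
#' m <- ConnectivityMatrix(matrix(c(0, .9, .9, 0), 2, 2))
#' net <- binarize(m, 0.5)
#' propagate(net, c(1, 0))@states
#' @export
propagate <- function(network, stimulus) {
  stopifnot(is(network, "ThresholdedNetwork"))
  N <- nrow(network@adjacency)
  if (length(stimulus) != N)
    stop(sprintf("stimulus length %d does not match network size %d",
                 length(stimulus), N))
  if (!all(stimulus %in% c(-1, 0, 1)))
    stop("stimulus entries must be in {-1, 0, 1}")
  d <- as.vector(network@retainedWeights %*% stimulus)
  tau <- max(network@wt, 0)
  states <- (d > tau) - (d < -tau)
  new("ResponseVector", states = as.numeric(states), drive = d)
}

# All 3^N stimulus configurations (columns) and their probabilities under
# independent entries with P(+1) = P(-1) = p, P(0) = 1 - 2p.
enumerateStimuli <- function(N, p) {
  K <- 3^N
  states <- c(-1, 0, 1)
  S <- matrix(0, N, K)
  idx <- 0:(K - 1)
  for (i in seq_len(N))
    S[i, ] <- states[((idx %/% 3^(i - 1)) %% 3) + 1]
  nz <- colSums(S != 0)
  probs <- p^nz * (1 - 2 * p)^(N - nz)
  list(S = S, probs = probs)
}

#' Exact joint distribution of one (stimulus, response) pair
#'
#' Enumerates all 3^N stimulus configurations, weighting each by its
#' probability under activation density p, and accumulates the exact joint
#' mass of (s_i, r_j). Serves as the oracle for the Monte-Carlo estimator.
#'
#' @param network a [ThresholdedNetwork-class] with at most `limit` nodes.
#' @param p activation density in (0, 0.5).
#' @param i stimulus node index.
#' @param j response node index.
#' @param limit enumeration cap (default 10 nodes, 59049 configurations).
#' @return 3 x 3 matrix over states (-1, 0, +1), rows = s_i, columns = r_j,
#'   summing to 1.
#' @export
enumerateExactJoint <- function(network, p, i, j, limit = 10) {
  stopifnot(is(network, "ThresholdedNetwork"))
  N <- nrow(network@adjacency)
  if (N > limit)
    stop(sprintf(
      "N = %d exceeds the enumeration limit %d; use the Monte-Carlo path",
      N, limit))
  if (p <= 0 || p >= 0.5) stop("'p' must lie strictly between 0 and 0.5")
  stopifnot(i >= 1, i <= N, j >= 1, j <= N)
  en <- enumerateStimuli(N, p)
  r <- ternaryResponse(network@retainedWeights, en$S, network@wt)
  tab <- matrix(0, 3, 3, dimnames = list(s = c("-1", "0", "1"),
                                         r = c("-1", "0", "1")))
  states <- c(-1, 0, 1)
  for (a in 1:3)
    for (b in 1:3)
      tab[a, b] <- sum(en$probs[en$S[i, ] == states[a] & r[j, ] == states[b]])
  tab
}
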