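# Thresholding weighted matrices into binary adjacency and the topology
# measures of the sweep. The standard graph computations (connected
# components, transitivity) are delegated to igraph.

#' Compute the cut-off threshold from weight statistics
#'
#' w_t = <|w|> + n * sigma_|w|, with the mean and the *population* standard
#' deviation taken over the N(N-1)/2 off-diagonal upper-triangle |w|
#' values. Sweeping n traces the phase transitions of the network.
#'
#' @param matrix a [ConnectivityMatrix-class].
#' @param n multiplier of the standard deviation.
#' @return a [ThresholdSpec-class].
#' @examples
#' m <- ConnectivityMatrix(matrix(c(0, .5, .5, 0), 2, 2))
#' wt(computeThreshold(m, 0))
#' @export
computeThreshold <- function(matrix, n) {
  stopifnot(is(matrix, "ConnectivityMatrix"), is.numeric(n), length(n) == 1)
  v <- abs(upperTriVals(matrix@weights))
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  if (sigma == 0)
    warning("all off-diagonal |w| identical; threshold degenerates to the mean")
  new("ThresholdSpec", n = n, meanAbsW = mu, sdAbsW = sigma,
      wt = mu + n * sigma)
}

#' Binarize a weighted matrix at a threshold
#'
#' Keeps the connections with |w_ij| strictly above w_t; negative
#' connections survive by magnitude and the retained weights preserve their
#' sign. Ties at the threshold are excluded.
#'
#' @param matrix a [ConnectivityMatrix-class].
#' @param wt threshold value, or a [ThresholdSpec-class].
#' @return a [ThresholdedNetwork-class].
#' @export
binarize <- function(matrix, wt) {
  stopifnot(is(matrix, "ConnectivityMatrix"))
  if (is(wt, "ThresholdSpec")) wt <- wt@wt
  stopifnot(is.numeric(wt), length(wt) == 1)
  w <- matrix@weights
  a <- (abs(w) > wt) * 1
  diag(a) <- 0
  new("ThresholdedNetwork", adjacency = a, retainedWeights = w * a, wt = wt)
}

asIgraph <- function(network) {
  igraph::graph_from_adjacency_matrix(network@adjacency,
                                      mode = "undirected", diag = FALSE)
}

#' Largest connected component fraction
#'
#' Size of the largest connected component of the binarized graph divided
#' by the total number of nodes N; isolated nodes count as components of
#' size 1, so the value lies in \[1/N, 1\].
#'
#' @param network a [ThresholdedNetwork-class].
#' @return fraction in (0, 1\].
#' @export
largestComponentFraction <- function(network) {
  stopifnot(is(network, "ThresholdedNetwork"))
  comp <- igraph::components(asIgraph(network))
  max(comp$csize) / nrow(network@adjacency)
}

#' Clustering coefficient (transitivity)
#'
#' Global transitivity, 3 x triangles / connected triples, of the binarized
#' graph; 0 when no connected triples exist. The mean local clustering
#' coefficient is available as a flagged alternative.
#'
#' @param network a [ThresholdedNetwork-class].
#' @param type "global" (default) or "local-mean".
#' @return value in \[0, 1\].
#' @export
clusteringCoefficient <- function(network, type = c("global", "local-mean")) {
  stopifnot(is(network, "ThresholdedNetwork"))
  type <- match.arg(type)
  g <- asIgraph(network)
  val <- if (type == "global") {
    igraph::transitivity(g, type = "global")
  } else {
    mean(igraph::transitivity(g, type = "local", isolates = "zero"))
  }
  if (is.nan(val)) 0 else val
}

#' Stepwise change of the clustering coefficient along a sweep
#'
#' Delta C(i) = C(i) - C(i+1) for i = 0 ... len-2, indexed from the
#' smallest threshold multiplier; a large positive step marks the collapse
#' of clustered structure.
#'
#' @param n strictly increasing threshold multipliers.
#' @param clustering the matching clustering coefficients C(i).
#' @return data frame with columns `n` (all but the last input point) and
#'   `delta_clustering`.
#' @export
deltaClustering <- function(n, clustering) {
  if (length(n) < 2) stop("need at least 2 points to difference")
  if (length(n) != length(clustering))
    stop("'n' and 'clustering' must have the same length")
  if (any(diff(n) <= 0)) stop("'n' must be strictly increasing")
  data.frame(n = n[-length(n)], delta_clustering = -diff(clustering))
}
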