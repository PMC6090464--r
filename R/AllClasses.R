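# Central S4 containers. Constructors normalise benign deviations (nonzero
# diagonal, float-level asymmetry) and reject everything else; validity
# methods re-check the invariants on stored objects.

#' ConnectivityMatrix: one subject's weighted functional network
#'
#' A symmetric real matrix of signed correlation weights between brain
#' regions, with zero diagonal and every entry in \[-1, 1\].
#'
#' @slot subjectId single character label for the subject.
#' @slot weights square numeric matrix of connection weights.
#' @aliases ConnectivityMatrix-class
#' @exportClass ConnectivityMatrix
setClass("ConnectivityMatrix",
  representation(subjectId = "character", weights = "matrix"))

setValidity("ConnectivityMatrix", function(object) {
  w <- object@weights
  msg <- character()
  if (!is.numeric(w) || nrow(w) != ncol(w)) {
    msg <- c(msg, "weights must be a square numeric matrix")
  } else {
    if (nrow(w) < 2) msg <- c(msg, "need at least 2 regions")
    if (any(abs(w) > 1 + 1e-9)) msg <- c(msg, "entries must lie in [-1, 1]")
    if (max(abs(w - t(w))) > 1e-9) msg <- c(msg, "weights must be symmetric")
    if (any(diag(w) != 0)) msg <- c(msg, "diagonal entries must be 0")
  }
  if (length(object@subjectId) != 1) msg <- c(msg, "subjectId must be a single label")
  if (length(msg)) msg else TRUE
})

#' ThresholdSpec: a cut-off threshold derived from weight statistics
#'
#' Records the threshold rule w_t = <|w|> + n * sigma_|w|, where the mean
#' and the population standard deviation are taken over the off-diagonal
#' upper-triangle |w| values of one matrix.
#'
#' @slot n numeric multiplier of the standard deviation.
#' @slot meanAbsW mean absolute off-diagonal weight.
#' @slot sdAbsW population standard deviation of the absolute weights.
#' @slot wt the resulting cut-off threshold.
#' @aliases ThresholdSpec-class
#' @exportClass ThresholdSpec
setClass("ThresholdSpec",
  representation(n = "numeric", meanAbsW = "numeric", sdAbsW = "numeric",
                 wt = "numeric"))

setValidity("ThresholdSpec", function(object) {
  if (abs(object@wt - (object@meanAbsW + object@n * object@sdAbsW)) > 1e-12)
    return("wt must equal meanAbsW + n * sdAbsW")
  if (object@sdAbsW < 0) return("sdAbsW must be nonnegative")
  TRUE
})

#' ThresholdedNetwork: binary adjacency plus the retained signed weights
#'
#' Produced by [binarize()]: a_ij = 1 exactly when |w_ij| > w_t (strict),
#' and the surviving entries keep their sign.
#'
#' @slot adjacency square 0/1 matrix, symmetric, zero diagonal.
#' @slot retainedWeights signed weights where adjacency is 1, else 0.
#' @slot wt the threshold used.
#' @aliases ThresholdedNetwork-class
#' @exportClass ThresholdedNetwork
setClass("ThresholdedNetwork",
  representation(adjacency = "matrix", retainedWeights = "matrix",
                 wt = "numeric"))

setValidity("ThresholdedNetwork", function(object) {
  a <- object@adjacency
  rw <- object@retainedWeights
  msg <- character()
  if (nrow(a) != ncol(a)) msg <- c(msg, "adjacency must be square")
  if (!all(a %in% c(0, 1))) msg <- c(msg, "adjacency entries must be 0 or 1")
  if (!identical(dim(a), dim(rw)))
    msg <- c(msg, "adjacency and retainedWeights must have the same shape")
  else {
    if (max(abs(a - t(a))) != 0) msg <- c(msg, "adjacency must be symmetric")
    if (any(diag(a) != 0)) msg <- c(msg, "adjacency diagonal must be 0")
    if (any(rw[a == 0] != 0))
      msg <- c(msg, "retainedWeights must be 0 where adjacency is 0")
  }
  if (length(msg)) msg else TRUE
})

#' MutualInfoResult: mutual information of one (network, p) cell
#'
#' Pairwise mutual information m(i,j) in nats between every stimulus node i
#' and response node j, with the two-level average: per-node
#' <m(j)> = sum_i m(i,j) / (N-1) and network mean m = mean_j <m(j)>.
#'
#' @slot pairwise N x N matrix of m(i,j); diagonal fixed at 0.
#' @slot perNode per-node averages <m(j)>.
#' @slot networkMean the network-level average m.
#' @slot nTrials Monte-Carlo trials used (0 for the exact variant).
#' @slot p activation density of the stimuli.
#' @slot wt threshold of the underlying network.
#' @slot seed RNG seed used (NA for the exact variant).
#' @aliases MutualInfoResult-class
#' @exportClass MutualInfoResult
setClass("MutualInfoResult",
  representation(pairwise = "matrix", perNode = "numeric",
                 networkMean = "numeric", nTrials = "numeric",
                 p = "numeric", wt = "numeric", seed = "numeric"))

setValidity("MutualInfoResult", function(object) {
  msg <- character()
  if (any(object@pairwise < -1e-12)) msg <- c(msg, "m(i,j) must be nonnegative")
  if (length(object@perNode) != nrow(object@pairwise))
    msg <- c(msg, "perNode length must equal the network size")
  if (length(msg)) msg else TRUE
})

#' DistributionFit: one distribution model fitted to surviving weights
#'
#' @slot modelName "boundary_power" or "truncated_power_law".
#' @slot params named numeric parameters (gamma, or alpha and x_c).
#' @slot logLik maximized log-likelihood.
#' @slot ksDistance Kolmogorov-Smirnov distance of the fitted model.
#' @slot nValues number of weight values fitted.
#' @slot wt lower bound of the fit domain (the threshold).
#' @aliases DistributionFit-class
#' @exportClass DistributionFit
setClass("DistributionFit",
  representation(modelName = "character", params = "numeric",
                 logLik = "numeric", ksDistance = "numeric",
                 nValues = "numeric", wt = "numeric"))

setValidity("DistributionFit", function(object) {
  msg <- character()
  if (!object@modelName %in% c("boundary_power", "truncated_power_law"))
    msg <- c(msg, "unknown modelName")
  if (object@ksDistance < 0 || object@ksDistance > 1)
    msg <- c(msg, "ksDistance must lie in [0, 1]")
  if (object@modelName == "boundary_power" &&
      !is.na(object@params["gamma"]) && object@params["gamma"] <= -1)
    msg <- c(msg, "boundary_power gamma must exceed -1")
  if (object@modelName == "truncated_power_law" &&
      !is.na(object@params["x_c"]) && object@params["x_c"] <= 0)
    msg <- c(msg, "truncated_power_law x_c must be positive")
  if (length(msg)) msg else TRUE
})

#' EnsembleSpec: parameters of the synthetic connectome generator
#'
#' See [generateEnsemble()] for the construction the fields control.
#'
#' @slot nRegions number of regions N.
#' @slot nSubjects number of subject matrices to generate.
#' @slot gamma boundary-power exponent of the |w| magnitudes (> -1).
#' @slot backboneDegree even ring-lattice degree of the strong-edge backbone.
#' @slot rewireProb Watts-Strogatz rewiring probability in \[0, 1\].
#' @slot backboneQuantile fraction of the top weight magnitudes routed to
#'   backbone edges, in (0, 1\].
#' @slot noiseSd standard deviation of the per-subject Gaussian perturbation.
#' @slot seed master RNG seed for the ensemble.
#' @aliases EnsembleSpec-class
#' @exportClass EnsembleSpec
setClass("EnsembleSpec",
  representation(nRegions = "numeric", nSubjects = "numeric",
                 gamma = "numeric", backboneDegree = "numeric",
                 rewireProb = "numeric", backboneQuantile = "numeric",
                 noiseSd = "numeric", seed = "numeric"))

setValidity("EnsembleSpec", function(object) {
  msg <- character()
  if (object@nRegions < 2) msg <- c(msg, "nRegions must be at least 2")
  if (object@nSubjects < 1) msg <- c(msg, "nSubjects must be positive")
  if (object@gamma <= -1) msg <- c(msg, "gamma must exceed -1")
  k <- object@backboneDegree
  if (k <= 0 || k %% 2 != 0) msg <- c(msg, "backboneDegree must be a positive even count")
  if (k >= object@nRegions) msg <- c(msg, "backboneDegree must be smaller than nRegions")
  if (object@rewireProb < 0 || object@rewireProb > 1)
    msg <- c(msg, "rewireProb must lie in [0, 1]")
  if (object@backboneQuantile <= 0 || object@backboneQuantile > 1)
    msg <- c(msg, "backboneQuantile must lie in (0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' ResponseVector: one-step response of the transfer model
#'
#' @slot states ternary responses in \{-1, 0, +1\}.
#' @slot drive the summed weighted input each node received.
#' @aliases ResponseVector-class
#' @exportClass ResponseVector
setClass("ResponseVector",
  representation(states = "numeric", drive = "numeric"))

setValidity("ResponseVector", function(object) {
  if (length(object@states) != length(object@drive))
    return("states and drive must have the same length")
  if (!all(object@states %in% c(-1, 0, 1)))
    return("states must be in {-1, 0, 1}")
  TRUE
})

#' SweepConfig: configuration of a threshold/activation-density sweep
#'
#' @slot input a list of [ConnectivityMatrix-class] objects, an
#'   [EnsembleSpec-class], or a directory of matrix files.
#' @slot nGrid strictly increasing threshold multipliers.
#' @slot pValues distinct activation densities in (0, 0.5).
#' @slot nTrials Monte-Carlo trials per cell.
#' @slot masterSeed master seed; every cell seed derives from it.
#' @slot models distribution models to fit on the surviving weights.
#' @slot miPairs "all" (divisor N-1 over all ordered pairs) or "adjacent".
#' @aliases SweepConfig-class
#' @exportClass SweepConfig
setClass("SweepConfig",
  representation(input = "ANY", nGrid = "numeric", pValues = "numeric",
                 nTrials = "numeric", masterSeed = "numeric",
                 models = "character", miPairs = "character"))

setValidity("SweepConfig", function(object) {
  msg <- character()
  if (length(object@nGrid) < 1 || any(diff(object@nGrid) <= 0))
    msg <- c(msg, "nGrid must be strictly increasing")
  if (any(object@pValues <= 0) || any(object@pValues >= 0.5) ||
      anyDuplicated(object@pValues))
    msg <- c(msg, "pValues must be distinct and in (0, 0.5)")
  if (object@nTrials < 1) msg <- c(msg, "nTrials must be positive")
  bad <- setdiff(object@models, c("boundary_power", "truncated_power_law"))
  if (length(bad)) msg <- c(msg, paste("unknown models:", paste(bad, collapse = ", ")))
  if (!object@miPairs %in% c("all", "adjacent"))
    msg <- c(msg, "miPairs must be 'all' or 'adjacent'")
  if (length(msg)) msg else TRUE
})

#' SweepResult: per-subject and ensemble-averaged sweep tables
#'
#' @slot subjectTable one row per (subject, n, p) cell.
#' @slot ensembleTable arithmetic mean over subjects per (n, p) cell.
#' @slot config the [SweepConfig-class] that produced the tables.
#' @slot failures log of cells whose distribution fits were skipped.
#' @aliases SweepResult-class
#' @exportClass SweepResult
setClass("SweepResult",
  representation(subjectTable = "data.frame", ensembleTable = "data.frame",
                 config = "SweepConfig", failures = "data.frame"))
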