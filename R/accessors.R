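# Accessors and show() methods. Slot access from user code should go
# through these.

#' Accessors for critnet objects
#'
#' Extract the stored components of the S4 containers: the weight matrix,
#' number of regions and subject label of a [ConnectivityMatrix-class]; the
#' adjacency, retained weights and threshold of a
#' [ThresholdedNetwork-class]; the pairwise/per-node/network-level mutual
#' information of a [MutualInfoResult-class]; the name, parameters,
#' likelihood and KS distance of a [DistributionFit-class]; and the
#' per-subject and ensemble tables of a [SweepResult-class].
#'
#' @param x,object an object of the documented class.
#' @param ... unused.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases nRegions subjectId adjacency retainedWeights wt pairwiseMI
#'   perNodeMI networkMean modelName fitParams ksDist subjectTable
#'   ensembleTable
NULL

#' @rdname accessors
#' @exportMethod nRegions
setMethod("nRegions", "ConnectivityMatrix", function(x) nrow(x@weights))

#' @rdname accessors
#' @exportMethod subjectId
setMethod("subjectId", "ConnectivityMatrix", function(x) x@subjectId)

#' @rdname accessors
#' @exportMethod weights
setMethod("weights", "ConnectivityMatrix", function(object, ...) object@weights)

#' @rdname accessors
#' @exportMethod adjacency
setMethod("adjacency", "ThresholdedNetwork", function(x) x@adjacency)

#' @rdname accessors
#' @exportMethod retainedWeights
setMethod("retainedWeights", "ThresholdedNetwork", function(x) x@retainedWeights)

#' @rdname accessors
setMethod("nRegions", "ThresholdedNetwork", function(x) nrow(x@adjacency))

#' @rdname accessors
#' @exportMethod wt
setMethod("wt", "ThresholdedNetwork", function(x) x@wt)

#' @rdname accessors
setMethod("wt", "ThresholdSpec", function(x) x@wt)

#' @rdname accessors
setMethod("wt", "MutualInfoResult", function(x) x@wt)

#' @rdname accessors
setMethod("wt", "DistributionFit", function(x) x@wt)

#' @rdname accessors
#' @exportMethod pairwiseMI
setMethod("pairwiseMI", "MutualInfoResult", function(x) x@pairwise)

#' @rdname accessors
#' @exportMethod perNodeMI
setMethod("perNodeMI", "MutualInfoResult", function(x) x@perNode)

#' @rdname accessors
#' @exportMethod networkMean
setMethod("networkMean", "MutualInfoResult", function(x) x@networkMean)

#' @rdname accessors
#' @exportMethod modelName
setMethod("modelName", "DistributionFit", function(x) x@modelName)

#' @rdname accessors
#' @exportMethod fitParams
setMethod("fitParams", "DistributionFit", function(x) x@params)

#' @rdname accessors
#' @exportMethod ksDist
setMethod("ksDist", "DistributionFit", function(x) x@ksDistance)

#' @rdname accessors
#' @exportMethod logLik
setMethod("logLik", "DistributionFit", function(object, ...) object@logLik)

#' @rdname accessors
#' @exportMethod subjectTable
setMethod("subjectTable", "SweepResult", function(x) x@subjectTable)

#' @rdname accessors
#' @exportMethod ensembleTable
setMethod("ensembleTable", "SweepResult", function(x) x@ensembleTable)

setMethod("show", "ConnectivityMatrix", function(object) {
  w <- object@weights
  cat(sprintf("ConnectivityMatrix '%s': %d x %d regions\n",
              object@subjectId, nrow(w), ncol(w)))
  v <- abs(upperTriVals(w))
  cat(sprintf("  |w| mean %.4f, sd %.4f, max %.4f\n",
              mean(v), sqrt(mean((v - mean(v))^2)), max(v)))
})

setMethod("show", "ThresholdSpec", function(object) {
  cat(sprintf("ThresholdSpec: w_t = %.6g (<|w|> = %.6g, sigma = %.6g, n = %g)\n",
              object@wt, object@meanAbsW, object@sdAbsW, object@n))
})

setMethod("show", "ThresholdedNetwork", function(object) {
  a <- object@adjacency
  cat(sprintf("ThresholdedNetwork: %d nodes, %d edges at w_t = %.6g\n",
              nrow(a), sum(a) / 2, object@wt))
})

setMethod("show", "MutualInfoResult", function(object) {
  cat(sprintf(
    "MutualInfoResult: network mean m = %.6g nats (p = %g, w_t = %.6g, %s)\n",
    object@networkMean, object@p, object@wt,
    if (object@nTrials > 0) sprintf("%d trials", object@nTrials) else "exact"))
})

setMethod("show", "DistributionFit", function(object) {
  cat(sprintf("DistributionFit '%s' on %d values above w_t = %.6g\n",
              object@modelName, object@nValues, object@wt))
  cat("  params:", paste(sprintf("%s = %.6g", names(object@params),
                                 object@params), collapse = ", "), "\n")
  cat(sprintf("  logLik = %.6g, KS distance = %.6g\n",
              object@logLik, object@ksDistance))
})

setMethod("show", "EnsembleSpec", function(object) {
  cat(sprintf(
    "EnsembleSpec: %d subjects, N = %d, gamma = %g, backbone k = %d (rewire %g),\n  quantile %g, noise sd %g, seed %d\n",
    object@nSubjects, object@nRegions, object@gamma, object@backboneDegree,
    object@rewireProb, object@backboneQuantile, object@noiseSd, object@seed))
})

setMethod("show", "SweepConfig", function(object) {
  cat(sprintf(
    "SweepConfig: n in [%g, %g] (%d points), p = {%s}, %d trials, seed %d\n",
    min(object@nGrid), max(object@nGrid), length(object@nGrid),
    paste(object@pValues, collapse = ", "), object@nTrials,
    object@masterSeed))
})

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult: %d subject rows, %d ensemble rows\n",
              nrow(object@subjectTable), nrow(object@ensembleTable)))
  if (nrow(object@failures))
    cat(sprintf("  %d cells skipped a distribution fit (see @failures)\n",
                nrow(object@failures)))
})
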