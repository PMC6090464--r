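# Generics for the accessor layer. Methods live in accessors.R.

#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @export
setGeneric("weights")

#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @export
setGeneric("retainedWeights", function(x) standardGeneric("retainedWeights"))

#' @export
setGeneric("wt", function(x) standardGeneric("wt"))

#' @export
setGeneric("pairwiseMI", function(x) standardGeneric("pairwiseMI"))

#' @export
setGeneric("perNodeMI", function(x) standardGeneric("perNodeMI"))

#' @export
setGeneric("networkMean", function(x) standardGeneric("networkMean"))

#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))

#' @export
setGeneric("fitParams", function(x) standardGeneric("fitParams"))

#' @export
setGeneric("ksDist", function(x) standardGeneric("ksDist"))

#' @export
setGeneric("subjectTable", function(x) standardGeneric("subjectTable"))

#' @export
setGeneric("ensembleTable", function(x) standardGeneric("ensembleTable"))
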