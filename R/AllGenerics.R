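#' @rdname PPINetwork-class
#' @param object,net a \code{PPINetwork}
#' @export
setGeneric("numNodes", function(object) standardGeneric("numNodes"))

#' @rdname PPINetwork-class
#' @export
setGeneric("numEdges", function(object) standardGeneric("numEdges"))

#' @rdname PPINetwork-class
#' @export
setGeneric("nodeLabels", function(object) standardGeneric("nodeLabels"))

#' @rdname PPINetwork-class
#' @export
setGeneric("edgeMatrix", function(object) standardGeneric("edgeMatrix"))

#' @rdname PPINetwork-class
#' @export
setGeneric("adjacencyMatrix", function(object) standardGeneric("adjacencyMatrix"))

#' Average degree of a network
#'
#' Returns \code{2 m / n}, the mean number of edges per node.
#'
#' @param net a [PPINetwork-class]
#' @return a single numeric value
#' @examples
#' net <- ppiNetwork(cbind(c("a", "b"), c("b", "c")))
#' averageDegree(net) # 2 * 2 / 3
#' @export
setGeneric("averageDegree", function(net) standardGeneric("averageDegree"))

#' @rdname NodeSimilarity-class
#' @param object a \code{NodeSimilarity}
#' @export
setGeneric("simScores", function(object) standardGeneric("simScores"))

#' @rdname NetworkAlignment-class
#' @param object a \code{NetworkAlignment}
#' @export
setGeneric("targetIndices", function(object) standardGeneric("targetIndices"))

#' @rdname GOAnnotation-class
#' @param object a \code{GOAnnotation}
#' @param label node label to look up
#' @export
setGeneric("goTerms", function(object, label) standardGeneric("goTerms"))
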