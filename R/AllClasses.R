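#' @import methods
NULL

#' Undirected protein-protein interaction network
#'
#' A simple undirected graph over string-labelled nodes. Node indices are
#' fixed by the order of \code{labels} (first appearance in the source file
#' when read with [readEdgeList()]); all matrices in the package are indexed
#' by this order. Edges are stored canonically with the smaller index first;
#' self-loops and duplicate edges are not representable.
#'
#' @slot labels character vector of unique node labels; position = node index.
#' @slot edges integer matrix with two columns, one row per undirected edge,
#'   \code{edges[, 1] < edges[, 2]}, no duplicate rows.
#'
#' @seealso [ppiNetwork()], [readEdgeList()], [averageDegree()]
#' @exportClass PPINetwork
setClass("PPINetwork",
  representation(labels = "character", edges = "matrix"),
  validity = function(object) {
    n <- length(object@labels)
    e <- object@edges
    if (anyDuplicated(object@labels)) return("node labels must be unique")
    if (n < 1L) return("a network needs at least one node")
    if (ncol(e) != 2L) return("edges must have two columns")
    if (!is.integer(e)) return("edge indices must be integers")
    if (nrow(e)) {
      if (any(e < 1L) || any(e > n)) return("edge endpoint index out of range")
      if (any(e[, 1L] >= e[, 2L])) {
        return("edges must be canonical (first index < second; no self-loops)")
      }
      if (anyDuplicated(e)) return("duplicate edges are not allowed")
    }
    TRUE
  }
)

#' Cross-network node similarity matrix
#'
#' Dense non-negative matrix of similarity scores between the nodes of a
#' source network (rows) and a target network (columns), e.g. BLAST
#' bit-scores. Row/column order follows the node indexing of the two
#' networks it was built against.
#'
#' @slot scores numeric matrix, all entries finite and >= 0.
#'
#' @seealso [nodeSimilarity()], [readSimilarity()], [blendedSimilarity()]
#' @exportClass NodeSimilarity
setClass("NodeSimilarity",
  representation(scores = "matrix"),
  validity = function(object) {
    s <- object@scores
    if (!is.numeric(s)) return("scores must be numeric")
    if (any(!is.finite(s))) return("scores must be finite")
    if (any(s < 0)) return("scores must be non-negative")
    TRUE
  }
)

#' Injective node alignment between two networks
#'
#' A global alignment maps every node of the source network to a distinct
#' node of the target network. \code{targetOf[i] = j} means source node
#' \code{i} is aligned to target node \code{j} (1-based indices).
#'
#' @slot targetOf integer vector of length n1 with distinct entries in
#'   \code{1..nTargets}.
#' @slot nTargets integer, number of nodes in the target network.
#'
#' @seealso [networkAlignment()], [conservedEdges()], [alignmentReport()]
#' @exportClass NetworkAlignment
setClass("NetworkAlignment",
  representation(targetOf = "integer", nTargets = "integer"),
  validity = function(object) {
    t <- object@targetOf
    n2 <- object@nTargets
    if (length(n2) != 1L || is.na(n2) || n2 < 1L) return("invalid target size")
    if (length(t) < 1L) return("alignment must cover at least one source node")
    if (length(t) > n2) return("source network larger than target network")
    if (anyNA(t)) return("alignment entries must not be NA")
    if (any(t < 1L) || any(t > n2)) return("target index out of range")
    if (anyDuplicated(t)) return("alignment must be injective")
    TRUE
  }
)

#' Search parameters for the discrete bat optimizer
#'
#' Population and acceptance parameters of the bat metaheuristic. Frequency
#' bounds \code{fMin}/\code{fMax} control the binarized flight frequency,
#' \code{theta} the geometric loudness decay on acceptance, \code{gamma} the
#' pulse-rate growth, \code{loudness0}/\code{rate0} the per-bat initial
#' loudness and pulse-rate ceiling. \code{patience} is the number of
#' consecutive iterations without improvement of the best objective after
#' which the search stops.
#'
#' @seealso [batParams()], [batAlign()]
#' @exportClass BatParams
setClass("BatParams",
  representation(
    popSize = "integer", maxIters = "integer", patience = "integer",
    fMin = "numeric", fMax = "numeric", theta = "numeric", gamma = "numeric",
    loudness0 = "numeric", rate0 = "numeric"
  ),
  validity = function(object) {
    if (object@popSize < 1L) return("popSize must be >= 1")
    if (object@maxIters < 0L) return("maxIters must be >= 0")
    if (object@patience < 1L) return("patience must be >= 1")
    if (object@fMin > object@fMax) return("fMin must be <= fMax")
    if (object@theta <= 0 || object@theta >= 1) return("theta must be in (0, 1)")
    if (object@gamma <= 0) return("gamma must be > 0")
    if (object@loudness0 <= 0) return("loudness0 must be > 0")
    if (object@rate0 < 0 || object@rate0 > 1) return("rate0 must be in [0, 1]")
    TRUE
  }
)

#' GO term annotations for network nodes
#'
#' Maps node labels to sets of GO term identifiers. Looking up a label with
#' no annotation returns the empty set.
#'
#' @slot terms named list; each element a character vector of GO term IDs.
#'
#' @seealso [goAnnotation()], [readAnnotations()], [gocScore()]
#' @exportClass GOAnnotation
setClass("GOAnnotation",
  representation(terms = "list"),
  validity = function(object) {
    if (length(object@terms)) {
      if (is.null(names(object@terms)) || anyDuplicated(names(object@terms))) {
        return("terms must be a uniquely named list")
      }
      if (!all(vapply(object@terms, is.character, logical(1L)))) {
        return("each term set must be a character vector")
      }
    }
    TRUE
  }
)

#' A synthetic alignment instance with known ground truth
#'
#' Bundle of a source network, a perturbed target copy, the true injective
#' mapping between them, and a similarity matrix concentrated on the true
#' pairs. \code{nRewired} records how many copied edges were rewired, so
#' that \code{conservedEdges(trueMap) == numEdges(net1) - nRewired} holds
#' by construction.
#'
#' @seealso [generatePair()]
#' @exportClass SyntheticPair
setClass("SyntheticPair",
  representation(
    net1 = "PPINetwork", net2 = "PPINetwork",
    trueMap = "NetworkAlignment", scores = "NodeSimilarity",
    nRewired = "integer"
  )
)

#' Result of a bat-search alignment run
#'
#' @slot alignment the best [NetworkAlignment-class] found.
#' @slot objective conserved-edge count of the best alignment.
#' @slot trace numeric vector; element 1 is the best objective after
#'   initialization, element t+1 after iteration t. Non-decreasing.
#' @slot iterations number of iterations executed.
#' @slot converged TRUE if the run stopped on patience rather than on the
#'   iteration cap.
#' @slot params the [BatParams-class] used.
#'
#' @seealso [batAlign()]
#' @exportClass BatAlignResult
setClass("BatAlignResult",
  representation(
    alignment = "NetworkAlignment", objective = "numeric", trace = "numeric",
    iterations = "integer", converged = "logical", params = "BatParams"
  )
)
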