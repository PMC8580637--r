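#' Build a network from labelled edge pairs
#'
#' Constructs a [PPINetwork-class] from a two-column matrix or data frame of
#' node-label pairs. Node order is fixed by first appearance (scanning rows
#' left to right), self-loops are dropped and parallel edges collapsed; the
#' numbers dropped are reported via [message()].
#'
#' @param edges two-column character matrix or data frame; each row one
#'   undirected interaction.
#' @param isolated optional character vector of additional node labels with
#'   no incident edges (appended after the edge-derived nodes).
#' @return a [PPINetwork-class]
#' @examples
#' net <- ppiNetwork(cbind(c("a", "b", "b"), c("b", "a", "c")))
#' numNodes(net); numEdges(net)
#' @export
ppiNetwork <- function(edges, isolated = character()) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("'edges' must have exactly two columns")
  storage.mode(edges) <- "character"
  labels <- unique(c(as.vector(t(edges)), isolated))
  i <- match(edges[, 1L], labels)
  j <- match(edges[, 2L], labels)
  loops <- i == j
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    i <- i[!loops]; j <- j[!loops]
  }
  lo <- pmin(i, j); hi <- pmax(i, j)
  dup <- duplicated(cbind(lo, hi))
  if (any(dup)) {
    message(sum(dup), " duplicate edge(s) collapsed")
    lo <- lo[!dup]; hi <- hi[!dup]
  }
  e <- cbind(lo, hi)
  storage.mode(e) <- "integer"
  dimnames(e) <- NULL
  new("PPINetwork", labels = labels, edges = e)
}

#' @rdname PPINetwork-class
#' @export
setMethod("numNodes", "PPINetwork", function(object) length(object@labels))

#' @rdname PPINetwork-class
#' @export
setMethod("numEdges", "PPINetwork", function(object) nrow(object@edges))

#' @rdname PPINetwork-class
#' @export
setMethod("nodeLabels", "PPINetwork", function(object) object@labels)

#' @rdname PPINetwork-class
#' @export
setMethod("edgeMatrix", "PPINetwork", function(object) object@edges)

#' @rdname PPINetwork-class
#' @export
setMethod("adjacencyMatrix", "PPINetwork", function(object) {
  n <- length(object@labels)
  A <- matrix(0, n, n, dimnames = list(object@labels, object@labels))
  e <- object@edges
  if (nrow(e)) {
    A[e] <- 1
    A[e[, c(2L, 1L), drop = FALSE]] <- 1
  }
  A
})

#' @rdname averageDegree
#' @export
setMethod("averageDegree", "PPINetwork", function(net) {
  n <- numNodes(net)
  if (n == 0L) stop("average degree is undefined for an empty network")
  2 * numEdges(net) / n
})

setMethod("show", "PPINetwork", function(object) {
  cat("PPINetwork with", numNodes(object), "nodes and", numEdges(object),
      "edges (mean degree", sprintf("%.3f", averageDegree(object)), ")\n")
})

#' Convert a network to an igraph object
#'
#' @param net a [PPINetwork-class]
#' @return an undirected \pkg{igraph} graph with vertex attribute
#'   \code{name} carrying the node labels
#' @export
asIgraph <- function(net) {
  igraph::graph_from_data_frame(
    d = data.frame(
      from = net@labels[net@edges[, 1L]],
      to = net@labels[net@edges[, 2L]],
      stringsAsFactors = FALSE
    ),
    directed = FALSE,
    vertices = data.frame(name = net@labels, stringsAsFactors = FALSE)
  )
}

# canonical scalar keys of a network's edge set (lo-1)*n + hi; exact for
# the node counts handled here (< 2^26)
.edgeKeys <- function(net) {
  e <- net@edges
  (e[, 1L] - 1) * length(net@labels) + e[, 2L]
}

.pairKeys <- function(a, b, n) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  (lo - 1) * n + hi
}

#' Construct a node similarity matrix
#'
#' @param scores numeric matrix of non-negative similarity scores; rows are
#'   source-network nodes, columns target-network nodes.
#' @return a [NodeSimilarity-class]
#' @export
nodeSimilarity <- function(scores) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  new("NodeSimilarity", scores = scores)
}

#' @rdname NodeSimilarity-class
#' @export
setMethod("simScores", "NodeSimilarity", function(object) object@scores)

setMethod("show", "NodeSimilarity", function(object) {
  s <- object@scores
  cat("NodeSimilarity:", nrow(s), "x", ncol(s), "scores in [",
      sprintf("%.4g", min(s)), ",", sprintf("%.4g", max(s)), "];",
      sum(s > 0), "nonzero\n")
})

#' Construct an injective alignment
#'
#' @param targetOf integer vector; entry \code{i} is the target-node index
#'   aligned to source node \code{i}. Entries must be distinct.
#' @param nTargets number of nodes in the target network.
#' @return a [NetworkAlignment-class]
#' @examples
#' networkAlignment(c(3L, 1L, 2L), nTargets = 5L)
#' @export
networkAlignment <- function(targetOf, nTargets) {
  new("NetworkAlignment",
      targetOf = as.integer(targetOf), nTargets = as.integer(nTargets))
}

#' @rdname NetworkAlignment-class
#' @export
setMethod("targetIndices", "NetworkAlignment", function(object) object@targetOf)

setMethod("show", "NetworkAlignment", function(object) {
  cat("NetworkAlignment of", length(object@targetOf), "source nodes into",
      object@nTargets, "targets\n")
})

#' Aligned label pairs
#'
#' Returns the alignment as a two-column character matrix of
#' (source label, target label) rows, in source index order.
#'
#' @param alignment a [NetworkAlignment-class] (or integer vector)
#' @param net1,net2 the aligned [PPINetwork-class] objects
#' @export
alignedPairs <- function(alignment, net1, net2) {
  t <- .targetOf(alignment, numNodes(net1), numNodes(net2))
  cbind(source = net1@labels, target = net2@labels[t])
}

# accept either a NetworkAlignment or a bare integer vector
.targetOf <- function(alignment, n1 = NULL, n2 = NULL) {
  t <- if (is(alignment, "NetworkAlignment")) alignment@targetOf
       else as.integer(alignment)
  if (!is.null(n1) && length(t) != n1) {
    stop("alignment length ", length(t), " does not match source size ", n1)
  }
  if (!is.null(n2) && (any(t < 1L) || any(t > n2))) {
    stop("alignment targets out of range for a network of size ", n2)
  }
  t
}

#' Construct a GO annotation map
#'
#' @param terms named list mapping node labels to character vectors of GO
#'   term identifiers; duplicates within a set are removed.
#' @return a [GOAnnotation-class]
#' @export
goAnnotation <- function(terms = list()) {
  terms <- lapply(terms, function(x) unique(as.character(x)))
  new("GOAnnotation", terms = terms)
}

#' @rdname GOAnnotation-class
#' @export
setMethod("goTerms", "GOAnnotation", function(object, label) {
  x <- object@terms[[label]]
  if (is.null(x)) character() else x
})

setMethod("show", "GOAnnotation", function(object) {
  cat("GOAnnotation:", length(object@terms), "annotated labels,",
      length(unique(unlist(object@terms, use.names = FALSE))),
      "distinct terms\n")
})

setMethod("show", "SyntheticPair", function(object) {
  cat("SyntheticPair:", numNodes(object@net1), "->", numNodes(object@net2),
      "nodes;", object@nRewired, "of", numEdges(object@net1),
      "copied edges rewired\n")
})

setMethod("show", "BatParams", function(object) {
  cat("BatParams: pop", object@popSize, "| maxIters", object@maxIters,
      "| patience", object@patience,
      sprintf("| f [%g, %g] | theta %g | gamma %g | A0 %g | r0 %g\n",
              object@fMin, object@fMax, object@theta, object@gamma,
              object@loudness0, object@rate0))
})

setMethod("show", "BatAlignResult", function(object) {
  cat("BatAlignResult:", object@objective, "conserved edges after",
      object@iterations, "iterations",
      if (object@converged) "(stopped on patience)\n" else "(iteration cap)\n")
})
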