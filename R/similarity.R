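# Blended node similarity: S = alpha * B + (1 - alpha) * A1 B A2'
# with both terms max-normalized so alpha acts as a convex weight.

#' Scale a similarity matrix to [0, 1] by its global maximum
#'
#' Divides every entry by the matrix maximum when that maximum is positive;
#' an all-zero matrix is returned unchanged.
#'
#' @param x a [NodeSimilarity-class] or plain numeric matrix
#' @return same type as the input
#' @export
maxNormalize <- function(x) {
  m <- if (is(x, "NodeSimilarity")) x@scores else x
  mx <- max(m)
  if (mx > 0) m <- m / mx
  if (is(x, "NodeSimilarity")) nodeSimilarity(m) else m
}

#' Neighbourhood topology term of the blended similarity
#'
#' Entry (i, j) sums the similarity scores over all pairs (u, v) with u a
#' neighbour of source node i and v a neighbour of target node j — the
#' adjacency triple product \eqn{A_1 B A_2^T}. A node with high-scoring
#' neighbour pairs is topologically supported even when its own sequence
#' score is weak.
#'
#' @param B a [NodeSimilarity-class] (or matrix) of shape n1 x n2
#' @param net1,net2 the two [PPINetwork-class] objects
#' @return a [NodeSimilarity-class]
#' @export
topologyTerm <- function(B, net1, net2) {
  m <- if (is(B, "NodeSimilarity")) B@scores else B
  if (nrow(m) != numNodes(net1) || ncol(m) != numNodes(net2)) {
    stop("similarity matrix shape (", nrow(m), " x ", ncol(m),
         ") does not match the networks (", numNodes(net1), " x ",
         numNodes(net2), ")")
  }
  A1 <- adjacencyMatrix(net1)
  A2 <- adjacencyMatrix(net2)
  out <- A1 %*% m %*% A2 # A2 symmetric, so A2 == t(A2)
  dimnames(out) <- list(net1@labels, net2@labels)
  nodeSimilarity(out)
}

#' Blend sequence and topological node similarity
#'
#' Computes \eqn{S = \alpha B' + (1 - \alpha) T'} where \eqn{B'} is the
#' max-normalized sequence score matrix and \eqn{T'} the max-normalized
#' neighbourhood term [topologyTerm()] computed from \eqn{B'}. With
#' \code{alpha = 1} only sequence information is used; with
#' \code{alpha = 0} only network topology. Raw bit-scores and neighbour
#' sums live on very different scales, so each term is normalized to
#' \code{[0, 1]} before blending; the result is again in \code{[0, 1]}.
#'
#' @param B a [NodeSimilarity-class] (or matrix) of raw scores, n1 x n2
#' @param net1,net2 the two [PPINetwork-class] objects
#' @param alpha weight of the sequence term, in \code{[0, 1]}; default 0.4
#' @return a [NodeSimilarity-class]
#' @examples
#' n1 <- ppiNetwork(cbind(c("a", "b"), c("b", "c")))
#' n2 <- ppiNetwork(cbind(c("x", "y"), c("y", "z")))
#' B <- nodeSimilarity(diag(3))
#' blendedSimilarity(B, n1, n2, alpha = 0.4)
#' @export
blendedSimilarity <- function(B, net1, net2, alpha = 0.4) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("'alpha' must be a single value in [0, 1]")
  }
  Bn <- maxNormalize(if (is(B, "NodeSimilarity")) B@scores else B)
  Tn <- maxNormalize(topologyTerm(Bn, net1, net2)@scores)
  S <- alpha * Bn + (1 - alpha) * Tn
  dimnames(S) <- list(net1@labels, net2@labels)
  nodeSimilarity(S)
}
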