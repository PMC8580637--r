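# Alignment quality metrics: topological (EC, ICS, S3) and biological
# (GOC), plus node correctness against a known ground-truth mapping.

#' Image of the source edge set under an alignment
#'
#' Returns the conserved target edges — the target-network edges that are
#' images of source edges — as a two-column character matrix of target
#' labels. Its row count equals [conservedEdges()].
#'
#' @inheritParams conservedEdges
#' @return two-column character matrix (may have zero rows)
#' @export
conservedEdgeImage <- function(alignment, net1, net2) {
  t <- .targetOf(alignment, numNodes(net1), numNodes(net2))
  e1 <- net1@edges
  if (!nrow(e1)) {
    return(matrix(character(), 0L, 2L))
  }
  a <- t[e1[, 1L]]; b <- t[e1[, 2L]]
  cons <- .pairKeys(a, b, numNodes(net2)) %in% .edgeKeys(net2)
  lo <- pmin(a, b)[cons]; hi <- pmax(a, b)[cons]
  unname(cbind(net2@labels[lo], net2@labels[hi]))
}

#' Edges of the target network induced on the aligned node set
#'
#' Counts the target edges with both endpoints in f(V1), the image of the
#' source node set.
#'
#' @param alignment a [NetworkAlignment-class] or integer target vector
#' @param net2 target [PPINetwork-class]
#' @return integer count
#' @export
inducedEdgeCount <- function(alignment, net2) {
  t <- .targetOf(alignment, NULL, numNodes(net2))
  inSet <- logical(numNodes(net2))
  inSet[t] <- TRUE
  e2 <- net2@edges
  if (!nrow(e2)) return(0L)
  sum(inSet[e2[, 1L]] & inSet[e2[, 2L]])
}

#' Edge correctness (EC)
#'
#' Conserved edges divided by the number of source edges. Penalizes mapping
#' sparse regions onto dense ones but not the converse.
#'
#' @inheritParams conservedEdges
#' @return numeric in [0, 1], or \code{NA} when the source has no edges
#' @export
edgeCorrectness <- function(alignment, net1, net2) {
  m1 <- numEdges(net1)
  if (m1 == 0L) return(NA_real_)
  conservedEdges(alignment, net1, net2) / m1
}

#' Induced conserved structure (ICS)
#'
#' Conserved edges divided by the target edges induced on the aligned node
#' set. Penalizes mapping dense regions onto sparse ones but not the
#' converse.
#'
#' @inheritParams conservedEdges
#' @return numeric in [0, 1], or \code{NA} when the induced count is zero
#' @export
inducedConservedStructure <- function(alignment, net1, net2) {
  ind <- inducedEdgeCount(alignment, net2)
  if (ind == 0L) return(NA_real_)
  conservedEdges(alignment, net1, net2) / ind
}

#' Symmetric substructure score (S3)
#'
#' \deqn{S^3 = |f(E_1)| / (|E_1| + |E_2(G_2(f(V_1)))| - |f(E_1)|)}
#' — conserved edges over the union of source edges and induced target
#' edges. Unlike EC and ICS it penalizes both sparse-to-dense and
#' dense-to-sparse misalignment, and never exceeds either of them.
#'
#' @inheritParams conservedEdges
#' @return numeric in [0, 1], or \code{NA} when both networks are edgeless
#'   on the aligned region
#' @examples
#' tri <- ppiNetwork(cbind(c("a", "b", "c"), c("b", "c", "a")))
#' s3Score(1:3, tri, tri) # 1 for a perfect self-alignment
#' @export
s3Score <- function(alignment, net1, net2) {
  cons <- conservedEdges(alignment, net1, net2)
  ind <- inducedEdgeCount(alignment, net2)
  denom <- numEdges(net1) + ind - cons
  if (denom == 0L) return(NA_real_)
  cons / denom
}

#' Gene Ontology consistency (GOC)
#'
#' Sums, over every aligned pair (u, f(u)), the Jaccard index of their GO
#' term sets. Pairs where both sets are empty contribute 0 to the sum and
#' are excluded from the mean, which is reported alongside for cross-size
#' comparison.
#'
#' @inheritParams conservedEdges
#' @param annot1,annot2 [GOAnnotation-class] for source and target nodes
#' @return list with \code{sum} (the literal GOC score) and \code{mean}
#'   (Jaccard mean over pairs with at least one term; \code{NA} when there
#'   are none)
#' @export
gocScore <- function(alignment, net1, net2, annot1, annot2) {
  t <- .targetOf(alignment, numNodes(net1), numNodes(net2))
  jac <- vapply(seq_along(t), function(i) {
    g1 <- goTerms(annot1, net1@labels[i])
    g2 <- goTerms(annot2, net2@labels[t[i]])
    u <- length(union(g1, g2))
    if (u == 0L) return(NA_real_)
    length(intersect(g1, g2)) / u
  }, numeric(1L))
  annotated <- !is.na(jac)
  list(
    sum = sum(jac[annotated]),
    mean = if (any(annotated)) mean(jac[annotated]) else NA_real_
  )
}

#' Node correctness against a ground-truth mapping
#'
#' Fraction of source nodes aligned to their true targets; only meaningful
#' for synthetic pairs where the truth is known.
#'
#' @param alignment a [NetworkAlignment-class] or integer target vector
#' @param trueMap the ground-truth alignment, same source length
#' @return numeric in [0, 1]
#' @export
nodeCorrectness <- function(alignment, trueMap) {
  a <- if (is(alignment, "NetworkAlignment")) alignment@targetOf else as.integer(alignment)
  b <- if (is(trueMap, "NetworkAlignment")) trueMap@targetOf else as.integer(trueMap)
  if (length(a) != length(b)) {
    stop("alignment and ground truth cover different numbers of source nodes")
  }
  mean(a == b)
}

#' Full quality report for an alignment
#'
#' Computes all defined metrics in one pass. Metrics whose denominator is
#' zero, and metrics whose inputs (annotations, ground truth) were not
#' supplied, are reported as \code{NA}.
#'
#' @inheritParams conservedEdges
#' @param annot1,annot2 optional [GOAnnotation-class] objects
#' @param trueMap optional ground-truth [NetworkAlignment-class]
#' @return named list: \code{conserved}, \code{induced}, \code{ec},
#'   \code{ics}, \code{s3}, \code{gocSum}, \code{gocMean},
#'   \code{nodeCorrectness}
#' @export
alignmentReport <- function(alignment, net1, net2,
                            annot1 = NULL, annot2 = NULL, trueMap = NULL) {
  goc <- if (!is.null(annot1) && !is.null(annot2)) {
    gocScore(alignment, net1, net2, annot1, annot2)
  } else {
    list(sum = NA_real_, mean = NA_real_)
  }
  list(
    conserved = conservedEdges(alignment, net1, net2),
    induced = inducedEdgeCount(alignment, net2),
    ec = edgeCorrectness(alignment, net1, net2),
    ics = inducedConservedStructure(alignment, net1, net2),
    s3 = s3Score(alignment, net1, net2),
    gocSum = goc$sum,
    gocMean = goc$mean,
    nodeCorrectness = if (is.null(trueMap)) NA_real_ else
      nodeCorrectness(alignment, trueMap)
  )
}
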