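# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (adjacency-matrix lookups, nested loops, explicit
# enumeration) so they never share code paths with the implementation.

# network with n nodes from an explicit integer edge matrix
makeNet <- function(n, edges) {
  e <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(e)) {
    e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    e <- unique(e[e[, 1L] != e[, 2L], , drop = FALSE])
  }
  storage.mode(e) <- "integer"
  new("PPINetwork", labels = paste0("n", seq_len(n)), edges = e)
}

randomNetwork <- function(n, p) {
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  makeNet(n, pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE])
}

randomInjection <- function(n1, n2) sample.int(n2, n1)

# conserved edges by direct adjacency lookup
oracleConserved <- function(targetOf, net1, net2) {
  A2 <- adjacencyMatrix(net2)
  e1 <- edgeMatrix(net1)
  cnt <- 0L
  for (k in seq_len(nrow(e1))) {
    if (A2[targetOf[e1[k, 1L]], targetOf[e1[k, 2L]]] == 1) cnt <- cnt + 1L
  }
  cnt
}

# induced target edges by filtering E2 on endpoint membership
oracleInduced <- function(targetOf, net2) {
  e2 <- edgeMatrix(net2)
  cnt <- 0L
  for (k in seq_len(nrow(e2))) {
    if (e2[k, 1L] %in% targetOf && e2[k, 2L] %in% targetOf) cnt <- cnt + 1L
  }
  cnt
}

# GOC sum/mean by an explicit per-pair Jaccard loop
oracleGoc <- function(targetOf, net1, net2, terms1, terms2) {
  s <- 0; npairs <- 0L
  for (i in seq_along(targetOf)) {
    g1 <- terms1[[nodeLabels(net1)[i]]]
    g2 <- terms2[[nodeLabels(net2)[targetOf[i]]]]
    if (is.null(g1)) g1 <- character()
    if (is.null(g2)) g2 <- character()
    u <- union(g1, g2)
    if (length(u)) {
      s <- s + length(intersect(g1, g2)) / length(u)
      npairs <- npairs + 1L
    }
  }
  list(sum = s, mean = if (npairs) s / npairs else NA_real_)
}

# neighbour-pair score sum by triple nested loop
oracleTopologyTerm <- function(B, net1, net2) {
  A1 <- adjacencyMatrix(net1)
  A2 <- adjacencyMatrix(net2)
  out <- matrix(0, nrow(B), ncol(B))
  for (i in seq_len(nrow(B))) {
    for (j in seq_len(ncol(B))) {
      for (u in which(A1[i, ] == 1)) {
        for (v in which(A2[j, ] == 1)) {
          out[i, j] <- out[i, j] + B[u, v]
        }
      }
    }
  }
  out
}

# sequential global argmax with row/column deletion (distinct entries only)
oracleGreedy <- function(S) {
  n1 <- nrow(S)
  target <- rep(NA_integer_, n1)
  repeat {
    if (max(S, na.rm = TRUE) <= 0) break
    ij <- which(S == max(S, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    target[ij[1L]] <- ij[2L]
    S[ij[1L], ] <- NA
    S[, ij[2L]] <- NA
    if (all(is.na(S))) break
  }
  target
}

# all permutations of 1..n, one per row
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

# at least k distinct canonical pair keys (lo - 1) * n + hi, lo < hi
.randomPairKeys <- function(n, k) {
  keys <- numeric(0)
  while (length(keys) < k) {
    a <- sample.int(n, k, replace = TRUE)
    b <- sample.int(n, k, replace = TRUE)
    ok <- a != b
    keys <- unique(c(keys, (pmin(a, b)[ok] - 1) * n + pmax(a, b)[ok]))
  }
  keys
}

expect_injective <- function(targetOf, n2) {
  expect_false(anyNA(targetOf))
  expect_true(all(targetOf >= 1L & targetOf <= n2))
  expect_equal(anyDuplicated(targetOf), 0L)
}
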