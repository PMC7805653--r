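# Shared fixtures and independent oracles for the test suite.

# Random small attributed graph (Erdos-Renyi by edge inclusion).
randomGraph <- function(n, pEdge = 0.4, labels = c("a", "b"), symbols = NULL,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < pEdge
  e <- pairs[keep, , drop = FALSE]
  attributedGraph(
    e, n,
    vertexLabels = sample(labels, n, replace = TRUE),
    edgeSymbols = if (!is.null(symbols) && nrow(e))
      sample(symbols, nrow(e), replace = TRUE) else NULL)
}

# Independent all-pairs shortest-path oracle (Floyd-Warshall on the dense
# adjacency), deliberately not using igraph.
floydWarshall <- function(g) {
  n <- g@nVertices
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  if (nrow(g@edges)) for (k in seq_len(nrow(g@edges))) {
    u <- g@edges[k, 1L]; v <- g@edges[k, 2L]
    d[u, v] <- 1; d[v, u] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Loop-form shift/aggregate oracle: direct double sum over types and parts.
aggregateLoopOracle <- function(h, l, Hprev) {
  alpha <- piAlphabets(h)[[l]]
  n <- length(alpha)
  d <- ncol(Hprev)
  out <- matrix(0, levelSizes(h)[l + 1L], n * d)
  for (k in seq_along(alpha)) {
    R <- as.matrix(relationMatrix(h, l, alpha[k]))
    for (s in seq_len(nrow(R))) for (sp in seq_len(ncol(R)))
      if (R[s, sp] != 0)
        out[s, ] <- out[s, ] + R[s, sp] * shiftRepresentation(Hprev[sp, ], k - 1L, n)
  }
  out
}

# From-scratch recursive implementation of the per-object forward
# computation (object-by-object, no matrix algebra).
forwardRecursionOracle <- function(h, model) {
  L <- nLevels(h)
  applyMLP <- function(x, layers, rawFinal) {
    for (k in seq_along(layers)) {
      z <- as.numeric(x %*% layers[[k]]$W) + layers[[k]]$b
      x <- if (k == length(layers) && rawFinal) z
           else ifelse(z > 0, z, model@leakySlope * z)
    }
    x
  }
  reps <- vector("list", L + 1L)
  nBottom <- levelSizes(h)[1L]
  reps[[1L]] <- t(vapply(seq_len(nBottom), function(s)
    applyMLP(bottomAttributes(h)[s, , drop = FALSE], model@params[[1L]],
             rawFinal = (L == 0L) && !model@activateTop),
    numeric(model@outDims[1L])))
  for (l in seq_len(L)) {
    alpha <- piAlphabets(h)[[l]]
    nT <- length(alpha)
    d <- ncol(reps[[l]])
    rows <- t(vapply(seq_len(levelSizes(h)[l + 1L]), function(s) {
      a <- numeric(nT * d)
      for (k in seq_along(alpha)) {
        R <- relationMatrix(h, l, alpha[k])
        for (sp in seq_len(ncol(R))) if (R[s, sp] != 0)
          a <- a + R[s, sp] * shiftRepresentation(reps[[l]][sp, ], k - 1L, nT)
      }
      applyMLP(matrix(a, 1L), model@params[[l + 1L]],
               rawFinal = (l == L) && !model@activateTop)
    }, numeric(model@outDims[l + 1L])))
    reps[[l + 1L]] <- rows
  }
  reps
}

# Finite-difference gradient check; returns the worst relative error over a
# deterministic subsample of coordinates.
finiteDiffCheck <- function(h, labels, model, nCoords = 5L, eps = 1e-6) {
  g <- saenGradients(h, labels, model)
  worst <- 0
  for (l in seq_along(model@params)) for (k in seq_along(model@params[[l]]))
    for (nm in c("W", "b")) {
      P <- model@params[[l]][[k]][[nm]]
      for (idx in seq_len(min(length(P), nCoords))) {
        m2 <- model
        m2@params[[l]][[k]][[nm]][idx] <- P[idx] + eps
        lp <- saenGradients(h, labels, m2)$loss
        m2@params[[l]][[k]][[nm]][idx] <- P[idx] - eps
        lm <- saenGradients(h, labels, m2)$loss
        num <- (lp - lm) / (2 * eps)
        an <- g$grads[[l]][[k]][[nm]][idx]
        worst <- max(worst, abs(num - an) / max(1e-8, abs(num), abs(an)))
      }
    }
  worst
}

# Relabel the vertices of a graph by a permutation (oracle-side helper for
# isomorphism-invariance checks).
permuteGraph <- function(g, perm) {
  e <- g@edges
  if (nrow(e)) e <- cbind(perm[e[, 1L]], perm[e[, 2L]])
  inv <- order(perm)
  attributedGraph(e, g@nVertices,
                  attributes = g@attributes[inv, , drop = FALSE],
                  vertexLabels = if (length(g@vertexLabels)) g@vertexLabels[inv] else NULL,
                  edgeSymbols = if (length(g@edgeSymbols)) g@edgeSymbols else NULL)
}
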