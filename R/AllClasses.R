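#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal bdiag rowSums colSums t crossprod
#' @importFrom stats rnorm runif sd
#' @importFrom utils head
NULL

#' Attributed undirected graph
#'
#' A simple undirected graph with a numeric attribute vector per vertex and,
#' optionally, a categorical symbol per edge. Edges are stored canonically
#' with the smaller vertex index first; self loops and parallel edges are
#' rejected. Vertices are indexed 1..n.
#'
#' @slot nVertices number of vertices.
#' @slot edges integer matrix with one row per undirected edge, columns
#'   (u, v), u < v.
#' @slot attributes numeric matrix with one row per vertex (the vector
#'   attached to each vertex; categorical labels are one-hot encoded
#'   upstream, at dataset assembly).
#' @slot vertexLabels optional character vector of raw categorical labels
#'   (length nVertices or 0).
#' @slot edgeSymbols optional character vector of edge symbols, parallel to
#'   the rows of `edges` (length nrow(edges) or 0).
#'
#' @seealso [attributedGraph()]
#' @export
setClass("AttributedGraph",
  representation(
    nVertices    = "integer",
    edges        = "matrix",
    attributes   = "matrix",
    vertexLabels = "character",
    edgeSymbols  = "character"
  )
)

setValidity("AttributedGraph", function(object) {
  n <- object@nVertices
  e <- object@edges
  msgs <- character(0)
  if (length(n) != 1L || is.na(n) || n < 1L)
    msgs <- c(msgs, "graph must have at least one vertex")
  if (ncol(e) != 2L)
    msgs <- c(msgs, "edges must have two columns")
  if (nrow(e) > 0L) {
    if (any(e < 1L) || any(e > n))
      msgs <- c(msgs, "edge endpoints out of range")
    if (any(e[, 1L] == e[, 2L]))
      msgs <- c(msgs, "self loops are not allowed")
    if (any(e[, 1L] > e[, 2L]))
      msgs <- c(msgs, "edges must be stored with the smaller endpoint first")
    key <- paste(e[, 1L], e[, 2L])
    if (anyDuplicated(key))
      msgs <- c(msgs, "parallel edges are not allowed")
  }
  if (nrow(object@attributes) != n)
    msgs <- c(msgs, "attributes must have one row per vertex")
  if (length(object@vertexLabels) != 0L && length(object@vertexLabels) != n)
    msgs <- c(msgs, "vertexLabels must be empty or have one entry per vertex")
  if (length(object@edgeSymbols) != 0L && length(object@edgeSymbols) != nrow(e))
    msgs <- c(msgs, "edgeSymbols must be empty or have one entry per edge")
  if (length(msgs)) msgs else TRUE
})

#' Multi-level part-of hierarchy (H-decomposition)
#'
#' Levels S_0..S_L of objects, connected by typed part-of relations between
#' consecutive levels only. For each level l >= 1 and each membership type
#' pi in the level's alphabet Pi_l there is a sparse non-negative integer
#' matrix R_{l,pi} of shape |S_l| x |S_{l-1}|; entry (s, s') counts how many
#' times s' is a part of s with role pi. Attributes live on the bottom
#' level as a dense matrix with one row per atomic object.
#'
#' List slot index l corresponds to the relation entering level l from
#' level l-1 (so `relations[[1]]` connects S_1 to S_0). The alphabet order
#' is fixed at construction and defines the column-block layout of the
#' concatenated level matrix used by the shift step.
#'
#' @slot levelSizes integer vector of length L+1 with |S_l|, l = 0..L.
#' @slot objectIds list of length L+1; character ids of the objects of each
#'   level, in their fixed row order.
#' @slot piAlphabets list of length L; ordered, duplicate-free membership
#'   type alphabet Pi_l for each l = 1..L.
#' @slot relations list of length L; element l is a named list over Pi_l of
#'   sparse matrices R_{l,pi}.
#' @slot attributes numeric matrix |S_0| x p of bottom-level attributes.
#' @slot compressed whether the object is the output of domain compression
#'   (in which case relation entries are cardinalities and may exceed 1).
#'
#' @seealso [buildHDecomposition()], [buildEGD()], [buildNEGD()],
#'   [domainCompress()]
#' @export
setClass("HDecomposition",
  representation(
    levelSizes  = "integer",
    objectIds   = "list",
    piAlphabets = "list",
    relations   = "list",
    attributes  = "matrix",
    compressed  = "logical"
  )
)

setValidity("HDecomposition", function(object) {
  sizes <- object@levelSizes
  L <- length(sizes) - 1L
  msgs <- character(0)
  if (L < 1L) msgs <- c(msgs, "need at least two levels")
  if (any(sizes < 1L)) msgs <- c(msgs, "every level must be non-empty")
  if (length(object@objectIds) != L + 1L)
    msgs <- c(msgs, "objectIds must have one entry per level")
  for (l in seq_along(object@objectIds)) {
    ids <- object@objectIds[[l]]
    if (length(ids) != sizes[l])
      msgs <- c(msgs, sprintf("objectIds[[%d]] length disagrees with levelSizes", l))
    if (anyDuplicated(ids))
      msgs <- c(msgs, sprintf("duplicate object ids at level %d", l - 1L))
  }
  if (anyDuplicated(unlist(object@objectIds)))
    msgs <- c(msgs, "levels must be disjoint (object ids repeat across levels)")
  if (length(object@piAlphabets) != L || length(object@relations) != L)
    msgs <- c(msgs, "piAlphabets and relations must have one entry per level l = 1..L")
  else for (l in seq_len(L)) {
    alpha <- object@piAlphabets[[l]]
    if (anyDuplicated(alpha))
      msgs <- c(msgs, sprintf("membership alphabet at level %d has duplicates", l))
    rel <- object@relations[[l]]
    if (!identical(names(rel), alpha))
      msgs <- c(msgs, sprintf("relations[[%d]] must be named by the level alphabet, in order", l))
    tot <- NULL
    for (pi in names(rel)) {
      R <- rel[[pi]]
      if (nrow(R) != sizes[l + 1L] || ncol(R) != sizes[l])
        msgs <- c(msgs, sprintf("R_{%d,%s} has wrong shape (relations must span consecutive levels)", l, pi))
      v <- R@x
      if (length(v) && (any(v < 0) || any(v != round(v))))
        msgs <- c(msgs, sprintf("R_{%d,%s} must hold non-negative integer counts", l, pi))
      tot <- if (is.null(tot)) Matrix::rowSums(R) else tot + Matrix::rowSums(R)
    }
    if (!is.null(tot) && any(tot == 0))
      msgs <- c(msgs, sprintf("level %d has compound objects with no parts", l))
  }
  if (nrow(object@attributes) != sizes[1L])
    msgs <- c(msgs, "attributes must have one row per bottom-level object")
  if (length(msgs)) msgs else TRUE
})

#' Compression/decompression maps of a domain-compressed hierarchy
#'
#' Per-level pairs (C_l, D_l) together with the compressed attribute matrix
#' and compressed typed relations. D_l is boolean with exactly one 1 per row
#' (each original object falls in exactly one equivalence class); C_l is a
#' left pseudo-inverse of D_l, either in averaging form (transpose of D with
#' rows divided by their sums) or representer form (one nonzero per row,
#' picking the first original object of each class).
#'
#' @slot C,D lists of length L+1 of sparse matrices (index l+1 holds the
#'   level-l pair).
#' @slot Xcomp compressed bottom-level attribute matrix (distinct rows of X
#'   in first-occurrence order).
#' @slot relationsComp compressed relations, same layout as the
#'   `relations` slot of [HDecomposition-class].
#' @slot piAlphabets alphabets carried over from the source hierarchy.
#' @slot originalSizes,compressedSizes per-level object counts before and
#'   after compression.
#' @slot variant "averaging" or "representer".
#' @seealso [domainCompress()], [compressedHDecomposition()]
#' @export
setClass("CompressionMaps",
  representation(
    C               = "list",
    D               = "list",
    Xcomp           = "matrix",
    relationsComp   = "list",
    piAlphabets     = "list",
    originalSizes   = "integer",
    compressedSizes = "integer",
    variant         = "character"
  )
)

setValidity("CompressionMaps", function(object) {
  msgs <- character(0)
  if (length(object@C) != length(object@D))
    msgs <- c(msgs, "C and D must pair up per level")
  for (l in seq_along(object@D)) {
    D <- object@D[[l]]
    if (any(Matrix::rowSums(D) != 1))
      msgs <- c(msgs, sprintf("each row of D_%d must have exactly one 1", l - 1L))
    CD <- object@C[[l]] %*% D
    if (max(abs(CD - Diagonal(ncol(D)))) > 1e-12)
      msgs <- c(msgs, sprintf("C_%d is not a left inverse of D_%d", l - 1L, l - 1L))
  }
  if (any(object@compressedSizes > object@originalSizes))
    msgs <- c(msgs, "compression cannot increase level sizes")
  if (length(msgs)) msgs else TRUE
})

#' Per-level feedforward parameters of a shift-aggregate-extract network
#'
#' One extractor per level of the hierarchy. The level-l extractor consumes
#' aggregate rows of width n(l) * d(l-1) (p for l = 0, with n(0) = 1 by
#' convention) and emits d(l)-dimensional representations; the top-level
#' output width is the class count. All hidden and output units use leaky
#' rectification except the top level's final layer, which emits raw class
#' scores for the loss.
#'
#' @slot params list of length L+1; element l+1 is the layer list of the
#'   level-l extractor, each layer a list with weight matrix `W` (in x out)
#'   and bias vector `b`.
#' @slot p bottom attribute width.
#' @slot nTypes integer vector of length L with the alphabet sizes n(l).
#' @slot outDims integer vector of length L+1 with the representation
#'   widths d(l); `outDims[L+1]` equals `nClasses`.
#' @slot nClasses number of classes.
#' @slot leakySlope negative-part slope of the leaky rectifier.
#' @slot l2 L2 penalty coefficient on the weights.
#' @slot activateTop whether to apply the activation to the final scores
#'   (default layout leaves them raw for the cross-entropy head).
#' @seealso [newSaenModel()], [saenForward()], [saenTrain()]
#' @export
setClass("SaenModel",
  representation(
    params      = "list",
    p           = "integer",
    nTypes      = "integer",
    outDims     = "integer",
    nClasses    = "integer",
    leakySlope  = "numeric",
    l2          = "numeric",
    activateTop = "logical"
  )
)

setValidity("SaenModel", function(object) {
  msgs <- character(0)
  L <- length(object@nTypes)
  if (length(object@params) != L + 1L)
    msgs <- c(msgs, "need one extractor per level")
  if (length(object@outDims) != L + 1L)
    msgs <- c(msgs, "outDims must have one entry per level")
  if (any(object@outDims < 1L)) msgs <- c(msgs, "all representation widths must be >= 1")
  if (object@outDims[L + 1L] != object@nClasses)
    msgs <- c(msgs, "top-level output width must equal the class count")
  for (l in 0:L) {
    layers <- object@params[[l + 1L]]
    wIn <- if (l == 0L) object@p else object@nTypes[l] * object@outDims[l]
    for (k in seq_along(layers)) {
      W <- layers[[k]]$W
      if (nrow(W) != wIn)
        msgs <- c(msgs, sprintf("level %d layer %d input width %d != expected %d", l, k, nrow(W), wIn))
      if (length(layers[[k]]$b) != ncol(W))
        msgs <- c(msgs, sprintf("level %d layer %d bias length mismatch", l, k))
      wIn <- ncol(W)
    }
    if (wIn != object@outDims[l + 1L])
      msgs <- c(msgs, sprintf("level %d output width %d != declared d(l) = %d", l, wIn, object@outDims[l + 1L]))
  }
  if (length(msgs)) msgs else TRUE
})

#' Labeled collection of attributed graphs
#'
#' @slot graphs list of [AttributedGraph-class] objects.
#' @slot labels integer class labels, contiguous 0..C-1.
#' @slot labelLevels original label values, in the order of their codes.
#' @slot name dataset name.
#' @slot provenance list describing where the data came from (loaded
#'   directory, or generator parameters and seed).
#' @seealso [readBenchmarkDataset()], [generateTwoClassCollection()]
#' @export
setClass("GraphDataset",
  representation(
    graphs      = "list",
    labels      = "integer",
    labelLevels = "character",
    name        = "character",
    provenance  = "list"
  )
)

setValidity("GraphDataset", function(object) {
  msgs <- character(0)
  if (length(object@graphs) == 0L) msgs <- c(msgs, "dataset must contain at least one graph")
  if (length(object@labels) != length(object@graphs))
    msgs <- c(msgs, "one label per graph required")
  C <- length(object@labelLevels)
  if (C > 0L && !all(object@labels %in% 0:(C - 1L)))
    msgs <- c(msgs, "labels must be contiguous codes 0..C-1")
  if (length(msgs)) msgs else TRUE
})

#' Result of repeated stratified k-fold cross-validation
#'
#' @slot repeatAccuracies one pooled accuracy per repetition.
#' @slot mean,sd mean and standard deviation of the repeat accuracies.
#' @slot config snapshot of the decomposition and model configuration.
#' @slot seed base seed; repeat r uses seed + r.
#' @slot folds list (one per repeat) of integer fold assignments per graph.
#' @export
setClass("CVResult",
  representation(
    repeatAccuracies = "numeric",
    mean             = "numeric",
    sd               = "numeric",
    config           = "list",
    seed             = "integer",
    folds            = "list"
  )
)

setMethod("show", "AttributedGraph", function(object) {
  cat(sprintf("AttributedGraph: %d vertices, %d edges, %d attribute dim%s%s\n",
              object@nVertices, nrow(object@edges), ncol(object@attributes),
              if (length(object@vertexLabels)) ", labeled vertices" else "",
              if (length(object@edgeSymbols)) ", symbolic edges" else ""))
})

setMethod("show", "HDecomposition", function(object) {
  L <- length(object@levelSizes) - 1L
  cat(sprintf("HDecomposition with %d levels%s\n", L + 1L,
              if (object@compressed) " (compressed)" else ""))
  cat("  level sizes:", paste(object@levelSizes, collapse = ", "), "\n")
  cat("  alphabets:  ",
      paste(vapply(object@piAlphabets, function(a) paste0("{", paste(a, collapse = ","), "}"),
                   character(1)), collapse = " "), "\n")
  cat(sprintf("  bottom attributes: %d x %d\n",
              nrow(object@attributes), ncol(object@attributes)))
})

setMethod("show", "CompressionMaps", function(object) {
  cat(sprintf("CompressionMaps (%s pseudo-inverse)\n", object@variant))
  cat("  sizes:", paste(sprintf("%d->%d", object@originalSizes, object@compressedSizes),
                        collapse = ", "), "\n")
})

setMethod("show", "SaenModel", function(object) {
  L <- length(object@nTypes)
  cat(sprintf("SaenModel: %d levels, p = %d, classes = %d\n", L + 1L, object@p, object@nClasses))
  for (l in 0:L) {
    widths <- vapply(object@params[[l + 1L]], function(x) ncol(x$W), integer(1))
    cat(sprintf("  level %d: layers %s\n", l, paste(widths, collapse = "-")))
  }
})

setMethod("show", "GraphDataset", function(object) {
  cat(sprintf("GraphDataset '%s': %d graphs, %d classes\n",
              object@name, length(object@graphs), length(object@labelLevels)))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %d repeats, accuracy %.4f +/- %.4f\n",
              length(object@repeatAccuracies), object@mean, object@sd))
})
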