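#' Assemble a labeled graph dataset
#'
#' Class labels are recoded to contiguous integers 0..C-1 in sorted order
#' of the original values; the original values are kept in `labelLevels`.
#' When every graph carries categorical vertex labels and no explicit
#' attributes were supplied, labels are one-hot encoded over the sorted
#' label alphabet of the whole collection, so attribute columns line up
#' across graphs.
#'
#' @param graphs list of [AttributedGraph-class] objects.
#' @param labels per-graph class labels (any atomic type).
#' @param name dataset name.
#' @param provenance free-form provenance record.
#' @param encodeLabels re-encode vertex labels over the collection-wide
#'   alphabet (default TRUE when all graphs are labeled).
#' @return a [GraphDataset-class].
#' @export
newGraphDataset <- function(graphs, labels, name = "dataset",
                            provenance = list(), encodeLabels = TRUE) {
  if (length(graphs) == 0L) stop("dataset must contain at least one graph")
  lev <- sort(unique(labels))
  codes <- as.integer(match(labels, lev) - 1L)
  allLabeled <- all(vapply(graphs, function(g) length(g@vertexLabels) > 0L, logical(1)))
  if (encodeLabels && allLabeled) {
    alphabet <- sort(unique(unlist(lapply(graphs, function(g) g@vertexLabels))))
    graphs <- lapply(graphs, function(g) {
      g@attributes <- oneHot(g@vertexLabels, alphabet)
      g
    })
  }
  new("GraphDataset", graphs = graphs, labels = codes,
      labelLevels = as.character(lev), name = name, provenance = provenance)
}

.readIntLines <- function(path) {
  as.integer(trimws(readLines(path)))
}

#' Read a multi-file graph-classification benchmark directory
#'
#' Expects the standard layout: `name_A.txt` (comma-separated 1-based
#' global vertex-id pairs), `name_graph_indicator.txt` (graph id per
#' vertex), `name_graph_labels.txt` (class per graph) and optionally
#' `name_node_labels.txt`, `name_node_attributes.txt` and
#' `name_edge_labels.txt`. Parsing is whitespace tolerant and an edge
#' listed in both directions is stored once. Node labels are one-hot
#' encoded over the dataset when no attribute file is present.
#'
#' @param dir directory holding the files.
#' @param name dataset name (file prefix).
#' @return a [GraphDataset-class].
#' @export
readBenchmarkDataset <- function(dir, name) {
  pathOf <- function(suffix) file.path(dir, paste0(name, "_", suffix, ".txt"))
  for (mandatory in c("A", "graph_indicator", "graph_labels"))
    if (!file.exists(pathOf(mandatory)))
      stop(sprintf("missing mandatory file %s", pathOf(mandatory)))
  indicator <- .readIntLines(pathOf("graph_indicator"))
  glabels <- trimws(readLines(pathOf("graph_labels")))
  nG <- length(glabels)
  nV <- length(indicator)
  if (any(indicator < 1L) || any(indicator > nG))
    stop("graph_indicator references a nonexistent graph id")
  edgeLines <- trimws(readLines(pathOf("A")))
  edgeLines <- edgeLines[nzchar(edgeLines)]
  parts <- strsplit(edgeLines, "[,[:space:]]+")
  if (length(parts) && any(lengths(parts) != 2L))
    stop("malformed edge line in the A file")
  E <- if (length(parts)) {
    matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
  } else matrix(integer(0), 0L, 2L)
  if (nrow(E) && (any(is.na(E)) || any(E < 1L) || any(E > nV)))
    stop("dangling vertex id in the edge list")
  if (nrow(E) && any(indicator[E[, 1L]] != indicator[E[, 2L]]))
    stop("edge connects vertices of different graphs")
  nodeLabels <- if (file.exists(pathOf("node_labels")))
    trimws(readLines(pathOf("node_labels"))) else NULL
  if (!is.null(nodeLabels) && length(nodeLabels) != nV)
    stop("vertex count mismatch between node_labels and graph_indicator")
  nodeAttrs <- if (file.exists(pathOf("node_attributes"))) {
    rows <- strsplit(trimws(readLines(pathOf("node_attributes"))), "[,[:space:]]+")
    if (length(rows) != nV)
      stop("vertex count mismatch between node_attributes and graph_indicator")
    matrix(as.numeric(unlist(rows)), nrow = nV, byrow = TRUE)
  } else NULL
  edgeLabels <- if (file.exists(pathOf("edge_labels"))) {
    el <- trimws(readLines(pathOf("edge_labels")))
    if (length(el) != nrow(E))
      stop("edge count mismatch between edge_labels and A")
    el
  } else NULL
  globalToLocal <- integer(nV)
  graphs <- vector("list", nG)
  for (gi in seq_len(nG)) {
    vs <- which(indicator == gi)
    if (length(vs) == 0L) stop(sprintf("graph %d has no vertices", gi))
    globalToLocal[vs] <- seq_along(vs)
    rows <- if (nrow(E)) which(indicator[E[, 1L]] == gi) else integer(0)
    e <- cbind(globalToLocal[E[rows, 1L]], globalToLocal[E[rows, 2L]])
    graphs[[gi]] <- attributedGraph(
      e, length(vs),
      attributes   = if (!is.null(nodeAttrs)) nodeAttrs[vs, , drop = FALSE] else NULL,
      vertexLabels = if (!is.null(nodeLabels)) nodeLabels[vs] else NULL,
      edgeSymbols  = if (!is.null(edgeLabels) && length(rows)) edgeLabels[rows]
                     else if (!is.null(edgeLabels)) character(0) else NULL)
  }
  newGraphDataset(graphs, glabels, name = name,
                  provenance = list(source = "file", dir = dir),
                  encodeLabels = is.null(nodeAttrs))
}

#' Write a dataset in the multi-file benchmark layout
#'
#' Inverse of [readBenchmarkDataset()] up to vertex ordering: each
#' undirected edge is listed once, graph labels are written as the original
#' (pre-recode) values, vertex labels go to `name_node_labels.txt` when all
#' graphs carry them and to `name_node_attributes.txt` otherwise, and edge
#' symbols go to `name_edge_labels.txt` when present.
#'
#' @param ds a [GraphDataset-class].
#' @param dir output directory (created if needed).
#' @param name file prefix (default: the dataset's name).
#' @return `dir`, invisibly.
#' @export
writeBenchmarkDataset <- function(ds, dir, name = ds@name) {
  stopifnot(is(ds, "GraphDataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pathOf <- function(suffix) file.path(dir, paste0(name, "_", suffix, ".txt"))
  offsets <- c(0L, cumsum(vapply(ds@graphs, function(g) g@nVertices, integer(1))))
  edges <- character(0); edgeSyms <- character(0)
  indicator <- integer(0)
  allLabeled <- all(vapply(ds@graphs, function(g) length(g@vertexLabels) > 0L, logical(1)))
  haveSyms <- any(vapply(ds@graphs, function(g) length(g@edgeSymbols) > 0L, logical(1)))
  nodeLabels <- character(0); nodeAttrs <- character(0)
  for (gi in seq_along(ds@graphs)) {
    g <- ds@graphs[[gi]]
    indicator <- c(indicator, rep(gi, g@nVertices))
    if (nrow(g@edges)) {
      edges <- c(edges, sprintf("%d, %d", g@edges[, 1L] + offsets[gi],
                                g@edges[, 2L] + offsets[gi]))
      edgeSyms <- c(edgeSyms,
                    if (length(g@edgeSymbols)) g@edgeSymbols
                    else rep("e", nrow(g@edges)))
    }
    if (allLabeled) nodeLabels <- c(nodeLabels, g@vertexLabels)
    else nodeAttrs <- c(nodeAttrs, apply(g@attributes, 1L, paste, collapse = ", "))
  }
  writeLines(edges, pathOf("A"))
  writeLines(as.character(indicator), pathOf("graph_indicator"))
  writeLines(ds@labelLevels[ds@labels + 1L], pathOf("graph_labels"))
  if (allLabeled) writeLines(nodeLabels, pathOf("node_labels"))
  else writeLines(nodeAttrs, pathOf("node_attributes"))
  if (haveSyms) writeLines(edgeSyms, pathOf("edge_labels"))
  invisible(dir)
}

#' Generate a synthetic two-class graph collection
#'
#' Builds `nGraphs` random graphs split evenly between two classes that
#' differ by a planted, decomposition-visible signal. With
#' `signal$type = "label"` all vertices carry label "a" and class-1 graphs
#' flip `round(strength * nVertices / 2)` vertices to "b", so radius-1
#' ego-graph neighborhoods already separate the classes; with
#' `"triangle"` class-1 graphs close that many random wedges into
#' triangles; with `"none"` (or strength 0) the two classes are
#' exchangeable. The `"uniform"` degree model wires Erdos-Renyi graphs
#' with 2n edges; `"skewed"` uses preferential attachment, whose maximum
#' degree grows with graph size like the heavy-tailed social-network
#' benchmarks. Edge symbols are assigned from a two-letter alphabet by
#' endpoint parity.
#'
#' @param nGraphs even number of graphs.
#' @param nVertices vertices per graph, >= 4.
#' @param signal list with `type` ("label", "triangle" or "none") and
#'   `strength` in 0..1.
#' @param degreeModel "uniform" or "skewed".
#' @param seed RNG seed; a fixed seed reproduces the collection exactly.
#' @return a [GraphDataset-class].
#' @export
generateTwoClassCollection <- function(nGraphs, nVertices,
                                       signal = list(type = "label", strength = 1),
                                       degreeModel = c("uniform", "skewed"),
                                       seed = 1L) {
  degreeModel <- match.arg(degreeModel)
  if (nGraphs %% 2L != 0L) stop("nGraphs must be even")
  if (nVertices < 4L) stop("need at least 4 vertices per graph")
  type <- match.arg(signal$type, c("label", "triangle", "none"))
  strength <- if (is.null(signal$strength)) 1 else signal$strength
  if (strength < 0 || strength > 1) stop("invalid signal spec: strength must be in [0, 1]")
  set.seed(seed)
  labels <- rep(0:1, length.out = nGraphs)
  graphs <- vector("list", nGraphs)
  k <- round(strength * nVertices / 2)
  for (i in seq_len(nGraphs)) {
    ig <- if (degreeModel == "uniform") {
      igraph::sample_gnm(nVertices, m = min(2L * nVertices, choose(nVertices, 2L)))
    } else {
      igraph::sample_pa(nVertices, power = 1, m = 2, directed = FALSE)
    }
    e <- igraph::as_edgelist(ig)
    storage.mode(e) <- "integer"
    vlab <- rep("a", nVertices)
    if (type == "label" && labels[i] == 1L && k > 0L)
      vlab[seq_len(k)] <- "b"
    if (type == "triangle" && labels[i] == 1L && k > 0L) {
      key <- function(m) paste(pmin(m[, 1L], m[, 2L]), pmax(m[, 1L], m[, 2L]))
      added <- 0L; guard <- 0L
      while (added < k && guard < 100L * k) {
        guard <- guard + 1L
        v <- sample.int(nVertices, 1L)
        nb <- unique(c(e[e[, 1L] == v, 2L], e[e[, 2L] == v, 1L]))
        if (length(nb) >= 2L) {
          uw <- sample(nb, 2L)
          if (!key(matrix(uw, 1L)) %in% key(e)) {
            e <- rbind(e, sort(uw))
            added <- added + 1L
          }
        }
      }
    }
    sym <- c("s", "t")[(rowSums(e) %% 2L) + 1L]
    graphs[[i]] <- attributedGraph(e, nVertices, vertexLabels = vlab,
                                   edgeSymbols = if (nrow(e)) sym else NULL)
  }
  newGraphDataset(graphs, labels, name = "synthetic-two-class",
                  provenance = list(source = "generator", nGraphs = nGraphs,
                                    nVertices = nVertices, signal = type,
                                    strength = strength,
                                    degreeModel = degreeModel, seed = seed))
}

#' Worked-example fixtures of the compression algorithm
#'
#' `"example1"` is the four-level hierarchy (levels named A-D, arc types
#' blue and red) whose compression collapses the bottom objects A1, A3, A4
#' (shared categorical attribute), the pairs B1/B2 and B3/B4, and C1/C3,
#' leaving a single red arc of cardinality 2 from D1 to the representative
#' of C1. C2's wiring is a fixture convention (the narration leaves it
#' open): it swaps the arc types of C1 (red to B2, blue to B4) so that C2
#' stays distinct after the level-B collapse.
#'
#' `"example3"` is the four-object bottom level with attribute rows
#' [0,3], [0,3], [4,1], [0,3] (objects A1..A4, where A3 carries the odd
#' attribute) wrapped in a minimal two-level hierarchy, together with the
#' expected compression matrices: `Xcomp`, the boolean `D`, the averaging
#' pseudo-inverse `C` and the representer pseudo-inverse `Cprime`. Note
#' that the two examples deliberately disagree on which bottom object is
#' the odd one out; each fixture encodes its own example's statement.
#'
#' @param which `"example1"` or `"example3"`.
#' @return a list with element `h` (the [HDecomposition-class]); for
#'   `"example3"` also `X`, `Xcomp`, `D`, `C`, `Cprime`.
#' @export
workedExampleFixture <- function(which = c("example1", "example3")) {
  which <- match.arg(which)
  if (which == "example3") {
    X <- matrix(c(0, 3,
                  0, 3,
                  4, 1,
                  0, 3), 4L, 2L, byrow = TRUE)
    h <- buildHDecomposition(
      levels = list(paste0("A", 1:4), "T"),
      relations = list(list(part = data.frame(parent = "T", part = paste0("A", 1:4)))),
      piAlphabets = list("part"),
      attributes = X)
    return(list(
      h = h, X = X,
      Xcomp = matrix(c(0, 3, 4, 1), 2L, 2L, byrow = TRUE),
      D = matrix(c(1, 0, 1, 0, 0, 1, 1, 0), 4L, 2L, byrow = TRUE),
      C = matrix(c(1/3, 1/3, 0, 1/3, 0, 0, 1, 0), 2L, 4L, byrow = TRUE),
      Cprime = matrix(c(1, 0, 0, 0, 0, 0, 1, 0), 2L, 4L, byrow = TRUE)))
  }
  purple <- c(0, 3); orange <- c(4, 1)
  X <- rbind(purple, orange, purple, purple)
  rownames(X) <- NULL
  arc <- function(parent, part) data.frame(parent = parent, part = part)
  relB <- list(
    blue = arc(c("B1", "B2"), c("A1", "A1")),
    red  = arc(c("B1", "B2", "B3", "B3", "B4", "B4"),
               c("A2", "A2", "A3", "A4", "A3", "A4")))
  relC <- list(
    blue = arc(c("C1", "C3", "C2"), c("B1", "B1", "B4")),
    red  = arc(c("C1", "C3", "C2"), c("B3", "B3", "B2")))
  relD <- list(
    blue = arc(character(0), character(0)),
    red  = arc(c("D1", "D1"), c("C1", "C3")))
  h <- buildHDecomposition(
    levels = list(paste0("A", 1:4), paste0("B", 1:4), paste0("C", 1:3), "D1"),
    relations = list(relB, relC, relD),
    piAlphabets = list(c("blue", "red"), c("blue", "red"), c("blue", "red")),
    attributes = X)
  list(h = h)
}

#' Summary statistics of a graph dataset
#'
#' Size, average vertex count, average maximum node degree (the mean over
#' graphs of each graph's maximum vertex degree) and the class histogram.
#'
#' @param ds a [GraphDataset-class].
#' @return list with `size`, `avgVertices`, `avgMaxDegree`, `avgEdges` and
#'   `labelHistogram`.
#' @export
datasetStats <- function(ds) {
  stopifnot(is(ds, "GraphDataset"))
  maxDeg <- vapply(ds@graphs, function(g) {
    if (nrow(g@edges) == 0L) return(0)
    max(tabulate(c(g@edges[, 1L], g@edges[, 2L]), nbins = g@nVertices))
  }, numeric(1))
  hist <- table(factor(ds@labelLevels[ds@labels + 1L], levels = ds@labelLevels))
  list(size = length(ds@graphs),
       avgVertices = mean(vapply(ds@graphs, function(g) g@nVertices, integer(1))),
       avgMaxDegree = mean(maxDeg),
       avgEdges = mean(vapply(ds@graphs, function(g) nrow(g@edges), integer(1))),
       labelHistogram = as.list(hist))
}

#' Random H-decomposition with categorical attributes
#'
#' Draws a hierarchy with the given level sizes and alphabet sizes: bottom
#' attributes are integer codes from a small category set (so duplicates --
#' and hence compressible symmetries -- occur), and every compound object
#' receives 1 to `maxParts` distinct (part, type) incidences. Used for
#' property checks of the matrix-form computation and of losslessness.
#'
#' @param levelSizes integer vector of |S_l|, bottom first (length L+1).
#' @param nTypes integer vector of alphabet sizes n(l), l = 1..L.
#' @param p attribute width.
#' @param nCategories number of distinct attribute codes per column.
#' @param maxParts maximum incidences per compound object.
#' @param seed optional RNG seed.
#' @return an [HDecomposition-class].
#' @export
randomHDecomposition <- function(levelSizes, nTypes, p = 3L, nCategories = 3L,
                                 maxParts = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  levelSizes <- as.integer(levelSizes)
  L <- length(levelSizes) - 1L
  stopifnot(L >= 1L, length(nTypes) == L)
  X <- matrix(sample(0:(nCategories - 1L), levelSizes[1L] * p, replace = TRUE),
              levelSizes[1L], p)
  ids <- lapply(0:L, function(l) sprintf("L%d.%d", l, seq_len(levelSizes[l + 1L])))
  alphas <- lapply(seq_len(L), function(l) paste0("t", seq_len(nTypes[l])))
  relations <- lapply(seq_len(L), function(l) {
    nUp <- levelSizes[l + 1L]; nDown <- levelSizes[l]
    inc <- do.call(rbind, lapply(seq_len(nUp), function(s) {
      kMax <- min(maxParts, nDown * nTypes[l])
      k <- sample.int(kMax, 1L)
      pick <- sample.int(nDown * nTypes[l], k)
      cbind(s, (pick - 1L) %% nDown + 1L, (pick - 1L) %/% nDown + 1L)
    }))
    out <- lapply(seq_len(nTypes[l]), function(t) {
      rows <- inc[inc[, 3L] == t, , drop = FALSE]
      sparseMatrix(i = rows[, 1L], j = rows[, 2L], x = rep(1, nrow(rows)),
                   dims = c(nUp, nDown))
    })
    names(out) <- alphas[[l]]
    out
  })
  buildHDecomposition(ids, relations, alphas, X)
}
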