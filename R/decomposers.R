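#' Construct an attributed undirected graph
#'
#' Edges are canonicalized so the smaller endpoint comes first; a pair listed
#' in both directions is stored once (the usual convention of benchmark edge
#' lists that duplicate each undirected edge). Self loops and contradictory
#' duplicate edge symbols are rejected.
#'
#' If `attributes` is missing, categorical `vertexLabels` are one-hot encoded
#' over the graph's own sorted label set; with neither, every vertex gets the
#' constant attribute 1. Dataset readers and generators encode labels over
#' the whole collection instead, so that attribute columns line up across
#' graphs.
#'
#' @param edges two-column matrix or data frame of vertex index pairs
#'   (1-based); may have zero rows.
#' @param nVertices number of vertices.
#' @param attributes optional numeric matrix, one row per vertex.
#' @param vertexLabels optional character vector of categorical labels.
#' @param edgeSymbols optional character vector parallel to the rows of
#'   `edges`.
#' @return an [AttributedGraph-class].
#' @export
attributedGraph <- function(edges, nVertices, attributes = NULL,
                            vertexLabels = NULL, edgeSymbols = NULL) {
  nVertices <- as.integer(nVertices)
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(integer(0), 0L, 2L)
  storage.mode(edges) <- "integer"
  if (nrow(edges) > 0L) {
    if (any(edges[, 1L] == edges[, 2L])) stop("self loops are not allowed")
    flip <- edges[, 1L] > edges[, 2L]
    edges[flip, ] <- edges[flip, 2:1]
    key <- paste(edges[, 1L], edges[, 2L])
    keep <- !duplicated(key)
    if (!is.null(edgeSymbols)) {
      edgeSymbols <- as.character(edgeSymbols)
      agree <- tapply(edgeSymbols, key, function(s) length(unique(s)) == 1L)
      if (!all(agree)) stop("duplicate edge listed with conflicting symbols")
      edgeSymbols <- edgeSymbols[keep]
    }
    edges <- edges[keep, , drop = FALSE]
    ord <- order(edges[, 1L], edges[, 2L])
    edges <- edges[ord, , drop = FALSE]
    if (!is.null(edgeSymbols)) edgeSymbols <- edgeSymbols[ord]
  }
  if (is.null(attributes)) {
    attributes <- if (!is.null(vertexLabels)) {
      oneHot(as.character(vertexLabels), sort(unique(as.character(vertexLabels))))
    } else matrix(1, nVertices, 1L)
  }
  attributes <- as.matrix(attributes)
  storage.mode(attributes) <- "double"
  new("AttributedGraph",
      nVertices    = nVertices,
      edges        = edges,
      attributes   = attributes,
      vertexLabels = if (is.null(vertexLabels)) character(0) else as.character(vertexLabels),
      edgeSymbols  = if (is.null(edgeSymbols)) character(0) else as.character(edgeSymbols))
}

#' One-hot encoding over a fixed alphabet
#'
#' Values outside the alphabet yield all-zero rows (used to encode, e.g.,
#' vertex identifiers unseen in a training split).
#' @param values character vector to encode.
#' @param alphabet ordered alphabet defining the columns.
#' @return numeric matrix length(values) x length(alphabet).
#' @export
oneHot <- function(values, alphabet) {
  m <- matrix(0, length(values), length(alphabet),
              dimnames = list(NULL, alphabet))
  j <- match(values, alphabet)
  ok <- !is.na(j)
  m[cbind(which(ok), j[ok])] <- 1
  m
}

.asIgraph <- function(g) {
  ig <- igraph::make_empty_graph(n = g@nVertices, directed = FALSE)
  if (nrow(g@edges) > 0L)
    ig <- igraph::add_edges(ig, t(g@edges))
  ig
}

#' Induced subgraph
#'
#' The subgraph on a vertex subset, keeping exactly the edges with both
#' endpoints inside it; attributes, labels and edge symbols are restricted.
#' Vertices are renumbered 1..|V_g| in the order given.
#'
#' @param g an [AttributedGraph-class].
#' @param vids vertex indices to keep.
#' @return an [AttributedGraph-class].
#' @export
inducedSubgraph <- function(g, vids) {
  vids <- as.integer(vids)
  if (any(vids < 1L) || any(vids > g@nVertices) || anyDuplicated(vids))
    stop("unknown or duplicated vertex id in the subset")
  if (nrow(g@edges) > 0L) {
    keep <- g@edges[, 1L] %in% vids & g@edges[, 2L] %in% vids
    e <- g@edges[keep, , drop = FALSE]
    e <- cbind(match(e[, 1L], vids), match(e[, 2L], vids))
    sym <- if (length(g@edgeSymbols)) g@edgeSymbols[keep] else NULL
  } else {
    e <- matrix(integer(0), 0L, 2L)
    sym <- if (length(g@edgeSymbols)) character(0) else NULL
  }
  attributedGraph(e, length(vids),
                  attributes   = g@attributes[vids, , drop = FALSE],
                  vertexLabels = if (length(g@vertexLabels)) g@vertexLabels[vids] else NULL,
                  edgeSymbols  = sym)
}

#' Ego graph of radius r
#'
#' The subgraph induced by all vertices whose shortest-path distance from
#' the root is at most r. Ego graphs never cross connected components
#' (infinite distances are excluded). Member vertices are ordered by
#' increasing original index, which fixes the part order deterministically.
#'
#' @param g an [AttributedGraph-class].
#' @param v root vertex index.
#' @param r radius, r >= 0 (r = 0 gives the single root vertex, no edges).
#' @return a list with elements `graph` (the induced
#'   [AttributedGraph-class]), `root` (the root's position inside it) and
#'   `members` (the original indices of its vertices).
#' @export
egoGraph <- function(g, v, r) {
  v <- as.integer(v)
  if (v < 1L || v > g@nVertices) stop("unknown root vertex")
  stopifnot(r >= 0)
  d <- igraph::distances(.asIgraph(g), v = v)[1L, ]
  members <- which(is.finite(d) & d <= r)
  list(graph = inducedSubgraph(g, members),
       root = match(v, members),
       members = members)
}

#' Weisfeiler-Lehman color refinement
#'
#' Iteration-0 colors encode the distinct vertex attribute rows; each later
#' iteration recolors a vertex by an injective dictionary lookup of the pair
#' (own color, sorted multiset of neighbor colors). The dictionary assigns
#' codes in first-encounter order, so colors are reproducible for a fixed
#' input order, and can be passed back in to color further graphs
#' consistently (e.g., a test split with the training dictionary); keys not
#' yet in the dictionary receive fresh codes.
#'
#' @param g an [AttributedGraph-class].
#' @param iterations number of refinement rounds, >= 0.
#' @param dictionary optional dictionary from a previous call (the
#'   `"dictionary"` attribute of its result).
#' @return integer vector of final colors (1-based codes) with attributes
#'   `"dictionary"` (list of per-iteration key-to-code maps and the running
#'   code counter) and `"history"` (n x (iterations+1) color matrix).
#' @export
wlColors <- function(g, iterations, dictionary = NULL) {
  stopifnot(iterations >= 0)
  n <- g@nVertices
  adj <- vector("list", n)
  if (nrow(g@edges) > 0L)
    for (k in seq_len(nrow(g@edges))) {
      u <- g@edges[k, 1L]; w <- g@edges[k, 2L]
      adj[[u]] <- c(adj[[u]], w)
      adj[[w]] <- c(adj[[w]], u)
    }
  if (is.null(dictionary))
    dictionary <- list(maps = vector("list", iterations + 1L), counter = 0L)
  if (length(dictionary$maps) < iterations + 1L)
    dictionary$maps <- c(dictionary$maps,
                         vector("list", iterations + 1L - length(dictionary$maps)))
  lookup <- function(keys, it) {
    map <- dictionary$maps[[it + 1L]]
    if (is.null(map)) map <- integer(0)
    for (k in keys[!keys %in% names(map)]) {
      dictionary$counter <<- dictionary$counter + 1L
      map[[k]] <- dictionary$counter
    }
    dictionary$maps[[it + 1L]] <<- map
    unname(map[keys])
  }
  keys0 <- apply(g@attributes, 1L, paste, collapse = "\r")
  col <- lookup(keys0, 0L)
  history <- matrix(0L, n, iterations + 1L)
  history[, 1L] <- col
  if (iterations > 0L) for (it in seq_len(iterations)) {
    keys <- vapply(seq_len(n), function(v) {
      paste(col[v], paste(sort(col[adj[[v]]]), collapse = ","), sep = "|")
    }, character(1))
    col <- lookup(keys, it)
    history[, it + 1L] <- col
  }
  structure(as.integer(col), dictionary = dictionary, history = history)
}

#' Ego-graph H-decomposition (EGD)
#'
#' Three levels: the bottom level holds the graph's vertices with their
#' attribute vectors; level 1 holds every ego graph g_{v,r} for all roots v
#' and radii r = 0..R, related to its root with type ROOT and to every other
#' member with type ELEM; the top level holds the whole graph, related to
#' each ego graph with the radius r as membership type.
#'
#' @param g an [AttributedGraph-class] with vertex attributes.
#' @param radius maximum ego-graph radius R >= 0.
#' @param idPrefix prefix for generated object ids (used when merging
#'   several graphs into one hierarchy).
#' @return an [HDecomposition-class] with levels of sizes
#'   (|V|, |V|(R+1), 1).
#' @export
buildEGD <- function(g, radius, idPrefix = "") {
  stopifnot(is(g, "AttributedGraph"), radius >= 0)
  n <- g@nVertices
  radii <- 0:radius
  dmat <- igraph::distances(.asIgraph(g))
  vIds <- paste0(idPrefix, "v", seq_len(n))
  egoIds <- as.vector(vapply(seq_len(n), function(v)
    paste0(idPrefix, "g", v, ".r", radii), character(length(radii))))
  egoIndex <- function(v, r) (v - 1L) * (radius + 1L) + r + 1L
  rootI <- integer(0); rootJ <- integer(0)
  elemI <- integer(0); elemJ <- integer(0)
  radI <- vector("list", length(radii)); names(radI) <- as.character(radii)
  for (v in seq_len(n)) {
    d <- dmat[v, ]
    for (r in radii) {
      members <- which(is.finite(d) & d <= r)
      idx <- egoIndex(v, r)
      rootI <- c(rootI, idx); rootJ <- c(rootJ, v)
      others <- members[members != v]
      elemI <- c(elemI, rep(idx, length(others))); elemJ <- c(elemJ, others)
      radI[[as.character(r)]] <- c(radI[[as.character(r)]], idx)
    }
  }
  nEgo <- n * (radius + 1L)
  rel1 <- list(
    ROOT = sparseMatrix(i = rootI, j = rootJ, x = rep(1, length(rootI)),
                        dims = c(nEgo, n)),
    ELEM = sparseMatrix(i = elemI, j = elemJ, x = rep(1, length(elemI)),
                        dims = c(nEgo, n)))
  rel2 <- lapply(radI, function(ii)
    sparseMatrix(i = rep(1L, length(ii)), j = ii, x = rep(1, length(ii)),
                 dims = c(1L, nEgo)))
  buildHDecomposition(
    levels = list(vIds, egoIds, paste0(idPrefix, "G")),
    relations = list(rel1, rel2),
    piAlphabets = list(c("ROOT", "ELEM"), as.character(radii)),
    attributes = g@attributes)
}

#' Nested ego-graph H-decomposition (NEGD)
#'
#' Three levels built from radius-1 ego graphs. Level 1 holds g_{v,1} for
#' every vertex v, entering the top level with its vertex count |V_v| as
#' membership type. Its parts are the ego graphs g_{w,1} of its members w,
#' with type ROOT when w = v and the edge symbol f_E(v, w) otherwise. Bottom
#' objects are identified by the Weisfeiler-Lehman color of their root after
#' `wlIterations` rounds: two ego graphs with the same color are one shared
#' object, and the bottom attribute rows are one-hot encodings of the
#' identifiers. Because of the sharing, an incidence can carry a count > 1
#' when two members of an ego graph have the same identifier and symbol.
#'
#' @param g an [AttributedGraph-class]; without edge symbols a single
#'   default symbol is assumed.
#' @param wlIterations rounds of color refinement used for the identifiers.
#' @return an [HDecomposition-class].
#' @seealso [decomposeCollection()] for decomposing a whole dataset with a
#'   shared identifier dictionary and training-time alphabets.
#' @export
buildNEGD <- function(g, wlIterations = 4L) {
  decomposeCollection(list(g), method = "negd", wlIterations = wlIterations)
}

#' Decompose a graph collection into one merged hierarchy
#'
#' Applies the chosen decomposition to every graph and merges the results
#' into a single [HDecomposition-class] whose top level has one object per
#' graph, in dataset order. Merging before compression lets domain
#' compression collapse identical substructures across graphs.
#'
#' For NEGD the Weisfeiler-Lehman identifiers are computed on the disjoint
#' union of the collection so that they are comparable across graphs, and
#' bottom-level objects are shared across the whole collection. The
#' membership alphabets observed here (ego-graph sizes, edge symbols,
#' identifier set) are returned in the `"alphabets"` attribute; passing them
#' back in decomposes a held-out split against the *training* alphabets. An
#' ego-graph size unseen at training time is an error unless
#' `nearestSize = TRUE`, which maps it to the closest declared size (ties
#' toward the smaller); identifiers unseen at training time get all-zero
#' attribute rows.
#'
#' @param graphs a [GraphDataset-class] or list of
#'   [AttributedGraph-class] objects.
#' @param method "egd" or "negd".
#' @param radius EGD maximum radius.
#' @param wlIterations NEGD identifier refinement rounds.
#' @param alphabets alphabets from a previous (training) call.
#' @param nearestSize map unseen NEGD ego-graph sizes to the nearest
#'   declared size instead of failing.
#' @return an [HDecomposition-class] with attribute `"alphabets"`.
#' @export
decomposeCollection <- function(graphs, method = c("egd", "negd"), radius = 1L,
                                wlIterations = 4L, alphabets = NULL,
                                nearestSize = FALSE) {
  method <- match.arg(method)
  if (is(graphs, "GraphDataset")) graphs <- graphs@graphs
  stopifnot(length(graphs) >= 1L)
  if (method == "egd") {
    hs <- lapply(seq_along(graphs), function(i)
      buildEGD(graphs[[i]], radius, idPrefix = sprintf("g%d.", i)))
    h <- mergeHDecompositions(hs)
    attr(h, "alphabets") <- list(method = "egd", radius = radius)
    return(h)
  }
  .negdCollection(graphs, wlIterations, alphabets, nearestSize)
}

.negdCollection <- function(graphs, wlIterations, alphabets = NULL,
                            nearestSize = FALSE) {
  nG <- length(graphs)
  offsets <- c(0L, cumsum(vapply(graphs, function(g) g@nVertices, integer(1))))
  union <- .disjointUnion(graphs)
  colors <- wlColors(union, wlIterations,
                     dictionary = alphabets$wlDictionary)
  dict <- attr(colors, "dictionary")
  colorLevels <- if (is.null(alphabets)) {
    as.character(colors[!duplicated(colors)])
  } else alphabets$colorLevels
  # bottom level: one object per distinct identifier seen in this collection,
  # first-encounter order
  seen <- as.character(colors[!duplicated(colors)])
  bottomIds <- paste0("c", seen)
  X <- oneHot(seen, colorLevels)
  symAll <- if (length(union@edgeSymbols)) union@edgeSymbols else
    rep("e", nrow(union@edges))
  symAlpha <- if (is.null(alphabets)) sort(unique(symAll)) else alphabets$edgeSymbols
  unknownSym <- setdiff(unique(symAll), symAlpha)
  if (length(unknownSym))
    stop(sprintf("edge symbol(s) %s not in the declared alphabet",
                 paste(unknownSym, collapse = ", ")))
  pi1 <- c("ROOT", symAlpha)
  # adjacency with symbols on the union graph
  n <- union@nVertices
  adj <- vector("list", n)
  if (nrow(union@edges)) for (k in seq_len(nrow(union@edges))) {
    u <- union@edges[k, 1L]; w <- union@edges[k, 2L]
    adj[[u]] <- rbind(adj[[u]], c(w, k))
    adj[[w]] <- rbind(adj[[w]], c(u, k))
  }
  egoIds <- character(n)
  egoSizes <- integer(n)
  tri1 <- list()  # per pi: list of (i, j) with counts accumulated later
  acc <- new.env(parent = emptyenv())
  for (pi in pi1) assign(pi, list(i = integer(0), j = integer(0)), envir = acc)
  gOf <- rep(seq_len(nG), times = diff(offsets))
  for (v in seq_len(n)) {
    gi <- gOf[v]
    egoIds[v] <- sprintf("g%d.e%d", gi, v - offsets[gi])
    nb <- adj[[v]]
    egoSizes[v] <- 1L + if (is.null(nb)) 0L else nrow(nb)
    rootPart <- match(as.character(colors[v]), seen)
    e <- get("ROOT", envir = acc)
    assign("ROOT", list(i = c(e$i, v), j = c(e$j, rootPart)), envir = acc)
    if (!is.null(nb)) for (k in seq_len(nrow(nb))) {
      w <- nb[k, 1L]
      sym <- symAll[nb[k, 2L]]
      part <- match(as.character(colors[w]), seen)
      e <- get(sym, envir = acc)
      assign(sym, list(i = c(e$i, v), j = c(e$j, part)), envir = acc)
    }
  }
  rel1 <- lapply(pi1, function(pi) {
    e <- get(pi, envir = acc)
    sparseMatrix(i = e$i, j = e$j, x = rep(1, length(e$i)),
                 dims = c(n, length(bottomIds)))
  })
  names(rel1) <- pi1
  sizeAlpha <- if (is.null(alphabets)) {
    as.character(sort(unique(egoSizes)))
  } else alphabets$sizes
  typeOf <- as.character(egoSizes)
  unseen <- setdiff(unique(typeOf), sizeAlpha)
  if (length(unseen)) {
    if (!nearestSize)
      stop(sprintf(
        "ego-graph size(s) %s unseen in the declared alphabet; enable nearestSize mapping to proceed",
        paste(unseen, collapse = ", ")))
    declared <- as.integer(sizeAlpha)
    for (u in unseen) {
      gap <- abs(declared - as.integer(u))
      typeOf[typeOf == u] <- as.character(declared[which.min(gap)])
    }
  }
  rel2 <- lapply(sizeAlpha, function(s) {
    idx <- which(typeOf == s)
    sparseMatrix(i = gOf[idx], j = idx, x = rep(1, length(idx)),
                 dims = c(nG, n))
  })
  names(rel2) <- sizeAlpha
  h <- buildHDecomposition(
    levels = list(bottomIds, egoIds, paste0("G", seq_len(nG))),
    relations = list(rel1, rel2),
    piAlphabets = list(pi1, sizeAlpha),
    attributes = X)
  attr(h, "alphabets") <- list(method = "negd", wlIterations = wlIterations,
                               wlDictionary = dict, colorLevels = colorLevels,
                               edgeSymbols = symAlpha, sizes = sizeAlpha)
  h
}

.disjointUnion <- function(graphs) {
  if (length(graphs) == 1L) return(graphs[[1L]])
  offsets <- c(0L, cumsum(vapply(graphs, function(g) g@nVertices, integer(1))))
  edges <- do.call(rbind, lapply(seq_along(graphs), function(i) {
    e <- graphs[[i]]@edges
    if (nrow(e)) e + offsets[i] else e
  }))
  haveSym <- any(vapply(graphs, function(g) length(g@edgeSymbols) > 0L, logical(1)))
  sym <- if (haveSym) {
    unlist(lapply(graphs, function(g) {
      if (length(g@edgeSymbols)) g@edgeSymbols else rep("e", nrow(g@edges))
    }), use.names = FALSE)
  } else NULL
  attributedGraph(edges, offsets[length(offsets)],
                  attributes = do.call(rbind, lapply(graphs, function(g) g@attributes)),
                  edgeSymbols = sym)
}
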