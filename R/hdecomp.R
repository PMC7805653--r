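#' Build a validated H-decomposition
#'
#' Assembles levels, typed part-of relations and bottom-level attributes into
#' an immutable, validated [HDecomposition-class]. Object and alphabet order
#' is preserved exactly as given; it fixes the row order of every level and
#' the column-block layout of the concatenated level matrices, so the built
#' object is reproducible bit for bit.
#'
#' Relations can be given either as matrices (|S_l| x |S_{l-1}|, sparse or
#' dense) or as data frames of incidences with columns `parent`, `part` and
#' optionally `count`, using object ids; ids that are not registered at the
#' adjacent levels are rejected, which also enforces that relations only span
#' consecutive levels.
#'
#' @param levels list of length L+1; character ids of the objects of each
#'   level, bottom first.
#' @param relations list of length L; element l is a named list over the
#'   level-l alphabet of relation matrices or incidence data frames.
#' @param piAlphabets list of length L of ordered membership-type alphabets.
#' @param attributes numeric matrix with one row per bottom-level object.
#' @param compressed mark the result as the output of domain compression
#'   (allows cardinalities > 1 by construction; they also arise for builders
#'   that share parts, see [buildNEGD()]).
#' @return an [HDecomposition-class].
#' @examples
#' h <- buildHDecomposition(
#'   levels = list(c("v1"), c("g1")),
#'   relations = list(list(only = data.frame(parent = "g1", part = "v1"))),
#'   piAlphabets = list("only"),
#'   attributes = matrix(1, 1, 1))
#' levelSizes(h)
#' @export
buildHDecomposition <- function(levels, relations, piAlphabets, attributes,
                                compressed = FALSE) {
  levels <- lapply(levels, as.character)
  L <- length(levels) - 1L
  if (L < 1L) stop("an H-decomposition needs at least two levels")
  if (length(relations) != L || length(piAlphabets) != L)
    stop("need one relation set and one alphabet per level l = 1..L")
  piAlphabets <- lapply(piAlphabets, as.character)
  rel <- vector("list", L)
  for (l in seq_len(L)) {
    alpha <- piAlphabets[[l]]
    given <- relations[[l]]
    out <- vector("list", length(alpha))
    names(out) <- alpha
    for (pi in alpha) {
      x <- given[[pi]]
      if (is.null(x)) {
        # a type can be unobserved; it still contributes a zero block
        out[[pi]] <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                  dims = c(length(levels[[l + 1L]]), length(levels[[l]])))
      } else if (is.data.frame(x)) {
        out[[pi]] <- .incidenceToMatrix(x, levels[[l + 1L]], levels[[l]], l, pi)
      } else {
        out[[pi]] <- as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
      }
    }
    extra <- setdiff(names(given), alpha)
    if (length(extra))
      stop(sprintf("relation types %s at level %d are not in the alphabet",
                   paste(extra, collapse = ", "), l))
    rel[[l]] <- out
  }
  attributes <- as.matrix(attributes)
  storage.mode(attributes) <- "double"
  new("HDecomposition",
      levelSizes  = vapply(levels, length, integer(1)),
      objectIds   = levels,
      piAlphabets = piAlphabets,
      relations   = rel,
      attributes  = attributes,
      compressed  = isTRUE(compressed))
}

.incidenceToMatrix <- function(df, parentIds, partIds, l, pi) {
  i <- match(as.character(df$parent), parentIds)
  j <- match(as.character(df$part), partIds)
  if (anyNA(i))
    stop(sprintf("unregistered parent id '%s' in relation R_{%d,%s}",
                 df$parent[which(is.na(i))[1L]], l, pi))
  if (anyNA(j))
    stop(sprintf("unregistered part id '%s' in relation R_{%d,%s}",
                 df$part[which(is.na(j))[1L]], l, pi))
  x <- if (is.null(df$count)) rep(1, length(i)) else as.numeric(df$count)
  sparseMatrix(i = i, j = j, x = x, dims = c(length(parentIds), length(partIds)))
}

#' Concatenated level matrix R_l
#'
#' Horizontal concatenation of the typed relation matrices R_{l,pi} in
#' alphabet order, of shape |S_l| x n(l)|S_{l-1}|. Multiplying it by the
#' block-diagonal replication of the previous level's representations (see
#' [blockDiagRepresentations()]) performs the shift-and-aggregate step in
#' matrix form.
#'
#' @param h an [HDecomposition-class].
#' @param l level index, 1..L.
#' @return a sparse matrix.
#' @export
assembleLevelMatrix <- function(h, l) {
  stopifnot(is(h, "HDecomposition"), l >= 1L, l <= nLevels(h))
  do.call(cbind, unname(h@relations[[l]]))
}

#' Block-diagonal replication of a representation matrix
#'
#' Repeats `H_prev` n times along the diagonal, giving the
#' n|S_{l-1}| x n d matrix that pairs with [assembleLevelMatrix()]: their
#' product equals the loop-form shift/aggregate sum over parts and types.
#'
#' @param H_prev dense representation matrix (one row per object of the
#'   level below).
#' @param n number of diagonal copies (the alphabet size n(l)).
#' @return `H_prev` itself for n = 1, otherwise a sparse block-diagonal
#'   matrix.
#' @export
blockDiagRepresentations <- function(H_prev, n) {
  stopifnot(n >= 1L)
  if (n == 1L) return(H_prev)
  bdiag(replicate(n, H_prev, simplify = FALSE))
}

#' Serialize an H-decomposition to a JSON container
#'
#' The container holds the metadata (level sizes, object ids, alphabets),
#' each typed relation in coordinate triplet form (row, col, count) and the
#' dense attribute matrix. [readHDecomposition()] restores a structurally
#' identical object: same object order, same matrices, same alphabets.
#'
#' @param h an [HDecomposition-class].
#' @param path file path to write to / read from.
#' @return `writeHDecomposition` returns `path` invisibly;
#'   `readHDecomposition` returns the restored [HDecomposition-class].
#' @export
writeHDecomposition <- function(h, path) {
  stopifnot(is(h, "HDecomposition"))
  L <- nLevels(h)
  relOut <- lapply(seq_len(L), function(l) {
    lapply(h@relations[[l]], function(R) {
      T <- as(R, "TsparseMatrix")
      list(i = T@i + 1L, j = T@j + 1L, x = T@x)
    })
  })
  obj <- list(
    format      = "saen-hdecomposition",
    version     = 1L,
    compressed  = h@compressed,
    levelSizes  = h@levelSizes,
    objectIds   = h@objectIds,
    piAlphabets = h@piAlphabets,
    attributes  = unname(h@attributes),
    relations   = relOut
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeHDecomposition
#' @export
readHDecomposition <- function(path) {
  # parse without jsonlite's simplification heuristics: equal-length id lists
  # must not collapse into matrices
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed H-decomposition container: ",
                                           conditionMessage(e)))
  if (!identical(obj$format, "saen-hdecomposition"))
    stop("malformed H-decomposition container: wrong or missing format tag")
  if (!identical(as.integer(obj$version), 1L))
    stop(sprintf("unsupported H-decomposition container version %s", obj$version))
  sizes <- as.integer(unlist(obj$levelSizes))
  L <- length(sizes) - 1L
  ids <- lapply(obj$objectIds, function(v) as.character(unlist(v)))
  alphas <- lapply(obj$piAlphabets, function(v) as.character(unlist(v)))
  if (L < 1L || length(alphas) != L || length(obj$relations) != L)
    stop("malformed H-decomposition container: level structure inconsistent")
  relations <- vector("list", L)
  for (l in seq_len(L)) {
    stored <- obj$relations[[l]]
    relations[[l]] <- lapply(alphas[[l]], function(pi) {
      trip <- stored[[pi]]
      if (is.null(trip))
        stop("malformed H-decomposition container: missing relation block")
      sparseMatrix(i = as.integer(unlist(trip$i)), j = as.integer(unlist(trip$j)),
                   x = as.numeric(unlist(trip$x)),
                   dims = c(sizes[l + 1L], sizes[l]))
    })
    names(relations[[l]]) <- alphas[[l]]
  }
  X <- do.call(rbind, lapply(obj$attributes, function(row) as.numeric(unlist(row))))
  if (is.null(X) || nrow(X) != sizes[1L])
    stop("malformed H-decomposition container: attribute block truncated")
  buildHDecomposition(ids, relations, alphas, X,
                      compressed = isTRUE(obj$compressed))
}

#' Structural equality of two H-decompositions
#'
#' TRUE when levels, object orders, alphabets, relation matrices and
#' attributes all agree exactly.
#' @param a,b two [HDecomposition-class] objects.
#' @return logical.
#' @export
hdEqual <- function(a, b) {
  if (!identical(a@levelSizes, b@levelSizes)) return(FALSE)
  if (!identical(a@objectIds, b@objectIds)) return(FALSE)
  if (!identical(a@piAlphabets, b@piAlphabets)) return(FALSE)
  if (!isTRUE(all.equal(unname(a@attributes), unname(b@attributes),
                        tolerance = 0))) return(FALSE)
  for (l in seq_along(a@relations))
    for (pi in names(a@relations[[l]])) {
      d <- a@relations[[l]][[pi]] - b@relations[[l]][[pi]]
      if (length(d@x) && max(abs(d@x)) > 0) return(FALSE)
    }
  identical(a@compressed, b@compressed)
}

#' Merge per-graph hierarchies into one collection hierarchy
#'
#' Stacks hierarchies of equal depth and attribute width into a single
#' [HDecomposition-class] whose levels are the disjoint unions of the input
#' levels (ids are prefixed with the input index to keep them unique).
#' Alphabets are unioned in first-encounter order; types absent from an
#' input contribute zero blocks. Used to train on a whole split at once so
#' that domain compression can collapse symmetries across graphs, not just
#' within one.
#'
#' @param hs list of [HDecomposition-class] objects.
#' @return merged [HDecomposition-class].
#' @export
mergeHDecompositions <- function(hs) {
  stopifnot(length(hs) >= 1L)
  if (length(hs) == 1L) return(hs[[1L]])
  L <- nLevels(hs[[1L]])
  if (!all(vapply(hs, nLevels, integer(1)) == L))
    stop("all hierarchies must have the same number of levels")
  p <- ncol(hs[[1L]]@attributes)
  if (!all(vapply(hs, function(h) ncol(h@attributes), integer(1)) == p))
    stop("all hierarchies must share the attribute width")
  ids <- lapply(0:L, function(l) {
    unlist(lapply(seq_along(hs), function(i)
      paste0("m", i, ":", hs[[i]]@objectIds[[l + 1L]])), use.names = FALSE)
  })
  alphas <- lapply(seq_len(L), function(l) {
    a <- character(0)
    for (h in hs) a <- union(a, h@piAlphabets[[l]])
    a
  })
  relations <- lapply(seq_len(L), function(l) {
    out <- lapply(alphas[[l]], function(pi) {
      blocks <- lapply(hs, function(h) {
        if (pi %in% h@piAlphabets[[l]]) h@relations[[l]][[pi]]
        else sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                          dims = c(h@levelSizes[l + 1L], h@levelSizes[l]))
      })
      as(bdiag(blocks), "CsparseMatrix")
    })
    names(out) <- alphas[[l]]
    out
  })
  X <- do.call(rbind, lapply(hs, function(h) h@attributes))
  buildHDecomposition(ids, relations, alphas, X,
                      compressed = all(vapply(hs, function(h) h@compressed, logical(1))))
}
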