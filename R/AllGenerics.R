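#' Number of levels above the bottom of a hierarchy
#'
#' For an object with levels S_0..S_L this returns L.
#' @param x an object with a level structure.
#' @return integer L.
#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))

#' Per-level object counts
#' @param x an object with a level structure.
#' @return integer vector of length L+1.
#' @export
setGeneric("levelSizes", function(x) standardGeneric("levelSizes"))

#' Membership-type alphabets
#' @param x an object carrying per-level type alphabets.
#' @return list of character vectors, one per level l = 1..L.
#' @export
setGeneric("piAlphabets", function(x) standardGeneric("piAlphabets"))

#' Typed part-of relation matrix
#'
#' The sparse count matrix R_{l,pi} connecting level l to level l-1.
#' @param x a hierarchy.
#' @param l level index, 1..L.
#' @param pi membership type (a value of the level-l alphabet).
#' @return a sparse |S_l| x |S_{l-1}| matrix.
#' @export
setGeneric("relationMatrix", function(x, l, pi) standardGeneric("relationMatrix"))

#' Bottom-level attribute matrix
#' @param x a hierarchy.
#' @return dense numeric matrix, one row per atomic object.
#' @export
setGeneric("bottomAttributes", function(x) standardGeneric("bottomAttributes"))

#' Per-level compression / decompression matrices
#' @param x a [CompressionMaps-class] object.
#' @param l level index, 0..L.
#' @return a sparse matrix.
#' @rdname cdAccessors
#' @export
setGeneric("compressionMatrix", function(x, l) standardGeneric("compressionMatrix"))

#' @rdname cdAccessors
#' @export
setGeneric("decompressionMatrix", function(x, l) standardGeneric("decompressionMatrix"))

#' Graphs of a dataset
#' @param x a [GraphDataset-class].
#' @return list of [AttributedGraph-class] objects.
#' @export
setGeneric("graphList", function(x) standardGeneric("graphList"))

#' Class labels of a dataset
#' @param x a [GraphDataset-class].
#' @return integer vector of 0-based class codes.
#' @export
setGeneric("graphLabels", function(x) standardGeneric("graphLabels"))

setMethod("nLevels", "HDecomposition", function(x) length(x@levelSizes) - 1L)
setMethod("levelSizes", "HDecomposition", function(x) x@levelSizes)
setMethod("piAlphabets", "HDecomposition", function(x) x@piAlphabets)
setMethod("bottomAttributes", "HDecomposition", function(x) x@attributes)
setMethod("relationMatrix", "HDecomposition", function(x, l, pi) {
  stopifnot(l >= 1L, l <= nLevels(x))
  rel <- x@relations[[l]]
  if (missing(pi)) return(rel)
  if (!pi %in% names(rel))
    stop(sprintf("no membership type '%s' at level %d", pi, l))
  rel[[as.character(pi)]]
})

setMethod("compressionMatrix", "CompressionMaps", function(x, l) x@C[[l + 1L]])
setMethod("decompressionMatrix", "CompressionMaps", function(x, l) x@D[[l + 1L]])
setMethod("levelSizes", "CompressionMaps", function(x) x@compressedSizes)

setMethod("graphList", "GraphDataset", function(x) x@graphs)
setMethod("graphLabels", "GraphDataset", function(x) x@labels)
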