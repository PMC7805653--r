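#' Compression/decompression pair of a matrix with repeated rows
#'
#' Groups identical rows of `M` in first-occurrence order. The boolean
#' decompression matrix `D` has a 1 in entry (i, j) exactly when row i of
#' `M` falls in equivalence class j, so `M = D %*% Mcomp` where `Mcomp`
#' keeps each distinct row once. The left pseudo-inverse `C` comes in two
#' variants: `"averaging"` transposes `D` and divides each row by its sum;
#' `"representer"` keeps a single 1 per row, at the first original row of
#' the class, which is sparser. Either way `C %*% D` is the identity on
#' classes and `Mcomp = C %*% M`.
#'
#' Entries must be exactly comparable (integer or categorical codes,
#' including post-collapse cardinality counts); real-valued input is
#' rejected because representation-preserving collapse is only sound for
#' categorical attributes.
#'
#' @param M matrix (dense or sparse) with discrete entries.
#' @param variant pseudo-inverse form, `"representer"` (default) or
#'   `"averaging"`.
#' @return list with sparse `C`, sparse `D`, `Mcomp`, the integer class
#'   assignment `classes` and the `representatives` row indices.
#' @export
computeCD <- function(M, variant = c("representer", "averaging")) {
  variant <- match.arg(variant)
  vals <- if (is(M, "sparseMatrix")) M@x else M
  if (any(vals != round(vals)))
    stop("compression requires exactly comparable (categorical/integer-coded) entries; got real values")
  Md <- as.matrix(M)
  n <- nrow(Md)
  keys <- do.call(paste, c(as.data.frame(Md), sep = "\r"))
  representatives <- which(!duplicated(keys))
  classes <- match(keys, keys[representatives])
  m <- length(representatives)
  D <- sparseMatrix(i = seq_len(n), j = classes, x = rep(1, n), dims = c(n, m))
  C <- if (variant == "averaging") {
    counts <- tabulate(classes, nbins = m)
    as(Diagonal(x = 1 / counts) %*% Matrix::t(D), "CsparseMatrix")
  } else {
    sparseMatrix(i = seq_len(m), j = representatives, x = rep(1, m),
                 dims = c(m, n))
  }
  list(C = C, D = D, Mcomp = M[representatives, , drop = FALSE],
       classes = classes, representatives = representatives)
}

#' Losslessly compress an H-decomposition by collapsing symmetric objects
#'
#' Bottom-up pass over the hierarchy. First the bottom level is grouped by
#' identical attribute rows. Then, at each level l, every typed relation is
#' column-compressed by the decompression matrix of the level below (which
#' collapses fan-in onto the merged parts, accumulating integer
#' cardinalities), the column-compressed matrices are concatenated over the
#' full alphabet in its fixed order, identical rows of the concatenation
#' are grouped (objects made of the same parts with the same types, for
#' every type), and the resulting compression matrix is applied on the left
#' to obtain the compressed typed relations.
#'
#' Objects merged this way provably share their representation for every
#' value of the network parameters, so the compressed hierarchy yields the
#' original one exactly through `H_l = D_l %*% H_l_comp` (see
#' [decompressRepresentations()] and [verifyLossless()]).
#'
#' @param h an [HDecomposition-class] with categorical (integer-coded)
#'   bottom attributes.
#' @param variant pseudo-inverse form, see [computeCD()].
#' @return a [CompressionMaps-class].
#' @export
domainCompress <- function(h, variant = c("representer", "averaging")) {
  stopifnot(is(h, "HDecomposition"))
  variant <- match.arg(variant)
  L <- nLevels(h)
  C <- vector("list", L + 1L)
  D <- vector("list", L + 1L)
  cd <- computeCD(h@attributes, variant)
  C[[1L]] <- cd$C; D[[1L]] <- cd$D
  Xcomp <- as.matrix(cd$Mcomp)
  relComp <- vector("list", L)
  for (l in seq_len(L)) {
    alpha <- h@piAlphabets[[l]]
    colComp <- lapply(h@relations[[l]], function(R)
      as(R %*% D[[l]], "CsparseMatrix"))
    cd <- computeCD(do.call(cbind, unname(colComp)), variant)
    C[[l + 1L]] <- cd$C; D[[l + 1L]] <- cd$D
    relComp[[l]] <- lapply(colComp, function(Rc) {
      # entries are provably integral (rows within a class are identical);
      # round away the fp noise of the averaging variant
      Matrix::drop0(round(as(C[[l + 1L]] %*% Rc, "CsparseMatrix"), 9))
    })
    names(relComp[[l]]) <- alpha
  }
  # slot name C would partially match new()'s Class formal; fill slots directly
  maps <- new("CompressionMaps")
  maps@C <- C; maps@D <- D
  maps@Xcomp <- Xcomp
  maps@relationsComp <- relComp
  maps@piAlphabets <- h@piAlphabets
  maps@originalSizes <- h@levelSizes
  maps@compressedSizes <- vapply(D, ncol, integer(1))
  maps@variant <- variant
  validObject(maps)
  maps
}

#' The compressed hierarchy as an H-decomposition
#'
#' Rebuilds a first-class [HDecomposition-class] from the compressed
#' matrices, so the same forward pass, training and serialization code runs
#' on it unchanged. Each equivalence class keeps the object id of its first
#' original member.
#'
#' @param h the original [HDecomposition-class].
#' @param maps the [CompressionMaps-class] from [domainCompress()].
#' @return an [HDecomposition-class] with `compressed = TRUE`.
#' @export
compressedHDecomposition <- function(h, maps) {
  stopifnot(is(h, "HDecomposition"), is(maps, "CompressionMaps"))
  L <- nLevels(h)
  ids <- lapply(0:L, function(l) {
    Dt <- as(maps@D[[l + 1L]], "TsparseMatrix")
    reps <- as.integer(tapply(Dt@i + 1L,
                              factor(Dt@j + 1L, levels = seq_len(ncol(Dt))),
                              min))
    h@objectIds[[l + 1L]][reps]
  })
  buildHDecomposition(ids, maps@relationsComp, maps@piAlphabets,
                      maps@Xcomp, compressed = TRUE)
}

#' Expand compressed representations back to the original objects
#'
#' Row i of the result is the representation of the equivalence class that
#' original object i belongs to.
#'
#' @param H_comp dense matrix of per-class representations.
#' @param D the level's boolean decompression matrix.
#' @return dense matrix with one row per original object.
#' @export
decompressRepresentations <- function(H_comp, D) {
  if (ncol(D) != nrow(H_comp))
    stop("decompression matrix and compressed representations do not conform")
  as.matrix(D %*% H_comp)
}

#' Check that compression preserves the forward computation
#'
#' Runs the forward pass on the original hierarchy and on its compressed
#' form, decompresses every level's representations and returns the largest
#' relative discrepancy across levels. Collapsibility is
#' parameter-universal, so this should be at numerical noise level for any
#' model.
#'
#' @param h an [HDecomposition-class] with categorical attributes.
#' @param model a matching [SaenModel-class].
#' @param variant pseudo-inverse form, see [computeCD()].
#' @return the maximum relative error over levels (0 when both structures
#'   agree exactly).
#' @export
verifyLossless <- function(h, model, variant = c("representer", "averaging")) {
  variant <- match.arg(variant)
  maps <- domainCompress(h, variant)
  hc <- compressedHDecomposition(h, maps)
  full <- saenForward(h, model)
  comp <- saenForward(hc, model)
  worst <- 0
  for (l in 0:nLevels(h)) {
    Hl <- full$H[[l + 1L]]
    Hl2 <- decompressRepresentations(comp$H[[l + 1L]], maps@D[[l + 1L]])
    scale <- max(abs(Hl), 1e-12)
    worst <- max(worst, max(abs(Hl - Hl2)) / scale)
  }
  worst
}

#' Summary of a compression run
#'
#' Per-level original and compressed object counts and relation nonzeros,
#' plus the on-disk size ratio of the two serialized containers.
#'
#' @param h the original [HDecomposition-class].
#' @param maps its [CompressionMaps-class].
#' @return a JSON-friendly list with `levels` (per-level counts and
#'   ratios), `nnz` (relation nonzeros before/after), `bytes`
#'   (serialized container sizes) and `sizeRatio`.
#' @export
compressionReport <- function(h, maps) {
  stopifnot(is(h, "HDecomposition"), is(maps, "CompressionMaps"))
  L <- nLevels(h)
  nnz <- function(rel) sum(vapply(rel, function(lv)
    sum(vapply(lv, function(R) length(R@x), numeric(1))), numeric(1)))
  tmp1 <- tempfile(fileext = ".json"); tmp2 <- tempfile(fileext = ".json")
  on.exit(unlink(c(tmp1, tmp2)), add = TRUE)
  writeHDecomposition(h, tmp1)
  writeHDecomposition(compressedHDecomposition(h, maps), tmp2)
  b1 <- file.size(tmp1); b2 <- file.size(tmp2)
  list(
    variant = maps@variant,
    levels = data.frame(
      level = 0:L,
      original = as.integer(maps@originalSizes),
      compressed = as.integer(maps@compressedSizes),
      ratio = maps@compressedSizes / maps@originalSizes),
    nnz = list(original = nnz(h@relations), compressed = nnz(maps@relationsComp)),
    bytes = list(original = b1, compressed = b2),
    sizeRatio = b2 / b1)
}
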