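test_that("computeCD factorizes a matrix over its distinct rows", {
  M <- matrix(c(2, 2, 1, 2, 1, 1, 2, 1), 4, 2)
  for (variant in c("representer", "averaging")) {
    cd <- computeCD(M, variant)
    # D has one 1 per row, C is a left inverse, D %*% Mcomp rebuilds M
    expect_equal(Matrix::rowSums(cd$D), rep(1, 4), ignore_attr = TRUE)
    expect_equal(as.matrix(cd$C %*% cd$D), diag(nrow(cd$Mcomp)),
                 ignore_attr = TRUE)
    expect_equal(as.matrix(cd$D %*% cd$Mcomp), M, ignore_attr = TRUE)
    expect_equal(as.matrix(cd$C %*% M), as.matrix(cd$Mcomp), ignore_attr = TRUE)
  }
  # sparsity shapes: representer has one nonzero per row; averaging rows sum to 1
  cd <- computeCD(M, "representer")
  expect_equal(Matrix::rowSums(cd$C != 0), rep(1, nrow(cd$Mcomp)),
               ignore_attr = TRUE)
  cd <- computeCD(M, "averaging")
  expect_equal(Matrix::rowSums(cd$C), rep(1, nrow(cd$Mcomp)), ignore_attr = TRUE)

  # all-distinct rows: identity maps
  Md <- matrix(1:6, 3, 2)
  cd <- computeCD(Md)
  expect_equal(as.matrix(cd$D), diag(3), ignore_attr = TRUE)
  expect_equal(as.matrix(cd$C), diag(3), ignore_attr = TRUE)
  expect_equal(as.matrix(cd$Mcomp), Md, ignore_attr = TRUE)

  # real-valued input is rejected
  expect_error(computeCD(matrix(c(0.5, 1), 2, 1)), "categorical")
})

test_that("domain compression is the identity on fully distinct structures", {
  h <- buildHDecomposition(
    levels = list(c("v1", "v2", "v3"), c("s1", "s2")),
    relations = list(list(t = data.frame(parent = c("s1", "s2", "s2"),
                                         part = c("v1", "v2", "v3")))),
    piAlphabets = list("t"),
    attributes = matrix(c(1, 2, 3), 3, 1))
  maps <- domainCompress(h)
  expect_identical(maps@compressedSizes, maps@originalSizes)
  for (l in 0:1) {
    expect_equal(as.matrix(decompressionMatrix(maps, l)),
                 diag(maps@originalSizes[l + 1]), ignore_attr = TRUE)
    expect_equal(as.matrix(compressionMatrix(maps, l)),
                 diag(maps@originalSizes[l + 1]), ignore_attr = TRUE)
  }
  rep <- compressionReport(h, maps)
  expect_equal(rep$levels$ratio, rep(1, 2))
})

test_that("duplicate copies collapse to a single copy below the top", {
  g <- randomGraph(7, pEdge = 0.4, seed = 171)
  one <- decomposeCollection(list(g), method = "egd", radius = 1)
  k <- 4
  many <- decomposeCollection(rep(list(g), k), method = "egd", radius = 1)
  mapsOne <- domainCompress(one)
  mapsMany <- domainCompress(many)
  L <- nLevels(one)
  expect_identical(mapsMany@compressedSizes[seq_len(L)],
                   mapsOne@compressedSizes[seq_len(L)])
  # the top level keeps one class: all copies are identical graphs
  expect_identical(mapsMany@compressedSizes[L + 1], 1L)
})

test_that("compression is idempotent and monotone under duplication", {
  h <- randomHDecomposition(c(10, 8, 4), c(2, 2), seed = 181)
  maps <- domainCompress(h)
  hc <- compressedHDecomposition(h, maps)
  again <- domainCompress(hc)
  expect_identical(again@compressedSizes, again@originalSizes)

  # duplicating an existing object (same parts, same types) never grows
  # the compressed sizes
  dup <- buildHDecomposition(
    levels = list(h@objectIds[[1]], c(h@objectIds[[2]], "extra"), h@objectIds[[3]]),
    relations = list(
      lapply(h@relations[[1]], function(R) rbind(R, R[1, , drop = FALSE])),
      lapply(h@relations[[2]], function(R)
        cbind(R, Matrix::Matrix(0, nrow(R), 1, sparse = TRUE)))),
    piAlphabets(h),
    bottomAttributes(h))
  mapsDup <- domainCompress(dup)
  expect_identical(mapsDup@compressedSizes, maps@compressedSizes)
})

test_that("permutation of a level relabels classes without changing content", {
  h <- randomHDecomposition(c(9, 6, 3), c(2, 2), seed = 191)
  maps <- domainCompress(h)
  set.seed(192)
  perm <- sample(9)
  hp <- buildHDecomposition(
    list(h@objectIds[[1]][perm], h@objectIds[[2]], h@objectIds[[3]]),
    list(lapply(h@relations[[1]], function(R) R[, perm, drop = FALSE]),
         h@relations[[2]]),
    piAlphabets(h),
    bottomAttributes(h)[perm, , drop = FALSE])
  mapsP <- domainCompress(hp)
  expect_identical(mapsP@compressedSizes, maps@compressedSizes)
  # upper levels see the same multiset of column-compressed part patterns
  expect_equal(sort(as.vector(mapsP@Xcomp)), sort(as.vector(maps@Xcomp)))
})

test_that("decompression expands class rows back to object rows", {
  D <- Matrix::sparseMatrix(i = 1:4, j = c(1, 1, 2, 1), x = 1)
  Hc <- matrix(c(1, 2, 3, 4), 2, 2)
  out <- decompressRepresentations(Hc, D)
  expect_equal(out, Hc[c(1, 1, 2, 1), ])
  expect_equal(as.matrix(decompressRepresentations(Hc, Matrix::Diagonal(2))), Hc)
  expect_error(decompressRepresentations(matrix(0, 3, 2), D), "conform")
})

test_that("forward on the compressed structure is lossless at every level", {
  for (seed in 201:205) {
    set.seed(seed)
    L <- sample(1:3, 1)
    sizes <- sample(5:30, L + 1, replace = TRUE)
    nt <- sample(1:3, L, replace = TRUE)
    h <- randomHDecomposition(sizes, nt, seed = seed)
    m <- newSaenModel(h, dims = sample(2:5, L, replace = TRUE), nClasses = 3,
                      seed = seed + 1)
    expect_lt(verifyLossless(h, m, "representer"), 1e-6)
    expect_lt(verifyLossless(h, m, "averaging"), 1e-6)
  }
})

test_that("compression reports round-trip through JSON", {
  h <- randomHDecomposition(c(8, 5, 2), c(2, 1), seed = 211)
  maps <- domainCompress(h)
  rep <- compressionReport(h, maps)
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(rep, tmp, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$levels$original, rep$levels$original)
  expect_equal(back$sizeRatio, rep$sizeRatio)
  expect_true(back$bytes$compressed <= back$bytes$original)
})
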