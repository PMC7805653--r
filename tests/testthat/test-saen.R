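test_that("shift places the vector in the right orthogonal block", {
  expect_identical(shiftRepresentation(c(3, 1), 0, 1), c(3, 1))
  expect_identical(shiftRepresentation(c(1, 2), 1, 3), c(0, 0, 1, 2, 0, 0))
  expect_error(shiftRepresentation(c(1, 2), 3, 3), "out of range")

  set.seed(91)
  h <- rnorm(4)
  shifted <- lapply(0:2, function(k) shiftRepresentation(h, k, 3))
  # norms preserved, blocks orthogonal, stacking recovers the replication
  for (s in shifted) expect_equal(sqrt(sum(s^2)), sqrt(sum(h^2)))
  expect_equal(sum(shifted[[1]] * shifted[[2]]), 0)
  expect_equal(Reduce(`+`, shifted), rep(h, times = 3))
})

test_that("aggregate equals the loop-form double sum", {
  # a single part of type pi contributes exactly its shifted row
  h <- buildHDecomposition(
    levels = list(c("v1", "v2"), c("s1")),
    relations = list(list(a = data.frame(parent = character(0), part = character(0)),
                          b = data.frame(parent = "s1", part = "v2"))),
    piAlphabets = list(c("a", "b")),
    attributes = matrix(c(1, 0, 0, 1), 2, 2))
  Hprev <- matrix(c(5, 6, 7, 8), 2, 2)
  expect_equal(aggregateLevel(h, 1, Hprev)[1, ],
               shiftRepresentation(Hprev[2, ], 1, 2))

  # a collapsed arc of cardinality 2 contributes twice the shifted row
  fx <- workedExampleFixture("example1")
  maps <- domainCompress(fx$h)
  hc <- compressedHDecomposition(fx$h, maps)
  set.seed(92)
  HC <- matrix(rnorm(2 * levelSizes(hc)[3]), levelSizes(hc)[3], 2)
  aggD <- aggregateLevel(hc, 3, HC)
  c1 <- match("C1", hc@objectIds[[3]])
  redIdx <- match("red", piAlphabets(hc)[[3]]) - 1L
  expect_equal(aggD[1, ], 2 * shiftRepresentation(HC[c1, ], redIdx, 2))

  # random instances against the loop-form oracle
  for (seed in 93:95) {
    hr <- randomHDecomposition(c(6, 5, 4), c(3, 2), seed = seed)
    set.seed(seed)
    H0 <- matrix(rnorm(6 * 3), 6, 3)
    expect_equal(aggregateLevel(hr, 1, H0), aggregateLoopOracle(hr, 1, H0))
    H1 <- matrix(rnorm(5 * 2), 5, 2)
    expect_equal(aggregateLevel(hr, 2, H1), aggregateLoopOracle(hr, 2, H1))
  }
})

test_that("extract applies the stack row-wise", {
  layers <- list(list(W = matrix(0, 3, 2), b = c(0, 0)))
  A <- matrix(rnorm(12), 4, 3)
  expect_equal(extractLevel(A, layers), matrix(0, 4, 2))

  idLayers <- list(list(W = diag(3), b = numeric(3)))
  Apos <- matrix(abs(rnorm(12)), 4, 3)
  expect_equal(extractLevel(Apos, idLayers), Apos)

  # row independence: permuting input rows permutes output rows
  set.seed(101)
  layers <- list(list(W = matrix(rnorm(12), 3, 4), b = rnorm(4)),
                 list(W = matrix(rnorm(8), 4, 2), b = rnorm(2)))
  A <- matrix(rnorm(18), 6, 3)
  perm <- sample(6)
  expect_equal(extractLevel(A, layers)[perm, ], extractLevel(A[perm, ], layers))

  expect_error(extractLevel(matrix(0, 2, 5), idLayers), "width")
})

test_that("forward matches a from-scratch per-object recursion", {
  # chain decomposition: one object per level composes the extractors
  chain <- buildHDecomposition(
    levels = list("v", "m", "t"),
    relations = list(list(only = data.frame(parent = "m", part = "v")),
                     list(only = data.frame(parent = "t", part = "m"))),
    piAlphabets = list("only", "only"),
    attributes = matrix(c(2, 1), 1, 2))
  m <- newSaenModel(chain, dims = c(3, 3), nClasses = 2, seed = 103)
  fw <- saenForward(chain, m)
  x <- bottomAttributes(chain)
  h0 <- extractLevel(x, m@params[[1]], m@leakySlope)
  h1 <- extractLevel(h0, m@params[[2]], m@leakySlope)
  h2 <- extractLevel(h1, m@params[[3]], m@leakySlope, rawFinal = TRUE)
  expect_equal(fw$scores, h2)

  # random three-level instance against the recursion oracle
  for (seed in 104:106) {
    h <- randomHDecomposition(c(6, 4, 3, 2), c(2, 1, 3), seed = seed)
    m <- newSaenModel(h, dims = c(3, 2, 4), nClasses = 2,
                      hidden = list(integer(0), 3L, integer(0), 2L),
                      seed = seed)
    fw <- saenForward(h, m)
    oracle <- forwardRecursionOracle(h, m)
    for (l in 0:3) expect_equal(fw$H[[l + 1]], oracle[[l + 1]],
                                ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("kernel features are the identity-extractor forward map", {
  # all n(l) = 1: features sum bottom attributes weighted by path multiplicity
  chain <- buildHDecomposition(
    levels = list(c("v1", "v2"), "m", "t"),
    relations = list(list(only = data.frame(parent = c("m", "m"), part = c("v1", "v2"))),
                     list(only = data.frame(parent = "t", part = "m"))),
    piAlphabets = list("only", "only"),
    attributes = matrix(c(1, 2, 10, 20), 2, 2))
  expect_equal(kernelFeatures(chain), matrix(c(3, 30), 1, 2),
               ignore_attr = TRUE)

  # width multiplies by n(l) per level; the cap guards the blow-up
  h <- randomHDecomposition(c(5, 4, 3, 2), c(2, 3, 2), p = 2, seed = 111)
  K <- kernelFeatures(h)
  expect_identical(ncol(K), 2L * 2L * 3L * 2L)
  expect_error(kernelFeatures(h, cap = 10), "cap")

  # identity extractors with slope 1 reproduce the feature map
  m <- newSaenModel(h, dims = c(2, 4, 12), nClasses = 24, leakySlope = 1)
  for (l in 1:4) m@params[[l]][[1]]$W <- diag(nrow(m@params[[l]][[1]]$W))
  expect_equal(saenForward(h, m)$scores, K, ignore_attr = TRUE)
})

test_that("training descends the objective and a zero rate is a no-op", {
  h <- randomHDecomposition(c(8, 6, 4), c(2, 2), seed = 121)
  labels <- rep(0:1, 2)
  m <- newSaenModel(h, dims = c(4, 4), nClasses = 2, l2 = 1e-4, seed = 122)

  frozen <- saenTrain(h, labels, m, epochs = 5, learningRate = 0)
  expect_identical(frozen$model@params, m@params)
  expect_equal(diff(frozen$loss), rep(0, 4))

  fit <- saenTrain(h, labels, m, epochs = 200, learningRate = 0.02)
  expect_lt(fit$loss[200], fit$loss[1])
})

test_that("analytic gradients match finite differences", {
  h <- randomHDecomposition(c(5, 4, 3), c(2, 2), p = 2, seed = 131)
  m <- newSaenModel(h, dims = c(3, 3), nClasses = 2,
                    hidden = list(4L, integer(0), 3L), l2 = 1e-3, seed = 132)
  expect_lt(finiteDiffCheck(h, c(0L, 1L, 0L), m), 1e-5)
})

test_that("a separable synthetic collection is learned to high accuracy", {
  ds <- generateTwoClassCollection(30, 8, seed = 141)
  h <- decomposeCollection(ds, method = "egd", radius = 1)
  maps <- domainCompress(h)
  hc <- compressedHDecomposition(h, maps)
  m <- newSaenModel(hc, dims = c(8, 8), nClasses = 2, l2 = 1e-4, seed = 142)
  fit <- saenTrain(hc, graphLabels(ds), m, epochs = 60, learningRate = 0.05,
                   decompression = decompressionMatrix(maps, nLevels(h)))
  pred <- saenPredict(hc, fit$model,
                      decompression = decompressionMatrix(maps, nLevels(h)))
  expect_gte(mean(pred$labels == graphLabels(ds)), 0.95)
})

test_that("prediction breaks ties toward the lower class and ignores object order", {
  # tie-break via the forward path: force equal scores with zero weights
  h <- buildHDecomposition(
    levels = list("v", "t"),
    relations = list(list(only = data.frame(parent = "t", part = "v"))),
    piAlphabets = list("only"),
    attributes = matrix(1, 1, 1))
  mz <- newSaenModel(h, dims = 2, nClasses = 2, seed = 152)
  for (l in 1:2) for (k in seq_along(mz@params[[l]])) {
    mz@params[[l]][[k]]$W[] <- 0
    mz@params[[l]][[k]]$b[] <- 0
  }
  expect_identical(saenPredict(h, mz)$labels, 0L)

  # object reordering within lower levels leaves predictions untouched
  hr <- randomHDecomposition(c(6, 5, 4), c(2, 2), seed = 153)
  m <- newSaenModel(hr, dims = c(3, 3), nClasses = 3, seed = 154)
  perm <- sample(6)
  hp <- buildHDecomposition(
    list(hr@objectIds[[1]][perm], hr@objectIds[[2]], hr@objectIds[[3]]),
    list(lapply(hr@relations[[1]], function(R) R[, perm, drop = FALSE]),
         hr@relations[[2]]),
    piAlphabets(hr),
    bottomAttributes(hr)[perm, , drop = FALSE])
  expect_identical(saenPredict(hp, m)$labels, saenPredict(hr, m)$labels)
})

test_that("model checkpoints round-trip", {
  m <- newSaenModel(3, c(2, 2), c(4, 4), nClasses = 2,
                    hidden = list(3L, integer(0), 2L), l2 = 1e-3, seed = 161)
  tmp <- tempfile(fileext = ".json")
  writeSaenModel(m, tmp)
  m2 <- readSaenModel(tmp)
  expect_equal(m2@params, m@params)
  expect_identical(m2@outDims, m@outDims)
  bad <- tempfile(fileext = ".json")
  writeLines("{}", bad)
  expect_error(readSaenModel(bad), "malformed")
})
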