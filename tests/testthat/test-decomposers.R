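test_that("inducedSubgraph keeps exactly the internal edges", {
  tri <- attributedGraph(rbind(c(1, 2), c(1, 3), c(2, 3)), 3,
                         vertexLabels = c("x", "y", "z"))
  whole <- inducedSubgraph(tri, 1:3)
  expect_identical(whole@edges, tri@edges)
  expect_identical(whole@vertexLabels, tri@vertexLabels)

  pair <- inducedSubgraph(tri, c(1, 2))
  expect_identical(pair@edges, matrix(c(1L, 2L), 1, 2))

  expect_error(inducedSubgraph(tri, c(1, 9)), "unknown")

  # brute-force filter oracle on random instances
  for (seed in 1:5) {
    g <- randomGraph(9, seed = seed)
    vids <- sort(sample(9, 5))
    sub <- inducedSubgraph(g, vids)
    expected <- g@edges[g@edges[, 1] %in% vids & g@edges[, 2] %in% vids, ,
                        drop = FALSE]
    expected <- cbind(match(expected[, 1], vids), match(expected[, 2], vids))
    expect_equal(sub@edges[order(sub@edges[, 1], sub@edges[, 2]), , drop = FALSE],
                 expected[order(expected[, 1], expected[, 2]), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("egoGraph matches shortest-path balls", {
  g <- randomGraph(10, pEdge = 0.25, seed = 41)
  # radius 0: the root alone, no edges
  e0 <- egoGraph(g, 3, 0)
  expect_identical(e0$members, 3L)
  expect_identical(nrow(e0$graph@edges), 0L)

  # radius beyond the eccentricity: the whole connected component
  d <- floydWarshall(g)
  comp <- which(is.finite(d[3, ]))
  eBig <- egoGraph(g, 3, 10)
  expect_identical(eBig$members, comp)

  # Floyd-Warshall oracle at radius 2, several roots and graphs
  for (seed in 42:44) {
    g <- randomGraph(11, pEdge = 0.2, seed = seed)
    dd <- floydWarshall(g)
    for (v in c(1, 5, 11)) {
      eg <- egoGraph(g, v, 2)
      expect_identical(eg$members, which(dd[v, ] <= 2))
      expect_identical(eg$members[eg$root], as.integer(v))
    }
  }
  expect_error(egoGraph(g, 99, 1), "unknown root")
})

test_that("ego graphs grow monotonically with the radius", {
  g <- randomGraph(12, pEdge = 0.2, seed = 51)
  for (v in c(2, 7)) for (r in 0:3)
    expect_true(all(egoGraph(g, v, r)$members %in% egoGraph(g, v, r + 1)$members))
})

test_that("buildEGD lays out roots, elements and radii", {
  # single vertex, R = 1: two ego graphs, both only containing the root
  h1 <- buildEGD(attributedGraph(matrix(integer(0), 0, 2), 1), 1)
  expect_identical(levelSizes(h1), c(1L, 2L, 1L))
  expect_equal(Matrix::rowSums(relationMatrix(h1, 1, "ROOT")), c(1, 1))
  expect_equal(Matrix::rowSums(relationMatrix(h1, 1, "ELEM")), c(0, 0))

  # path a-b-c at R = 1: ego of b has parts {b:ROOT, a:ELEM, c:ELEM}
  path <- attributedGraph(rbind(c(1, 2), c(2, 3)), 3)
  hp <- buildEGD(path, 1)
  expect_identical(piAlphabets(hp), list(c("ROOT", "ELEM"), c("0", "1")))
  bEgo <- match("g2.r1", hp@objectIds[[2]])
  expect_identical(which(as.matrix(relationMatrix(hp, 1, "ROOT"))[bEgo, ] != 0), 2L)
  expect_identical(which(as.matrix(relationMatrix(hp, 1, "ELEM"))[bEgo, ] != 0),
                   c(1L, 3L))

  # all entries are 0/1 before compression, and ELEM incidences count
  # sum over (v, r) of (|g_{v,r}| - 1)
  g <- randomGraph(9, pEdge = 0.3, seed = 61)
  h <- buildEGD(g, 2)
  for (l in 1:2) for (pi in piAlphabets(h)[[l]])
    expect_true(all(relationMatrix(h, l, pi)@x == 1))
  dd <- floydWarshall(g)
  sizes <- unlist(lapply(1:9, function(v) vapply(0:2, function(r)
    sum(dd[v, ] <= r), numeric(1))))
  expect_equal(sum(relationMatrix(h, 1, "ELEM")), sum(sizes - 1))
})

test_that("color refinement is attribute-seeded, injective and isomorphism-invariant", {
  # uniform attributes, no refinement: one color
  g <- randomGraph(6, seed = 71, labels = "a")
  expect_identical(length(unique(as.integer(wlColors(g, 0)))), 1L)

  # star: one round separates the hub from the leaves
  star <- attributedGraph(rbind(c(1, 2), c(1, 3), c(1, 4)), 4)
  cs <- wlColors(star, 1)
  expect_identical(length(unique(as.integer(cs))), 2L)
  expect_identical(as.integer(cs[2]), as.integer(cs[3]))
  expect_false(cs[1] == cs[2])

  # color counts never decrease across iterations
  g <- randomGraph(10, pEdge = 0.3, seed = 72)
  hist <- attr(wlColors(g, 4), "history")
  counts <- apply(hist, 2, function(col) length(unique(col)))
  expect_true(all(diff(counts) >= 0))

  # isomorphic graphs yield identical color multisets
  for (seed in 73:75) {
    g <- randomGraph(8, pEdge = 0.35, seed = seed)
    perm <- sample(8)
    g2 <- permuteGraph(g, perm)
    c1 <- as.integer(wlColors(g, 3))
    c2 <- as.integer(wlColors(g2, 3))
    expect_identical(sort(table(c1)), sort(table(c2)), ignore_attr = TRUE)
    # the shared-dictionary coloring maps vertex v of g to perm[v] of g2
    c2shared <- as.integer(wlColors(g2, 3,
                                    dictionary = attr(wlColors(g, 3), "dictionary")))
    expect_identical(c2shared[perm], c1)
  }
})

test_that("buildNEGD types ego graphs by size and parts by root/edge symbol", {
  # edgeless graph: every ego graph is a single root of size 1
  iso <- attributedGraph(matrix(integer(0), 0, 2), 3)
  hi <- buildNEGD(iso)
  expect_identical(piAlphabets(hi)[[2]], "1")
  expect_equal(Matrix::rowSums(relationMatrix(hi, 1, "ROOT")), rep(1, 3))

  # triangle with uniform labels and one symbol: all three ego graphs share
  # size type 3 and identical part multisets (ROOT x1, symbol x2 on the
  # shared identifier object)
  tri <- attributedGraph(rbind(c(1, 2), c(1, 3), c(2, 3)), 3,
                         edgeSymbols = c("a", "a", "a"))
  ht <- buildNEGD(tri)
  expect_identical(levelSizes(ht)[1], 1L)  # one shared identifier
  expect_identical(piAlphabets(ht)[[2]], "3")
  expect_equal(as.vector(relationMatrix(ht, 1, "ROOT")), rep(1, 3))
  expect_equal(as.vector(relationMatrix(ht, 1, "a")), rep(2, 3))

  # identifier sharing: indistinguishable neighborhoods get one bottom
  # object, hence identical one-hot rows
  path <- attributedGraph(rbind(c(1, 2), c(2, 3)), 3, edgeSymbols = c("a", "a"))
  hpth <- buildNEGD(path)
  # vertices 1 and 3 are symmetric; the bottom level has 2 identifiers
  expect_identical(levelSizes(hpth)[1], 2L)
  expect_identical(nrow(unique(bottomAttributes(hpth))), 2L)
})

test_that("decomposition of isomorphic graphs compresses identically", {
  for (method in c("egd", "negd")) {
    g <- randomGraph(8, pEdge = 0.35, symbols = c("s", "t"), seed = 81)
    g2 <- permuteGraph(g, sample(8))
    h1 <- if (method == "egd") buildEGD(g, 1) else buildNEGD(g)
    h2 <- if (method == "egd") buildEGD(g2, 1) else buildNEGD(g2)
    m1 <- domainCompress(h1)
    m2 <- domainCompress(h2)
    expect_identical(m1@compressedSizes, m2@compressedSizes)
  }
})

test_that("held-out decomposition uses training alphabets strictly", {
  train <- list(attributedGraph(rbind(c(1, 2)), 2, edgeSymbols = "a"))
  hTrain <- decomposeCollection(train, method = "negd")
  alpha <- attr(hTrain, "alphabets")
  # a triangle has ego-graph size 3, unseen in training
  tri <- attributedGraph(rbind(c(1, 2), c(1, 3), c(2, 3)), 3,
                         edgeSymbols = c("a", "a", "a"))
  expect_error(
    decomposeCollection(list(tri), method = "negd", alphabets = alpha),
    "unseen")
  hMapped <- decomposeCollection(list(tri), method = "negd", alphabets = alpha,
                                 nearestSize = TRUE)
  expect_identical(piAlphabets(hMapped)[[2]], alpha$sizes)
})
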