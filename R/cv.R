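.stratifiedFolds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop(sprintf("class %d has fewer members (%d) than folds (%d)",
                   cl, length(idx), k))
    fold[sample(idx)] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

.cvDefaults <- function(decomposition, model) {
  decomposition <- utils::modifyList(
    list(method = "egd", radius = 1L, wlIterations = 4L, nearestSize = TRUE),
    decomposition)
  model <- utils::modifyList(
    list(dims = c(8L, 8L), hidden = NULL, l2 = 1e-4, epochs = 60L,
         learningRate = 0.05, leakySlope = 0.01, variant = "representer",
         compress = TRUE),
    model)
  list(decomposition = decomposition, model = model)
}

# Fit one training split: decompose + merge, compress (training data only),
# train. Returns the trained model plus the training-time alphabets needed
# to decompose held-out graphs consistently.
.fitSplit <- function(ds, trainIdx, cfg, seed, labels = ds@labels) {
  dcfg <- cfg$decomposition; mcfg <- cfg$model
  h <- decomposeCollection(ds@graphs[trainIdx], method = dcfg$method,
                           radius = dcfg$radius,
                           wlIterations = dcfg$wlIterations)
  alphabets <- attr(h, "alphabets")
  compress <- isTRUE(mcfg$compress) &&
    all(h@attributes == round(h@attributes))
  if (compress) {
    maps <- domainCompress(h, mcfg$variant)
    hTrain <- compressedHDecomposition(h, maps)
    Dtop <- decompressionMatrix(maps, nLevels(h))
  } else {
    hTrain <- h
    Dtop <- NULL
  }
  nClasses <- length(ds@labelLevels)
  model <- newSaenModel(hTrain, dims = mcfg$dims, nClasses = nClasses,
                        hidden = mcfg$hidden, leakySlope = mcfg$leakySlope,
                        l2 = mcfg$l2, seed = seed)
  fit <- saenTrain(hTrain, labels[trainIdx], model,
                   epochs = mcfg$epochs, learningRate = mcfg$learningRate,
                   decompression = Dtop)
  list(model = fit$model, loss = fit$loss, alphabets = alphabets)
}

.predictSplit <- function(ds, testIdx, fit, cfg) {
  dcfg <- cfg$decomposition
  hTest <- decomposeCollection(ds@graphs[testIdx], method = dcfg$method,
                               radius = dcfg$radius,
                               wlIterations = dcfg$wlIterations,
                               alphabets = if (dcfg$method == "negd") fit$alphabets,
                               nearestSize = dcfg$nearestSize)
  saenPredict(hTest, fit$model)$labels
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repetition a fresh stratified fold assignment is drawn
#' (repeat r uses seed + r); within each fold the training split is
#' decomposed, merged into one hierarchy, compressed and trained, and the
#' held-out graphs are decomposed with the training-time alphabets and
#' evaluated uncompressed (compression is lossless, so predictions are
#' identical either way, and no held-out graph influences the training
#' structure or parameters). The accuracy of a repetition pools the fold
#' predictions over all graphs, which matches averaging fold accuracies
#' when fold sizes are equal; mean and standard deviation are taken over
#' the per-repetition accuracies.
#'
#' @param ds a [GraphDataset-class] with at least `folds` graphs per class.
#' @param decomposition list with `method` ("egd"/"negd"), `radius`,
#'   `wlIterations`, `nearestSize`.
#' @param model list with `dims`, `hidden`, `l2`, `epochs`,
#'   `learningRate`, `leakySlope`, `variant`, `compress`.
#' @param repeats,folds protocol shape (10 x 10-fold by default).
#' @param seed base seed; everything downstream is derived from it.
#' @param permuteLabels run the permutation-null variant of the protocol:
#'   every repetition freshly permutes the class labels (with the repeat's
#'   own seed) before fold assignment, training and scoring. Averaging over
#'   permutations estimates the chance level itself, whereas a single global
#'   shuffle only measures the residual association of that one draw.
#' @return a [CVResult-class].
#' @export
runCV <- function(ds, decomposition = list(), model = list(),
                  repeats = 10L, folds = 10L, seed = 1L,
                  permuteLabels = FALSE) {
  stopifnot(is(ds, "GraphDataset"))
  cfg <- .cvDefaults(decomposition, model)
  n <- length(ds@graphs)
  acc <- numeric(repeats)
  foldRecord <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    labels <- if (permuteLabels) sample(ds@labels) else ds@labels
    fold <- .stratifiedFolds(labels, folds)
    foldRecord[[r]] <- fold
    predicted <- integer(n)
    for (f in seq_len(folds)) {
      testIdx <- which(fold == f)
      trainIdx <- which(fold != f)
      fit <- .fitSplit(ds, trainIdx, cfg, seed = (seed + r) * 1000L + f,
                       labels = labels)
      predicted[testIdx] <- .predictSplit(ds, testIdx, fit, cfg)
    }
    acc[r] <- mean(predicted == labels)
  }
  new("CVResult", repeatAccuracies = acc, mean = mean(acc), sd = sd(acc),
      config = cfg, seed = as.integer(seed), folds = foldRecord)
}

#' Compression benchmark on a whole collection
#'
#' Decomposes and merges the collection, compresses it, and reports
#' serialized sizes with and without compression, the size ratio,
#' per-level object counts, and (non-normative) wall-clock timings.
#'
#' @param ds a [GraphDataset-class].
#' @param decomposition decomposition configuration, as in [runCV()].
#' @param variant pseudo-inverse form, see [computeCD()].
#' @return a JSON-friendly report list.
#' @export
runCompressionBenchmark <- function(ds, decomposition = list(),
                                    variant = "representer") {
  stopifnot(is(ds, "GraphDataset"))
  dcfg <- .cvDefaults(decomposition, list())$decomposition
  t0 <- proc.time()[["elapsed"]]
  h <- decomposeCollection(ds, method = dcfg$method, radius = dcfg$radius,
                           wlIterations = dcfg$wlIterations)
  t1 <- proc.time()[["elapsed"]]
  maps <- domainCompress(h, variant)
  t2 <- proc.time()[["elapsed"]]
  rep <- compressionReport(h, maps)
  rep$dataset <- ds@name
  rep$decomposition <- dcfg
  rep$wallClockSeconds <- list(decompose = t1 - t0, compress = t2 - t1,
                               note = "non-normative")
  rep
}
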