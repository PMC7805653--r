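#' Shift a representation into its membership-type block
#'
#' Kronecker product of the type's indicator vector with the part's
#' representation: the output is zero except for the block of the given
#' type, which holds the input vector unchanged (so its norm is preserved
#' and blocks of different types are orthogonal).
#'
#' @param h numeric representation vector of width d.
#' @param piIndex 0-based type index.
#' @param n alphabet size n(l).
#' @return numeric vector of width n * d.
#' @export
shiftRepresentation <- function(h, piIndex, n) {
  if (piIndex < 0L || piIndex >= n) stop("type index out of range")
  z <- numeric(n)
  z[piIndex + 1L] <- 1
  as.vector(kronecker(z, as.numeric(h)))
}

#' Shift-and-aggregate a level
#'
#' For every object of level l, sums the shifted representations of its
#' parts over all membership types: row s of the result is
#' sum over pi, s' part of s with type pi, of the type-pi shift of
#' H_prev[s', ]. Computed blockwise as the typed relation matrices times
#' `H_prev`, which equals the concatenated level matrix times the
#' block-diagonal replication of `H_prev`.
#'
#' @param h an [HDecomposition-class].
#' @param l level index, 1..L.
#' @param H_prev dense matrix of level-(l-1) representations, one row per
#'   object.
#' @return dense matrix with one row per level-l object and width
#'   n(l) * ncol(H_prev).
#' @export
aggregateLevel <- function(h, l, H_prev) {
  stopifnot(is(h, "HDecomposition"), l >= 1L, l <= nLevels(h))
  if (nrow(H_prev) != h@levelSizes[l])
    stop("H_prev must have one row per object of the level below")
  do.call(cbind, lapply(unname(h@relations[[l]]),
                        function(R) as.matrix(R %*% H_prev)))
}

.leaky <- function(Z, slope) ifelse(Z > 0, Z, slope * Z)
.leakyGrad <- function(Z, slope) ifelse(Z > 0, 1, slope)

.mlpForward <- function(A, layers, slope, rawFinal) {
  K <- length(layers)
  inputs <- vector("list", K)
  Zs <- vector("list", K)
  H <- A
  for (k in seq_len(K)) {
    inputs[[k]] <- H
    Z <- H %*% layers[[k]]$W
    Z <- sweep(Z, 2L, layers[[k]]$b, "+")
    Zs[[k]] <- Z
    H <- if (k == K && rawFinal) Z else .leaky(Z, slope)
  }
  list(H = H, inputs = inputs, Z = Zs)
}

.mlpBackward <- function(dH, cache, layers, slope, rawFinal) {
  K <- length(layers)
  grads <- vector("list", K)
  for (k in K:1) {
    dZ <- if (k == K && rawFinal) dH else dH * .leakyGrad(cache$Z[[k]], slope)
    grads[[k]] <- list(W = crossprod(cache$inputs[[k]], dZ),
                       b = colSums(dZ))
    dH <- dZ %*% t(layers[[k]]$W)
  }
  list(dA = dH, grads = grads)
}

#' Row-wise extraction through a level's feedforward stack
#'
#' Applies the level's layers to each row of the aggregate matrix. All
#' hidden and output units use leaky rectification; set `rawFinal = TRUE`
#' for the top level so that the last layer emits raw class scores for the
#' cross-entropy head.
#'
#' @param A dense aggregate matrix (rows are objects).
#' @param layers list of layers, each `list(W, b)`.
#' @param slope leaky-rectifier negative slope.
#' @param rawFinal skip the activation on the final layer.
#' @return dense matrix of extracted representations.
#' @export
extractLevel <- function(A, layers, slope = 0.01, rawFinal = FALSE) {
  if (length(layers) && nrow(layers[[1L]]$W) != ncol(A))
    stop(sprintf("extractor expects input width %d, got %d",
                 nrow(layers[[1L]]$W), ncol(A)))
  .mlpForward(as.matrix(A), layers, slope, rawFinal)$H
}

#' Create a shift-aggregate-extract model
#'
#' Allocates per-level extractor parameters whose widths chain correctly
#' across the hierarchy: the level-l extractor reads n(l) * d(l-1) inputs
#' (p at the bottom) and writes d(l) outputs, with the top-level output
#' width equal to the class count. Hidden widths per level mirror the usual
#' "5-3" style configuration strings (two hidden layers of widths 5 and 3).
#' Weights are Gaussian with the He scale sqrt(2 / fan-in); biases start at
#' zero.
#'
#' @param p bottom attribute width (or an [HDecomposition-class], from
#'   which `p` and `nTypes` are taken).
#' @param nTypes integer vector of alphabet sizes n(l), l = 1..L.
#' @param dims representation widths d(l) for l = 0..L-1 (the top width is
#'   `nClasses`).
#' @param nClasses number of classes.
#' @param hidden list of integer vectors of hidden-layer widths per level
#'   (default: none, a single linear layer per level).
#' @param leakySlope negative slope of the leaky rectifier (default 0.01).
#' @param l2 L2 penalty coefficient on all weight matrices.
#' @param activateTop apply the activation to the final class scores too
#'   (default FALSE: raw scores feed the loss).
#' @param seed optional RNG seed for the initialization.
#' @return a [SaenModel-class].
#' @export
newSaenModel <- function(p, nTypes, dims, nClasses, hidden = NULL,
                         leakySlope = 0.01, l2 = 0, activateTop = FALSE,
                         seed = NULL) {
  if (is(p, "HDecomposition")) {
    h <- p
    p <- ncol(h@attributes)
    nTypes <- lengths(h@piAlphabets)
  }
  p <- as.integer(p); nTypes <- as.integer(nTypes)
  L <- length(nTypes)
  dims <- as.integer(dims)
  if (length(dims) != L)
    stop("dims must give d(l) for l = 0..L-1")
  outDims <- c(dims, as.integer(nClasses))
  if (is.null(hidden)) hidden <- rep(list(integer(0)), L + 1L)
  if (length(hidden) != L + 1L)
    stop("hidden must list widths for every level 0..L")
  if (!is.null(seed)) set.seed(seed)
  params <- vector("list", L + 1L)
  for (l in 0:L) {
    wIn <- if (l == 0L) p else nTypes[l] * outDims[l]
    widths <- c(wIn, as.integer(hidden[[l + 1L]]), outDims[l + 1L])
    layers <- vector("list", length(widths) - 1L)
    for (k in seq_along(layers)) {
      layers[[k]] <- list(
        W = matrix(rnorm(widths[k] * widths[k + 1L], sd = sqrt(2 / widths[k])),
                   widths[k], widths[k + 1L]),
        b = numeric(widths[k + 1L]))
    }
    params[[l + 1L]] <- layers
  }
  new("SaenModel", params = params, p = p, nTypes = nTypes,
      outDims = outDims, nClasses = as.integer(nClasses),
      leakySlope = leakySlope, l2 = l2, activateTop = isTRUE(activateTop))
}

.checkModelMatch <- function(h, model) {
  if (ncol(h@attributes) != model@p)
    stop(sprintf("attribute width %d does not match model p = %d",
                 ncol(h@attributes), model@p))
  nl <- lengths(h@piAlphabets)
  if (length(nl) != length(model@nTypes) || any(nl != model@nTypes))
    stop("membership alphabet sizes of the hierarchy do not match the model")
}

#' Forward pass of a shift-aggregate-extract network
#'
#' Unfolds the computation over the levels: the bottom representations are
#' extracted from the attribute matrix, and each higher level extracts from
#' the shift-aggregated representations of the level below. The top-level
#' rows are the per-top-object class scores.
#'
#' @param h an [HDecomposition-class].
#' @param model a [SaenModel-class] whose dimensions match `h`.
#' @param cache keep per-layer caches (used internally for backprop).
#' @return list with `scores` (top-level matrix), `H` (list of per-level
#'   representation matrices, index l+1 for level l) and `A` (the aggregate
#'   inputs, `A[[1]]` being the attribute matrix).
#' @export
saenForward <- function(h, model, cache = FALSE) {
  stopifnot(is(h, "HDecomposition"), is(model, "SaenModel"))
  .checkModelMatch(h, model)
  L <- nLevels(h)
  slope <- model@leakySlope
  H <- vector("list", L + 1L)
  A <- vector("list", L + 1L)
  caches <- vector("list", L + 1L)
  A[[1L]] <- h@attributes
  for (l in 0:L) {
    if (l > 0L) A[[l + 1L]] <- aggregateLevel(h, l, H[[l]])
    rawFinal <- (l == L) && !model@activateTop
    fw <- .mlpForward(A[[l + 1L]], model@params[[l + 1L]], slope, rawFinal)
    H[[l + 1L]] <- fw$H
    if (cache) caches[[l + 1L]] <- fw[c("inputs", "Z")]
  }
  out <- list(scores = H[[L + 1L]], H = H, A = A)
  if (cache) out$caches <- caches
  out
}

#' Explicit feature map of the hierarchy kernel
#'
#' The shift/aggregate recursion without the extraction step: attribute
#' vectors are shifted and summed up the hierarchy unchanged, giving the
#' explicit feature vector of the corresponding part-based kernel. The
#' width multiplies by n(l) at every level, i.e., the top width is
#' p * prod(n(l)) -- exponential in the depth, which is why the guard cap
#' exists and why the network replaces this map with learned extractions.
#'
#' @param h an [HDecomposition-class].
#' @param cap maximum allowed feature width.
#' @return dense matrix of per-top-object feature vectors.
#' @export
kernelFeatures <- function(h, cap = 1e7) {
  stopifnot(is(h, "HDecomposition"))
  A <- h@attributes
  for (l in seq_len(nLevels(h))) {
    width <- length(h@piAlphabets[[l]]) * ncol(A)
    if (width > cap)
      stop(sprintf("explicit feature width %g at level %d exceeds the cap %g",
                   width, l, cap))
    A <- aggregateLevel(h, l, A)
  }
  A
}

.softmax <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

.weightPenalty <- function(params) {
  s <- 0
  for (layers in params) for (ly in layers) s <- s + sum(ly$W^2)
  s
}

#' Loss and analytic gradients of the cross-entropy objective
#'
#' Mean cross-entropy of the softmax of the top-level scores against the
#' labels, plus `l2 * sum(W^2)` over all weight matrices. When a top-level
#' decompression matrix is supplied (training on a compressed hierarchy),
#' scores are first decompressed so that every original top object
#' contributes to the loss with its own label.
#'
#' @param h an [HDecomposition-class].
#' @param labels integer class labels 0..C-1, one per (decompressed) top
#'   object.
#' @param model a [SaenModel-class].
#' @param decompression optional top-level decompression matrix D_L.
#' @return list with `loss`, `grads` (nested like the model's `params`
#'   slot) and `scores`.
#' @export
saenGradients <- function(h, labels, model, decompression = NULL) {
  L <- nLevels(h)
  slope <- model@leakySlope
  fw <- saenForward(h, model, cache = TRUE)
  S <- fw$scores
  if (!is.null(decompression)) S <- as.matrix(decompression %*% S)
  N <- nrow(S)
  if (length(labels) != N) stop("need one label per top-level object")
  if (any(labels < 0L) || any(labels >= model@nClasses))
    stop("labels must lie in 0..C-1")
  P <- .softmax(S)
  ll <- log(P[cbind(seq_len(N), labels + 1L)])
  loss <- -mean(ll) + model@l2 * .weightPenalty(model@params)
  dS <- P
  dS[cbind(seq_len(N), labels + 1L)] <- dS[cbind(seq_len(N), labels + 1L)] - 1
  dS <- dS / N
  dH <- if (!is.null(decompression)) as.matrix(Matrix::crossprod(decompression, dS)) else dS
  grads <- vector("list", L + 1L)
  for (l in L:0) {
    rawFinal <- (l == L) && !model@activateTop
    bk <- .mlpBackward(dH, fw$caches[[l + 1L]], model@params[[l + 1L]],
                       slope, rawFinal)
    grads[[l + 1L]] <- bk$grads
    if (l > 0L) {
      dA <- bk$dA
      d <- ncol(fw$H[[l]])
      rel <- h@relations[[l]]
      dH <- matrix(0, h@levelSizes[l], d)
      for (k in seq_along(rel)) {
        block <- dA[, ((k - 1L) * d + 1L):(k * d), drop = FALSE]
        dH <- dH + as.matrix(Matrix::crossprod(rel[[k]], block))
      }
    }
  }
  if (model@l2 > 0) {
    for (l in seq_along(grads)) for (k in seq_along(grads[[l]]))
      grads[[l]][[k]]$W <- grads[[l]][[k]]$W + 2 * model@l2 * model@params[[l]][[k]]$W
  }
  list(loss = loss, grads = grads, scores = S)
}

#' Train a shift-aggregate-extract network
#'
#' Full-batch gradient descent with Adam moment estimates on the mean
#' cross-entropy plus L2 penalty. The whole (merged, possibly compressed)
#' hierarchy is one batch: after compression the structures are small, so
#' full-batch updates are cheap and keep the trajectory reproducible for a
#' fixed seed on one thread.
#'
#' @param h an [HDecomposition-class] holding all training top objects.
#' @param labels integer labels 0..C-1 per (decompressed) top object.
#' @param model initial [SaenModel-class].
#' @param epochs number of full-batch updates.
#' @param learningRate Adam step size (0 leaves the parameters untouched).
#' @param decompression optional top-level decompression matrix D_L when
#'   training on a compressed hierarchy.
#' @param beta1,beta2,epsilon Adam moment decay rates and stabilizer.
#' @param seed optional RNG seed (the routine itself is deterministic; the
#'   seed is applied for reproducibility of any caller-visible RNG state).
#' @return list with `model` (trained) and `loss` (per-epoch trace,
#'   evaluated before each update).
#' @export
saenTrain <- function(h, labels, model, epochs = 100L, learningRate = 1e-3,
                      decompression = NULL, beta1 = 0.9, beta2 = 0.999,
                      epsilon = 1e-8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- model@params
  m <- rapply(params, function(x) x * 0, how = "replace")
  v <- m
  trace <- numeric(epochs)
  t <- 0L
  for (epoch in seq_len(epochs)) {
    model@params <- params
    g <- saenGradients(h, labels, model, decompression)
    if (!is.finite(g$loss))
      stop(sprintf("non-finite loss at epoch %d", epoch))
    trace[epoch] <- g$loss
    t <- t + 1L
    for (l in seq_along(params)) for (k in seq_along(params[[l]])) {
      for (nm in c("W", "b")) {
        gr <- g$grads[[l]][[k]][[nm]]
        m[[l]][[k]][[nm]] <- beta1 * m[[l]][[k]][[nm]] + (1 - beta1) * gr
        v[[l]][[k]][[nm]] <- beta2 * v[[l]][[k]][[nm]] + (1 - beta2) * gr^2
        mhat <- m[[l]][[k]][[nm]] / (1 - beta1^t)
        vhat <- v[[l]][[k]][[nm]] / (1 - beta2^t)
        params[[l]][[k]][[nm]] <- params[[l]][[k]][[nm]] -
          learningRate * mhat / (sqrt(vhat) + epsilon)
      }
    }
  }
  model@params <- params
  list(model = model, loss = trace)
}

#' Predict class labels for the top objects of a hierarchy
#'
#' Argmax of the top-level class scores, with ties broken deterministically
#' toward the lower class index.
#'
#' @param h an [HDecomposition-class].
#' @param model a trained [SaenModel-class].
#' @param decompression optional top-level decompression matrix.
#' @return list with `labels` (integer 0..C-1) and `scores` (matrix).
#' @export
saenPredict <- function(h, model, decompression = NULL) {
  S <- saenForward(h, model)$scores
  if (!is.null(decompression)) S <- as.matrix(decompression %*% S)
  list(labels = apply(S, 1L, which.max) - 1L, scores = S)
}

#' Serialize a model checkpoint
#'
#' JSON container holding the dimension metadata and every layer's weights
#' and biases; [readSaenModel()] restores an identical model.
#'
#' @param model a [SaenModel-class].
#' @param path file to write / read.
#' @return `writeSaenModel` returns `path` invisibly; `readSaenModel`
#'   returns the restored [SaenModel-class].
#' @export
writeSaenModel <- function(model, path) {
  stopifnot(is(model, "SaenModel"))
  obj <- list(
    format = "saen-model", version = 1L,
    p = model@p, nTypes = model@nTypes, outDims = model@outDims,
    nClasses = model@nClasses, leakySlope = model@leakySlope,
    l2 = model@l2, activateTop = model@activateTop,
    params = lapply(model@params, function(layers)
      lapply(layers, function(ly) list(W = unname(ly$W), b = unname(ly$b)))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSaenModel
#' @export
readSaenModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "saen-model"))
    stop("malformed model checkpoint")
  if (!identical(as.integer(obj$version), 1L))
    stop("unsupported model checkpoint version")
  params <- lapply(obj$params, function(layers)
    lapply(layers, function(ly) list(
      W = do.call(rbind, lapply(ly$W, function(row) as.numeric(unlist(row)))),
      b = as.numeric(unlist(ly$b)))))
  obj[c("p", "nTypes", "outDims")] <-
    lapply(obj[c("p", "nTypes", "outDims")], unlist)
  new("SaenModel", params = params, p = as.integer(obj$p),
      nTypes = as.integer(obj$nTypes), outDims = as.integer(obj$outDims),
      nClasses = as.integer(obj$nClasses), leakySlope = obj$leakySlope,
      l2 = obj$l2, activateTop = isTRUE(obj$activateTop))
}
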