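#' Describe the two-layer group-equivariant architecture
#'
#' Defaults follow the reference architecture: two 3x3 group-convolution
#' layers of 6 base filters each (6 * 4 = 24 channels per layer under p4),
#' 2x1 pooling of the frequency axis after each, relu, batch norm, dropout
#' in the second block, and a 2-class dense head on the orientation- and
#' spatially pooled features.
#'
#' @param group `"p4"` or `"p4m"` (or a [GroupSpec-class]).
#' @param baseFilters base filters per conv layer.
#' @param kernelSize odd spatial kernel size.
#' @param dropout dropout rate of the second block.
#' @param nClasses number of classes.
#' @param inputShape input image height and width.
#' @return a [NetworkSpec-class].
#' @export
networkSpec <- function(group = "p4", baseFilters = c(6L, 6L),
                        kernelSize = 3L, dropout = 0.2, nClasses = 2L,
                        inputShape = c(93L, 67L)) {
  if (is.character(group)) group <- groupSpec(group)
  new("NetworkSpec", group = group,
      baseFilters = as.integer(baseFilters),
      kernelSize = as.integer(kernelSize),
      poolShapes = list(c(2L, 1L), c(2L, 1L)),
      dropout = dropout, nClasses = as.integer(nClasses),
      inputShape = as.integer(inputShape))
}

#' Build an initialized network
#'
#' Weights are He-initialized from a seeded generator; all pruning masks
#' start at 1 (nothing pruned); batch-norm scales start at 1, shifts at 0.
#'
#' @param spec a [NetworkSpec-class].
#' @param seed integer seed for weight initialization.
#' @param gamma,epsilon,hysteresis pruning hyperparameters forwarded to
#'   every [PrunedLayerState-class].
#' @return a [DpgenNetwork-class].
#' @export
buildNetwork <- function(spec, seed = 1L, gamma = 8, epsilon = 1e-4,
                         hysteresis = 0.1) {
  stopifnot(is(spec, "NetworkSpec"))
  g <- spec@group; nG <- g@order
  k <- spec@kernelSize
  f1 <- spec@baseFilters[1]; f2 <- spec@baseFilters[2]
  .withSeed(seed, {
    W1 <- array(stats::rnorm(f1 * 1 * k * k, sd = sqrt(2 / (k * k))),
                c(f1, 1L, k, k))
    W2 <- array(stats::rnorm(f2 * f1 * nG * k * k,
                             sd = sqrt(2 / (f1 * nG * k * k))),
                c(f2, f1, nG, k, k))
    nFeat <- f2 * .headRows(spec)
    Wd <- matrix(stats::rnorm(nFeat * spec@nClasses, sd = sqrt(2 / nFeat)),
                 nFeat, spec@nClasses)
  })
  mk <- function(W, d1) prunedLayerState(
    matrix(as.numeric(W), d1), gamma = gamma, epsilon = epsilon,
    hysteresis = hysteresis)
  lift <- mk(W1, f1); lift@origDims <- dim(W1)
  gconv <- mk(W2, f2); gconv@origDims <- dim(W2)
  dense <- prunedLayerState(Wd, gamma = gamma, epsilon = epsilon,
                            hysteresis = hysteresis)
  nCh <- function(fb) fb * nG
  bn <- function(n) list(gamma = rep(1, n), beta = rep(0, n),
                         runMean = rep(0, n), runVar = rep(1, n))
  new("DpgenNetwork", spec = spec,
      layers = list(lift = lift, gconv = gconv, dense = dense),
      denseBias = rep(0, spec@nClasses),
      bn1 = bn(nCh(f1)), bn2 = bn(nCh(f2)),
      report = .emptyReport(), seed = as.integer(seed))
}

# image height left after the two conv (valid) + 2x1 pool blocks; the
# dense head keeps this frequency/electrode axis and averages over time
.headRows <- function(spec) {
  h <- spec@inputShape[1]; k <- spec@kernelSize
  for (i in 1:2) h <- (h - (k - 1L)) %/% 2L
  if (h < 1L) stop("input too short for the architecture", call. = FALSE)
  h
}

.emptyReport <- function() {
  new("TrainReport", loss = numeric(0), trainAccuracy = numeric(0),
      valAccuracy = numeric(0), evalIterations = integer(0),
      pruningReport = data.frame(), compression = 1, iterations = 0L)
}

#' Count trainable parameters
#'
#' @param object a [DpgenNetwork-class].
#' @param prunableOnly if `TRUE`, count only weights subject to pruning
#'   (convolution and dense weight tensors; biases and batch-norm
#'   parameters are exempt).
#' @return integer parameter count.
#' @export
parameterCount <- function(object, prunableOnly = FALSE) {
  prunable <- sum(vapply(object@layers, function(s) length(s@W), numeric(1)))
  if (prunableOnly) return(as.integer(prunable))
  extra <- length(object@denseBias) +
    2L * length(object@bn1$gamma) + 2L * length(object@bn2$gamma)
  as.integer(prunable + extra)
}

#' @describeIn DpgenNetwork-class the three pruned-layer states.
#' @export
setMethod("pruningStates", "DpgenNetwork", function(object) object@layers)

#' @describeIn DpgenNetwork-class the stored training report.
#' @export
setMethod("trainReport", "DpgenNetwork", function(object) object@report)

#' @describeIn compressionRatio for a network: over its three weight
#'   tensors.
#' @export
setMethod("compressionRatio", "DpgenNetwork", function(object) {
  compressionRatio(object@layers)
})

# ---------------------------------------------------------------------------
# Fast batched forward/backward.
#
# Activation layout everywhere: array (h, w, batch, channel-slice), slices
# ordered orientation-fastest within base filter, matching the canonical
# groupElements() order. Convolutions are computed as sums of 9 shifted
# GEMMs against expanded weight matrices; the expansion from the base
# parameter tensor to the per-orientation matrix is a fixed index gather
# precomputed per group (see .liftExpansion / .gconvExpansion), so gradients
# fold back onto the base tensor by the inverse scatter.
# ---------------------------------------------------------------------------

# expansion for the lifting layer: base tensor (out, in, k, k) ->
# matrix (in * k^2) x (out * |G|); entry (c, a, b | o, gi) is the base entry
# (o, c, gridPermutation(g)[a, b]).
.liftExpansion <- function(group, nOut, nIn, k) {
  els <- groupElements(group); nG <- length(els)
  kk <- k * k
  idx <- array(0L, c(nIn * kk, nOut * nG))
  for (gi in seq_len(nG)) {
    perm <- .gridPermutation(els[[gi]], k)      # length k^2
    for (o in seq_len(nOut)) {
      col <- (o - 1L) * nG + gi
      for (c in seq_len(nIn)) {
        rows <- (c - 1L) * kk + seq_len(kk)
        idx[rows, col] <- o + nOut * (c - 1L) + nOut * nIn * (perm - 1L)
      }
    }
  }
  idx
}

# expansion for a group-conv layer: base tensor (out, in, |G|, k, k) ->
# matrix (in * |G| * k^2) x (out * |G|); input slices ordered orientation-
# fastest; entry (c, si, a, b | o, gi) is the base entry
# (o, c, index(inverse(g) * s), gridPermutation(g)[a, b]).
.gconvExpansion <- function(group, nOut, nIn, k) {
  els <- groupElements(group); nG <- length(els)
  kk <- k * k
  idx <- array(0L, c(nIn * nG * kk, nOut * nG))
  for (gi in seq_len(nG)) {
    g <- els[[gi]]; gInv <- groupInverse(group, g)
    perm <- .gridPermutation(g, k)
    kiOf <- vapply(els, function(s)
      elementIndex(group, groupCompose(group, gInv, s)), integer(1))
    for (o in seq_len(nOut)) {
      col <- (o - 1L) * nG + gi
      for (c in seq_len(nIn)) for (si in seq_len(nG)) {
        rows <- ((c - 1L) * nG + (si - 1L)) * kk + seq_len(kk)
        idx[rows, col] <- o + nOut * (c - 1L) + nOut * nIn * (kiOf[si] - 1L) +
          nOut * nIn * nG * (perm - 1L)
      }
    }
  }
  idx
}

# package-local cache for expansion index tables
.dpgenCache <- new.env(parent = emptyenv())

.getExpansion <- function(kind, group, nOut, nIn, k) {
  key <- paste(kind, group@name, nOut, nIn, k, sep = "_")
  if (is.null(.dpgenCache[[key]]))
    .dpgenCache[[key]] <- switch(kind,
      lift = .liftExpansion(group, nOut, nIn, k),
      gconv = .gconvExpansion(group, nOut, nIn, k))
  .dpgenCache[[key]]
}

# conv forward: X (h, w, B, Cin) with expanded weights Wx
# ((Cin * k^2) x Cout); patch rows ordered slice-major, (a, b)
# column-major within slice. Returns (oh, ow, B, Cout) plus, on request,
# the im2col patch matrix for reuse by the backward pass.
.convForward <- function(X, Wx, k, keepPatches = FALSE) {
  d <- dim(X)
  res <- .convForwardC(X, Wx, d[1], d[2], d[3], d[4], k, keepPatches)
  Y <- res$Y
  dim(Y) <- c(d[1] - k + 1L, d[2] - k + 1L, d[3], ncol(Wx))
  list(Y = Y, P = res$P, dIn = d)
}

# conv backward from the cached patch matrix: returns dWx and (optionally)
# dX in the input layout
.convBackward <- function(fwd, Wx, k, dY, needInputGrad = TRUE) {
  d <- fwd$dIn
  dYm <- dY; dim(dYm) <- c(prod(dim(dY)[1:3]), dim(dY)[4])
  res <- .convBackwardC(fwd$P, Wx, dYm, d[1], d[2], d[3], d[4], k,
                        needInputGrad)
  dX <- NULL
  if (needInputGrad) {
    dX <- res$dX
    dim(dX) <- d
  }
  list(dX = dX, dWx = res$dWx)
}

# fold an expanded-weight gradient back onto the base parameter vector;
# within each column the index set is injective, so a vectorized
# scatter-add per column is exact
.foldExpandedGrad <- function(dWx, idx, nBase) {
  out <- numeric(nBase)
  for (j in seq_len(ncol(idx))) {
    ji <- idx[, j]
    o <- out[ji] + dWx[, j]
    out[ji] <- o
  }
  out
}

# batch norm over layout (h, w, B, C): per-channel statistics of the
# first three axes (compiled kernel)
.bnForward <- function(X, bn, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(X); n <- prod(d[1:3]); C <- d[4]
  res <- .bnForwardC(X, n, C, bn$gamma, bn$beta, bn$runMean, bn$runVar,
                     training, momentum, eps)
  Y <- res$Y; dim(Y) <- d
  if (training) { bn$runMean <- res$runMean; bn$runVar <- res$runVar }
  list(Y = Y, bn = bn, xhat = res$xhat, iv = res$iv, training = training)
}

.bnBackward <- function(dY, cache, bn) {
  d <- dim(dY); n <- prod(d[1:3]); C <- d[4]
  res <- .bnBackwardC(dY, cache$xhat, n, C, bn$gamma, cache$iv,
                      cache$training)
  dX <- res$dX; dim(dX) <- d
  list(dX = dX, dGamma = res$dGamma, dBeta = res$dBeta)
}

.relu <- function(X) {
  res <- .reluForwardC(X)
  Y <- res$Y; dim(Y) <- dim(X)
  list(Y = Y, M = res$M)
}

# 2x1 max pool over the height axis (frequency); drops a trailing odd row
.poolForward <- function(X) {
  d <- dim(X)
  res <- .pool2x1ForwardC(X, d[1], prod(d[-1]))
  Y <- res$Y; dim(Y) <- c(d[1] %/% 2L, d[2], d[3], d[4])
  list(Y = Y, M = res$M, inH = d[1])
}

.poolBackward <- function(dY, cache) {
  d <- dim(dY)
  dX <- .pool2x1BackwardC(dY, cache$M, cache$inH, prod(d[-1]))
  dim(dX) <- c(cache$inH, d[2], d[3], d[4])
  dX
}

# orientation max pool: (h, w, B, nBase * nG) -> (h, w, B, nBase)
.gpoolForward <- function(X, nG) {
  d <- dim(X); nBase <- d[4] %/% nG
  n <- prod(d[1:3])
  Xm <- X; dim(Xm) <- c(n, nG, nBase)
  Y <- matrix(0, n, nBase)
  arg <- matrix(1L, n, nBase)
  for (c in seq_len(nBase)) {
    block <- Xm[, , c]
    am <- max.col(block, ties.method = "first")
    arg[, c] <- am
    Y[, c] <- block[cbind(seq_len(n), am)]
  }
  dim(Y) <- c(d[1], d[2], d[3], nBase)
  list(Y = Y, arg = arg, nG = nG, dIn = d)
}

.gpoolBackward <- function(dY, cache) {
  d <- cache$dIn; n <- prod(d[1:3]); nG <- cache$nG; nBase <- d[4] %/% nG
  dYm <- dY; dim(dYm) <- c(n, nBase)
  dXm <- array(0, c(n, nG, nBase))
  for (c in seq_len(nBase))
    dXm[cbind(seq_len(n), cache$arg[, c], c)] <- dYm[, c]
  dim(dXm) <- d
  dXm
}

.softmax <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Full forward pass. X: array (h, w, B) or (h, w, B, 1).
# Returns probabilities and, when keepCache, everything backward needs.
.forwardBatch <- function(net, X, training = FALSE, dropMask = NULL,
                          keepCache = FALSE) {
  spec <- net@spec; g <- spec@group; nG <- g@order; k <- spec@kernelSize
  if (length(dim(X)) == 3L) dim(X) <- c(dim(X), 1L)
  B <- dim(X)[3]
  f1 <- spec@baseFilters[1]; f2 <- spec@baseFilters[2]

  idx1 <- .getExpansion("lift", g, f1, 1L, k)
  idx2 <- .getExpansion("gconv", g, f2, f1, k)
  W1x <- matrix(maskedWeights(net@layers$lift)[idx1], nrow(idx1))
  W2x <- matrix(maskedWeights(net@layers$gconv)[idx2], nrow(idx2))
  Wd <- maskedWeights(net@layers$dense)

  c1 <- .convForward(X, W1x, k, keepPatches = keepCache)
  bn1 <- .bnForward(c1$Y, net@bn1, training)
  r1 <- .relu(bn1$Y)
  p1 <- .poolForward(r1$Y)

  c2 <- .convForward(p1$Y, W2x, k, keepPatches = keepCache)
  bn2 <- .bnForward(c2$Y, net@bn2, training)
  r2 <- .relu(bn2$Y)
  if (training && spec@dropout > 0) {
    if (is.null(dropMask))
      dropMask <- array(
        (stats::runif(length(r2$Y)) >= spec@dropout) / (1 - spec@dropout),
        dim(r2$Y))
    D2 <- r2$Y * dropMask
  } else D2 <- r2$Y
  p2 <- .poolForward(D2)

  gp <- .gpoolForward(p2$Y, nG)
  dgp <- dim(gp$Y)                              # (h, w, B, nBase)
  # average over time (width) only; keep the frequency/electrode axis
  Fp <- aperm(gp$Y, c(2L, 1L, 3L, 4L))
  dim(Fp) <- c(dgp[2], dgp[1] * dgp[3] * dgp[4])
  fm <- array(colMeans(Fp), c(dgp[1], dgp[3], dgp[4]))   # (h, B, nBase)
  feats <- aperm(fm, c(2L, 1L, 3L))
  dim(feats) <- c(B, dgp[1] * dgp[4])           # (B x h*nBase)
  logits <- feats %*% Wd + rep(net@denseBias, each = B)
  probs <- .softmax(logits)

  out <- list(probs = probs, logits = logits)
  if (keepCache)
    out$cache <- list(c1 = c1, c2 = c2, W1x = W1x, W2x = W2x,
                      idx1 = idx1, idx2 = idx2,
                      bn1cache = bn1, bn2cache = bn2, r1 = r1, r2 = r2,
                      dropMask = dropMask, p1 = p1, p2 = p2, gp = gp,
                      feats = feats, spatial = dgp[1:2])
  out$bn1new <- bn1$bn; out$bn2new <- bn2$bn
  out
}

# Backward pass from labels (integer 0-based). Returns gradients with
# respect to the *masked* weight tensors plus BN/bias gradients.
.backwardBatch <- function(net, fwd, labels) {
  spec <- net@spec; k <- spec@kernelSize
  cache <- fwd$cache
  B <- nrow(fwd$probs)
  onehot <- matrix(0, B, spec@nClasses)
  onehot[cbind(seq_len(B), labels + 1L)] <- 1
  dLogits <- (fwd$probs - onehot) / B

  Wd <- maskedWeights(net@layers$dense)
  dWd <- crossprod(cache$feats, dLogits)
  dBd <- colSums(dLogits)
  dFeats <- dLogits %*% t(Wd)                       # (B x h*nBase)

  # spread the time average: every time step receives dFeats / w
  dgp <- dim(cache$gp$Y)                            # (h, w, B, nBase)
  v <- array(dFeats, c(B, dgp[1], dgp[4]))
  v <- aperm(v, c(2L, 1L, 3L)) / dgp[2]             # (h, B, nBase)
  dGp <- array(v, c(dgp[1], 1L, dgp[3], dgp[4]))[, rep(1L, dgp[2]), , ,
                                                 drop = FALSE]

  dP2 <- .gpoolBackward(dGp, cache$gp)
  dD2 <- .poolBackward(dP2, cache$p2)
  dR2 <- if (!is.null(cache$dropMask)) dD2 * cache$dropMask else dD2
  dBn2 <- dR2 * cache$r2$M
  bb2 <- .bnBackward(dBn2, cache$bn2cache, net@bn2)
  cb2 <- .convBackward(cache$c2, cache$W2x, k, bb2$dX, TRUE)
  dW2 <- .foldExpandedGrad(cb2$dWx, cache$idx2,
                           length(net@layers$gconv@W))

  dR1 <- .poolBackward(cb2$dX, cache$p1)
  dBn1 <- dR1 * cache$r1$M
  bb1 <- .bnBackward(dBn1, cache$bn1cache, net@bn1)
  cb1 <- .convBackward(cache$c1, cache$W1x, k, bb1$dX, FALSE)
  dW1 <- .foldExpandedGrad(cb1$dWx, cache$idx1,
                           length(net@layers$lift@W))

  list(lift = matrix(dW1, nrow(net@layers$lift@W)),
       gconv = matrix(dW2, nrow(net@layers$gconv@W)),
       dense = dWd, denseBias = dBd,
       bn1 = list(dGamma = bb1$dGamma, dBeta = bb1$dBeta),
       bn2 = list(dGamma = bb2$dGamma, dBeta = bb2$dBeta))
}

#' Forward a batch of spectral images through the network
#'
#' Evaluation-mode forward pass (dropout off, batch-norm running statistics)
#' with the masked weights.
#'
#' @param net a [DpgenNetwork-class].
#' @param images numeric array `[h x w x n]`, a single `[h x w]` matrix, or
#'   a list of [SpectralInput-class] objects.
#' @return matrix `[n x nClasses]` of class probabilities (rows sum to 1).
#' @export
predictProbs <- function(net, images) {
  X <- .imagesToArray(images)
  .forwardBatch(net, X, training = FALSE)$probs
}

# coerce images argument to (h, w, n) array
.imagesToArray <- function(images) {
  if (is.list(images) && length(images) > 0 &&
      all(vapply(images, is, logical(1), "SpectralInput"))) {
    proto <- images[[1]]@image
    images <- vapply(images, function(s) s@image,
                     matrix(0, nrow(proto), ncol(proto)))
    if (length(dim(images)) == 2L)
      dim(images) <- c(dim(images), 1L)
  }
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L))
  stopifnot(length(dim(images)) == 3L)
  images
}
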