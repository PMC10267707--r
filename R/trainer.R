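#' Training configuration for the alternating weight/mask loop
#'
#' @param beta base learning rate (`> 0`).
#' @param batchSize mini-batch size.
#' @param maxIterations iterations to run (`>= 0`).
#' @param gamma,epsilon,hysteresis pruning hyperparameters forwarded to
#'   every layer state.
#' @param maskUpdateStride update masks every this many iterations.
#' @param maskWarmup iterations to train before the first mask update;
#'   magnitude statistics at random initialization carry no signal, so the
#'   prune/splice cycle starts once magnitudes have differentiated.
#' @param prune set `FALSE` for the unpruned baseline (masks stay all-one).
#' @param seed root seed for batch sampling, dropout and initialization.
#' @param learningPolicy `"constant"` or `"step-decay"` (halves `beta`
#'   twice, at 1/3 and 2/3 of `maxIterations`).
#' @param momentum SGD momentum (0 = plain SGD, the default).
#' @param evalEvery record train/validation accuracy every this many
#'   iterations (0 = only at the end).
#' @return list of class `TrainConfig`.
#' @export
trainConfig <- function(beta = 0.05, batchSize = 8L, maxIterations = 300L,
                        gamma = 8, epsilon = 1e-4, hysteresis = 0.1,
                        maskUpdateStride = 1L, maskWarmup = 50L,
                        prune = TRUE, seed = 1L,
                        learningPolicy = c("constant", "step-decay"),
                        momentum = 0, evalEvery = 0L) {
  learningPolicy <- match.arg(learningPolicy)
  stopifnot(beta > 0, batchSize >= 1, maxIterations >= 0)
  structure(list(beta = beta, batchSize = as.integer(batchSize),
                 maxIterations = as.integer(maxIterations), gamma = gamma,
                 epsilon = epsilon, hysteresis = hysteresis,
                 maskUpdateStride = as.integer(maskUpdateStride),
                 maskWarmup = as.integer(maskWarmup), prune = prune,
                 seed = as.integer(seed), learningPolicy = learningPolicy,
                 momentum = momentum, evalEvery = as.integer(evalEvery)),
            class = "TrainConfig")
}

.crossEntropy <- function(probs, labels) {
  p <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
  -mean(log(pmax(p, 1e-12)))
}

#' Train a network with dynamic pruning and splicing
#'
#' The alternating optimization: every iteration a seeded mini-batch is
#' forwarded with the masked weights `W * T`, the cross-entropy loss is
#' backpropagated to the masked-weight gradients, each layer's mask is
#' refreshed from the current full-weight magnitude statistics (after the
#' warm-up, at the configured stride), and the weights -- masked entries
#' included -- are updated through the surrogate-gradient factors, so that
#' a pruned connection whose magnitude regrows is spliced back in. Masks
#' start at 1 everywhere. Training aborts (returning the last good state)
#' if the loss turns non-finite.
#'
#' @param net a [DpgenNetwork-class] (see [buildNetwork()]); its pruning
#'   hyperparameters are overwritten from `config`.
#' @param images training inputs: array `[h x w x n]` or list of
#'   [SpectralInput-class].
#' @param labels integer labels in `0..nClasses-1`.
#' @param config a [trainConfig()].
#' @param valImages,valLabels optional held-out set for the accuracy
#'   trajectory and the final report.
#' @return the trained network, with its [TrainReport-class] in
#'   `trainReport(net)`.
#' @export
trainNetwork <- function(net, images, labels, config = trainConfig(),
                         valImages = NULL, valLabels = NULL) {
  X <- .imagesToArray(images)
  labels <- as.integer(labels)
  n <- dim(X)[3]
  if (n == 0L) stop("empty training data", call. = FALSE)
  stopifnot(length(labels) == n,
            all(labels >= 0L & labels < net@spec@nClasses))
  hasVal <- !is.null(valImages)
  if (hasVal) valX <- .imagesToArray(valImages)

  for (nm in names(net@layers)) {
    net@layers[[nm]]@gamma <- config$gamma
    net@layers[[nm]]@epsilon <- config$epsilon
    net@layers[[nm]]@hysteresis <- config$hysteresis
  }

  loss <- numeric(config$maxIterations)
  evalIter <- integer(0); trainAcc <- numeric(0); valAcc <- numeric(0)
  vel <- NULL
  aborted <- FALSE

  .withSeed(.childSeed(config$seed, 7L), {
    iter <- 0L
    while (iter < config$maxIterations) {
      iter <- iter + 1L
      beta <- config$beta
      if (config$learningPolicy == "step-decay") {
        third <- max(1L, config$maxIterations %/% 3L)
        beta <- beta * 0.5^((iter - 1L) %/% third)
      }
      idx <- sample.int(n, min(config$batchSize, n))
      Xb <- X[, , idx, drop = FALSE]
      dim(Xb) <- c(dim(Xb), 1L)
      fwd <- .forwardBatch(net, Xb, training = TRUE, keepCache = TRUE)
      li <- .crossEntropy(fwd$probs, labels[idx])
      if (!is.finite(li)) { aborted <- TRUE; iter <- iter - 1L; break }
      loss[iter] <- li
      net@bn1 <- fwd$bn1new; net@bn2 <- fwd$bn2new
      grads <- .backwardBatch(net, fwd, labels[idx])

      # Mask update with the current weights (before the weight step)
      pruningActive <- config$prune && iter > config$maskWarmup
      if (pruningActive &&
          (iter - config$maskWarmup - 1L) %% config$maskUpdateStride == 0L) {
        for (nm in names(net@layers)) {
          st <- updateStats(net@layers[[nm]])
          st@mask <- updateMask(st)
          net@layers[[nm]] <- st
        }
      }

      # Weight update; the surrogate-gradient factors belong to the masked
      # objective, so they apply only while pruning is active -- the
      # unpruned baseline and the warm-up take plain SGD steps
      for (nm in names(net@layers)) {
        g <- grads[[nm]]
        if (config$momentum > 0) {
          if (is.null(vel)) vel <- list()
          v <- if (is.null(vel[[nm]])) g * 0 else vel[[nm]]
          v <- config$momentum * v + g
          vel[[nm]] <- v
          g <- v
        }
        if (pruningActive) {
          net@layers[[nm]] <- sgdStep(net@layers[[nm]], g, beta)
        } else {
          if (!all(is.finite(g)))
            stop("non-finite gradient", call. = FALSE)
          net@layers[[nm]]@W <- net@layers[[nm]]@W - beta * g
        }
      }
      net@denseBias <- net@denseBias - beta * grads$denseBias
      net@bn1$gamma <- net@bn1$gamma - beta * grads$bn1$dGamma
      net@bn1$beta <- net@bn1$beta - beta * grads$bn1$dBeta
      net@bn2$gamma <- net@bn2$gamma - beta * grads$bn2$dGamma
      net@bn2$beta <- net@bn2$beta - beta * grads$bn2$dBeta

      if (config$evalEvery > 0L && iter %% config$evalEvery == 0L) {
        evalIter <- c(evalIter, iter)
        trainAcc <- c(trainAcc,
                      evaluateNetwork(net, X, labels)$accuracy)
        valAcc <- c(valAcc, if (hasVal)
          evaluateNetwork(net, valX, valLabels)$accuracy else NA_real_)
      }
    }
    loss <- loss[seq_len(iter)]
  })

  rep <- pruningReport(net@layers)
  net@report <- new("TrainReport",
    loss = loss, trainAccuracy = trainAcc, valAccuracy = valAcc,
    evalIterations = evalIter, pruningReport = rep,
    compression = attr(rep, "compression"),
    iterations = length(loss))
  if (aborted)
    warning("training aborted on non-finite loss; returning last good state",
            call. = FALSE)
  net
}

#' Evaluate a network on labelled data
#'
#' Deterministic given weights and data: dropout disabled and batch-norm
#' running statistics frozen.
#'
#' @param net a [DpgenNetwork-class].
#' @param images array `[h x w x n]` or list of [SpectralInput-class].
#' @param labels optional integer labels.
#' @return list with `probabilities` (`n x nClasses`, rows sum to 1),
#'   `predictions`, and `accuracy` (`NA` without labels).
#' @export
evaluateNetwork <- function(net, images, labels = NULL) {
  X <- .imagesToArray(images)
  n <- dim(X)[3]
  probs <- matrix(0, n, net@spec@nClasses)
  step <- 32L
  for (s in seq(1L, n, by = step)) {
    e <- min(n, s + step - 1L)
    Xb <- X[, , s:e, drop = FALSE]
    dim(Xb) <- c(dim(Xb), 1L)
    probs[s:e, ] <- .forwardBatch(net, Xb, training = FALSE)$probs
  }
  pred <- max.col(probs, ties.method = "first") - 1L
  acc <- if (is.null(labels)) NA_real_ else mean(pred == as.integer(labels))
  list(probabilities = probs, predictions = pred, accuracy = acc)
}

#' Split data into training and validation parts
#'
#' Seeded random split at the given ratio (default 4:1).
#'
#' @param n number of items.
#' @param valFraction held-out fraction.
#' @param seed split seed.
#' @return list with integer index vectors `train` and `val`.
#' @export
trainValSplit <- function(n, valFraction = 0.2, seed = 1L) {
  nVal <- max(1L, round(n * valFraction))
  val <- .withSeed(.childSeed(seed, 11L), sort(sample.int(n, nVal)))
  list(train = setdiff(seq_len(n), val), val = val)
}

#' Sweep the pruning threshold multiple gamma
#'
#' Trains the unpruned baseline once, then one dynamically pruned network
#' per gamma, all from identical initialization, data split and batch
#' schedule. The selected model is the one achieving the largest
#' compression among those whose validation accuracy is within
#' `tolerance` of the unpruned baseline.
#'
#' @param images array `[h x w x n]` or list of [SpectralInput-class].
#' @param labels integer labels.
#' @param gammas gamma grid to sweep.
#' @param config a [trainConfig()]; its `gamma` is overridden per run.
#' @param spec a [NetworkSpec-class].
#' @param valFraction held-out fraction (default 4:1 split).
#' @param tolerance allowed validation-accuracy drop (absolute, default
#'   0.02 = two percentage points).
#' @return data.frame with one row per gamma (columns gamma, valAccuracy,
#'   compression, withinTolerance) plus attributes `baselineAccuracy`,
#'   `selected` (row index or NA) and `selectedCompression`.
#' @export
sweepGamma <- function(images, labels, gammas = c(2, 4, 6, 8, 10),
                       config = trainConfig(), spec = networkSpec(),
                       valFraction = 0.2, tolerance = 0.02) {
  X <- .imagesToArray(images)
  labels <- as.integer(labels)
  sp <- trainValSplit(dim(X)[3], valFraction, config$seed)
  Xtr <- X[, , sp$train, drop = FALSE]; ytr <- labels[sp$train]
  Xva <- X[, , sp$val, drop = FALSE]; yva <- labels[sp$val]

  base <- buildNetwork(spec, seed = .childSeed(config$seed, 3L))
  cfg0 <- config; cfg0$prune <- FALSE
  baseNet <- trainNetwork(base, Xtr, ytr, cfg0)
  baseAcc <- evaluateNetwork(baseNet, Xva, yva)$accuracy

  rows <- lapply(gammas, function(gm) {
    cfg <- config; cfg$gamma <- gm; cfg$prune <- TRUE
    net <- buildNetwork(spec, seed = .childSeed(config$seed, 3L),
                        gamma = gm, epsilon = config$epsilon,
                        hysteresis = config$hysteresis)
    net <- trainNetwork(net, Xtr, ytr, cfg)
    data.frame(gamma = gm,
               valAccuracy = evaluateNetwork(net, Xva, yva)$accuracy,
               compression = trainReport(net)@compression)
  })
  out <- do.call(rbind, rows)
  out$withinTolerance <- out$valAccuracy >= baseAcc - tolerance
  ok <- which(out$withinTolerance)
  sel <- if (length(ok) > 0) ok[which.max(out$compression[ok])] else NA_integer_
  attr(out, "baselineAccuracy") <- baseAcc
  attr(out, "selected") <- sel
  attr(out, "selectedCompression") <- if (is.na(sel)) NA_real_
    else out$compression[sel]
  out
}
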