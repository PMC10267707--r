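#' Magnitude statistics of a weight matrix
#'
#' Mean and sample standard deviation (denominator `m*n - 1`) of the
#' absolute values of the entries. These statistics set the per-layer
#' pruning threshold `t = mu + gamma * sigma`.
#'
#' @param W non-empty numeric matrix (or array, flattened).
#' @return list with elements `mu` and `sigma` (`sigma = 0` for a
#'   single-entry matrix).
#' @export
layerStats <- function(W) {
  w <- abs(as.numeric(W))
  if (length(w) == 0L) stop("empty weight matrix", call. = FALSE)
  mu <- mean(w)
  sigma <- if (length(w) > 1L) sqrt(sum((w - mu)^2) / (length(w) - 1L)) else 0
  list(mu = mu, sigma = sigma)
}

#' Create the pruning state for one weight tensor
#'
#' @param W numeric matrix or array of weights.
#' @param gamma threshold multiple (default 8): a weight is important when
#'   `|W| - mu` exceeds `gamma * sigma`.
#' @param epsilon stability floor in (0, 1) (default 1e-4).
#' @param hysteresis half-width of the dead zone around the threshold as a
#'   fraction of it (default 0.1); inside the band the previous mask state
#'   is kept, which damps prune/splice oscillation.
#' @param mask optional initial binary mask (default all ones: no weight
#'   pruned, the state every training run starts from).
#' @return a [PrunedLayerState-class] with up-to-date statistics.
#' @export
prunedLayerState <- function(W, gamma = 8, epsilon = 1e-4,
                             hysteresis = 0.1, mask = NULL) {
  origDims <- if (is.null(dim(W))) c(1L, length(W)) else as.integer(dim(W))
  Wm <- if (is.matrix(W)) W else matrix(as.numeric(W), nrow = 1L)
  if (is.null(mask)) mask <- matrix(1, nrow(Wm), ncol(Wm))
  st <- layerStats(Wm)
  new("PrunedLayerState", W = Wm, mask = mask, mu = st$mu, sigma = st$sigma,
      gamma = gamma, epsilon = epsilon,
      threshold = st$mu + gamma * st$sigma,
      hysteresis = hysteresis, origDims = origDims)
}

#' Refresh the magnitude statistics of a pruning state
#'
#' Recomputes `mu`, `sigma` and the threshold from the current full `W`
#' (masked entries included, so a regrown weight can be spliced back).
#'
#' @param state a [PrunedLayerState-class].
#' @return the state with updated `mu`, `sigma`, `threshold`.
#' @export
updateStats <- function(state) {
  st <- layerStats(state@W)
  state@mu <- st$mu
  state@sigma <- st$sigma
  state@threshold <- st$mu + state@gamma * st$sigma
  state
}

#' @describeIn PrunedLayerState-class log importance
#'   `d[i,j] = log(max(epsilon, |W[i,j]| - mu) / (gamma * sigma))`;
#'   non-negative exactly when the weight magnitude clears the threshold.
#'   When `sigma = 0` every weight is treated as important (`+Inf`).
#' @export
setMethod("importanceScores", "PrunedLayerState", function(object) {
  if (object@sigma == 0)
    return(matrix(Inf, nrow(object@W), ncol(object@W)))
  log(pmax(abs(object@W) - object@mu, object@epsilon) /
        (object@gamma * object@sigma))
})

#' Prune/splice mask update
#'
#' With the base threshold `t = mu + gamma * sigma` on `|W|`, an entry is
#' pruned (mask 0) below `(1 - hysteresis) * t`, retained or restored
#' (mask 1) at or above `(1 + hysteresis) * t`, and keeps its previous mask
#' inside the band. A pruned weight whose magnitude regrows past the upper
#' edge is therefore always restored (splicing), regardless of its history.
#'
#' @param state a [PrunedLayerState-class] with current statistics
#'   (see [updateStats()]).
#' @return the updated binary mask matrix.
#' @export
updateMask <- function(state) {
  t <- state@threshold
  aw <- abs(state@W)
  Tm <- state@mask
  Tm[aw < (1 - state@hysteresis) * t] <- 0
  Tm[aw >= (1 + state@hysteresis) * t] <- 1
  Tm
}

#' @describeIn PrunedLayerState-class the masked weights `W * mask`.
#' @export
setMethod("maskedWeights", "PrunedLayerState", function(object) {
  object@W * object@mask
})

#' Surrogate-gradient factor of the pruning operator
#'
#' The per-entry multiplier applied to the loss gradient with respect to the
#' masked weight to obtain the gradient with respect to the raw weight.
#' With `t` the current threshold and `epsilon` the stability floor:
#' `log(epsilon)` where `|W| <= epsilon * t`; `log(|W| / t) + 1` in the
#' pruned region `epsilon * t < |W| <= t`; and 1 in the retained region
#' `|W| > t`. The factor is continuous at `|W| = t`. Masked weights thus
#' keep receiving (attenuated, possibly sign-flipped) updates, which is
#' what makes later splicing possible. With `t = 0` (no pruning active) the
#' factor is 1 everywhere.
#'
#' @param state a [PrunedLayerState-class].
#' @return numeric matrix of multipliers, same shape as `W`.
#' @seealso [pruningSurrogate()] for the soft reparameterization whose
#'   derivative this factor is.
#' @export
gradFactor <- function(state) {
  t <- state@threshold
  f <- matrix(1, nrow(state@W), ncol(state@W))
  if (t <= 0) return(f)
  aw <- abs(state@W)
  eps <- state@epsilon
  mid <- aw > eps * t & aw <= t
  f[mid] <- log(aw[mid] / t) + 1
  f[aw <= eps * t] <- log(eps)
  f
}

#' Soft surrogate reparameterization of a pruned weight
#'
#' The declared piecewise map whose derivative is [gradFactor()]:
#' `log(epsilon) * W` where `|W| <= epsilon * t`; `W * log(|W| / t)` in the
#' pruned region; `W` itself where retained. Used by the finite-difference
#' checks of the gradient chain.
#'
#' @param state a [PrunedLayerState-class] (supplies `t` and `epsilon`).
#' @param W weights to map (default the state's own).
#' @return numeric matrix of surrogate weights.
#' @export
pruningSurrogate <- function(state, W = state@W) {
  t <- state@threshold
  if (t <= 0) return(W)
  aw <- abs(W)
  eps <- state@epsilon
  out <- W
  mid <- aw > eps * t & aw <= t
  out[mid] <- W[mid] * log(aw[mid] / t)
  low <- aw <= eps * t
  out[low] <- log(eps) * W[low]
  out
}

#' Masked stochastic gradient step
#'
#' `W <- W - beta * gradFactor(state) * grad`, where `grad` is the loss
#' gradient with respect to the masked weights. Pruned (mask 0) weights are
#' updated too, which enables later splicing.
#'
#' @param state a [PrunedLayerState-class].
#' @param grad gradient matrix with respect to `maskedWeights(state)`.
#' @param beta learning rate, `> 0` (0 leaves weights unchanged).
#' @return the state with updated `W` (statistics not yet refreshed).
#' @export
sgdStep <- function(state, grad, beta) {
  if (!all(is.finite(grad)))
    stop("non-finite gradient in sgdStep", call. = FALSE)
  state@W <- state@W - beta * gradFactor(state) * grad
  state
}

#' @describeIn compressionRatio for a single layer state.
#' @export
setMethod("compressionRatio", "PrunedLayerState", function(object) {
  compressionRatio(list(object))
})

#' @describeIn compressionRatio for a list of layer states.
#' @export
setMethod("compressionRatio", "list", function(object) {
  total <- sum(vapply(object, function(s) length(s@W), numeric(1)))
  kept <- sum(vapply(object, function(s) sum(s@mask), numeric(1)))
  if (kept == 0) stop("no weights retained: compression undefined",
                      call. = FALSE)
  total / kept
})

#' Per-layer retention summary
#'
#' @param states named list of [PrunedLayerState-class] objects.
#' @return data.frame with columns layer, total, retained, plus attributes
#'   `total`, `retained` and `compression`.
#' @export
pruningReport <- function(states) {
  df <- data.frame(
    layer = if (is.null(names(states))) as.character(seq_along(states))
            else names(states),
    total = vapply(states, function(s) length(s@W), numeric(1)),
    retained = vapply(states, function(s) sum(s@mask), numeric(1)),
    row.names = NULL)
  attr(df, "total") <- sum(df$total)
  attr(df, "retained") <- sum(df$retained)
  attr(df, "compression") <- if (sum(df$retained) > 0)
    sum(df$total) / sum(df$retained) else Inf
  df
}
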