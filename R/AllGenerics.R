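#' @describeIn PrunedLayerState-class element-wise product `W * mask`, the
#'   weights the masked forward pass actually uses.
#' @param object a `PrunedLayerState`.
#' @export
setGeneric("maskedWeights", function(object) standardGeneric("maskedWeights"))

#' @describeIn PrunedLayerState-class log importance score of every weight.
#' @export
setGeneric("importanceScores",
           function(object) standardGeneric("importanceScores"))

#' Compression factor of one or more pruned layers
#'
#' Total number of prunable weights divided by the number of weights whose
#' mask is 1.
#'
#' @param object a `PrunedLayerState`, a list of them, or a `DpgenNetwork`.
#' @return a single number `>= 1` whenever any weight is retained.
#' @export
setGeneric("compressionRatio",
           function(object) standardGeneric("compressionRatio"))

#' @describeIn DpgenNetwork-class the network's pruned-layer states.
#' @param object a `DpgenNetwork`.
#' @export
setGeneric("pruningStates", function(object) standardGeneric("pruningStates"))

#' @describeIn DpgenNetwork-class the training report stored on the network.
#' @export
setGeneric("trainReport", function(object) standardGeneric("trainReport"))

setMethod("show", "GroupSpec", function(object) {
  cat(sprintf("GroupSpec: %s (order %d)\n", object@name, object@order))
})

setMethod("show", "GroupElement", function(object) {
  cat(sprintf("GroupElement: r=%d m=%d\n", object@r, object@m))
})

setMethod("show", "TrialEpoch", function(object) {
  cat(sprintf("TrialEpoch: %d channels (%s) x %d samples @ %g Hz, label %d\n",
              nrow(object@data), paste(object@channels, collapse = ","),
              ncol(object@data), object@fs, object@label))
})

setMethod("show", "SpectralInput", function(object) {
  cat(sprintf(
    "SpectralInput: %d x %d image (%d electrodes x %d rows), label %d\n",
    object@nH, object@nT, object@nC, object@nFr, object@label))
})

setMethod("show", "PrunedLayerState", function(object) {
  cat(sprintf(
    "PrunedLayerState: %d weights, %d retained (gamma=%g, t=%.4g)\n",
    length(object@W), sum(object@mask), object@gamma, object@threshold))
})

setMethod("show", "DpgenNetwork", function(object) {
  s <- object@spec
  cat(sprintf(
    "DpgenNetwork: %s group, %d+%d base filters (%d channels/layer), input %dx%d\n",
    s@group@name, s@baseFilters[1], s@baseFilters[2],
    s@baseFilters[1] * s@group@order, s@inputShape[1], s@inputShape[2]))
  if (object@report@iterations > 0)
    cat(sprintf("  trained %d iterations, compression %.2fx\n",
                object@report@iterations, object@report@compression))
})

setMethod("show", "TrainReport", function(object) {
  cat(sprintf("TrainReport: %d iterations, final loss %.4f, compression %.2fx\n",
              object@iterations,
              if (object@iterations > 0) tail(object@loss, 1) else NA_real_,
              object@compression))
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d vertices, AUC = %.4f\n",
              length(object@fpr), object@auc))
})
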