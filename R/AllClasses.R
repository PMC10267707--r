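#' @import methods
NULL

#' Finite symmetry group of the square
#'
#' `GroupSpec` identifies one of the two finite groups used throughout the
#' package: `p4`, the four planar rotations by multiples of 90 degrees
#' (cyclic, order 4), or `p4m`, rotations plus horizontal mirroring
#' (dihedral, order 8).
#'
#' @slot name either `"p4"` or `"p4m"`.
#' @slot order group order: 4 for p4, 8 for p4m.
#'
#' @seealso [groupSpec()], [groupElements()], [groupCompose()]
#' @exportClass GroupSpec
setClass("GroupSpec",
  representation(name = "character", order = "integer"),
  validity = function(object) {
    if (!(object@name %in% c("p4", "p4m")))
      return("name must be 'p4' or 'p4m'")
    want <- if (object@name == "p4") 4L else 8L
    if (!identical(object@order, want))
      return(sprintf("order must be %d for group %s", want, object@name))
    TRUE
  })

#' Element of a square-symmetry group
#'
#' An element is the pair (r, m): flip horizontally `m` times, then rotate
#' counter-clockwise by `r` quarter turns. `m` is always 0 for p4 elements.
#'
#' @slot r integer in 0..3, number of 90-degree counter-clockwise rotations.
#' @slot m integer 0 or 1, horizontal-mirror flag.
#'
#' @seealso [groupElement()], [actOnGrid()]
#' @exportClass GroupElement
setClass("GroupElement",
  representation(r = "integer", m = "integer"),
  validity = function(object) {
    if (!(object@r %in% 0:3)) return("r must be in 0..3")
    if (!(object@m %in% 0:1)) return("m must be 0 or 1")
    TRUE
  })

#' One epoched EEG trial
#'
#' A single motor-imagery trial: a channels-by-samples matrix with its
#' montage labels, sampling rate and class label (0 = left, 1 = right).
#'
#' @slot channels character vector of electrode labels (e.g. C3, CZ, C4).
#' @slot fs sampling rate in Hz.
#' @slot data numeric matrix `[channels x samples]`.
#' @slot label integer class label, 0 (left) or 1 (right).
#'
#' @seealso [trialEpoch()], [generateTrial()], [assembleInput()]
#' @exportClass TrialEpoch
setClass("TrialEpoch",
  representation(channels = "character", fs = "numeric",
                 data = "matrix", label = "integer"),
  validity = function(object) {
    if (nrow(object@data) != length(object@channels))
      return("data must have one row per channel")
    if (!all(is.finite(object@data))) return("data must be finite")
    if (object@fs <= 0) return("fs must be positive")
    if (!(object@label %in% c(0L, 1L))) return("label must be 0 or 1")
    TRUE
  })

#' Stacked mu/beta time-frequency image
#'
#' The network input built from one trial: per electrode a 16-row mu-band
#' image stacked over a 15-row beta-band image (31 rows), electrodes stacked
#' in scalp order, giving (with the default C3/CZ/C4 montage) a 93 x 67
#' image. `rowMap` records, for every image row, the electrode, band and
#' center frequency it represents.
#'
#' @slot image numeric matrix `[nH x nT]`.
#' @slot rowMap data.frame with columns electrode, band, freq (Hz).
#' @slot nC number of electrodes.
#' @slot nFr rows per electrode.
#' @slot nT number of STFT frames.
#' @slot nH total rows, `nC * nFr`.
#' @slot label integer class label carried from the trial.
#'
#' @seealso [assembleInput()]
#' @exportClass SpectralInput
setClass("SpectralInput",
  representation(image = "matrix", rowMap = "data.frame",
                 nC = "integer", nFr = "integer", nT = "integer",
                 nH = "integer", label = "integer"),
  validity = function(object) {
    if (object@nH != object@nC * object@nFr)
      return("nH must equal nC * nFr")
    if (nrow(object@image) != object@nH || ncol(object@image) != object@nT)
      return("image dimensions must match nH x nT")
    if (nrow(object@rowMap) != object@nH)
      return("rowMap must have one row per image row")
    TRUE
  })

#' State of one dynamically pruned weight tensor
#'
#' Holds a layer's full weight matrix `W`, its binary mask `T` (1 = the
#' connection is active), the statistics of `|W|` (mean `mu`, sample
#' standard deviation `sigma`), the pruning hyperparameters `gamma`
#' (threshold multiple) and `epsilon` (stability floor), the derived
#' threshold `t = mu + gamma * sigma`, and the hysteresis band that
#' stabilizes the prune/splice cycle.
#'
#' @slot W numeric matrix of weights (a flattened view of the tensor;
#'   `origDims` remembers the tensor shape).
#' @slot mask binary matrix, same shape as `W`.
#' @slot mu mean of `abs(W)`.
#' @slot sigma sample standard deviation of `abs(W)` (denominator m*n - 1).
#' @slot gamma threshold multiple (default 8).
#' @slot epsilon stability floor in (0, 1) (default 1e-4).
#' @slot threshold derived pruning threshold `mu + gamma * sigma`.
#' @slot hysteresis half-width of the dead zone around the threshold,
#'   as a fraction of it (default 0.1).
#' @slot origDims integer vector, the shape of the underlying tensor.
#'
#' @seealso [prunedLayerState()], [updateMask()], [gradFactor()]
#' @exportClass PrunedLayerState
setClass("PrunedLayerState",
  representation(W = "matrix", mask = "matrix", mu = "numeric",
                 sigma = "numeric", gamma = "numeric", epsilon = "numeric",
                 threshold = "numeric", hysteresis = "numeric",
                 origDims = "integer"),
  validity = function(object) {
    if (!identical(dim(object@W), dim(object@mask)))
      return("W and mask must have identical shapes")
    if (!all(object@mask %in% c(0, 1))) return("mask entries must be 0 or 1")
    if (object@gamma <= 0) return("gamma must be positive")
    if (object@epsilon <= 0 || object@epsilon >= 1)
      return("epsilon must lie in (0, 1)")
    if (object@mu < 0 || object@sigma < 0) return("mu, sigma must be >= 0")
    if (object@threshold < 0) return("threshold must be >= 0")
    TRUE
  })

#' Architecture of the two-layer group-equivariant network
#'
#' @slot group a [GroupSpec-class] (p4 by default).
#' @slot baseFilters integer vector, base filters per conv layer
#'   (default `c(6, 6)`; with p4 each layer exposes 6 * 4 = 24 channels).
#' @slot kernelSize odd kernel size (default 3).
#' @slot poolShapes list of pooling shapes (default two `c(2, 1)` pools,
#'   halving the frequency axis only).
#' @slot dropout dropout rate applied in the second block.
#' @slot nClasses number of output classes (default 2).
#' @slot inputShape height and width of the input image (default 93 x 67).
#'
#' @seealso [networkSpec()], [buildNetwork()]
#' @exportClass NetworkSpec
setClass("NetworkSpec",
  representation(group = "GroupSpec", baseFilters = "integer",
                 kernelSize = "integer", poolShapes = "list",
                 dropout = "numeric", nClasses = "integer",
                 inputShape = "integer"),
  validity = function(object) {
    if (length(object@baseFilters) != 2 || any(object@baseFilters < 1))
      return("baseFilters must be two positive integers")
    if (object@kernelSize %% 2 != 1) return("kernelSize must be odd")
    if (object@dropout < 0 || object@dropout >= 1)
      return("dropout must be in [0, 1)")
    if (object@nClasses < 2) return("nClasses must be >= 2")
    if (length(object@inputShape) != 2) return("inputShape must be (h, w)")
    TRUE
  })

#' Training trace and compression summary
#'
#' @slot loss numeric, cross-entropy loss per iteration.
#' @slot trainAccuracy numeric, training accuracy at the evaluation points.
#' @slot valAccuracy numeric, validation accuracy at the evaluation points.
#' @slot evalIterations integers at which accuracies were measured.
#' @slot pruningReport data.frame: per-layer total and retained weights.
#' @slot compression overall compression factor (total / retained).
#' @slot iterations iterations executed.
#'
#' @exportClass TrainReport
setClass("TrainReport",
  representation(loss = "numeric", trainAccuracy = "numeric",
                 valAccuracy = "numeric", evalIterations = "integer",
                 pruningReport = "data.frame", compression = "numeric",
                 iterations = "integer"),
  validity = function(object) {
    if (length(object@loss) != object@iterations)
      return("loss trace length must equal iterations executed")
    TRUE
  })

#' A trained (or untrained) dynamic-pruning group-equivariant network
#'
#' Layer stack: lifting convolution (3x3) -> batch norm -> relu ->
#' 2x1 max pool -> group convolution (3x3) -> batch norm -> relu ->
#' dropout -> 2x1 max pool -> orientation max pool -> spatial mean pool ->
#' dense -> softmax. The lifting, group-conv and dense weight tensors are
#' each registered with a [PrunedLayerState-class]; biases and batch-norm
#' parameters are exempt from pruning.
#'
#' @slot spec the [NetworkSpec-class].
#' @slot layers named list of [PrunedLayerState-class] objects
#'   (`lift`, `gconv`, `dense`).
#' @slot denseBias numeric bias of the dense head.
#' @slot bn1,bn2 batch-norm parameter lists (gamma, beta, runMean, runVar).
#' @slot report a [TrainReport-class] (empty until trained).
#' @slot seed integer seed the weights were initialized from.
#'
#' @seealso [buildNetwork()], [trainNetwork()], [evaluateNetwork()]
#' @exportClass DpgenNetwork
setClass("DpgenNetwork",
  representation(spec = "NetworkSpec", layers = "list",
                 denseBias = "numeric", bn1 = "list", bn2 = "list",
                 report = "TrainReport", seed = "integer"),
  validity = function(object) {
    need <- c("lift", "gconv", "dense")
    if (!all(need %in% names(object@layers)))
      return("layers must contain 'lift', 'gconv' and 'dense'")
    ok <- vapply(object@layers[need], is, logical(1), "PrunedLayerState")
    if (!all(ok)) return("layer entries must be PrunedLayerState objects")
    TRUE
  })

#' Receiver operating characteristic curve
#'
#' @slot thresholds score thresholds (decreasing), one per curve vertex.
#' @slot fpr false-positive rates, non-decreasing.
#' @slot tpr true-positive rates, non-decreasing.
#' @slot auc area under the curve (trapezoid rule), in `[0, 1]`.
#'
#' @seealso [rocAuc()]
#' @exportClass RocCurve
setClass("RocCurve",
  representation(thresholds = "numeric", fpr = "numeric",
                 tpr = "numeric", auc = "numeric"),
  validity = function(object) {
    if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
      return("fpr and tpr must be non-decreasing")
    if (object@auc < 0 || object@auc > 1) return("auc must be in [0, 1]")
    TRUE
  })
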