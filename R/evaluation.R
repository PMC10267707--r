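#' Classification accuracy
#'
#' @param labels true labels.
#' @param predictions predicted labels, same length.
#' @return fraction of exact matches.
#' @export
classificationAccuracy <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length", call. = FALSE)
  if (length(labels) == 0L) stop("empty input", call. = FALSE)
  mean(labels == predictions)
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score as a threshold (ties grouped, so tied scores
#' move the curve diagonally in one step) and integrates by the trapezoid
#' rule; with score ties this equals the pairwise concordance probability
#' with half credit for ties.
#'
#' @param labels binary labels (0/1 or logical); both classes must occur.
#' @param scores numeric scores, larger = more positive.
#' @return a [RocCurve-class].
#' @export
rocAuc <- function(labels, scores) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(labels) == length(scores))
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- c(0, cumsum(y)[!duplicated(grp, fromLast = TRUE)])
  fp <- c(0, cumsum(1 - y)[!duplicated(grp, fromLast = TRUE)])
  tpr <- tp / nPos; fpr <- fp / nNeg
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  new("RocCurve", thresholds = c(Inf, unique(s)), fpr = fpr, tpr = tpr,
      auc = auc)
}

#' Compression summary table
#'
#' The four-column summary comparing the unpruned baseline with the
#' dynamically pruned network: average accuracy, parameter count (in
#' thousands), iterations (in thousands) and the compression factor.
#'
#' @param baseline,pruned trained [DpgenNetwork-class] objects (the
#'   baseline's masks are all ones, so its compression column prints
#'   `"1x"`).
#' @param accuracies numeric length 2: baseline and pruned accuracy (in
#'   percent or fraction, reported as given).
#' @return data.frame with rows GCNN and DPGEN and columns model,
#'   accuracy, parametersK, iterationsK, compression.
#' @export
compressionTable <- function(baseline, pruned, accuracies) {
  stopifnot(length(accuracies) == 2L)
  fmt <- function(net) {
    total <- parameterCount(net, prunableOnly = TRUE)
    kept <- sum(vapply(net@layers, function(s) sum(s@mask), numeric(1)))
    c(parametersK = kept / 1000,
      iterationsK = trainReport(net)@iterations / 1000,
      compression = total / kept)
  }
  b <- fmt(baseline); p <- fmt(pruned)
  data.frame(
    model = c("GCNN", "DPGEN"),
    accuracy = accuracies,
    parametersK = c(b["parametersK"], p["parametersK"]),
    iterationsK = c(b["iterationsK"], p["iterationsK"]),
    compression = sprintf("%.4gx", c(b["compression"], p["compression"])),
    row.names = NULL)
}
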