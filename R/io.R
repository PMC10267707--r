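#' Write trials to the documented CSV + JSON sidecar format
#'
#' Each trial `i` becomes `trial_%04d.csv` (header row of channel labels,
#' one row per sample) and `trial_%04d.json` (fields `fs`, `label`,
#' `montage`).
#'
#' @param trials list of [TrialEpoch-class].
#' @param path directory (created if needed).
#' @return the paths of the CSV files, invisibly.
#' @export
writeTrials <- function(trials, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    stem <- file.path(path, sprintf("trial_%04d", i))
    df <- as.data.frame(t(tr@data))
    names(df) <- tr@channels
    utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
    jsonlite::write_json(
      list(fs = tr@fs, label = tr@label, montage = tr@channels),
      paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
    paths[i] <- paste0(stem, ".csv")
  }
  invisible(paths)
}

#' Read trials
#'
#' @param path directory containing `trial_*.csv` / `trial_*.json` pairs.
#' @param format `"csv_json"` (bundled), or `"edf"`/`"gdf"`; the latter two
#'   need an external EDF/GDF reader, and raise an error naming it when it
#'   is unavailable.
#' @return list of [TrialEpoch-class].
#' @export
readTrials <- function(path, format = c("csv_json", "edf", "gdf")) {
  format <- match.arg(format)
  if (format %in% c("edf", "gdf"))
    stop(sprintf(
      "%s reading requires the optional 'edfReader' package, which is not installed; convert recordings to the CSV + JSON trial format instead",
      toupper(format)), call. = FALSE)
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  csvs <- sort(list.files(path, pattern = "^trial_[0-9]+\\.csv$",
                          full.names = TRUE))
  if (length(csvs) == 0L) stop("no trial_*.csv files in ", path,
                               call. = FALSE)
  lapply(csvs, function(f) {
    side <- sub("\\.csv$", ".json", f)
    if (!file.exists(side))
      stop("missing JSON sidecar for ", basename(f), call. = FALSE)
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    for (field in c("fs", "label", "montage"))
      if (is.null(meta[[field]]))
        stop("sidecar ", basename(side), " is missing field '", field, "'",
             call. = FALSE)
    df <- utils::read.csv(f, check.names = FALSE)
    if (!identical(names(df), as.character(meta$montage)))
      stop("channel header of ", basename(f),
           " does not match the sidecar montage", call. = FALSE)
    m <- unname(t(as.matrix(df)))
    trialEpoch(m, meta$montage, meta$fs, meta$label)
  })
}

#' Save a network checkpoint
#'
#' A single JSON named-array container: one entry per layer holding the
#' weight tensor `W`, the binary mask and the pruning hyperparameters,
#' plus batch-norm statistics and a manifest (architecture, group name,
#' canonical element order).
#'
#' @param net a [DpgenNetwork-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
saveCheckpoint <- function(net, path) {
  spec <- net@spec
  lay <- lapply(net@layers, function(s) list(
    W = as.numeric(s@W), mask = as.numeric(s@mask),
    dims = s@origDims, matDims = dim(s@W),
    gamma = s@gamma, epsilon = s@epsilon, hysteresis = s@hysteresis))
  els <- vapply(groupElements(spec@group),
                function(g) sprintf("r%dm%d", g@r, g@m), character(1))
  obj <- list(
    manifest = list(
      package = "dpgen", group = spec@group@name, elementOrder = els,
      baseFilters = spec@baseFilters, kernelSize = spec@kernelSize,
      dropout = spec@dropout, nClasses = spec@nClasses,
      inputShape = spec@inputShape, seed = net@seed),
    layers = lay, denseBias = net@denseBias,
    bn1 = net@bn1, bn2 = net@bn2)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path a file written by [saveCheckpoint()].
#' @return a [DpgenNetwork-class].
#' @export
loadCheckpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  man <- obj$manifest
  spec <- networkSpec(group = man$group, baseFilters = man$baseFilters,
                      kernelSize = man$kernelSize, dropout = man$dropout,
                      nClasses = man$nClasses, inputShape = man$inputShape)
  net <- buildNetwork(spec, seed = man$seed)
  for (nm in names(net@layers)) {
    l <- obj$layers[[nm]]
    st <- prunedLayerState(
      matrix(as.numeric(l$W), l$matDims[1], l$matDims[2]),
      gamma = l$gamma, epsilon = l$epsilon, hysteresis = l$hysteresis,
      mask = matrix(as.numeric(l$mask), l$matDims[1], l$matDims[2]))
    st@origDims <- as.integer(l$dims)
    net@layers[[nm]] <- st
  }
  net@denseBias <- obj$denseBias
  net@bn1 <- lapply(obj$bn1, as.numeric)
  net@bn2 <- lapply(obj$bn2, as.numeric)
  net
}

#' Export a training report as JSON
#'
#' Loss trace, accuracy trajectories, per-layer retention and the overall
#' compression factor.
#'
#' @param report a [TrainReport-class] (e.g. `trainReport(net)`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrainReport <- function(report, path) {
  jsonlite::write_json(list(
    loss = report@loss,
    trainAccuracy = report@trainAccuracy,
    valAccuracy = report@valAccuracy,
    evalIterations = report@evalIterations,
    pruning = report@pruningReport,
    compression = report@compression,
    iterations = report@iterations), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize spectral inputs
#'
#' JSON container with the image matrices, row maps and labels of a list
#' of [SpectralInput-class] objects.
#'
#' @param inputs list of [SpectralInput-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSpectralInputs <- function(inputs, path) {
  obj <- list(
    images = lapply(inputs, function(s) s@image),
    rowMap = inputs[[1]]@rowMap,
    labels = vapply(inputs, function(s) s@label, integer(1)),
    nC = inputs[[1]]@nC, nFr = inputs[[1]]@nFr, nT = inputs[[1]]@nT)
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname writeSpectralInputs
#' @export
readSpectralInputs <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  getImage <- function(i) {
    img <- if (is.array(obj$images) && length(dim(obj$images)) == 3L)
      obj$images[i, , ] else obj$images[[i]]
    matrix(as.numeric(img), nrow(img), ncol(img))
  }
  lapply(seq_along(obj$labels), function(i) {
    new("SpectralInput", image = getImage(i),
        rowMap = as.data.frame(obj$rowMap),
        nC = as.integer(obj$nC), nFr = as.integer(obj$nFr),
        nT = as.integer(obj$nT),
        nH = as.integer(obj$nC * obj$nFr),
        label = as.integer(obj$labels[i]))
  })
}
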