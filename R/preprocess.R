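#' Construct a trial epoch
#'
#' @param data numeric matrix `[channels x samples]`.
#' @param channels character electrode labels, one per row of `data`.
#' @param fs sampling rate in Hz.
#' @param label integer class label (0 = left, 1 = right).
#' @return a [TrialEpoch-class].
#' @export
trialEpoch <- function(data, channels, fs, label) {
  new("TrialEpoch", channels = as.character(channels), fs = fs,
      data = data, label = as.integer(label))
}

#' STFT imaging configuration
#'
#' Defaults reproduce the reference geometry: 1000-sample epochs, window
#' 64, hop 14 (67 frames), a 16-row mu image over 6-13 Hz and a 15-row
#' beta image over 17-30 Hz per electrode (31 rows), three electrodes
#' stacked to 93 rows. Band rows are magnitudes of a Hann-windowed,
#' zero-padded (512-point) transform interpolated onto fixed, equally
#' spaced center-frequency grids, which pins the image dimensions at any
#' sampling rate.
#'
#' @param window STFT window length in samples.
#' @param hop frame hop in samples.
#' @param nSamples epoch length in samples.
#' @param muBand,betaBand band edges in Hz.
#' @param muRows,betaRows rows per band.
#' @param nfft zero-padded transform length.
#' @param electrodes electrodes stacked top to bottom (scalp order).
#' @param standardize standardize each assembled image to zero mean, unit
#'   variance (applied last).
#' @return a list of class `StftConfig`.
#' @export
stftConfig <- function(window = 64L, hop = 14L, nSamples = 1000L,
                       muBand = c(6, 13), betaBand = c(17, 30),
                       muRows = 16L, betaRows = 15L, nfft = 512L,
                       electrodes = c("C3", "CZ", "C4"),
                       standardize = TRUE) {
  stopifnot(window <= nSamples, hop >= 1L, nfft >= window)
  structure(list(window = as.integer(window), hop = as.integer(hop),
                 nSamples = as.integer(nSamples), muBand = muBand,
                 betaBand = betaBand, muRows = as.integer(muRows),
                 betaRows = as.integer(betaRows), nfft = as.integer(nfft),
                 electrodes = electrodes, standardize = standardize),
            class = "StftConfig")
}

#' Reject trials with large-deviation samples
#'
#' A trial is dropped when any channel contains a sample whose absolute
#' deviation from that channel's across-dataset mean exceeds `k` times that
#' channel's across-dataset standard deviation. The order of the kept
#' trials is preserved.
#'
#' @param trials list of [TrialEpoch-class] with a common montage.
#' @param k rejection multiple (`> 0`, default 5).
#' @return the kept trials (possibly empty list).
#' @export
rejectArtifacts <- function(trials, k = 5) {
  stopifnot(k > 0)
  if (length(trials) == 0L) return(trials)
  channels <- trials[[1]]@channels
  stats <- lapply(seq_along(channels), function(ci) {
    x <- unlist(lapply(trials, function(tr) tr@data[ci, ]))
    c(mean(x), stats::sd(x))
  })
  keep <- vapply(trials, function(tr) {
    for (ci in seq_along(channels)) {
      m <- stats[[ci]][1]; s <- stats[[ci]][2]
      if (is.na(s) || s == 0) next
      if (any(abs(tr@data[ci, ] - m) > k * s)) return(FALSE)
    }
    TRUE
  }, logical(1))
  trials[keep]
}

#' Mean-center every channel of a trial
#'
#' @param trial a [TrialEpoch-class].
#' @return the trial with each channel's mean subtracted.
#' @export
centerTrial <- function(trial) {
  trial@data <- trial@data - rowMeans(trial@data)
  trial
}

#' Zero-phase band-pass filter a trial
#'
#' 4th-order Butterworth, applied forward and backward per channel
#' (`signal::filtfilt`), passband 6-30 Hz by default: the mu and beta
#' rhythms carrying the ERD/ERS signature.
#'
#' @param trial a [TrialEpoch-class].
#' @param low,high band edges in Hz.
#' @return the filtered trial.
#' @export
bandpassTrial <- function(trial, low = 6, high = 30) {
  if (trial@fs <= 2 * high)
    stop("sampling rate too low for the requested passband", call. = FALSE)
  bf <- signal::butter(4, c(low, high) / (trial@fs / 2), type = "pass")
  trial@data <- t(apply(trial@data, 1L, function(x)
    signal::filtfilt(bf, x)))
  trial
}

#' Number of STFT frames
#'
#' `floor((nSamples - window) / hop) + 1` sliding windows fit in the epoch.
#'
#' @param nSamples epoch length in samples (`>= window`).
#' @param window window length.
#' @param hop frame hop.
#' @return integer frame count (67 for the default 1000/64/14 geometry).
#' @export
stftFrameCount <- function(nSamples, window, hop) {
  if (nSamples < window)
    stop("epoch shorter than the STFT window", call. = FALSE)
  as.integer((nSamples - window) %/% hop + 1L)
}

# magnitude spectrogram: rows = frequency bins 0..nfft/2, cols = frames
.stftMagnitude <- function(x, cfg) {
  nF <- stftFrameCount(length(x), cfg$window, cfg$hop)
  n <- cfg$window
  win <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))   # Hann
  frames <- vapply(seq_len(nF), function(i) {
    seg <- x[((i - 1L) * cfg$hop + 1L):((i - 1L) * cfg$hop + n)] * win
    abs(stats::fft(c(seg, rep(0, cfg$nfft - n))))[seq_len(cfg$nfft / 2 + 1L)]
  }, numeric(cfg$nfft / 2 + 1L))
  frames
}

#' Band image of one channel
#'
#' Magnitude spectrogram of the signal, interpolated per frame onto a fixed
#' grid of equally spaced center frequencies: 16 points spanning the mu
#' band (6-13 Hz) or 15 points spanning the beta band (17-30 Hz), rows
#' ordered by ascending frequency.
#'
#' @param x numeric vector of length `cfg$nSamples`.
#' @param cfg an [stftConfig()].
#' @param fs sampling rate in Hz.
#' @param band `"mu"` or `"beta"`.
#' @return matrix `[band rows x frames]` with a `freqs` attribute giving
#'   the center frequencies.
#' @export
bandImage <- function(x, cfg, fs, band = c("mu", "beta")) {
  band <- match.arg(band)
  stopifnot(length(x) == cfg$nSamples)
  edges <- if (band == "mu") cfg$muBand else cfg$betaBand
  rows <- if (band == "mu") cfg$muRows else cfg$betaRows
  if (max(edges) > fs / 2)
    stop("band edge above the Nyquist frequency", call. = FALSE)
  mag <- .stftMagnitude(x, cfg)
  freqBins <- (seq_len(nrow(mag)) - 1L) * fs / cfg$nfft
  target <- seq(edges[1], edges[2], length.out = rows)
  img <- apply(mag, 2L, function(col)
    stats::approx(freqBins, col, xout = target)$y)
  img <- matrix(img, nrow = rows)
  attr(img, "freqs") <- target
  img
}

#' Assemble the stacked time-frequency input image
#'
#' For each configured electrode (scalp order C3, CZ, C4 by default) the
#' mu image is stacked above the beta image (31 rows), electrodes are
#' stacked top to bottom, and the full image is standardized to zero mean
#' and unit variance. The row map records electrode, band and center
#' frequency for every row.
#'
#' @param trial a preprocessed [TrialEpoch-class] containing the
#'   configured electrodes.
#' @param cfg an [stftConfig()].
#' @return a [SpectralInput-class] (93 x 67 for the defaults).
#' @export
assembleInput <- function(trial, cfg = stftConfig()) {
  missing <- setdiff(cfg$electrodes, trial@channels)
  if (length(missing) > 0)
    stop("trial is missing configured electrode(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  nT <- stftFrameCount(cfg$nSamples, cfg$window, cfg$hop)
  blocks <- list(); maps <- list()
  for (el in cfg$electrodes) {
    x <- trial@data[match(el, trial@channels), seq_len(cfg$nSamples)]
    mu <- bandImage(x, cfg, trial@fs, "mu")
    be <- bandImage(x, cfg, trial@fs, "beta")
    blocks[[el]] <- rbind(mu, be)
    maps[[el]] <- data.frame(
      electrode = el,
      band = c(rep("mu", cfg$muRows), rep("beta", cfg$betaRows)),
      freq = c(attr(mu, "freqs"), attr(be, "freqs")))
  }
  img <- do.call(rbind, blocks)
  rowMap <- do.call(rbind, c(maps, list(make.row.names = FALSE)))
  if (cfg$standardize) {
    s <- stats::sd(img)
    img <- (img - mean(img)) / (if (s > 0) s else 1)
  }
  nFr <- cfg$muRows + cfg$betaRows
  new("SpectralInput", image = unname(img), rowMap = rowMap,
      nC = length(cfg$electrodes), nFr = as.integer(nFr),
      nT = as.integer(nT), nH = as.integer(length(cfg$electrodes) * nFr),
      label = trial@label)
}

#' Run the full preprocessing pipeline on a set of trials
#'
#' Artifact rejection (k-sigma rule across the dataset), per-channel mean
#' centering, 6-30 Hz zero-phase band-pass, and STFT imaging.
#'
#' @param trials list of [TrialEpoch-class].
#' @param cfg an [stftConfig()].
#' @param rejectK rejection multiple for [rejectArtifacts()]; `NULL` or
#'   `Inf` disables rejection.
#' @param low,high band-pass edges in Hz.
#' @return list of [SpectralInput-class], one per kept trial.
#' @export
preprocessTrials <- function(trials, cfg = stftConfig(), rejectK = 5,
                             low = 6, high = 30) {
  if (!is.null(rejectK) && is.finite(rejectK))
    trials <- rejectArtifacts(trials, rejectK)
  lapply(trials, function(tr)
    assembleInput(bandpassTrial(centerTrial(tr), low, high), cfg))
}
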