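#' Configuration of the synthetic motor-imagery EEG generator
#'
#' The generator emulates the spectral signature the classifier relies on:
#' each channel is 1/f-like background noise plus a mu-band and a beta-band
#' oscillation with random frequency and phase. For a right-hand trial the
#' channel over the contralateral (left) motor cortex, C3, has its mu
#' amplitude attenuated by `erdDepth` (event-related desynchronization) and
#' its beta amplitude raised by `ersGain` (event-related synchronization);
#' a left-hand trial modulates C4; the midline CZ carries half of either
#' modulation.
#'
#' The `"easy"` preset (deep ERD 0.8, low noise 0.3) is the well-separated
#' regime used by the package's end-to-end learnability and compression
#' studies.
#'
#' @param fs sampling rate in Hz.
#' @param nSamples samples per trial.
#' @param montage ordered channel labels.
#' @param muFreq,betaFreq frequency ranges (Hz) the oscillations are drawn
#'   from, uniformly per trial.
#' @param muAmp,betaAmp baseline oscillation amplitudes (arbitrary units;
#'   mu dominant at rest).
#' @param erdDepth fraction in `[0, 1]` by which contralateral mu amplitude
#'   is reduced.
#' @param ersGain fraction `>= 0` by which contralateral beta amplitude is
#'   raised.
#' @param noiseScale standard deviation of the 1/f-like background.
#' @param noiseSlope spectral slope of the background (power ~ f^slope).
#' @param preset `"default"` or `"easy"`; the preset is applied first and
#'   explicit arguments override it.
#' @return a list of class `SynthConfig`.
#' @export
synthConfig <- function(fs = 250, nSamples = 1000L,
                        montage = c("C3", "CZ", "C4"),
                        muFreq = c(9, 12), betaFreq = c(18, 26),
                        muAmp = 2, betaAmp = 1,
                        erdDepth = 0.6, ersGain = 0.4,
                        noiseScale = 1, noiseSlope = -1,
                        preset = c("default", "easy")) {
  preset <- match.arg(preset)
  if (preset == "easy") {
    if (missing(erdDepth)) erdDepth <- 0.8
    if (missing(noiseScale)) noiseScale <- 0.3
  }
  stopifnot(erdDepth >= 0, erdDepth <= 1, ersGain >= 0,
            fs > 2 * max(betaFreq))
  structure(list(fs = fs, nSamples = as.integer(nSamples),
                 montage = montage, muFreq = muFreq, betaFreq = betaFreq,
                 muAmp = muAmp, betaAmp = betaAmp, erdDepth = erdDepth,
                 ersGain = ersGain, noiseScale = noiseScale,
                 noiseSlope = noiseSlope),
            class = "SynthConfig")
}

# 1/f-like noise: white noise shaped in the frequency domain
.pinkNoise <- function(n, fs, slope) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  freq <- c(1, seq_len(n - 1)) * fs / n          # avoid the DC singularity
  scale <- freq^(slope / 2)
  scale[1] <- 0                                  # drop DC
  x <- Re(stats::fft(W * scale, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Generate one synthetic motor-imagery trial
#'
#' @param label `"left"`/`"right"` (or 0/1).
#' @param cfg a [synthConfig()].
#' @param seed integer seed; the trial is a deterministic function of
#'   `(label, cfg, seed)`.
#' @return a [TrialEpoch-class].
#' @export
generateTrial <- function(label, cfg = synthConfig(), seed = 1L) {
  if (is.numeric(label)) label <- c("left", "right")[label + 1L]
  if (!label %in% c("left", "right"))
    stop("unknown label: ", label, call. = FALSE)
  contra <- if (label == "right") "C3" else "C4"
  t <- (seq_len(cfg$nSamples) - 1L) / cfg$fs
  data <- .withSeed(seed, {
    m <- matrix(0, length(cfg$montage), cfg$nSamples)
    for (ci in seq_along(cfg$montage)) {
      ch <- cfg$montage[ci]
      muScale <- 1; betaScale <- 1
      if (ch == contra) {
        muScale <- 1 - cfg$erdDepth
        betaScale <- 1 + cfg$ersGain
      } else if (ch == "CZ") {
        muScale <- 1 - cfg$erdDepth / 2
        betaScale <- 1 + cfg$ersGain / 2
      }
      fMu <- stats::runif(1, cfg$muFreq[1], cfg$muFreq[2])
      fBe <- stats::runif(1, cfg$betaFreq[1], cfg$betaFreq[2])
      phMu <- stats::runif(1, 0, 2 * pi)
      phBe <- stats::runif(1, 0, 2 * pi)
      m[ci, ] <-
        cfg$noiseScale * .pinkNoise(cfg$nSamples, cfg$fs, cfg$noiseSlope) +
        cfg$muAmp * muScale * sin(2 * pi * fMu * t + phMu) +
        cfg$betaAmp * betaScale * sin(2 * pi * fBe * t + phBe)
    }
    m
  })
  trialEpoch(data, cfg$montage, cfg$fs,
             if (label == "right") 1L else 0L)
}

#' Generate a balanced synthetic dataset
#'
#' Exactly `nPerClass` trials per class, each from a deterministically
#' derived per-trial seed, shuffled with the seeded generator.
#'
#' @param nPerClass trials per class (`>= 1`).
#' @param cfg a [synthConfig()].
#' @param seed root seed.
#' @return list with elements `trials` (list of [TrialEpoch-class]) and
#'   `labels` (integer vector, 0 = left / 1 = right).
#' @export
generateDataset <- function(nPerClass, cfg = synthConfig(), seed = 1L) {
  stopifnot(nPerClass >= 1)
  labels <- rep(c("left", "right"), each = nPerClass)
  trials <- lapply(seq_along(labels), function(i)
    generateTrial(labels[i], cfg, seed = .childSeed(seed, i)))
  ord <- .withSeed(.childSeed(seed, 0L), sample.int(length(trials)))
  list(trials = trials[ord],
       labels = vapply(trials[ord], function(tr) tr@label, integer(1)))
}
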