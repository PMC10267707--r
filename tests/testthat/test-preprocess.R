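test_that("the frame count follows the sliding-window formula", {
  expect_identical(stftFrameCount(1000, 64, 14), 67L)
  expect_identical(stftFrameCount(64, 64, 14), 1L)
  expect_error(stftFrameCount(63, 64, 14), "shorter")
  # frame-enumeration oracle over a parameter grid
  for (n in c(100, 250, 999)) for (w in c(16, 64)) for (h in c(5, 14, 31)) {
    count <- 0L; start <- 1L
    while (start + w - 1L <= n) { count <- count + 1L; start <- start + h }
    expect_identical(stftFrameCount(n, w, h), count)
  }
})

test_that("centering leaves every channel with zero mean", {
  tr <- trialEpoch(matrix(c(rep(3, 50), rnorm(50, 2)), 2, byrow = TRUE),
                   c("C3", "C4"), 250, 0L)
  ctr <- centerTrial(tr)
  expect_true(all(abs(rowMeans(ctr@data)) < 1e-10))
  expect_equal(ctr@data[1, ], rep(0, 50))        # constant channel
  expect_equal(centerTrial(ctr)@data, ctr@data, tolerance = 1e-12)
})

test_that("the band-pass keeps mu/beta content and rejects DC and slow drift", {
  fs <- 250; t <- (0:999) / fs
  probe <- function(f) trialEpoch(matrix(sin(2 * pi * f * t), 1),
                                  "C3", fs, 0L)
  amp <- function(tr) {
    x <- bandpassTrial(tr)@data[1, 200:800]      # ignore filter edges
    (max(x) - min(x)) / 2
  }
  expect_equal(amp(probe(20)), 1, tolerance = 0.05)
  expect_lt(amp(probe(1)), 0.1)
  dc <- trialEpoch(matrix(1, 1, 1000), "C3", fs, 0L)
  expect_lt(max(abs(bandpassTrial(dc)@data[1, 200:800])), 1e-3)
  slow <- trialEpoch(matrix(rnorm(1000), 1), "C3", 50, 0L)
  expect_error(bandpassTrial(slow), "sampling rate")
})

test_that("band images have the stated geometry and locate spectral peaks", {
  cfg <- stftConfig()
  fs <- 250; t <- (0:999) / fs
  img <- bandImage(sin(2 * pi * 10 * t), cfg, fs, "mu")
  expect_identical(dim(img), c(16L, 67L))
  freqs <- attr(img, "freqs")
  expect_equal(freqs, seq(6, 13, length.out = 16))
  expect_false(is.unsorted(freqs))
  expect_identical(which.max(rowMeans(img)), which.min(abs(freqs - 10)))
  be <- bandImage(sin(2 * pi * 22 * t), cfg, fs, "beta")
  expect_identical(dim(be), c(15L, 67L))
  expect_identical(which.max(rowMeans(be)),
                   which.min(abs(attr(be, "freqs") - 22)))
  expect_true(all(bandImage(rep(0, 1000), cfg, fs, "mu") == 0))
  expect_error(bandImage(rep(0, 1000), cfg, 40, "beta"), "Nyquist")
})

test_that("assembled inputs stack mu over beta per electrode in scalp order", {
  cfg <- stftConfig()
  tr <- generateTrial("right", synthConfig(), seed = 9)
  si <- assembleInput(tr, cfg)
  expect_identical(dim(si@image), c(93L, 67L))
  expect_identical(c(si@nC, si@nFr, si@nT, si@nH), c(3L, 31L, 67L, 93L))
  expect_identical(nrow(si@rowMap), 93L)
  expect_identical(unique(si@rowMap$electrode), c("C3", "CZ", "C4"))
  expect_identical(si@rowMap$band[1:31],
                   c(rep("mu", 16), rep("beta", 15)))
  # per-electrode block: rows ordered by ascending frequency within band
  for (el in c("C3", "CZ", "C4")) {
    sub <- si@rowMap[si@rowMap$electrode == el, ]
    expect_false(is.unsorted(sub$freq[sub$band == "mu"]))
    expect_false(is.unsorted(sub$freq[sub$band == "beta"]))
  }
  expect_equal(mean(si@image), 0, tolerance = 1e-10)
  expect_equal(sd(si@image), 1, tolerance = 1e-10)
  # single electrode
  one <- trialEpoch(tr@data[1, , drop = FALSE], "C3", tr@fs, 1L)
  si1 <- assembleInput(one, stftConfig(electrodes = "C3"))
  expect_identical(si1@nH, 31L)
  expect_error(assembleInput(one, cfg), "CZ")
})

test_that("artifact rejection drops exactly the trials with large-deviation samples", {
  set.seed(10)
  mk <- function() trialEpoch(matrix(rnorm(2 * 200), 2), c("C3", "C4"),
                              250, 0L)
  trials <- replicate(20, mk(), simplify = FALSE)
  expect_length(rejectArtifacts(trials, 5), 20)
  spiked <- trials
  spiked[[7]]@data[2, 50] <- 100
  kept <- rejectArtifacts(spiked, 5)
  expect_length(kept, 19)
  # order preserved, the spiked trial removed
  expect_identical(lapply(kept, function(x) x@data),
                   lapply(spiked[-7], function(x) x@data))
  # constant trials are never rejected (zero variance guard)
  flat <- replicate(3, trialEpoch(matrix(0, 1, 10), "C3", 250, 0L),
                    simplify = FALSE)
  expect_length(rejectArtifacts(flat, 1), 3)
  expect_length(rejectArtifacts(list(), 5), 0)
  # brute-force per-sample scan oracle
  k <- 2
  keepOracle <- vapply(seq_along(spiked), function(i) {
    ok <- TRUE
    for (ci in 1:2) {
      x <- unlist(lapply(spiked, function(tr) tr@data[ci, ]))
      m <- mean(x); s <- sd(x)
      if (any(abs(spiked[[i]]@data[ci, ] - m) > k * s)) ok <- FALSE
    }
    ok
  }, logical(1))
  expect_length(rejectArtifacts(spiked, k), sum(keepOracle))
})

test_that("the pipeline is deterministic and shows the ERD laterality", {
  cfg <- synthConfig(preset = "easy")
  tr <- generateTrial("right", cfg, seed = 42)
  a <- assembleInput(bandpassTrial(centerTrial(tr)))
  b <- assembleInput(bandpassTrial(centerTrial(tr)))
  expect_identical(a@image, b@image)
  # right-hand imagery: C3 mu rows darker than C4 mu rows
  c3mu <- a@rowMap$electrode == "C3" & a@rowMap$band == "mu"
  c4mu <- a@rowMap$electrode == "C4" & a@rowMap$band == "mu"
  expect_lt(mean(a@image[c3mu, ]), mean(a@image[c4mu, ]))
})
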