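test_that("magnitude statistics use absolute values and the m*n-1 denominator", {
  expect_equal(layerStats(matrix(c(1, -1, 1, -1), 2)), list(mu = 1, sigma = 0))
  expect_equal(layerStats(matrix(0, 2, 2)), list(mu = 0, sigma = 0))
  expect_equal(layerStats(matrix(5))$sigma, 0)
  set.seed(1)
  W <- matrix(rnorm(100), 10)
  st <- layerStats(W)
  a <- abs(as.numeric(W))
  expect_equal(st$mu, sum(a) / 100, tolerance = 1e-12)
  expect_equal(st$sigma, sqrt(sum((a - mean(a))^2) / 99), tolerance = 1e-12)
})

test_that("importance is the log distance-to-threshold ratio", {
  W <- matrix(c(0.05, 0.5, 2, -3), 2)
  st <- prunedLayerState(W, gamma = 2)
  d <- importanceScores(st)
  # exact zero where |W| - mu equals gamma * sigma
  Wz <- st@W
  Wz[1, 1] <- st@mu + st@gamma * st@sigma
  stz <- updateStats(st); stz@W <- Wz; stz <- updateStats(stz)
  dz <- log(max(stz@epsilon, abs(Wz[1, 1]) - stz@mu) /
              (stz@gamma * stz@sigma))
  expect_equal(importanceScores(stz)[1, 1], dz)
  # clamp at epsilon for weights at or below the mean magnitude
  below <- abs(st@W) <= st@mu
  expect_true(all(d[below] == log(st@epsilon / (st@gamma * st@sigma))))
  # sign agrees with the direct comparison |W| - mu vs gamma * sigma
  set.seed(2)
  Wr <- matrix(rnorm(200), 10)
  str <- prunedLayerState(Wr, gamma = 1)
  dr <- importanceScores(str)
  expect_identical(dr >= 0, abs(Wr) - str@mu >= str@gamma * str@sigma)
  # degenerate sigma = 0: everything important
  st0 <- prunedLayerState(matrix(1, 3, 3))
  expect_true(all(importanceScores(st0) == Inf))
})

test_that("mask updates prune, splice and respect the hysteresis band", {
  set.seed(3)
  W <- matrix(rnorm(100), 10)
  st <- prunedLayerState(W, gamma = 1, hysteresis = 0.1)
  t <- st@threshold
  # start all-pruned; one weight pushed above the upper edge is restored
  st@mask <- matrix(0, 10, 10)
  st@W[4, 7] <- 1.2 * t
  st <- updateStats(st)   # stats shift slightly; recompute the band
  Tn <- updateMask(st)
  expect_equal(Tn[4, 7], 1)
  expect_true(all(Tn %in% c(0, 1)))
  # inside the band the previous state is kept
  stMid <- prunedLayerState(W, gamma = 1, hysteresis = 0.5)
  inside <- abs(stMid@W) >= (1 - 0.5) * stMid@threshold &
    abs(stMid@W) < (1 + 0.5) * stMid@threshold
  stMid@mask <- matrix(0, 10, 10)
  expect_true(all(updateMask(stMid)[inside] == 0))
  stMid@mask <- matrix(1, 10, 10)
  expect_true(all(updateMask(stMid)[inside] == 1))
  # with no hysteresis the mask is the indicator of non-negative importance
  st0 <- prunedLayerState(W, gamma = 1, hysteresis = 0)
  expect_identical(updateMask(st0), (importanceScores(st0) >= 0) + 0)
})

test_that("masked weights are the Hadamard product", {
  set.seed(4)
  W <- matrix(rnorm(20), 4)
  st <- prunedLayerState(W)
  expect_identical(maskedWeights(st), W)
  st@mask <- matrix(0, 4, 5)
  expect_identical(maskedWeights(st), W * 0)
  st@mask <- matrix(rbinom(20, 1, 0.5), 4)
  expect_identical(maskedWeights(st), W * st@mask)
})

test_that("the gradient factor follows the three-branch surrogate and is continuous at t", {
  W <- matrix(seq(-2, 2, length.out = 9), 3)
  st <- prunedLayerState(W, gamma = 0.5, epsilon = 0.01)
  t <- st@threshold
  f <- gradFactor(st)
  aw <- abs(W)
  expect_true(all(f[aw <= 0.01 * t] == log(0.01)))
  mid <- aw > 0.01 * t & aw <= t
  expect_equal(f[mid], log(aw[mid] / t) + 1)
  expect_true(all(f[aw > t] == 1))
  # continuity: both branches give 1 at |W| = t
  stc <- st; stc@W[1, 1] <- t
  expect_equal(gradFactor(stc)[1, 1], 1)
  expect_equal(log(t / t) + 1, 1)
  # degenerate threshold: no pruning active
  st0 <- prunedLayerState(matrix(0, 2, 2))
  expect_true(all(gradFactor(st0) == 1))
})

test_that("the factor is the derivative of the declared soft surrogate", {
  set.seed(5)
  st <- prunedLayerState(matrix(rnorm(50), 5), gamma = 0.5, epsilon = 0.01)
  t <- st@threshold
  f <- gradFactor(st)
  h <- 1e-6
  # scalar probes placed inside each branch
  probes <- c(0.2 * 0.01 * t, -0.5 * 0.01 * t,   # floor region
              0.1 * t, 0.6 * t, -0.8 * t,        # pruned region
              1.5 * t, -2 * t)                   # retained region
  for (p in probes) {
    stp <- st; stp@W[1, 1] <- p
    fd <- (pruningSurrogate(st, matrix(p + h))[1, 1] -
             pruningSurrogate(st, matrix(p - h))[1, 1]) / (2 * h)
    expect_equal(gradFactor(stp)[1, 1], fd, tolerance = 1e-4)
  }
})

test_that("SGD steps scale the masked-weight gradient by the factor", {
  st <- prunedLayerState(matrix(c(0.1, 2, -0.3, 1.5), 2), gamma = 0.5)
  g <- matrix(c(1, -1, 0.5, 2), 2)
  upd <- sgdStep(st, g, beta = 0.1)
  expect_equal(upd@W, st@W - 0.1 * gradFactor(st) * g, tolerance = 1e-12)
  expect_identical(sgdStep(st, g * 0, 0.1)@W, st@W)   # zero gradient
  expect_error(sgdStep(st, matrix(c(1, NA, 1, 1), 2), 0.1), "non-finite")
})

test_that("compression is total weights over retained weights", {
  st1 <- prunedLayerState(matrix(rnorm(100), 10))
  expect_equal(compressionRatio(list(st1)), 1)
  # the headline operating point: 113,000 total, 7,500 retained
  big <- prunedLayerState(matrix(rnorm(113000), 100))
  big@mask <- matrix(0, 100, 1130)
  big@mask[seq_len(7500)] <- 1
  expect_equal(compressionRatio(list(big)), 113000 / 7500, tolerance = 1e-12)
  expect_gt(compressionRatio(list(big)), 15)
  # random masks against a direct count
  set.seed(6)
  sts <- lapply(1:3, function(i) {
    s <- prunedLayerState(matrix(rnorm(40), 5))
    s@mask <- matrix(rbinom(40, 1, 0.6), 5)
    s
  })
  kept <- sum(vapply(sts, function(s) sum(s@mask), numeric(1)))
  expect_equal(compressionRatio(sts), 120 / kept)
  sts[[1]]@mask[] <- 0; sts[[2]]@mask[] <- 0; sts[[3]]@mask[] <- 0
  expect_error(compressionRatio(sts), "retained")
})

test_that("retention is monotone in gamma on fixed weights", {
  set.seed(7)
  W <- matrix(rnorm(400), 20)
  kept <- vapply(c(0.5, 1, 2, 4), function(gm) {
    st <- prunedLayerState(W, gamma = gm, hysteresis = 0)
    sum(updateMask(st))
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("masks stay binary under arbitrary update sequences", {
  set.seed(8)
  st <- prunedLayerState(matrix(rnorm(64), 8), gamma = 1)
  for (i in 1:20) {
    st <- sgdStep(st, matrix(rnorm(64), 8), 0.05)
    st <- updateStats(st)
    st@mask <- updateMask(st)
    expect_true(all(st@mask %in% c(0, 1)))
  }
})
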