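test_that("zero iterations leave the network at its initialization", {
  blobs <- twoBlobImages(8)
  net <- buildNetwork(networkSpec(inputShape = c(23L, 17L)), seed = 4)
  W0 <- lapply(net@layers, function(s) s@W)
  out <- trainNetwork(net, blobs$X, blobs$labels,
                      trainConfig(maxIterations = 0L))
  expect_identical(lapply(out@layers, function(s) s@W), W0)
  for (s in out@layers) expect_true(all(s@mask == 1))
  r <- trainReport(out)
  expect_identical(r@iterations, 0L)
  expect_length(r@loss, 0)
  expect_length(r@trainAccuracy, 0)
})

test_that("training is reproducible from the seed and keeps masks binary", {
  blobs <- twoBlobImages(16)
  cfg <- trainConfig(beta = 0.02, maxIterations = 25L, gamma = 1,
                     maskWarmup = 5L, seed = 9)
  run <- function() {
    net <- buildNetwork(networkSpec(inputShape = c(23L, 17L)), seed = 4,
                        gamma = 1)
    trainNetwork(net, blobs$X, blobs$labels, cfg)
  }
  a <- run(); b <- run()
  expect_identical(trainReport(a)@loss, trainReport(b)@loss)
  expect_identical(a@layers$gconv@W, b@layers$gconv@W)
  expect_identical(a@layers$gconv@mask, b@layers$gconv@mask)
  for (s in a@layers) expect_true(all(s@mask %in% c(0, 1)))
})

test_that("the masked forward equals a dense network carrying W * T", {
  blobs <- twoBlobImages(10)
  net <- buildNetwork(networkSpec(inputShape = c(23L, 17L)), seed = 7)
  set.seed(11)
  for (nm in names(net@layers))
    net@layers[[nm]]@mask <- matrix(
      rbinom(length(net@layers[[nm]]@W), 1, 0.5),
      nrow(net@layers[[nm]]@W))
  dense <- net
  for (nm in names(dense@layers)) {
    dense@layers[[nm]]@W <- maskedWeights(net@layers[[nm]])
    dense@layers[[nm]]@mask[] <- 1
  }
  pm <- evaluateNetwork(net, blobs$X)$probabilities
  pd <- evaluateNetwork(dense, blobs$X)$probabilities
  expect_equal(pm, pd, tolerance = 1e-12)
})

test_that("a separable image set is learned with near-monotone full-batch loss", {
  blobs <- twoBlobImages(24, seed = 3)
  cfg <- trainConfig(beta = 0.05, batchSize = 24L, maxIterations = 60L,
                     prune = FALSE, seed = 2)
  net <- buildNetwork(networkSpec(inputShape = c(23L, 17L), dropout = 0),
                      seed = 8)
  net <- trainNetwork(net, blobs$X, blobs$labels, cfg)
  r <- trainReport(net)
  acc <- evaluateNetwork(net, blobs$X, blobs$labels)$accuracy
  expect_gt(acc, 0.95)
  drops <- diff(r@loss[1:51]) < 0
  expect_gte(sum(drops), 45)
})

test_that("evaluation is deterministic, near chance untrained, perfect for an oracle", {
  blobs <- twoBlobImages(40, seed = 6)
  net <- buildNetwork(networkSpec(inputShape = c(23L, 17L)), seed = 12)
  ev1 <- evaluateNetwork(net, blobs$X, blobs$labels)
  ev2 <- evaluateNetwork(net, blobs$X, blobs$labels)
  expect_identical(ev1$probabilities, ev2$probabilities)
  expect_equal(rowSums(ev1$probabilities), rep(1, 40), tolerance = 1e-12)
  expect_gte(ev1$accuracy, 0.3)       # binomial noise around chance
  expect_lte(ev1$accuracy, 0.7)
  expect_equal(classificationAccuracy(blobs$labels, blobs$labels), 1)
})

test_that("compression grows with gamma across trained models", {
  blobs <- twoBlobImages(24, seed = 17)
  comp <- vapply(c(0.5, 1, 2), function(gm) {
    cfg <- trainConfig(beta = 0.05, batchSize = 24L, maxIterations = 70L,
                       gamma = gm, maskWarmup = 30L, seed = 5)
    net <- buildNetwork(networkSpec(inputShape = c(23L, 17L), dropout = 0),
                        seed = 18, gamma = gm)
    net <- trainNetwork(net, blobs$X, blobs$labels, cfg)
    rep <- trainReport(net)@pruningReport
    attr(rep, "compression")
  }, numeric(1))
  # non-decreasing up to hysteresis slack
  expect_gte(comp[2], comp[1] * 0.9)
  expect_gte(comp[3], comp[2] * 0.9)
  expect_gt(comp[3], comp[1])
})

test_that("pruned training compresses while the loss still falls", {
  blobs <- twoBlobImages(24, seed = 13)
  cfg <- trainConfig(beta = 0.05, batchSize = 24L, maxIterations = 80L,
                     gamma = 1, maskWarmup = 30L, seed = 3)
  net <- buildNetwork(networkSpec(inputShape = c(23L, 17L), dropout = 0),
                      seed = 14, gamma = 1)
  net <- trainNetwork(net, blobs$X, blobs$labels, cfg)
  r <- trainReport(net)
  expect_gt(r@compression, 1)
  expect_lt(mean(tail(r@loss, 10)), mean(head(r@loss, 10)))
  expect_identical(nrow(r@pruningReport), 3L)
  expect_identical(sum(r@pruningReport$total), 54 + 1296 +
                     2 * (6 * dpgen:::.headRows(net@spec)))
})
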