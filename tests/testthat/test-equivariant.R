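test_that("lifting convolution matches the naive correlation oracle", {
  P <- groupSpec("p4")
  set.seed(1)
  f <- array(rnorm(25), c(1, 5, 5))
  psi <- array(rnorm(9), c(1, 1, 3, 3))
  out <- liftingConv(f, psi, P)
  els <- groupElements(P)
  for (gi in seq_along(els)) {
    kRot <- applyElementOracle(els[[gi]]@r, els[[gi]]@m, psi[1, 1, , ])
    expect_equal(out[1, gi, , ], corrOracle(f[1, , ], kRot), tolerance = 1e-12)
  }
})

test_that("an identity-symmetric delta kernel copies the input to every slot", {
  P <- groupSpec("p4")
  f <- array(rnorm(49), c(1, 7, 7))
  delta <- array(0, c(1, 1, 3, 3)); delta[1, 1, 2, 2] <- 1
  out <- liftingConv(f, delta, P)
  for (gi in 1:4)
    expect_equal(out[1, gi, , ], f[1, 2:6, 2:6])
})

test_that("lifting layer with 6 base filters exposes 24 channel slots", {
  P <- groupSpec("p4")
  f <- array(rnorm(81), c(1, 9, 9))
  psi <- array(rnorm(6 * 9), c(6, 1, 3, 3))
  out <- liftingConv(f, psi, P)
  expect_identical(dim(out)[1] * dim(out)[2], 24L)
})

test_that("group convolution matches a brute-force (g, g~) loop oracle", {
  for (nm in c("p4", "p4m")) {
    G <- groupSpec(nm)
    els <- groupElements(G)
    nG <- length(els)
    set.seed(2)
    f <- array(rnorm(2 * nG * 36), c(2, nG, 6, 6))
    psi <- array(rnorm(2 * 2 * nG * 9), c(2, 2, nG, 3, 3))
    out <- groupConv(f, psi, G)
    for (o in 1:2) for (gi in seq_len(nG)) {
      g <- els[[gi]]
      acc <- matrix(0, 4, 4)
      for (c in 1:2) for (si in seq_len(nG)) {
        ki <- elementIndex(G, groupCompose(G, groupInverse(G, g), els[[si]]))
        kMat <- applyElementOracle(g@r, g@m, psi[o, c, ki, , ])
        acc <- acc + corrOracle(f[c, si, , ], kMat)
      }
      expect_equal(out[o, gi, , ], acc, tolerance = 1e-10)
    }
  }
})

test_that("a group delta kernel reproduces each input slot", {
  P <- groupSpec("p4")
  f <- array(rnorm(4 * 36), c(1, 4, 6, 6))
  psi <- array(0, c(1, 1, 4, 3, 3))
  psi[1, 1, 1, 2, 2] <- 1              # identity slot, delta spatial profile
  out <- groupConv(f, psi, P)
  for (gi in 1:4)
    expect_equal(out[1, gi, , ], f[1, gi, 2:5, 2:5])
})

test_that("group convolution collapsed onto the identity element is ordinary convolution", {
  P <- groupSpec("p4")
  set.seed(3)
  fPlane <- matrix(rnorm(49), 7, 7)
  kPlane <- matrix(rnorm(9), 3, 3)
  f <- array(0, c(1, 4, 7, 7)); f[1, 1, , ] <- fPlane
  psi <- array(0, c(1, 1, 4, 3, 3)); psi[1, 1, 1, , ] <- kPlane
  out <- groupConv(f, psi, P)
  expect_equal(out[1, 1, , ], corrOracle(fPlane, kPlane), tolerance = 1e-12)
})

test_that("transform-then-convolve equals convolve-then-transform", {
  for (nm in c("p4", "p4m")) {
    G <- groupSpec(nm)
    nG <- G@order
    set.seed(4)
    for (rep in 1:3) {
      f <- array(rnorm(2 * nG * 49), c(2, nG, 7, 7))
      psi <- array(rnorm(2 * 2 * nG * 9), c(2, 2, nG, 3, 3))
      y <- groupConv(f, psi, G)
      fz <- array(rnorm(81), c(1, 9, 9))
      psiz <- array(rnorm(2 * 9), c(2, 1, 3, 3))
      yz <- liftingConv(fz, psiz, G)
      for (g in groupElements(G)) {
        expect_lt(max(abs(groupConv(transformFeature(g, f, G), psi, G) -
                            transformFeature(g, y, G))), 1e-5)
        expect_lt(max(abs(liftingConv(transformPlane(g, fz), psiz, G) -
                            transformFeature(g, yz, G))), 1e-5)
      }
    }
  }
})

test_that("feature transforms follow the permutation-matrix oracle", {
  G <- groupSpec("p4m")
  els <- groupElements(G)
  set.seed(6)
  f <- array(rnorm(2 * 8 * 25), c(2, 8, 5, 5))
  e <- groupIdentity(G)
  expect_identical(transformFeature(e, f, G), f)
  for (g in els) {
    tf <- transformFeature(g, f, G)
    back <- transformFeature(groupInverse(G, g), tf, G)
    expect_equal(back, f)
    # slot-by-slot oracle: output slot s holds input slot inverse(g)*s,
    # spatially mapped by g
    for (si in seq_along(els)) {
      src <- elementIndex(G, groupCompose(G, groupInverse(G, g), els[[si]]))
      expect_equal(tf[1, si, , ],
                   applyElementOracle(g@r, g@m, f[1, src, , ]))
    }
  }
})

test_that("orientation pooling is invariant up to the spatial transform", {
  P <- groupSpec("p4")
  f <- array(2.5, c(3, 4, 5, 5))
  expect_equal(groupPool(f, "max"), array(2.5, c(3, 5, 5)))
  expect_equal(groupPool(f, "mean"), array(2.5, c(3, 5, 5)))
  oneHot <- array(0, c(1, 4, 2, 2)); oneHot[1, 3, , ] <- 7
  expect_equal(groupPool(oneHot, "max"), array(7, c(1, 2, 2)))
  set.seed(7)
  fr <- array(rnorm(4 * 36), c(1, 4, 6, 6))
  pooled <- groupPool(fr, "max")
  for (g in groupElements(P)) {
    lhs <- groupPool(transformFeature(g, fr, P), "max")
    expect_equal(lhs[1, , ], applyElementOracle(g@r, g@m, pooled[1, , ]))
  }
})

test_that("the assembled network has the stated width and a probability head", {
  spec <- networkSpec()
  net <- buildNetwork(spec, seed = 2)
  expect_identical(spec@baseFilters[1] * spec@group@order, 24L)
  # hand-counted parameter sizes: lifting 6*1*3*3, group conv 6*6*4*3*3,
  # dense (6 * 21 head rows) * 2, dense bias 2, batch norm 2 * (24 + 24)
  expect_identical(parameterCount(net, prunableOnly = TRUE),
                   54L + 1296L + 252L)
  expect_identical(parameterCount(net), 54L + 1296L + 252L + 2L + 96L)
  probs <- predictProbs(net, matrix(rnorm(93 * 67), 93, 67))
  expect_equal(rowSums(probs), 1, tolerance = 1e-12)
  expect_true(all(probs >= 0))
})
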