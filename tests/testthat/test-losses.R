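test_that("shape-IoU loss agrees with an independent step-by-step oracle", {
  expect_equal(shapeIoULoss(c(0.5, 0.5, 0.2, 0.2), c(0.5, 0.5, 0.2, 0.2)), 0)
  # worked example against the oracle
  expect_equal(shapeIoULoss(c(0.5, 0.5, 0.2, 0.2), c(0.6, 0.5, 0.2, 0.4)),
               shapeIoUOracle(c(0.5, 0.5, 0.2, 0.2), c(0.6, 0.5, 0.2, 0.4)),
               tolerance = 1e-10)
  set.seed(5)
  for (i in 1:50) {
    p <- c(runif(2), runif(2, 0.05, 0.6))
    g <- c(runif(2), runif(2, 0.05, 0.6))
    sc <- sample(c(0, 0.5, 1), 1)
    expect_equal(shapeIoULoss(p, g, scale = sc),
                 shapeIoUOracle(p, g, scale = sc), tolerance = 1e-10)
  }
  expect_error(shapeIoULoss(c(0.5, 0.5, 0.2, 0.2), c(0.5, 0.5, 0, 0.2)),
               "positive")
})

test_that("shape-IoU: zero exponent, nonnegativity, translation invariance", {
  set.seed(6)
  for (i in 1:50) {
    p <- c(runif(2), runif(2, 0.05, 0.6))
    g <- c(runif(2), runif(2, 0.05, 0.6))
    l <- shapeIoULoss(p, g)
    expect_gte(l, 0)
    # scale = 0 makes the loss independent of the gt aspect weighting:
    # swapping gt width/height while swapping the matching pred axes too
    # (a transpose of the geometry) leaves the loss unchanged
    expect_equal(shapeIoULoss(p[c(2, 1, 4, 3)], g[c(2, 1, 4, 3)], scale = 0),
                 l, tolerance = 1e-12)
    # joint translation leaves the loss unchanged
    d <- runif(2, -3, 3)
    expect_equal(shapeIoULoss(p + c(d, 0, 0), g + c(d, 0, 0)), l,
                 tolerance = 1e-9)
  }
  # loss is 0 iff prediction equals ground truth
  expect_gt(shapeIoULoss(c(0.5, 0.5, 0.21, 0.2), c(0.5, 0.5, 0.2, 0.2)), 0)
})

test_that("analytic shape-IoU gradient matches central differences", {
  set.seed(7)
  worst <- 0
  for (i in 1:100) {
    p <- c(runif(2), runif(2, 0.05, 0.5))
    g <- c(runif(2), runif(2, 0.05, 0.5))
    sl <- shapeIoULoss(p, g, gradient = TRUE)
    h <- 1e-6
    num <- vapply(1:4, function(j) {
      pp <- p; pp[j] <- pp[j] + h
      pm <- p; pm[j] <- pm[j] - h
      (shapeIoULoss(pp, g) - shapeIoULoss(pm, g)) / (2 * h)
    }, numeric(1))
    worst <- max(worst, max(abs(num - sl$grad) / pmax(abs(num), 1e-3)))
  }
  expect_lt(worst, 1e-4)
})

test_that("slide weighting follows the three-branch form and bounds", {
  expect_equal(slideWeight(0.3, 0.5), 1)
  expect_equal(slideWeight(0.45, 0.5), exp(0.5))
  expect_equal(slideWeight(1, 0.5), 1)
  set.seed(8)
  for (i in 1:200) {
    mu <- runif(1, 0.05, 0.95); x <- runif(1)
    w <- slideWeight(x, mu)
    expect_gte(w, 1)
    ref <- if (x <= mu - 0.1) 1 else if (x < mu) exp(1 - mu) else exp(1 - x)
    expect_equal(w, ref)
  }
  # monotone non-increasing on [mu, 1]
  xs <- seq(0.4, 1, by = 0.01)
  expect_true(all(diff(slideWeight(xs, 0.4)) <= 1e-12))
})

test_that("slide-weighted BCE composes weights with plain BCE", {
  set.seed(9)
  p <- matrix(runif(30, 0.01, 0.99), 10)
  t <- matrix(rbinom(30, 1, 0.5), 10)
  plain <- -mean(t * log(p) + (1 - t) * log(1 - p))
  expect_equal(slideBce(p, t, weights = 1), plain)
  expect_lt(slideBce(matrix(c(1, 0), 1), matrix(c(1, 0), 1)), 1e-10)
  # oracle composition on known IoUs
  ious <- c(0.2, 0.6, 0.9); mu <- 0.55
  w <- slideWeight(ious, mu)
  expect_equal(w, c(1, exp(0.4), exp(0.1)))
  ps <- c(0.8, 0.6, 0.9); ts <- c(1, 1, 1)
  expect_equal(slideBce(ps, ts, w), mean(-log(ps) * w))
})

test_that("distribution-focal loss brackets continuous targets", {
  # integer target: plain cross-entropy against that bin
  z <- rnorm(16)
  p <- exp(z) / sum(exp(z))
  expect_equal(dflLoss(z, 5), -log(p[6]), tolerance = 1e-12)
  # uniform logits: log(16) regardless of target
  expect_equal(dflLoss(matrix(0, 1, 16), 3.7), log(16))
  expect_equal(dflLoss(matrix(0, 1, 16), 11), log(16))
  # linear bracketing identity at 3.7
  expect_equal(dflLoss(z, 3.7), 0.3 * -log(p[4]) + 0.7 * -log(p[5]),
               tolerance = 1e-12)
  # decode identity: one-hot spike at bin b decodes to b
  for (b in c(0, 3, 15)) {
    spike <- rep(-30, 16); spike[b + 1] <- 30
    expect_equal(dflDecode(spike), b, tolerance = 1e-9)
  }
})

test_that("task-aligned assignment matches a brute-force oracle", {
  # single gt with a single centered anchor
  a1 <- assignTargets(matrix(c(5, 5), 1), matrix(c(2, 2, 8, 8), 1),
                      matrix(0.9, 1, 1), matrix(c(1, 1, 9, 9), 1), 0L)
  expect_identical(a1$gtIndex, 1L)
  # zero ground truths: all negatives
  a0 <- assignTargets(matrix(c(5, 5), 1), matrix(c(2, 2, 8, 8), 1),
                      matrix(0.9, 1, 1), NULL, integer())
  expect_identical(a0$gtIndex, 0L)
  expect_true(all(a0$targetScores == 0))

  set.seed(10)
  for (rep in 1:20) {
    nA <- 20; nG <- 3; nC <- 4
    ap <- cbind(runif(nA, 0, 32), runif(nA, 0, 32))
    pb <- t(apply(cbind(runif(nA, 0, 28), runif(nA, 0, 28)), 1, function(z)
      c(z[1], z[2], z[1] + runif(1, 2, 8), z[2] + runif(1, 2, 8))))
    ps <- matrix(runif(nA * nC), nA, nC)
    gb <- t(replicate(nG, {
      x <- runif(1, 2, 20); y <- runif(1, 2, 20)
      c(x, y, x + runif(1, 4, 12), y + runif(1, 4, 12))
    }))
    gc <- sample(0:(nC - 1), nG, replace = TRUE)
    got <- assignTargets(ap, pb, ps, gb, gc, topk = 5)
    # exhaustive oracle over the alignment metric
    metric <- matrix(0, nA, nG); ov <- matrix(0, nA, nG)
    for (a in 1:nA) for (j in 1:nG) {
      inside <- ap[a, 1] > gb[j, 1] && ap[a, 1] < gb[j, 3] &&
        ap[a, 2] > gb[j, 2] && ap[a, 2] < gb[j, 4]
      ov[a, j] <- boxIoU(pb[a, ], gb[j, ])
      metric[a, j] <- if (inside) ps[a, gc[j] + 1]^0.5 * ov[a, j]^6 else 0
    }
    expIdx <- integer(nA)
    cand <- matrix(FALSE, nA, nG)
    for (j in 1:nG) {
      ord <- order(metric[, j], decreasing = TRUE)
      ord <- ord[metric[ord, j] > 0]
      cand[head(ord, 5), j] <- TRUE
    }
    for (a in 1:nA) {
      js <- which(cand[a, ])
      if (length(js)) expIdx[a] <- js[which.max(ov[a, js])]
    }
    expect_identical(got$gtIndex, expIdx)
  }
})
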