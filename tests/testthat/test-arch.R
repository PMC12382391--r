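test_that("closed-form block parameter counts", {
  expect_identical(convBlockParams(16, 32, 3), 4672)
  expect_identical(convBlockParams(1, 1, 1), 3)
  expect_identical(convBlockParams(128, 256, 3), 295424)
  expect_identical(ghostConvParams(16, 32), 2768)
  expect_identical(ghostConvParams(128, 256), 151168)
  # per-layer savings of the four ghost replacements, and their total
  savings <- vapply(list(c(16, 32), c(32, 64), c(64, 128), c(128, 256)),
                    function(p) convBlockParams(p[1], p[2], 3) -
                      ghostConvParams(p[1], p[2]), numeric(1))
  expect_equal(savings, c(1904, 8416, 35264, 144256))
  expect_equal(sum(savings), 189840)
  expect_identical(caBlockParams(384), 149382)
})

test_that("compression and speed-up ratios evaluate the rational forms", {
  expect_equal(compressionRatio(2, 256, 3, 3), 2 * 256 / (2 + 256 - 1))
  expect_equal(compressionRatio(1, 64, 3, 5), 1)
  expect_equal(speedupRatio(1, 64, 3, 5, hw = 100, n = 32), 1)
  expect_equal(speedupRatio(2, 256, 3, 3, hw = 7, n = 11),
               compressionRatio(2, 256, 3, 3))
  # the ratio tends to s as channels grow
  expect_lt(abs(compressionRatio(2, 1e9, 3, 5) - 2), 1e-6)
  expect_lt(abs(compressionRatio(4, 1e9, 3, 5) - 4), 1e-6)
})

test_that("live model parameter counts match the closed forms", {
  set.seed(1)
  base <- countParams(buildModel(modelConfig(nClasses = 15)))
  ghost <- countParams(buildModel(modelConfig(nClasses = 15, ghost = TRUE)))
  expect_equal(totalParams(base) - totalParams(ghost), 189840)
  ca <- countParams(buildModel(modelConfig(nClasses = 15, ca = TRUE)))
  expect_equal(totalParams(ca) - totalParams(base), caBlockParams(384))
  # every variant freezes exactly the 16-bin decode projection
  for (pr in list(base, ghost, ca))
    expect_equal(totalParams(pr) - trainableParams(pr), 16)
  # ghost layers in the live model match ghostConvParams per replaced layer
  m <- buildModel(modelConfig(nClasses = 15, ghost = TRUE))
  per <- countParams(m)@perLayer
  expect_equal(per$params[per$name == "ghost1"], ghostConvParams(16, 32))
  expect_equal(per$params[per$name == "ghost3"], ghostConvParams(32, 64))
  expect_equal(per$params[per$name == "ghost5"], ghostConvParams(64, 128))
  expect_equal(per$params[per$name == "ghost7"], ghostConvParams(128, 256))
})

test_that("ghost forward: shapes, zero propagation, identity cheap branch", {
  set.seed(2)
  g <- ghostConv(16, 32)
  out <- ghostForward(g, array(rnorm(64 * 64 * 16), c(64, 64, 16)))
  expect_equal(dim(out), c(32L, 32L, 32L))
  expect_error(ghostForward(g, array(0, c(64, 64, 8))), "channel")
  # zero input stays zero through bias-free conv + batch norm + SiLU
  z <- ghostForward(g, array(0, c(16, 16, 16)))
  expect_true(all(z == 0))
  # cheap branch with a centered delta kernel, norm and activation bypassed,
  # reproduces the intrinsic half exactly
  g2 <- ghostConv(16, 32)
  g2$cheap$Wd[] <- 0
  g2$cheap$Wd[13, ] <- 1           # center tap of the 5x5 kernel
  g2$cheap$rm[] <- 0; g2$cheap$rv[] <- 1 - 1e-3
  g2$cheap$bng[] <- 1; g2$cheap$bnb[] <- 0
  g2$cheap$act <- FALSE
  out2 <- ghostForward(g2, array(rnorm(32 * 32 * 16), c(32, 32, 16)),
                       train = FALSE)
  expect_equal(out2[, , 17:32], out2[, , 1:16], tolerance = 1e-12)
})

test_that("context aggregation block: residual identity, softmax, N = 1", {
  set.seed(3)
  ca <- caBlock(8)
  x <- array(rnorm(6 * 5 * 8), c(6, 5, 8))
  # zero value projection recovers the identity on any input
  ca$pv$W[] <- 0; ca$pv$b[] <- 0
  expect_equal(caForward(ca, x), x, tolerance = 1e-12)
  # attention weights over positions sum to 1
  ca2 <- caBlock(8)
  invisible(caForward(ca2, x, train = TRUE))
  expect_equal(sum(ca2$cc$s), 1, tolerance = 1e-6)
  expect_equal(sum(ca2$cc$a), 1, tolerance = 1e-6)
  expect_error(caForward(ca2, array(0, c(6, 5, 4))), "channel")
  # single spatial position: both softmaxes degenerate to 1, Q = P + v(P)
  ca3 <- caBlock(8)
  p1 <- array(rnorm(8), c(1, 1, 8))
  vProj <- (matrix(p1, 1, 8) %*% ca3$pv$W + ca3$pv$b) / sqrt(1 + 1e-3)
  q <- caForward(ca3, p1, train = FALSE)
  expect_equal(as.vector(q), as.vector(p1) + as.vector(vProj),
               tolerance = 1e-10)
})

test_that("full-size forward yields the three stride maps", {
  set.seed(4)
  m <- buildModel(modelConfig(nClasses = 15, ghost = TRUE, ca = TRUE))
  maps <- forwardPass(m, list(array(0.5, c(640, 640, 3))))
  expect_equal(vapply(maps, function(x) dim(x)[1], numeric(1)), c(80, 40, 20))
  expect_equal(vapply(maps, function(x) dim(x)[2], numeric(1)), c(80, 40, 20))
  expect_true(all(vapply(maps, function(x) dim(x)[3], numeric(1)) ==
                    4 * 16 + 15))
  expect_error(forwardPass(m, list(array(0.5, c(100, 100, 3)))), "32")
})
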