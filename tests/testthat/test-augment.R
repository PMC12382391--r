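pt <- function(p, M) as.vector(c(p, 1) %*% M)[1:2]

test_that("affine primitives reproduce their defining point maps", {
  expect_equal(rotationMatrix(0), diag(3))
  expect_equal(pt(c(1, 0), rotationMatrix(90)), c(0, 1), tolerance = 1e-12)
  expect_equal(pt(c(2, 1), rotationMatrix(30)),
               c(2 * cos(pi / 6) - sin(pi / 6),
                 2 * sin(pi / 6) + cos(pi / 6)), tolerance = 1e-12)
  expect_equal(shearMatrix(0), diag(3))
  expect_equal(pt(c(0, 1), shearMatrix(90)), c(1, 0), tolerance = 1e-12)
  expect_equal(pt(c(1, 2), shearMatrix(45)),
               c(1 + 2 * sqrt(2) / 2, 2 * sqrt(2) / 2), tolerance = 1e-12)
  expect_equal(shiftMatrix(0, 0), diag(3))
  expect_equal(pt(c(1, 1), shiftMatrix(3, -2)), c(4, -1))
  expect_equal(scaleMatrix(1, 1), diag(3))
  expect_equal(pt(c(4, 4), scaleMatrix(2, 0.5)), c(8, 2))
  expect_error(scaleMatrix(0, 1), "nonzero")
})

test_that("affine matrices form a group in the row-vector convention", {
  expect_equal(rotationMatrix(37) %*% rotationMatrix(-37), diag(3),
               tolerance = 1e-12)
  expect_equal(shiftMatrix(2, 3) %*% shiftMatrix(-5, 7), shiftMatrix(-3, 10))
  set.seed(4)
  for (i in 1:10) {
    A <- rotationMatrix(runif(1, -180, 180))
    B <- shearMatrix(runif(1, -45, 45))
    C <- shiftMatrix(runif(1, -9, 9), runif(1, -9, 9))
    expect_lt(max(abs((A %*% B) %*% C - A %*% (B %*% C))), 1e-12)
    # last column stays (0,0,1)'
    expect_equal((A %*% B %*% C)[, 3], c(0, 0, 1))
  }
})

test_that("applyAffine transforms image and boxes consistently", {
  li <- centeredBoxImage(64, w = 0.2, h = 0.1)
  id <- applyAffine(li, diag(3))
  expect_equal(imageData(id), imageData(li), tolerance = 1e-9)
  expect_equal(unname(boxes(id)), unname(boxes(li)), tolerance = 1e-12)
  # 90-degree rotation about the canvas center: (cx,cy,w,h) -> (1-cy,cx,h,w)
  li2 <- labeledImage(array(0.5, c(64, 64, 3)), cbind(0, 0.5, 0.25, 0.2, 0.1))
  r <- boxes(applyAffine(li2, rotationMatrix(90)))
  expect_equal(unname(r), unname(cbind(0, 0.75, 0.5, 0.1, 0.2)),
               tolerance = 1e-9)
  expect_error(applyAffine(li, matrix(0, 3, 3)), "invertible")
})

test_that("transformed box hulls agree with a dense boundary-point oracle", {
  set.seed(11)
  for (rep in 1:4) {
    trans <- rotationMatrix(runif(1, -40, 40)) %*%
      shearMatrix(runif(1, -20, 20)) %*%
      scaleMatrix(runif(1, 0.7, 1.3), runif(1, 0.7, 1.3)) %*%
      shiftMatrix(runif(1, -5, 5), runif(1, -5, 5))
    nb <- 50
    bx <- cbind(sample(0:4, nb, TRUE), runif(nb, 0.35, 0.65),
                runif(nb, 0.35, 0.65), runif(nb, 0.05, 0.2),
                runif(nb, 0.05, 0.2))
    li <- labeledImage(array(0.5, c(100, 100, 3)), bx)
    out <- applyAffine(li, trans, areaThresh = 0, minSide = 0)
    # oracle: map 1000 boundary points of each box through the same
    # center-conjugated transform and take their min/max hull
    M <- shiftMatrix(-50, -50) %*% trans %*% shiftMatrix(50, 50)
    for (i in seq_len(nb)) {
      cr <- centerToCorner(bx[i, 2:5, drop = FALSE], 100, 100)
      t <- seq(0, 1, length.out = 250)
      per <- rbind(cbind(cr[1] + t * (cr[3] - cr[1]), cr[2]),
                   cbind(cr[1] + t * (cr[3] - cr[1]), cr[4]),
                   cbind(cr[1], cr[2] + t * (cr[4] - cr[2])),
                   cbind(cr[3], cr[2] + t * (cr[4] - cr[2])))
      mp <- cbind(per, 1) %*% M
      hull <- c(max(min(mp[, 1]), 0), max(min(mp[, 2]), 0),
                min(max(mp[, 1]), 100), min(max(mp[, 2]), 100))
      got <- centerToCorner(boxes(out)[i, 2:5, drop = FALSE], 100, 100)
      expect_equal(as.vector(got), hull, tolerance = 1e-6)
    }
  }
})

test_that("apply_affine never emits a box outside the unit square", {
  set.seed(12)
  for (rep in 1:10) {
    trans <- rotationMatrix(runif(1, -180, 180)) %*%
      shiftMatrix(runif(1, -40, 40), runif(1, -40, 40)) %*%
      scaleMatrix(runif(1, 0.3, 2), runif(1, 0.3, 2))
    bx <- cbind(0, runif(8), runif(8), runif(8, 0.05, 0.3),
                runif(8, 0.05, 0.3))
    bx[, 2] <- pmin(pmax(bx[, 2], bx[, 4] / 2), 1 - bx[, 4] / 2)
    bx[, 3] <- pmin(pmax(bx[, 3], bx[, 5] / 2), 1 - bx[, 5] / 2)
    out <- boxes(applyAffine(labeledImage(array(0.5, c(64, 64, 3)), bx),
                             trans))
    if (nrow(out)) {
      crn <- centerToCorner(out[, 2:5, drop = FALSE], 1, 1)
      expect_true(all(crn >= -1e-9 & crn <= 1 + 1e-9))
    }
  }
})

test_that("RGB to HSV follows the hexcone formulas with the +360 wrap", {
  expect_equal(as.vector(rgbToHsv(c(1, 0, 0))), c(0, 1, 1))
  expect_equal(as.vector(rgbToHsv(c(0.5, 0.5, 0.5))), c(0, 0, 0.5))
  expect_equal(as.vector(rgbToHsv(c(1, 0, 0.5))), c(330, 1, 1))
  expect_error(rgbToHsv(c(1.2, 0, 0)), "0,1")
  # bounds hold on a 17^3 RGB grid
  g <- seq(0, 1, length.out = 17)
  hsv <- rgbToHsv(as.matrix(expand.grid(g, g, g)))
  expect_true(all(hsv[, 1] >= 0 & hsv[, 1] <= 360))
  expect_true(all(hsv[, 2] >= 0 & hsv[, 2] <= 1))
  expect_true(all(hsv[, 3] >= 0 & hsv[, 3] <= 1))
  # round trip within the 8-bit quantization budget
  back <- hsvToRgb(hsv)
  expect_lte(max(abs(back - as.matrix(expand.grid(g, g, g)))), 2 / 255)
})

test_that("HSV jitter respects gains and clipping", {
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  set.seed(1)
  expect_equal(hsvJitter(img, gains = c(0, 0, 0)), img, tolerance = 1e-9)
  # value gain forced to zero: black image (clip floor)
  img2 <- img
  hsv <- rgbToHsv(img2); hsv[, , 3] <- 0
  expect_true(all(hsvToRgb(hsv) == 0))
})

test_that("letterbox stretch and pad modes", {
  r0 <- letterbox(array(0.5, c(640, 640, 3)))
  expect_equal(c(r0$scaleX, r0$scaleY), c(1, 1))
  expect_equal(dim(imageData(r0$image)), c(640L, 640L, 3L))
  # stretch always yields exactly the target
  r1 <- letterbox(array(0.5, c(123, 457, 3)), target = c(640, 640))
  expect_equal(dim(imageData(r1$image))[1:2], c(640L, 640L))
  expect_equal(r1$pad, c(0L, 0L))
  # pad mode with the min ratio and symmetric gray padding
  r2 <- letterbox(array(0.5, c(1325, 2000, 3)), target = c(640, 640),
                  mode = "pad")
  expect_equal(r2$scaleX, 0.32)
  expect_equal(r2$pad, c(0, 108))
  expect_error(letterbox(array(0.5, c(8, 8, 3)), target = c(0, 640)),
               "positive")
})

test_that("mosaic places four images on a 2x2 board with remapped labels", {
  li <- centeredBoxImage(64, w = 0.25, h = 0.25)
  m <- mosaic(list(li, li, li, li), board = 128)
  expect_equal(dim(imageData(m)), c(128L, 128L, 3L))
  bx <- boxes(m)
  expect_identical(nrow(bx), 4L)
  # one box per quadrant, at the quadrant centers
  expect_equal(sort(bx[, 2]), c(0.25, 0.25, 0.75, 0.75))
  expect_equal(sort(bx[, 3]), c(0.25, 0.25, 0.75, 0.75))
  expect_equal(unname(bx[, 4:5]), matrix(0.125, 4, 2))
  # empty inputs stay empty
  e <- labeledImage(array(0.5, c(64, 64, 3)))
  expect_identical(nrow(boxes(mosaic(list(e, e, e, e), board = 128))), 0L)
  expect_error(mosaic(list(li, li, li), board = 128), "4")
  # per-quadrant offset arithmetic oracle
  lis <- lapply(1:4, function(i)
    labeledImage(array(0.5, c(64, 64, 3)),
                 cbind(i, 0.1 * i, 0.15 * i, 0.1, 0.2)))
  m2 <- mosaic(lis, board = 256)
  offs <- list(c(0, 0), c(0.5, 0), c(0, 0.5), c(0.5, 0.5))
  for (q in 1:4) {
    row <- boxes(m2)[q, ]
    expect_equal(unname(row[2:5]),
                 c(0.1 * q / 2 + offs[[q]][1], 0.15 * q / 2 + offs[[q]][2],
                   0.05, 0.1), tolerance = 1e-12)
  }
})

test_that("mosaic conserves labels when nothing is clipped", {
  set.seed(21)
  lis <- lapply(1:4, function(i) {
    nb <- sample(0:3, 1)
    bx <- if (nb) cbind(sample(0:2, nb, TRUE), runif(nb, 0.3, 0.7),
                        runif(nb, 0.3, 0.7), runif(nb, 0.05, 0.15),
                        runif(nb, 0.05, 0.15))
          else matrix(numeric(), 0, 5)
    labeledImage(array(0.5, c(64, 64, 3)), bx)
  })
  total <- sum(vapply(lis, function(l) nrow(boxes(l)), integer(1)))
  expect_identical(nrow(boxes(mosaic(lis, board = 128))), total)
})

test_that("object-set augmentation multiplies every class count exactly", {
  set.seed(31)
  li1 <- centeredBoxImage(48, w = 0.3, h = 0.25, cls = 0)
  out1 <- augmentObjectSet(list(li1), multiplicity = 6)
  expect_length(out1, 6L)
  expect_identical(sum(vapply(out1, function(l) nrow(boxes(l)), integer(1))),
                   6L)
  # mixed classes over several images
  lis <- lapply(1:5, function(i) {
    nb <- sample(1:3, 1)
    labeledImage(array(0.5, c(48, 48, 3)),
                 cbind(sample(0:4, nb, TRUE), runif(nb, 0.35, 0.65),
                       runif(nb, 0.35, 0.65), runif(nb, 0.1, 0.2),
                       runif(nb, 0.1, 0.2)))
  })
  before <- table(factor(unlist(lapply(lis, function(l) boxes(l)[, 1])),
                         levels = 0:4))
  out <- augmentObjectSet(lis, multiplicity = 6)
  after <- table(factor(unlist(lapply(out, function(l) boxes(l)[, 1])),
                        levels = 0:4))
  expect_equal(as.vector(after), 6 * as.vector(before))
})
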