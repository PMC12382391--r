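test_that("scene generation is deterministic and honours the object range", {
  cfg <- sceneConfig(imageSize = 64, objectsPerImage = c(2, 5), seed = 7)
  s1 <- generateScene(cfg, 0)
  s2 <- generateScene(cfg, 0)
  expect_identical(s1@image, s2@image)
  expect_identical(instanceMasks(s1), instanceMasks(s2))
  expect_true(length(instanceMasks(s1)) >= 2 && length(instanceMasks(s1)) <= 5)
  # different scene index gives a different scene from the same root seed
  s3 <- generateScene(cfg, 1)
  expect_false(identical(s1@image, s3@image))
  # empty case
  s0 <- generateScene(sceneConfig(imageSize = 64,
                                  objectsPerImage = c(0, 0), seed = 1))
  expect_identical(length(instanceMasks(s0)), 0L)
  expect_error(sceneConfig(imageSize = 16), "32")
})

test_that("sampled class labels follow the configured frequencies", {
  cfg <- sceneConfig(imageSize = 32, objectsPerImage = c(6, 6),
                     occlusionProb = 0, blurProb = 0, seed = 123)
  labels <- unlist(lapply(0:1666, function(i)
    sceneLabels(generateScene(cfg, i))))
  expect_gte(length(labels), 10000)
  labels <- labels[1:10000]
  w <- cfg@classWeights / sum(cfg@classWeights)
  obs <- tabulate(labels + 1L, nbins = 15L)
  # chi-square goodness of fit, alpha = 0.01
  p <- stats::chisq.test(obs, p = w)$p.value
  expect_gt(p, 0.01)
  # every class frequency within 3 sigma of its multinomial expectation
  sigma <- sqrt(10000 * w * (1 - w))
  expect_true(all(abs(obs - 10000 * w) <= 3 * sigma + 1))
})

test_that("maskToBbox returns the tightest half-open box", {
  m <- matrix(FALSE, 8, 12); m[5, 10] <- TRUE
  expect_equal(unname(maskToBbox(m)), c(9, 4, 10, 5))
  m2 <- matrix(FALSE, 10, 10); m2[3:6, 4:8] <- TRUE
  expect_equal(unname(maskToBbox(m2)), c(3, 2, 8, 6))
  expect_error(maskToBbox(matrix(FALSE, 4, 4)), "foreground")
  # brute-force pixel-scan oracle on random sparse masks
  set.seed(3)
  for (i in 1:20) {
    m3 <- matrix(FALSE, 30, 40)
    idx <- sample(length(m3), 50)
    m3[idx] <- TRUE
    rc <- which(m3, arr.ind = TRUE)
    expect_equal(unname(maskToBbox(m3)),
                 c(min(rc[, 2]) - 1, min(rc[, 1]) - 1,
                   max(rc[, 2]), max(rc[, 1])))
  }
})

test_that("dataset writing: split, label format, round trip", {
  cfg <- sceneConfig(imageSize = 64, objectsPerImage = c(1, 3), seed = 5)
  scenes <- lapply(0:9, function(i) generateScene(cfg, i))
  d <- withr::local_tempdir()
  man <- writeDataset(scenes, d, splitRatio = 0.8, seed = 2)
  expect_length(man$train, 8L)
  expect_length(man$val, 2L)
  # identical write is byte-identical (determinism)
  d2 <- withr::local_tempdir()
  writeDataset(scenes, d2, splitRatio = 0.8, seed = 2)
  f1 <- list.files(d, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in grep("labels/", f1, value = TRUE))
    expect_identical(readLines(file.path(d, f)),
                     readLines(file.path(d2, f)))

  # exact normalization of a centered box
  li <- labeledImage(array(0, c(640, 640, 3)),
                     cbind(0, 0.5, 0.5, 0.1, 0.1))
  d3 <- withr::local_tempdir()
  writeDataset(list(li, li), d3, splitRatio = 0.5, seed = 0)
  lbl <- list.files(file.path(d3, "labels"), recursive = TRUE,
                    full.names = TRUE)[1]
  expect_identical(readLines(lbl), "0 0.500000 0.500000 0.100000 0.100000")

  # write -> read round trip within the 6-decimal label quantization
  set.seed(9)
  boxes100 <- cbind(sample(0:14, 100, TRUE),
                    runif(100, 0.3, 0.7), runif(100, 0.3, 0.7),
                    runif(100, 0.05, 0.2), runif(100, 0.05, 0.2))
  liBig <- labeledImage(array(0, c(640, 640, 3)), boxes100)
  d4 <- withr::local_tempdir()
  writeDataset(list(liBig, liBig), d4, splitRatio = 0.5, seed = 0)
  ds <- readDataset(file.path(d4, "dataset.yaml"))
  back <- readLabels(ds$train$label[1])
  expect_equal(nrow(back), 100L)
  expect_lte(max(abs(back[, 2:5] - boxes100[, 2:5])), 0.5 / 640)
  # scenes convert with full-extent boxes matching their masks
  sc <- scenes[[1]]
  li2 <- asLabeledImage(sc)
  expect_identical(nrow(boxes(li2)), length(instanceMasks(sc)))
})
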