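test_that("detection matching implements the single-claim greedy rule", {
  gt <- data.frame(image = "1", class = 0, cx = 0.5, cy = 0.5,
                   w = 0.2, h = 0.2)
  d1 <- data.frame(image = "1", class = 0, confidence = 0.9,
                   cx = 0.5, cy = 0.5, w = 0.2, h = 0.2)
  m1 <- matchDetections(d1, gt)
  expect_identical(m1$counts$TP, 1L)
  expect_identical(m1$counts$FP, 0L)
  expect_identical(m1$counts$FN, 0L)
  # two detections on one gt: one TP, one FP
  d2 <- rbind(d1, transform(d1, confidence = 0.8))
  m2 <- matchDetections(d2, gt)
  expect_identical(m2$counts$TP, 1L)
  expect_identical(m2$counts$FP, 1L)
  expect_error(matchDetections(transform(d1, confidence = 1.2), gt), "0,1")
})

test_that("precision/recall/F1 identities", {
  expect_equal(unname(precisionRecallF1(0, 0, 0)), c(0, 0, 0),
               ignore_attr = TRUE)
  expect_equal(unname(precisionRecallF1(9, 1, 3)[1, "P"]), 0.9)
  expect_equal(unname(precisionRecallF1(9, 1, 3)[1, "R"]), 0.75)
  # P = R = p gives F1 = p (harmonic-mean identity)
  for (p in c(0.1, 0.5, 0.92)) expect_equal(f1Score(p, p), p)
  # published ablation rows reproduce from their printed P and R
  expect_lt(abs(f1Score(0.86302, 0.70668) - 0.77706), 5e-6)
  expect_lt(abs(f1Score(0.89959, 0.82258) - 0.859363), 5e-6)
})

test_that("average precision: degenerate curves and both conventions", {
  # perfect detector: all TPs before any FP
  n <- 7
  expect_equal(averagePrecision((1:n) / n, rep(1, n)), 1)
  expect_equal(averagePrecision((1:n) / n, rep(1, n),
                                method = "continuous"), 1)
  # zero TP
  expect_equal(averagePrecision(rep(0, 4), rep(0, 4)), 0)
  # 5-detection toy curve against direct envelope evaluation
  tp <- c(1, 0, 1, 1, 0); nGt <- 4
  rec <- cumsum(tp) / nGt
  prec <- cumsum(tp) / 1:5
  expect_equal(averagePrecision(rec, prec), apOracle101(rec, prec))
  expect_equal(meanAP(c(1, 0)), 0.5)
  expect_equal(meanAP(rep(0.73, 5)), 0.73)
  expect_equal(mapRange(seq(0.95, 0.5, by = -0.05)), 0.725)
})

test_that("matching and AP agree with oracles on 1000 random toy cases", {
  set.seed(20)
  for (i in 1:1000) {
    case <- randomToyCase()
    thr <- sample(c(0.3, 0.5, 0.7), 1)
    got <- matchDetections(case$dets, case$gts, thr)
    expect_identical(got$tp, matchOracle(case$dets, case$gts, thr))
    # per-class AP against the direct envelope oracle
    for (cl in unique(case$gts$class)) {
      di <- which(case$dets$class == cl)
      nGt <- sum(case$gts$class == cl)
      if (!length(di)) next
      o <- order(case$dets$confidence[di], decreasing = TRUE)
      ctp <- cumsum(got$tp[di][o])
      rec <- ctp / nGt
      prec <- ctp / seq_along(ctp)
      expect_equal(averagePrecision(rec, prec), apOracle101(rec, prec))
    }
  }
})

test_that("AP monotonicity under extra detections and IoU thresholds", {
  set.seed(21)
  for (i in 1:20) {
    case <- randomToyCase(nDet = 8, nGt = 5)
    ev <- evaluateDetections(case$dets, case$gts)
    # threshold monotonicity: mAP@0.5 >= mAP@0.5:0.95
    expect_gte(map50(ev) + 1e-12, map5095(ev))
    # adding a low-confidence false positive never increases class AP
    fp <- data.frame(image = "1", class = case$gts$class[1],
                     confidence = 1e-4, cx = 0.01, cy = 0.01,
                     w = 0.01, h = 0.01)
    ev2 <- evaluateDetections(rbind(case$dets, fp), case$gts)
    cl <- case$gts$class[1]
    ap1 <- perClass(ev)$AP[perClass(ev)$class == cl]
    ap2 <- perClass(ev2)$AP[perClass(ev2)$class == cl]
    if (length(ap1) && length(ap2)) expect_lte(ap2, ap1 + 1e-12)
  }
})

test_that("evaluation on ground truth itself is perfect", {
  set.seed(22)
  gts <- do.call(rbind, lapply(1:3, function(im) {
    n <- 3
    data.frame(image = as.character(im), class = sample(0:2, n, TRUE),
               cx = runif(n, 0.3, 0.7), cy = runif(n, 0.3, 0.7),
               w = runif(n, 0.05, 0.2), h = runif(n, 0.05, 0.2))
  }))
  dets <- cbind(gts[, 1:2], confidence = 1, gts[, 3:6])
  ev <- evaluateDetections(dets, gts)
  expect_equal(map50(ev), 1)
  expect_equal(map5095(ev), 1)
  expect_true(all(perClass(ev)$F1 == 1))
})

test_that("detections round-trip through the text format", {
  d <- data.frame(image = c("a", "b"), class = c(0L, 3L),
                  confidence = c(0.9, 0.25), cx = c(0.5, 0.25),
                  cy = c(0.5, 0.75), w = c(0.1, 0.2), h = c(0.1, 0.05))
  f <- withr::local_tempfile()
  writeDetections(d, f)
  back <- readDetections(f)
  expect_equal(back$class, d$class)
  expect_equal(back$cx, d$cx, tolerance = 1e-6)
  expect_equal(readDetections(withr::local_tempfile())$class, integer(0))
})
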