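# Shared fixtures and independent oracles, built in code at test time.

# flat test image with one centered box
centeredBoxImage <- function(size = 64, w = 0.2, h = 0.1, cls = 0) {
  labeledImage(array(0.5, c(size, size, 3)), cbind(cls, 0.5, 0.5, w, h))
}

# scene configuration for trivially separable single-class blobs:
# one large high-contrast ellipse per image, no occlusion/blur/illumination
separableSceneConfig <- function(seed, imageSize = 64) {
  sceneConfig(imageSize = imageSize, nClasses = 15,
              classWeights = c(1, rep(0, 14)),
              objectsPerImage = c(1L, 1L), occlusionProb = 0,
              blurProb = 0, illuminationRange = c(1, 1),
              areaRange = c(0.15, 0.30), seed = seed)
}

# independent step-by-step evaluation of the shape-aware IoU loss, written
# directly from its defining formulas (scalar, no vectorisation, no shared
# code with the implementation)
shapeIoUOracle <- function(pred, gt, scale = 0, theta = 4, eps = 1e-7,
                           alpha = 1) {
  interW <- min(pred[1] + pred[3] / 2, gt[1] + gt[3] / 2) -
    max(pred[1] - pred[3] / 2, gt[1] - gt[3] / 2)
  interH <- min(pred[2] + pred[4] / 2, gt[2] + gt[4] / 2) -
    max(pred[2] - pred[4] / 2, gt[2] - gt[4] / 2)
  inter <- max(interW, 0) * max(interH, 0)
  un <- pred[3] * pred[4] + gt[3] * gt[4] - inter
  iou <- inter / un
  ww <- 2 * gt[3]^scale / (gt[3]^scale + gt[4]^scale)
  hh <- 2 * gt[4]^scale / (gt[3]^scale + gt[4]^scale)
  cw <- max(pred[1] + pred[3] / 2, gt[1] + gt[3] / 2) -
    min(pred[1] - pred[3] / 2, gt[1] - gt[3] / 2)
  ch <- max(pred[2] + pred[4] / 2, gt[2] + gt[4] / 2) -
    min(pred[2] - pred[4] / 2, gt[2] - gt[4] / 2)
  c2 <- (cw^2 + ch^2 + eps)^alpha
  dist <- hh * (pred[1] - gt[1])^2 / c2 + ww * (pred[2] - gt[2])^2 / c2
  omw <- hh * abs(pred[3] - gt[3]) / max(pred[3], gt[3])
  omh <- ww * abs(pred[4] - gt[4]) / max(pred[4], gt[4])
  1 - iou + dist + 0.5 * ((1 - exp(-omw))^theta + (1 - exp(-omh))^theta)
}

# independent greedy matcher: per class, detections in descending confidence
# claim the unmatched ground truth of highest IoU above the threshold
matchOracle <- function(dets, gts, thr) {
  tp <- logical(nrow(dets))
  for (cl in unique(c(dets$class, gts$class))) {
    di <- which(dets$class == cl)
    gi <- which(gts$class == cl)
    used <- logical(length(gi))
    for (k in di[order(-dets$confidence[di])]) {
      if (!length(gi)) break
      best <- -1; bestJ <- 0
      for (jj in seq_along(gi)) {
        if (used[jj]) next
        a <- c(dets$cx[k] - dets$w[k] / 2, dets$cy[k] - dets$h[k] / 2,
               dets$cx[k] + dets$w[k] / 2, dets$cy[k] + dets$h[k] / 2)
        g <- gi[jj]
        b <- c(gts$cx[g] - gts$w[g] / 2, gts$cy[g] - gts$h[g] / 2,
               gts$cx[g] + gts$w[g] / 2, gts$cy[g] + gts$h[g] / 2)
        iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
        ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
        iou <- iw * ih / ((a[3] - a[1]) * (a[4] - a[2]) +
                            (b[3] - b[1]) * (b[4] - b[2]) - iw * ih)
        if (iou > best) { best <- iou; bestJ <- jj }
      }
      if (bestJ > 0 && best >= thr) { used[bestJ] <- TRUE; tp[k] <- TRUE }
    }
  }
  tp
}

# direct evaluation of the interpolated precision envelope at the 101 grid
# points, by explicit maximisation (no shared code with averagePrecision)
apOracle101 <- function(recall, precision) {
  grid <- seq(0, 1, length.out = 101)
  vals <- vapply(grid, function(g) {
    sel <- recall >= g - 1e-12
    if (!any(sel)) 0 else max(precision[sel])
  }, numeric(1))
  mean(vals)
}

# random toy detection problem on a single image
randomToyCase <- function(nDet = 6, nGt = 4, nCls = 2) {
  mkBox <- function(n) {
    cx <- runif(n, 0.2, 0.8); cy <- runif(n, 0.2, 0.8)
    w <- runif(n, 0.05, 0.4); h <- runif(n, 0.05, 0.4)
    cbind(cx, cy, w, h)
  }
  d <- mkBox(nDet); g <- mkBox(nGt)
  list(dets = data.frame(image = "1", class = sample(0:(nCls - 1), nDet,
                                                     replace = TRUE),
                         confidence = runif(nDet), cx = d[, 1], cy = d[, 2],
                         w = d[, 3], h = d[, 4]),
       gts = data.frame(image = "1", class = sample(0:(nCls - 1), nGt,
                                                    replace = TRUE),
                        cx = g[, 1], cy = g[, 2], w = g[, 3], h = g[, 4]))
}
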