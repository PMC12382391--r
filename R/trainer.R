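# Training and prediction driver: wires the synthetic data / augmentation /
# architecture / loss / metric layers together. SGD with momentum, cosine
# learning-rate decay with linear warmup (separate bias group), mosaic
# augmentation disabled for the final closeMosaic epochs, per-epoch JSON
# history, best checkpoint by validation mAP@0.5.

#' Learning-rate schedule of a training run
#'
#' Cosine decay from \code{lr0} to \code{lr0 * lrf} across epochs, with
#' linear warmup over the first \code{warmupEpochs} epochs: the weight group
#' warms from 0, the bias group from \code{warmupBiasLr}. The momentum
#' warmup value is clamped at the nominal momentum.
#'
#' @param cfg a \code{\link{trainConfig}}.
#' @param nBatches batches per epoch.
#' @return data.frame with one row per iteration: \code{iter}, \code{epoch},
#'   \code{lr}, \code{biasLr}.
#' @export
lrSchedule <- function(cfg, nBatches) {
  epochFactor <- function(e)
    ((1 + cos(pi * (e - 1) / cfg@epochs)) / 2) * (1 - cfg@lrf) + cfg@lrf
  nw <- max(round(cfg@warmupEpochs * nBatches), 1L)
  rows <- lapply(seq_len(cfg@epochs), function(e) {
    lrE <- cfg@lr0 * epochFactor(e)
    it <- (e - 1L) * nBatches + seq_len(nBatches)
    warm <- pmin(it / nw, 1)
    data.frame(iter = it, epoch = e,
               lr = warm * lrE,
               biasLr = cfg@warmupBiasLr + warm * (lrE - cfg@warmupBiasLr))
  })
  do.call(rbind, rows)
}

#' Recalibrate batch-norm running statistics
#'
#' Replaces every batch-norm layer's running mean/variance by the exact
#' average of the batch statistics over a set of forward passes. Useful in
#' short training runs, where the default exponential update (momentum 0.03)
#' has not yet converged to the activation distribution.
#'
#' @param model a model from \code{\link{buildModel}}.
#' @param images list of H x W x 3 arrays or \code{LabeledImage}s.
#' @param batch images per calibration batch.
#' @return Invisibly, the model (updated in place).
#' @export
calibrateBatchNorm <- function(model, images, batch = 8L) {
  stopifnot(inherits(model, "ricePestModel"))
  imgs <- lapply(images, function(x) if (is(x, "LabeledImage")) x@image else x)
  bnLeaves <- Filter(function(l) isTRUE(l$useBn) || l$type == "dwconv",
                     model$leaves)
  nbat <- ceiling(length(imgs) / batch)
  for (b in seq_len(nbat)) {
    idx <- ((b - 1L) * batch + 1L):min(b * batch, length(imgs))
    for (l in bnLeaves) l$bnMom <- 1 / b   # cumulative mean of batch stats
    modelForwardT(model, tensorFromImages(imgs[idx]), train = TRUE)
  }
  for (l in bnLeaves) l$bnMom <- 0.03
  invisible(model)
}

# Load a split into memory as letterboxed LabeledImages at imgsz.
#' @noRd
loadSplit <- function(df, imgsz) {
  lapply(seq_len(nrow(df)), function(i) {
    li <- readLabeledImage(df$image[i], df$label[i])
    letterbox(li, target = c(imgsz, imgsz))$image
  })
}

# LabeledImage -> ground-truth list for the loss (pixel corner boxes).
#' @noRd
gtFromLabeled <- function(li, imgsz) {
  bx <- li@boxes
  if (!nrow(bx)) return(list(boxes = matrix(numeric(), 0L, 4L),
                             classes = integer()))
  list(boxes = centerToCorner(bx[, 2:5, drop = FALSE], imgsz, imgsz),
       classes = as.integer(bx[, 1L]))
}

#' Train a detector
#'
#' @param model a model from \code{\link{buildModel}}.
#' @param data path to a dataset YAML (see \code{\link{writeDataset}}) or the
#'   list returned by \code{\link{readDataset}}.
#' @param cfg a \code{\link{trainConfig}}.
#' @param boxLoss "shape_iou" (default) or "iou" (ablation baseline).
#' @param clsLoss "slide" (default) or "bce".
#' @param mu slide threshold: "auto" (mean IoU of the batch's positive
#'   samples) or a fixed value in (0,1).
#' @param shapeScale shape-scale exponent of the box loss (default 0).
#' @param historyPath optional JSON file receiving the per-epoch history.
#' @param valConf confidence threshold for validation predictions.
#' @param verbose print per-epoch progress.
#' @return Invisibly, a list: \code{model} (parameters set to the best
#'   validation checkpoint), \code{history} (data.frame: epoch, boxLoss,
#'   clsLoss, dflLoss, valMap50, valMap5095, lr, mosaicBatches),
#'   \code{bestEpoch}, \code{bestMap50}.
#' @export
trainModel <- function(model, data, cfg = trainConfig(),
                       boxLoss = "shape_iou", clsLoss = "slide", mu = "auto",
                       shapeScale = 0, historyPath = NULL, valConf = 0.001,
                       verbose = interactive()) {
  stopifnot(inherits(model, "ricePestModel"))
  validObject(cfg)
  if (is.character(data)) data <- readDataset(data)
  if (nrow(data$train) == 0L) stop("training split is empty")
  imgsz <- cfg@imgsz
  if (imgsz %% 32L != 0L) stop("imgsz must be divisible by 32")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(cfg@seed)

  train <- loadSplit(data$train, imgsz)
  val <- if (nrow(data$val)) loadSplit(data$val, imgsz) else list()
  nTrain <- length(train)
  nb <- ceiling(nTrain / cfg@batch)
  sched <- lrSchedule(cfg, nb)
  gains <- c(box = cfg@boxGain, cls = cfg@clsGain, dfl = cfg@dflGain)

  history <- data.frame()
  bestMap <- -Inf; bestEpoch <- 0L; bestParams <- NULL; sinceBest <- 0L
  iter <- 0L
  for (epoch in seq_len(cfg@epochs)) {
    useMosaic <- epoch <= cfg@epochs - cfg@closeMosaic
    perm <- sample.int(nTrain)
    eBox <- 0; eCls <- 0; eDfl <- 0; mosaicBatches <- 0L
    for (b in seq_len(nb)) {
      idx <- perm[((b - 1L) * cfg@batch + 1L):min(b * cfg@batch, nTrain)]
      batch <- lapply(idx, function(i) {
        if (useMosaic) {
          quad <- train[sample.int(nTrain, 4L, replace = TRUE)]
          m <- mosaic(quad, board = 2L * imgsz, augmentFn = simpleAugment)
          letterbox(m, target = c(imgsz, imgsz))$image
        } else train[[i]]
      })
      if (useMosaic) mosaicBatches <- mosaicBatches + 1L
      levels <- modelForwardT(model, tensorFromImages(
        lapply(batch, function(li) li@image)), train = TRUE)
      gtList <- lapply(batch, gtFromLabeled, imgsz = imgsz)
      ls <- detectionLossAndGrad(levels, gtList, model$strides,
                                 model$cfg@nClasses, model$cfg@regMax,
                                 gains = gains, boxLoss = boxLoss,
                                 clsLoss = clsLoss, mu = mu,
                                 shapeScale = shapeScale)
      zeroGrads(model)
      modelBackwardT(model, ls$grads)
      iter <- iter + 1L
      s <- sched[iter, ]
      sgdStep(model, lr = s$lr, lrBias = s$biasLr,
              momentum = min(cfg@momentum, cfg@warmupMomentum),
              wd = cfg@weightDecay)
      eBox <- eBox + ls$box; eCls <- eCls + ls$cls; eDfl <- eDfl + ls$dfl
    }
    eBox <- eBox / nb; eCls <- eCls / nb; eDfl <- eDfl / nb

    valMap50 <- NA_real_; valMap5095 <- NA_real_
    if (length(val)) {
      calibrateBatchNorm(model, train[seq_len(min(32L, nTrain))],
                         batch = cfg@batch)
      ev <- evaluateModel(model, val, confThreshold = valConf,
                          imgsz = imgsz)
      valMap50 <- ev@map50; valMap5095 <- ev@map5095
      if (valMap50 > bestMap) {
        bestMap <- valMap50; bestEpoch <- epoch
        bestParams <- getParamVector(model)
        sinceBest <- 0L
      } else sinceBest <- sinceBest + 1L
    }
    history <- rbind(history, data.frame(
      epoch = epoch, boxLoss = eBox, clsLoss = eCls, dflLoss = eDfl,
      valMap50 = valMap50, valMap5095 = valMap5095,
      lr = sched$lr[min(iter, nrow(sched))], mosaicBatches = mosaicBatches))
    if (verbose)
      message(sprintf(
        "epoch %d/%d box %.4f cls %.4f dfl %.4f val mAP50 %.4f",
        epoch, cfg@epochs, eBox, eCls, eDfl, valMap50))
    if (!is.null(historyPath))
      jsonlite::write_json(history, historyPath, dataframe = "rows",
                           auto_unbox = TRUE, digits = NA)
    if (length(val) && sinceBest >= cfg@patience) break
    if (any(!is.finite(c(eBox, eCls, eDfl))))
      stop("non-finite training loss")
  }
  if (!is.null(bestParams)) setParamVector(model, bestParams)
  invisible(list(model = model, history = history, bestEpoch = bestEpoch,
                 bestMap50 = if (is.finite(bestMap)) bestMap else NA_real_))
}

#' Decode a distribution-focal prediction to continuous offsets
#'
#' Expectation of the softmax over the bins: a one-hot logit spike at bin b
#' decodes to exactly b.
#'
#' @param predDist n x regMax matrix (or vector) of bin logits.
#' @return numeric vector of continuous offsets in \code{[0, regMax - 1]}.
#' @export
dflDecode <- function(predDist) {
  if (is.null(dim(predDist))) predDist <- matrix(predDist, nrow = 1L)
  as.vector(softmaxRows(predDist) %*% (0:(ncol(predDist) - 1L)))
}

# Greedy class-wise non-maximum suppression; boxes in corner form.
#' @noRd
nmsClasswise <- function(boxes, conf, cls, iouNms, maxDet) {
  keep <- integer(0)
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    idx <- idx[order(conf[idx], decreasing = TRUE)]
    while (length(idx)) {
      keep <- c(keep, idx[1L])
      if (length(idx) == 1L) break
      ious <- boxIoU(boxes[rep(idx[1L], length(idx) - 1L), , drop = FALSE],
                     boxes[idx[-1L], , drop = FALSE])
      idx <- idx[-1L][ious <= iouNms]
    }
  }
  head(keep[order(conf[keep], decreasing = TRUE)], maxDet)
}

#' Run a trained detector on images
#'
#' Images are letterboxed (stretch) to \code{imgsz}, passed through the
#' network, distribution-focal logits are decoded to boxes via the bin
#' expectation, class scores thresholded, and class-wise non-maximum
#' suppression applied.
#'
#' @param model a model from \code{\link{buildModel}} (trained).
#' @param images list of H x W x 3 arrays, \code{LabeledImage}s, or PNG
#'   paths; a single such object is also accepted.
#' @param confThreshold minimum class score (default 0.25).
#' @param iouNms non-maximum-suppression IoU threshold (default 0.7).
#' @param maxDet maximum detections per image (default 300).
#' @param imgsz network input size (divisible by 32).
#' @param imageIds identifiers for the \code{image} column (default indices).
#' @return data.frame of detections: \code{image}, \code{class} (0-based),
#'   \code{confidence}, \code{cx}, \code{cy}, \code{w}, \code{h}
#'   (normalized to the original image).
#' @export
predictModel <- function(model, images, confThreshold = 0.25, iouNms = 0.7,
                         maxDet = 300L, imgsz = 640L, imageIds = NULL) {
  stopifnot(inherits(model, "ricePestModel"))
  if (!is.list(images)) images <- list(images)
  imgs <- lapply(images, function(x) {
    if (is.character(x)) x <- readLabeledImage(x, "")@image
    if (is(x, "LabeledImage")) x <- x@image
    letterbox(x, target = c(imgsz, imgsz))$image@image
  })
  if (is.null(imageIds)) imageIds <- as.character(seq_along(imgs))
  N <- length(imgs)
  levels <- modelForwardT(model, tensorFromImages(imgs), train = FALSE)
  nc <- model$cfg@nClasses; regMax <- model$cfg@regMax
  nb <- 4L * regMax
  hw <- vapply(levels, function(t) t$H * t$W, integer(1L))
  anchors <- do.call(rbind, lapply(seq_along(levels), function(l)
    levelAnchors(levels[[l]]$H, levels[[l]]$W, model$strides[l])))
  strideA <- rep(model$strides, hw)
  out <- list()
  for (n in seq_len(N)) {
    Xn <- do.call(rbind, lapply(seq_along(levels), function(l)
      levels[[l]]$X[((n - 1L) * hw[l] + 1L):(n * hw[l]), , drop = FALSE]))
    E <- vapply(1:4, function(sd)
      dflDecode(Xn[, (sd - 1L) * regMax + seq_len(regMax), drop = FALSE]),
      numeric(nrow(Xn)))
    ltrb <- E * strideA
    boxesC <- cbind(anchors[, 1L] - ltrb[, 1L], anchors[, 2L] - ltrb[, 2L],
                    anchors[, 1L] + ltrb[, 3L], anchors[, 2L] + ltrb[, 4L])
    scores <- 1 / (1 + exp(-Xn[, nb + seq_len(nc), drop = FALSE]))
    hits <- which(scores >= confThreshold, arr.ind = TRUE)
    if (!nrow(hits)) next
    bx <- boxesC[hits[, 1L], , drop = FALSE]
    bx[, c(1L, 3L)] <- pmin(pmax(bx[, c(1L, 3L)], 0), imgsz)
    bx[, c(2L, 4L)] <- pmin(pmax(bx[, c(2L, 4L)], 0), imgsz)
    cf <- scores[hits]
    cl <- hits[, 2L] - 1L
    keep <- nmsClasswise(bx, cf, cl, iouNms, maxDet)
    if (!length(keep)) next
    cc <- cornerToCenter(bx[keep, , drop = FALSE], imgsz, imgsz)
    out[[length(out) + 1L]] <- data.frame(
      image = imageIds[n], class = cl[keep], confidence = cf[keep],
      cx = cc[, 1L], cy = cc[, 2L], w = cc[, 3L], h = cc[, 4L])
  }
  if (!length(out))
    return(data.frame(image = character(), class = integer(),
                      confidence = numeric(), cx = numeric(),
                      cy = numeric(), w = numeric(), h = numeric()))
  do.call(rbind, out)
}

#' Evaluate a detector on labelled images
#'
#' @param model a trained model.
#' @param images list of \code{LabeledImage}s (e.g. a loaded validation
#'   split).
#' @param confThreshold prediction confidence threshold (a low value such as
#'   0.001 is the usual validation setting).
#' @param iouNms,maxDet,imgsz see \code{\link{predictModel}}.
#' @return An \code{\link{EvalReport-class}}.
#' @export
evaluateModel <- function(model, images, confThreshold = 0.001,
                          iouNms = 0.7, maxDet = 300L, imgsz = 640L) {
  ids <- as.character(seq_along(images))
  dets <- predictModel(model, images, confThreshold = confThreshold,
                       iouNms = iouNms, maxDet = maxDet, imgsz = imgsz,
                       imageIds = ids)
  gts <- do.call(rbind, lapply(seq_along(images), function(i) {
    bx <- images[[i]]@boxes
    if (!nrow(bx)) return(NULL)
    data.frame(image = ids[i], class = as.integer(bx[, 1L]),
               cx = bx[, 2L], cy = bx[, 3L], w = bx[, 4L], h = bx[, 5L])
  }))
  if (is.null(gts))
    gts <- data.frame(image = character(), class = integer(),
                      cx = numeric(), cy = numeric(), w = numeric(),
                      h = numeric())
  evaluateDetections(dets, gts)
}

#' Save / load model weights
#'
#' Checkpoints store the model configuration and a flat parameter vector.
#'
#' @param model a model from \code{\link{buildModel}}.
#' @param path checkpoint file (RDS).
#' @return \code{saveModel}: invisibly, the path; \code{loadModel}: the
#'   rebuilt model.
#' @export
saveModel <- function(model, path) {
  cfg <- model$cfg
  saveRDS(list(nClasses = cfg@nClasses, ghostLayers = cfg@ghostLayers,
               caEnabled = cfg@caEnabled, depthMultiple = cfg@depthMultiple,
               widthMultiple = cfg@widthMultiple,
               maxChannels = cfg@maxChannels, regMax = cfg@regMax,
               params = getParamVector(model)), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  s <- readRDS(path)
  cfg <- modelConfig(nClasses = s$nClasses, ghost = s$ghostLayers,
                     ca = s$caEnabled, depthMultiple = s$depthMultiple,
                     widthMultiple = s$widthMultiple,
                     maxChannels = s$maxChannels, regMax = s$regMax)
  m <- buildModel(cfg)
  setParamVector(m, s$params)
  m
}
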