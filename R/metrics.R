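# Detection evaluation: greedy confidence-ordered matching, precision /
# recall / F1, average precision via the interpolated precision-recall
# envelope, and the two mAP aggregates.

#' Match detections to ground truths within one image
#'
#' Per class, detections are sorted by descending confidence; each claims the
#' unmatched ground truth with the highest IoU at or above the threshold (one
#' match per ground truth). Remaining detections are false positives,
#' unmatched ground truths false negatives.
#'
#' @param dets detection matrix/data.frame with columns \code{class},
#'   \code{confidence}, \code{cx}, \code{cy}, \code{w}, \code{h} (normalized
#'   center-size).
#' @param gts ground-truth matrix/data.frame with columns \code{class},
#'   \code{cx}, \code{cy}, \code{w}, \code{h}.
#' @param iouThreshold minimum IoU for a correct detection (default 0.5).
#' @return list with \code{tp} (logical per detection, original order) and
#'   \code{counts} (data.frame class/TP/FP/FN over all involved classes).
#' @export
matchDetections <- function(dets, gts, iouThreshold = 0.5) {
  dets <- as.data.frame(dets); gts <- as.data.frame(gts)
  if (nrow(dets) && (any(dets$confidence < 0) || any(dets$confidence > 1)))
    stop("confidence must lie in [0,1]")
  tp <- logical(nrow(dets))
  classes <- sort(unique(c(dets$class, gts$class)))
  counts <- data.frame(class = classes, TP = 0L, FP = 0L, FN = 0L)
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    di <- which(dets$class == cl)
    gi <- which(gts$class == cl)
    gMatched <- logical(length(gi))
    if (length(di)) {
      dOrd <- di[order(dets$confidence[di], decreasing = TRUE)]
      dBox <- centerToCorner(as.matrix(dets[dOrd, c("cx", "cy", "w", "h")]),
                             1, 1)
      gBox <- if (length(gi))
        centerToCorner(as.matrix(gts[gi, c("cx", "cy", "w", "h")]), 1, 1)
      else matrix(numeric(), 0L, 4L)
      for (k in seq_along(dOrd)) {
        if (!length(gi)) break
        ious <- boxIoU(dBox[rep(k, length(gi)), , drop = FALSE], gBox)
        ious[gMatched] <- -1
        best <- which.max(ious)
        if (length(best) && ious[best] >= iouThreshold) {
          gMatched[best] <- TRUE
          tp[dOrd[k]] <- TRUE
        }
      }
    }
    counts$TP[ci] <- sum(tp[di])
    counts$FP[ci] <- length(di) - sum(tp[di])
    counts$FN[ci] <- length(gi) - sum(gMatched)
  }
  list(tp = tp, counts = counts)
}

#' Precision, recall and F1 from confusion counts
#'
#' \code{P = TP/(TP+FP)}, \code{R = TP/(TP+FN)},
#' \code{F1 = 2 P R / (P + R)}; a zero denominator yields 0.
#'
#' @param TP,FP,FN confusion counts (vectorized).
#' @return matrix with columns \code{P}, \code{R}, \code{F1}.
#' @examples
#' precisionRecallF1(TP = 9, FP = 1, FN = 3)  # P = 0.9, R = 0.75
#' @export
precisionRecallF1 <- function(TP, FP, FN) {
  P <- ifelse(TP + FP > 0, TP / (TP + FP), 0)
  R <- ifelse(TP + FN > 0, TP / (TP + FN), 0)
  F1 <- ifelse(P + R > 0, 2 * P * R / (P + R), 0)
  cbind(P = P, R = R, F1 = F1)
}

#' F1 score from precision and recall
#'
#' @param P,R precision and recall fractions.
#' @return F1 = 2 P R / (P + R), 0 when both vanish.
#' @examples
#' f1Score(0.89959, 0.82258)  # 0.859363
#' @export
f1Score <- function(P, R) ifelse(P + R > 0, 2 * P * R / (P + R), 0)

#' Average precision from a precision-recall curve
#'
#' Area under the interpolated precision envelope (maximum precision at
#' recall >= r). \code{"interp101"} (the default, the dominant modern
#' convention) samples the envelope at 101 equally spaced recall points;
#' \code{"continuous"} integrates the envelope across every distinct recall
#' value.
#'
#' @param recall,precision precision-recall points in cumulative detection
#'   order (recall non-decreasing).
#' @param method "interp101" or "continuous".
#' @return AP in [0,1]; 0 for an empty curve.
#' @export
averagePrecision <- function(recall, precision,
                             method = c("interp101", "continuous")) {
  method <- match.arg(method)
  if (!length(recall)) return(0)
  p <- precision
  if (length(p) > 1L)
    for (i in rev(seq_len(length(p) - 1L))) p[i] <- max(p[i], p[i + 1L])
  if (method == "interp101") {
    grid <- seq(0, 1, length.out = 101L)
    idx <- findInterval(grid, recall, left.open = TRUE) + 1L
    vals <- ifelse(idx <= length(p), p[pmin(idx, length(p))], 0)
    return(mean(vals))
  }
  sum(diff(c(0, recall)) * p)
}

#' Mean average precision over classes
#'
#' Unweighted mean of per-class AP over the evaluated categories.
#'
#' @param perClassAp numeric vector of per-class AP values.
#' @return mAP in [0,1]; 0 for no classes.
#' @export
meanAP <- function(perClassAp) {
  if (!length(perClassAp)) return(0)
  mean(perClassAp)
}

#' Mean AP over the IoU threshold range 0.5 to 0.95
#'
#' Arithmetic mean of per-threshold mAP values at IoU 0.5, 0.55, ..., 0.95.
#'
#' @param perThresholdMap numeric vector of the 10 per-threshold mAP values.
#' @return mAP@0.5:0.95.
#' @export
mapRange <- function(perThresholdMap) mean(perThresholdMap)

# Cumulative tp/conf -> AP for one class at one threshold.
#' @noRd
apFromFlags <- function(tp, conf, nGt, method = "interp101") {
  if (nGt == 0L || !length(tp)) return(if (nGt == 0L) NA_real_ else 0)
  o <- order(conf, decreasing = TRUE)
  ctp <- cumsum(tp[o])
  rec <- ctp / nGt
  prec <- ctp / seq_along(ctp)
  averagePrecision(rec, prec, method)
}

#' Evaluate detections against ground truths
#'
#' Full evaluation over a set of images: per-class precision, recall, F1 and
#' confusion counts at IoU 0.5, per-class AP, mAP@0.5 and mAP@0.5:0.95
#' (matching rerun at each threshold 0.5:0.05:0.95). Classes with neither
#' ground truths nor detections are excluded from the means.
#'
#' @param dets data.frame with columns \code{image}, \code{class},
#'   \code{confidence}, \code{cx}, \code{cy}, \code{w}, \code{h}.
#' @param gts data.frame with columns \code{image}, \code{class}, \code{cx},
#'   \code{cy}, \code{w}, \code{h}.
#' @param apMethod AP discretization, see \code{\link{averagePrecision}}.
#' @return An \code{\link{EvalReport-class}}.
#' @export
evaluateDetections <- function(dets, gts, apMethod = "interp101") {
  dets <- as.data.frame(dets); gts <- as.data.frame(gts)
  classes <- sort(unique(c(dets$class, gts$class)))
  imgs <- unique(c(dets$image, gts$image))
  thresholds <- seq(0.5, 0.95, by = 0.05)
  nGtClass <- vapply(classes, function(cl) sum(gts$class == cl), numeric(1L))

  # per-threshold tp flags for every detection
  tpAll <- matrix(FALSE, nrow(dets), length(thresholds))
  counts50 <- data.frame(class = classes, TP = 0L, FP = 0L, FN = 0L)
  for (im in imgs) {
    di <- which(dets$image == im)
    gi <- which(gts$image == im)
    for (ti in seq_along(thresholds)) {
      mm <- matchDetections(dets[di, , drop = FALSE],
                            gts[gi, , drop = FALSE], thresholds[ti])
      tpAll[di, ti] <- mm$tp
      if (ti == 1L && nrow(mm$counts)) {
        j <- match(mm$counts$class, classes)
        counts50$TP[j] <- counts50$TP[j] + mm$counts$TP
        counts50$FP[j] <- counts50$FP[j] + mm$counts$FP
        counts50$FN[j] <- counts50$FN[j] + mm$counts$FN
      }
    }
  }

  apMat <- matrix(NA_real_, length(classes), length(thresholds))
  for (ci in seq_along(classes)) {
    di <- which(dets$class == classes[ci])
    for (ti in seq_along(thresholds))
      apMat[ci, ti] <- apFromFlags(tpAll[di, ti], dets$confidence[di],
                                   nGtClass[ci], apMethod)
  }
  prf <- precisionRecallF1(counts50$TP, counts50$FP, counts50$FN)
  perClass <- data.frame(class = classes, P = prf[, 1L], R = prf[, 2L],
                         F1 = prf[, 3L],
                         AP = ifelse(is.na(apMat[, 1L]), 0, apMat[, 1L]),
                         TP = counts50$TP, FP = counts50$FP,
                         FN = counts50$FN)
  evald <- !is.na(apMat[, 1L])
  m50 <- meanAP(apMat[evald, 1L])
  perThr <- colMeans(apMat[evald, , drop = FALSE])
  new("EvalReport", perClass = perClass, map50 = m50,
      map5095 = if (any(evald)) mapRange(perThr) else 0)
}

#' Write/read a detections text file
#'
#' One line per detection: \code{image_id class confidence cx cy w h}
#' (normalized center-size coordinates).
#'
#' @param dets data.frame as in \code{\link{evaluateDetections}}.
#' @param path output file.
#' @return \code{writeDetections}: invisibly, the path;
#'   \code{readDetections}: the data.frame.
#' @export
writeDetections <- function(dets, path) {
  writeLines(sprintf("%s %d %.6f %.6f %.6f %.6f %.6f",
                     as.character(dets$image), as.integer(dets$class),
                     dets$confidence, dets$cx, dets$cy, dets$w, dets$h),
             path)
  invisible(path)
}

#' @rdname writeDetections
#' @export
readDetections <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    return(data.frame(image = character(), class = integer(),
                      confidence = numeric(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric()))
  read.table(path, col.names = c("image", "class", "confidence",
                                 "cx", "cy", "w", "h"),
             colClasses = c("character", "integer", rep("numeric", 5L)))
}
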