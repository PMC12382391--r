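# Canonical bounding-box conversions. Two representations are used across the
# package:
#   * pixel corner boxes: columns x0, y0, x1, y1, half-open on the max edge,
#     0-based pixel coordinates ([x0, x1) x [y0, y1));
#   * normalized center boxes: columns cx, cy, w, h in [0,1].
# These two helpers are the single conversion path; everything else calls them.

#' Convert pixel corner boxes to normalized center-size boxes
#'
#' @param corners n x 4 matrix (x0, y0, x1, y1), half-open pixel coordinates.
#' @param width,height canvas size in pixels.
#' @return n x 4 matrix (cx, cy, w, h) normalized to [0,1].
#' @examples
#' cornerToCenter(matrix(c(288, 288, 352, 352), 1), 640, 640)
#' @export
cornerToCenter <- function(corners, width, height) {
  corners <- rbindMat(corners, 4L)
  out <- cbind(cx = (corners[, 1L] + corners[, 3L]) / 2 / width,
               cy = (corners[, 2L] + corners[, 4L]) / 2 / height,
               w = (corners[, 3L] - corners[, 1L]) / width,
               h = (corners[, 4L] - corners[, 2L]) / height)
  out
}

#' Convert normalized center-size boxes to pixel corner boxes
#'
#' @param centers n x 4 matrix (cx, cy, w, h) normalized to [0,1].
#' @param width,height canvas size in pixels.
#' @return n x 4 matrix (x0, y0, x1, y1), half-open pixel coordinates.
#' @export
centerToCorner <- function(centers, width, height) {
  centers <- rbindMat(centers, 4L)
  cbind(x0 = (centers[, 1L] - centers[, 3L] / 2) * width,
        y0 = (centers[, 2L] - centers[, 4L] / 2) * height,
        x1 = (centers[, 1L] + centers[, 3L] / 2) * width,
        y1 = (centers[, 2L] + centers[, 4L] / 2) * height)
}

# coerce vectors to single-row matrices with nc columns
#' @noRd
rbindMat <- function(x, nc) {
  if (is.null(dim(x))) matrix(x, ncol = nc) else as.matrix(x)
}

#' Intersection over union of axis-aligned boxes
#'
#' Elementwise IoU between rows of \code{a} and rows of \code{b} (recycled if
#' either has one row): intersection area divided by union area, 0 for
#' disjoint boxes.
#'
#' @param a,b matrices of boxes in corner form (x0, y0, x1, y1); any common
#'   unit (pixel or normalized) as long as both use the same one.
#' @return numeric vector of IoU fractions in [0,1].
#' @examples
#' boxIoU(c(0, 0, 1, 1), c(0.5, 0, 1.5, 1))  # 1/3
#' @export
boxIoU <- function(a, b) {
  a <- rbindMat(a, 4L); b <- rbindMat(b, 4L)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L) b <- b[rep(1L, n), , drop = FALSE]
  iw <- pmax(0, pmin(a[, 3L], b[, 3L]) - pmax(a[, 1L], b[, 1L]))
  ih <- pmax(0, pmin(a[, 4L], b[, 4L]) - pmax(a[, 2L], b[, 2L]))
  inter <- iw * ih
  areaA <- pmax(0, a[, 3L] - a[, 1L]) * pmax(0, a[, 4L] - a[, 2L])
  areaB <- pmax(0, b[, 3L] - b[, 1L]) * pmax(0, b[, 4L] - b[, 2L])
  un <- areaA + areaB - inter
  ifelse(un > 0, inter / un, 0)
}

# Cross IoU matrix: nrow(a) x nrow(b), corner form.
#' @noRd
boxIoUMatrix <- function(a, b) {
  a <- rbindMat(a, 4L); b <- rbindMat(b, 4L)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L) return(matrix(0, na, nb))
  iw <- pmax(0, outer(a[, 3L], b[, 3L], pmin) - outer(a[, 1L], b[, 1L], pmax))
  ih <- pmax(0, outer(a[, 4L], b[, 4L], pmin) - outer(a[, 2L], b[, 2L], pmax))
  inter <- iw * ih
  areaA <- pmax(0, a[, 3L] - a[, 1L]) * pmax(0, a[, 4L] - a[, 2L])
  areaB <- pmax(0, b[, 3L] - b[, 1L]) * pmax(0, b[, 4L] - b[, 2L])
  un <- outer(areaA, areaB, "+") - inter
  out <- inter / un
  out[un <= 0] <- 0
  out
}
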