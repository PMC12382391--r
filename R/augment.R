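# Augmentation algebra: affine transforms in the row-vector convention
# [x' y' 1] = [x y 1] %*% M (so translations live in the last row and the last
# column is (0,0,1)'), HSV conversion and jitter, letterbox, mosaic, and the
# per-object multiplicity driver. Angles are accepted in degrees; trigonometry
# is done in radians internally.

#' @noRd
deg2rad <- function(d) d * pi / 180

#' Affine rotation matrix (row-vector convention)
#'
#' Counterclockwise rotation by \code{beta} degrees about the origin:
#' \code{x' = x cos(beta) - y sin(beta)}, \code{y' = x sin(beta) + y cos(beta)}.
#'
#' @param beta rotation angle in degrees.
#' @return 3 x 3 matrix \code{M} with \code{[x' y' 1] = [x y 1] \%*\% M}.
#' @examples
#' c(1, 0, 1) %*% rotationMatrix(90)  # (0, 1, 1)
#' @export
rotationMatrix <- function(beta) {
  stopifnot(is.finite(beta))
  b <- deg2rad(beta)
  matrix(c(cos(b), sin(b), 0,
           -sin(b), cos(b), 0,
           0, 0, 1), 3L, 3L, byrow = TRUE)
}

#' Affine shear matrix (row-vector convention)
#'
#' Shear along the y-direction by \code{alpha} degrees:
#' \code{x' = x + y sin(alpha)}, \code{y' = y cos(alpha)}.
#'
#' @param alpha shear angle in degrees.
#' @return 3 x 3 matrix in the row-vector convention.
#' @export
shearMatrix <- function(alpha) {
  stopifnot(is.finite(alpha))
  a <- deg2rad(alpha)
  matrix(c(1, 0, 0,
           sin(a), cos(a), 0,
           0, 0, 1), 3L, 3L, byrow = TRUE)
}

#' Affine translation matrix (row-vector convention)
#'
#' @param xt,yt shifts in pixels: \code{x' = x + xt}, \code{y' = y + yt}.
#' @return 3 x 3 matrix in the row-vector convention.
#' @export
shiftMatrix <- function(xt, yt) {
  matrix(c(1, 0, 0,
           0, 1, 0,
           xt, yt, 1), 3L, 3L, byrow = TRUE)
}

#' Affine anisotropic scaling matrix (row-vector convention)
#'
#' @param xzoom,yzoom scale factors: \code{x' = x * xzoom},
#'   \code{y' = y * yzoom}. Zero factors are rejected (non-invertible).
#' @return 3 x 3 matrix in the row-vector convention.
#' @export
scaleMatrix <- function(xzoom, yzoom = xzoom) {
  if (xzoom == 0 || yzoom == 0) stop("zoom factors must be nonzero")
  diag(c(xzoom, yzoom, 1))
}

# Bilinear resize to (h, w); plain separable gather.
#' @noRd
resizeBilinear <- function(img, h, w) {
  hs <- dim(img)[1L]; ws <- dim(img)[2L]
  sy <- (seq_len(h) - 0.5) * hs / h - 0.5
  sx <- (seq_len(w) - 0.5) * ws / w - 0.5
  y0 <- pmin(pmax(floor(sy), 0), hs - 1); fy <- pmin(pmax(sy - y0, 0), 1)
  x0 <- pmin(pmax(floor(sx), 0), ws - 1); fx <- pmin(pmax(sx - x0, 0), 1)
  y1 <- pmin(y0 + 1, hs - 1); x1 <- pmin(x0 + 1, ws - 1)
  out <- array(0, c(h, w, dim(img)[3L]))
  for (ch in seq_len(dim(img)[3L])) {
    p <- img[, , ch]
    a <- p[cbind(rep(y0 + 1, w), rep(x0 + 1, each = h))]
    b <- p[cbind(rep(y0 + 1, w), rep(x1 + 1, each = h))]
    cc <- p[cbind(rep(y1 + 1, w), rep(x0 + 1, each = h))]
    d <- p[cbind(rep(y1 + 1, w), rep(x1 + 1, each = h))]
    fyv <- rep(fy, w); fxv <- rep(fx, each = h)
    out[, , ch] <- matrix(a * (1 - fyv) * (1 - fxv) + b * (1 - fyv) * fxv +
                          cc * fyv * (1 - fxv) + d * fyv * fxv, h, w)
  }
  out
}

#' Apply an affine transform to an image and its boxes
#'
#' The transform is applied about the canvas center (it is conjugated with
#' shifts moving the source center to the origin and the origin to the output
#' center), so a 90-degree rotation of a square canvas keeps content in view.
#' The image is resampled through the inverse map with bilinear interpolation;
#' each box is transformed by mapping its four corners and taking the
#' axis-aligned hull, then clipping to the canvas. Boxes whose visible area
#' falls below \code{areaThresh} of their unclipped transformed area, or whose
#' minimum side drops below \code{minSide} pixels, are dropped.
#'
#' @param x a \code{\link{labeledImage}}.
#' @param trans 3 x 3 affine matrix in the row-vector convention (must be
#'   invertible).
#' @param outSize output canvas c(width, height); defaults to the input size.
#' @param fill border fill value in [0,1] (default neutral gray 114/255).
#' @param areaThresh,minSide box survival thresholds after clipping.
#' @return A \code{\link{labeledImage}} on the output canvas.
#' @examples
#' img <- array(0.5, c(64, 64, 3))
#' li <- labeledImage(img, cbind(0, 0.5, 0.25, 0.2, 0.1))
#' boxes(applyAffine(li, rotationMatrix(90)))  # (0.75, 0.5, 0.1, 0.2)
#' @export
applyAffine <- function(x, trans, outSize = NULL, fill = 114 / 255,
                        areaThresh = 0.1, minSide = 2) {
  stopifnot(is(x, "LabeledImage"))
  img <- x@image
  hs <- dim(img)[1L]; ws <- dim(img)[2L]
  if (is.null(outSize)) outSize <- c(ws, hs)
  wd <- outSize[1L]; hd <- outSize[2L]
  dt <- det(trans)
  if (!is.finite(dt) || abs(dt) < 1e-12) stop("transform is not invertible")
  M <- shiftMatrix(-ws / 2, -hs / 2) %*% trans %*% shiftMatrix(wd / 2, hd / 2)
  Minv <- solve(M)

  xc <- rep(seq_len(wd) - 0.5, each = hd)
  yc <- rep(seq_len(hd) - 0.5, wd)
  sxy <- cbind(xc, yc, 1) %*% Minv
  sx <- sxy[, 1L] - 0.5; sy <- sxy[, 2L] - 0.5
  inside <- sx > -0.5 & sx < ws - 0.5 & sy > -0.5 & sy < hs - 0.5
  x0 <- pmin(pmax(floor(sx), 0), ws - 1); fx <- pmin(pmax(sx - x0, 0), 1)
  y0 <- pmin(pmax(floor(sy), 0), hs - 1); fy <- pmin(pmax(sy - y0, 0), 1)
  x1 <- pmin(x0 + 1, ws - 1); y1 <- pmin(y0 + 1, hs - 1)
  out <- array(fill, c(hd, wd, 3L))
  for (ch in 1:3) {
    p <- img[, , ch]
    v <- p[cbind(y0 + 1, x0 + 1)] * (1 - fy) * (1 - fx) +
      p[cbind(y0 + 1, x1 + 1)] * (1 - fy) * fx +
      p[cbind(y1 + 1, x0 + 1)] * fy * (1 - fx) +
      p[cbind(y1 + 1, x1 + 1)] * fy * fx
    plane <- matrix(fill, hd, wd)
    plane[inside] <- v[inside]
    out[, , ch] <- plane
  }

  bx <- x@boxes
  newBoxes <- matrix(numeric(), 0L, 5L)
  if (nrow(bx)) {
    corners <- centerToCorner(bx[, 2:5, drop = FALSE], ws, hs)
    keep <- logical(nrow(bx)); hull <- matrix(0, nrow(bx), 4L)
    for (i in seq_len(nrow(bx))) {
      cs <- rbind(c(corners[i, 1L], corners[i, 2L]),
                  c(corners[i, 3L], corners[i, 2L]),
                  c(corners[i, 1L], corners[i, 4L]),
                  c(corners[i, 3L], corners[i, 4L]))
      mapped <- cbind(cs, 1) %*% M
      hx <- range(mapped[, 1L]); hy <- range(mapped[, 2L])
      areaPre <- diff(hx) * diff(hy)
      cx0 <- max(hx[1L], 0); cx1 <- min(hx[2L], wd)
      cy0 <- max(hy[1L], 0); cy1 <- min(hy[2L], hd)
      vw <- max(0, cx1 - cx0); vh <- max(0, cy1 - cy0)
      if (vw * vh >= areaThresh * areaPre && vw >= minSide && vh >= minSide) {
        keep[i] <- TRUE
        hull[i, ] <- c(cx0, cy0, cx1, cy1)
      }
    }
    if (any(keep))
      newBoxes <- cbind(bx[keep, 1L],
                        cornerToCenter(hull[keep, , drop = FALSE], wd, hd))
  }
  labeledImage(out, newBoxes)
}

#' Convert RGB to HSV (hexcone model)
#'
#' Value is the channel maximum; hue is piecewise by the dominant channel with
#' a +360 wrap for negative angles (0 when R = G = B); saturation is
#' \code{(V - min)/V} for \code{V > 0} and 0 otherwise. Outputs satisfy
#' \code{0 <= H <= 360}, \code{0 <= S <= 1}, \code{0 <= V <= 1}.
#'
#' @param x RGB fractions in [0,1]: an n x 3 matrix or an H x W x 3 array.
#' @return Same shape as the input with channels (H, S, V).
#' @examples
#' rgbToHsv(matrix(c(1, 0, 0.5), 1))  # H = 330, S = 1, V = 1
#' @export
rgbToHsv <- function(x) {
  arr <- length(dim(x)) == 3L
  m <- if (arr) matrix(x, ncol = 3L) else rbindMat(x, 3L)
  if (any(m < 0) || any(m > 1)) stop("RGB channels must lie in [0,1]")
  r <- m[, 1L]; g <- m[, 2L]; b <- m[, 3L]
  v <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- v - mn
  h <- numeric(length(v))
  eq <- d == 0
  iR <- !eq & v == r
  iG <- !eq & !iR & v == g
  iB <- !eq & !iR & !iG
  h[iR] <- 60 * (g[iR] - b[iR]) / d[iR]
  h[iG] <- 120 + 60 * (b[iG] - r[iG]) / d[iG]
  h[iB] <- 240 + 60 * (r[iB] - g[iB]) / d[iB]
  h[h < 0] <- h[h < 0] + 360
  s <- ifelse(v > 0, d / v, 0)
  out <- cbind(H = h, S = s, V = v)
  if (arr) array(out, dim(x)) else out
}

#' Convert HSV to RGB (hexcone model inverse)
#'
#' @param x HSV values: n x 3 matrix or H x W x 3 array with H in [0,360],
#'   S and V in [0,1].
#' @return Same shape with RGB fractions in [0,1].
#' @export
hsvToRgb <- function(x) {
  arr <- length(dim(x)) == 3L
  m <- if (arr) matrix(x, ncol = 3L) else rbindMat(x, 3L)
  h <- (m[, 1L] %% 360) / 60
  s <- pmin(pmax(m[, 2L], 0), 1)
  v <- pmin(pmax(m[, 3L], 0), 1)
  cc <- v * s
  xx <- cc * (1 - abs(h %% 2 - 1))
  mm <- v - cc
  i <- floor(h) %% 6
  r <- ifelse(i == 0 | i == 5, cc, ifelse(i == 1 | i == 4, xx, 0))
  g <- ifelse(i == 0 | i == 3, xx, ifelse(i == 1 | i == 2, cc, 0))
  b <- ifelse(i == 2 | i == 5, xx, ifelse(i == 3 | i == 4, cc, 0))
  out <- cbind(R = r + mm, G = g + mm, B = b + mm)
  if (arr) array(out, dim(x)) else out
}

#' Random multiplicative HSV jitter
#'
#' Draws one multiplicative gain per channel, uniform in \code{[1-g, 1+g]},
#' and applies it in HSV space: hue wraps modulo 360, saturation and value are
#' clipped to [0,1]. Uses the current RNG state.
#'
#' @param img H x W x 3 RGB array in [0,1].
#' @param gains length-3 nonnegative jitter amplitudes (h, s, v).
#' @return Jittered RGB array.
#' @export
hsvJitter <- function(img, gains = c(0.015, 0.7, 0.4)) {
  f <- 1 + runif(3L, -1, 1) * gains
  hsv <- rgbToHsv(img)
  d <- dim(hsv)
  m <- matrix(hsv, ncol = 3L)
  m[, 1L] <- (m[, 1L] * f[1L]) %% 360
  m[, 2L] <- pmin(pmax(m[, 2L] * f[2L], 0), 1)
  m[, 3L] <- pmin(pmax(m[, 3L] * f[3L], 0), 1)
  hsvToRgb(array(m, d))
}

#' Letterbox an image to a target size
#'
#' Two policies: \code{"stretch"} (the default) rescales width and height
#' independently so the output is exactly the target with no padding;
#' \code{"pad"} applies the single ratio \code{min(target_w/W, target_h/H)}
#' and pads symmetrically with neutral gray to reach the target.
#'
#' @param x a \code{\link{labeledImage}} or plain H x W x 3 array.
#' @param target output size c(width, height), both positive.
#' @param mode "stretch" or "pad".
#' @return list with \code{image} (a \code{LabeledImage}; boxes remapped),
#'   \code{scaleX}, \code{scaleY} (applied ratios) and \code{pad}
#'   (left, top) pixels.
#' @examples
#' r <- letterbox(array(0.5, c(1325, 2000, 3)), target = c(640, 640),
#'                mode = "pad")
#' r$scaleX; r$pad  # 0.32, c(0, 108)
#' @export
letterbox <- function(x, target = c(640L, 640L), mode = c("stretch", "pad")) {
  mode <- match.arg(mode)
  if (any(target <= 0)) stop("target size must be positive")
  li <- if (is(x, "LabeledImage")) x else labeledImage(x)
  img <- li@image
  hs <- dim(img)[1L]; ws <- dim(img)[2L]
  tw <- target[1L]; th <- target[2L]
  if (mode == "stretch") {
    out <- if (hs == th && ws == tw) img else resizeBilinear(img, th, tw)
    res <- labeledImage(out, li@boxes)  # normalized boxes are scale-free
    return(list(image = res, scaleX = tw / ws, scaleY = th / hs,
                pad = c(0L, 0L)))
  }
  r <- min(tw / ws, th / hs)
  nw <- round(ws * r); nh <- round(hs * r)
  scaled <- resizeBilinear(img, nh, nw)
  padL <- floor((tw - nw) / 2); padT <- floor((th - nh) / 2)
  out <- array(114 / 255, c(th, tw, 3L))
  out[padT + seq_len(nh), padL + seq_len(nw), ] <- scaled
  bx <- li@boxes
  if (nrow(bx)) {
    bx[, 2L] <- (bx[, 2L] * nw + padL) / tw
    bx[, 3L] <- (bx[, 3L] * nh + padT) / th
    bx[, 4L] <- bx[, 4L] * nw / tw
    bx[, 5L] <- bx[, 5L] * nh / th
  }
  list(image = labeledImage(out, bx), scaleX = r, scaleY = r,
       pad = c(padL, padT))
}

#' Randomized simple augmentation
#'
#' Composes the four printed affine primitives (rotation, shear, shift, scale)
#' with random magnitudes and applies HSV jitter; the standard single-image
#' augmentation used by \code{\link{mosaic}} and
#' \code{\link{augmentObjectSet}}. Uses the current RNG state.
#'
#' @param li a \code{\link{labeledImage}}.
#' @param degrees,shear maximal rotation / shear angles (degrees).
#' @param translate maximal shift as a fraction of the canvas.
#' @param scale maximal relative zoom deviation (factors in
#'   \code{[1-scale, 1+scale]}).
#' @param hsvGains passed to \code{\link{hsvJitter}}.
#' @return An augmented \code{LabeledImage} of the same size.
#' @export
simpleAugment <- function(li, degrees = 10, translate = 0.1, scale = 0.25,
                          shear = 5, hsvGains = c(0.015, 0.7, 0.4)) {
  stopifnot(is(li, "LabeledImage"))
  ws <- dim(li@image)[2L]; hs <- dim(li@image)[1L]
  tr <- rotationMatrix(runif(1, -degrees, degrees)) %*%
    shearMatrix(runif(1, -shear, shear)) %*%
    scaleMatrix(1 + runif(1, -scale, scale), 1 + runif(1, -scale, scale)) %*%
    shiftMatrix(runif(1, -translate, translate) * ws,
                runif(1, -translate, translate) * hs)
  out <- applyAffine(li, tr)
  labeledImage(hsvJitter(out@image, hsvGains), out@boxes)
}

#' Mosaic augmentation
#'
#' Combines exactly four labelled images into a 2 x 2 board: each input is
#' independently augmented (by \code{augmentFn}, if given), letterboxed to a
#' board quadrant, and placed left/right in the first and second rows; labels
#' are remapped into board coordinates.
#'
#' @param imgs list of exactly 4 \code{\link{labeledImage}} objects.
#' @param board board side in pixels (default 2x the train image size).
#' @param augmentFn optional function \code{LabeledImage -> LabeledImage}
#'   applied to each input before placement (e.g. \code{\link{simpleAugment}});
#'   \code{NULL} disables the per-input augmentation.
#' @param mode letterbox policy for the quadrants.
#' @return A \code{LabeledImage} of size board x board containing the union of
#'   surviving boxes.
#' @export
mosaic <- function(imgs, board = 1280L, augmentFn = NULL,
                   mode = c("stretch", "pad")) {
  if (length(imgs) != 4L) stop("mosaic requires exactly 4 images")
  mode <- match.arg(mode)
  half <- board %/% 2L
  out <- array(114 / 255, c(board, board, 3L))
  allBoxes <- matrix(numeric(), 0L, 5L)
  offs <- list(c(0L, 0L), c(half, 0L), c(0L, half), c(half, half))
  for (q in 1:4) {
    li <- imgs[[q]]
    if (!is.null(augmentFn)) li <- augmentFn(li)
    lb <- letterbox(li, target = c(half, half), mode = mode)$image
    ox <- offs[[q]][1L]; oy <- offs[[q]][2L]
    out[oy + seq_len(half), ox + seq_len(half), ] <- lb@image
    bx <- lb@boxes
    if (nrow(bx)) {
      bx[, 2L] <- (bx[, 2L] * half + ox) / board
      bx[, 3L] <- (bx[, 3L] * half + oy) / board
      bx[, 4L] <- bx[, 4L] * half / board
      bx[, 5L] <- bx[, 5L] * half / board
      allBoxes <- rbind(allBoxes, bx)
    }
  }
  labeledImage(out, allBoxes)
}

#' Expand a labelled set by per-object augmentation multiplicity
#'
#' Emits \code{multiplicity} randomized augmented instances per input image,
#' guaranteeing that every annotation survives: a draw that would lose boxes
#' to clipping is retried, falling back to photometric-only jitter, so the
#' output annotation count is exactly \code{multiplicity} times the input
#' count for every class.
#'
#' @param imgs list of \code{\link{labeledImage}} objects.
#' @param multiplicity integer number of augmented instances per input.
#' @param augmentFn randomized augmentation (default
#'   \code{\link{simpleAugment}}); must be count-preserving up to clipping.
#' @param maxTries retries per draw before the photometric fallback.
#' @return list of \code{multiplicity * length(imgs)} labelled images.
#' @export
augmentObjectSet <- function(imgs, multiplicity = 6L,
                             augmentFn = simpleAugment, maxTries = 20L) {
  out <- vector("list", length(imgs) * multiplicity)
  k <- 0L
  for (li in imgs) {
    n0 <- nrow(li@boxes)
    for (m in seq_len(multiplicity)) {
      cand <- NULL
      for (tries in seq_len(maxTries)) {
        cand <- augmentFn(li)
        if (nrow(cand@boxes) == n0) break
        cand <- NULL
      }
      if (is.null(cand))
        cand <- labeledImage(hsvJitter(li@image), li@boxes)
      k <- k + 1L
      out[[k]] <- cand
    }
  }
  out
}
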