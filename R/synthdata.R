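# Synthetic pest-scene generator. Scenes emulate the nuisance structure of
# field imagery (textured foliage background, pests of class-specific hue and
# multi-scale size, partial occlusion by foliage stripes, motion blur,
# illumination shifts) without claiming photorealism. Masks always record the
# FULL object extent, including parts later hidden by occluders, matching a
# whole-pest annotation convention.

# Counter-based per-scene seed stream: reproducible under parallel generation.
#' @noRd
sceneSeed <- function(root, index) {
  as.integer((as.numeric(root) + as.numeric(index) * 1000003) %% 2147483647)
}

# Low-frequency value noise field in [0,1], bilinearly upsampled from a coarse
# grid; used for the foliage background texture.
#' @noRd
valueNoise <- function(h, w, cell = 16L) {
  gh <- max(2L, ceiling(h / cell) + 1L)
  gw <- max(2L, ceiling(w / cell) + 1L)
  g <- matrix(runif(gh * gw), gh, gw)
  ys <- (seq_len(h) - 1) / cell
  xs <- (seq_len(w) - 1) / cell
  y0 <- pmin(floor(ys), gh - 2); x0 <- pmin(floor(xs), gw - 2)
  fy <- ys - y0; fx <- xs - x0
  a <- g[cbind(rep(y0 + 1, w), rep(x0 + 1, each = h))]
  b <- g[cbind(rep(y0 + 1, w), rep(x0 + 2, each = h))]
  cc <- g[cbind(rep(y0 + 2, w), rep(x0 + 1, each = h))]
  d <- g[cbind(rep(y0 + 2, w), rep(x0 + 2, each = h))]
  fyv <- rep(fy, w); fxv <- rep(fx, each = h)
  matrix(a * (1 - fyv) * (1 - fxv) + b * (1 - fyv) * fxv +
         cc * fyv * (1 - fxv) + d * fyv * fxv, h, w)
}

# Rotated-ellipse mask on the pixel grid (0-based centers at pixel centers).
#' @noRd
ellipseMask <- function(h, w, cx, cy, a, b, theta) {
  x <- rep(seq_len(w) - 0.5, each = h) - cx
  y <- rep(seq_len(h) - 0.5, w) - cy
  u <- (x * cos(theta) + y * sin(theta)) / a
  v <- (-x * sin(theta) + y * cos(theta)) / b
  matrix(u * u + v * v <= 1, h, w)
}

# Average of shifted copies along a line: cheap motion-blur kernel.
#' @noRd
motionBlur <- function(img, len, angle) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  ts <- seq(-(len - 1) / 2, (len - 1) / 2)
  out <- array(0, dim(img))
  for (t in ts) {
    dy <- round(t * sin(angle)); dx <- round(t * cos(angle))
    ys <- pmin(pmax(seq_len(h) + dy, 1L), h)
    xs <- pmin(pmax(seq_len(w) + dx, 1L), w)
    out <- out + img[ys, xs, , drop = FALSE]
  }
  out / length(ts)
}

#' Generate a synthetic pest scene with instance masks
#'
#' Draws a textured foliage background and a multinomial sample of elliptical
#' "pests" (per-class characteristic hue with jitter, axis ratio 1.2-3, area
#' 0.2-8\% of the canvas), then applies the nuisance factors of the
#' configuration: foliage stripes over objects, motion blur, illumination
#' scaling. Deterministic given \code{(cfg, sceneIndex)}: scene i of a root
#' seed always produces byte-identical output.
#'
#' @param cfg a \code{\link{sceneConfig}}.
#' @param sceneIndex non-negative integer selecting the per-scene RNG stream
#'   fanned out from \code{cfg@seed}.
#' @return A \code{\link{MaskedScene-class}} object; masks record the full
#'   object extent even under occluders.
#' @examples
#' sc <- generateScene(sceneConfig(imageSize = 64, seed = 7), sceneIndex = 0)
#' length(instanceMasks(sc))
#' @export
generateScene <- function(cfg, sceneIndex = 0L) {
  stopifnot(is(cfg, "SceneConfig"))
  validObject(cfg)
  w <- cfg@imageSize[1L]; h <- cfg@imageSize[2L]
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(sceneSeed(cfg@seed, sceneIndex))

  # foliage background: greenish base modulated by low- and high-frequency noise
  coarse <- valueNoise(h, w, cell = max(8L, round(min(h, w) / 8)))
  fine <- matrix(runif(h * w, -0.04, 0.04), h, w)
  img <- array(0, c(h, w, 3L))
  img[, , 1L] <- 0.16 + 0.18 * coarse + fine
  img[, , 2L] <- 0.30 + 0.28 * coarse + fine
  img[, , 3L] <- 0.10 + 0.12 * coarse + fine

  nObj <- if (cfg@objectsPerImage[1L] == cfg@objectsPerImage[2L])
    cfg@objectsPerImage[1L]
  else sample(cfg@objectsPerImage[1L]:cfg@objectsPerImage[2L], 1L)
  labels <- integer(0)
  masks <- list()
  if (nObj > 0L) {
    labels <- sample.int(cfg@nClasses, nObj, replace = TRUE,
                         prob = cfg@classWeights) - 1L
    for (i in seq_len(nObj)) {
      areaFrac <- exp(runif(1, log(cfg@areaRange[1L]),
                            log(cfg@areaRange[2L])))
      ratio <- runif(1, 1.2, 3)
      a <- sqrt(areaFrac * w * h * ratio / pi)
      b <- a / ratio
      theta <- runif(1, 0, pi)
      cx <- runif(1, 0.12 * w, 0.88 * w)
      cy <- runif(1, 0.12 * h, 0.88 * h)
      m <- ellipseMask(h, w, cx, cy, a, b, theta)
      if (!any(m)) m[pmin(h, pmax(1, round(cy))), pmin(w, pmax(1, round(cx)))] <- TRUE
      hue <- (labels[i] / cfg@nClasses) * 360 + rnorm(1, 0, 8)
      hue <- hue %% 360
      sat <- runif(1, 0.55, 0.95)
      val <- runif(1, 0.35, 0.95)
      npix <- sum(m)
      tex <- pmin(pmax(val * (1 + rnorm(npix, 0, 0.12)), 0), 1)
      rgb1 <- hsvToRgb(cbind(rep(hue, npix), rep(sat, npix), tex))
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[m] <- rgb1[, ch]
        img[, , ch] <- plane
      }
      masks[[i]] <- m
    }
    # foliage occluders drawn AFTER all objects; masks keep full extent
    for (i in seq_len(nObj)) {
      if (runif(1) < cfg@occlusionProb) {
        bb <- maskToBbox(masks[[i]])
        ocx <- runif(1, bb[1L], bb[3L]); ocy <- runif(1, bb[2L], bb[4L])
        olen <- max(w, h)
        owid <- max(2, 0.18 * min(bb[3L] - bb[1L], bb[4L] - bb[2L]) + 1)
        oang <- runif(1, 0, pi)
        om <- ellipseMask(h, w, ocx, ocy, olen, owid, oang)
        g <- hsvToRgb(cbind(runif(1, 95, 135), runif(1, 0.5, 0.8),
                            runif(1, 0.25, 0.6)))
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[om] <- g[, ch]
          img[, , ch] <- plane
        }
      }
    }
  }
  if (runif(1) < cfg@blurProb)
    img <- motionBlur(img, len = sample(c(5L, 7L, 9L), 1L),
                      angle = runif(1, 0, pi))
  img <- img * runif(1, cfg@illuminationRange[1L], cfg@illuminationRange[2L])
  img <- pmin(pmax(img, 0), 1)
  # quantize to 8-bit so in-memory scenes match their PNG round trip
  img <- round(img * 255) / 255
  new("MaskedScene", image = img, masks = masks, labels = as.integer(labels))
}

#' @noRd
.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

#' @noRd
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Tightest axis-aligned bounding box of a binary mask
#'
#' @param mask logical (or 0/1) matrix, row = y, column = x.
#' @return numeric length-4 vector (x0, y0, x1, y1): the tightest half-open
#'   pixel box \code{[x0, x1) x [y0, y1)}, 0-based, containing every
#'   foreground pixel.
#' @examples
#' m <- matrix(FALSE, 8, 12); m[5, 10] <- TRUE
#' maskToBbox(m)  # c(9, 4, 10, 5)
#' @export
maskToBbox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask has no foreground pixel")
  c(x0 = min(idx[, 2L]) - 1, y0 = min(idx[, 1L]) - 1,
    x1 = max(idx[, 2L]), y1 = max(idx[, 1L]))
}

#' @rdname boxes
#' @export
setMethod("boxes", "MaskedScene", function(x) {
  if (!length(x@masks))
    return(matrix(numeric(), 0L, 5L,
                  dimnames = list(NULL, c("class", "x0", "y0", "x1", "y1"))))
  bb <- t(vapply(x@masks, maskToBbox, numeric(4L)))
  cbind(class = as.numeric(x@labels), bb)
})

#' Convert a MaskedScene to a LabeledImage
#'
#' Masks become normalized center-size boxes via \code{\link{maskToBbox}}.
#'
#' @param scene a \code{MaskedScene}.
#' @return A \code{\link{labeledImage}}.
#' @export
asLabeledImage <- function(scene) {
  stopifnot(is(scene, "MaskedScene"))
  d <- dim(scene@image)
  bb <- boxes(scene)
  lb <- if (nrow(bb)) cbind(bb[, 1L, drop = FALSE],
                            cornerToCenter(bb[, 2:5, drop = FALSE],
                                           d[2L], d[1L]))
        else matrix(numeric(), 0L, 5L)
  labeledImage(scene@image, lb)
}

#' Write scenes as a YOLO-layout dataset
#'
#' Writes PNG images, YOLO label text files (one line per object:
#' \code{class cx cy w h}, normalized, 6-decimal fixed point) and a dataset
#' YAML (\code{path}, \code{train}, \code{val}, \code{names}) under
#' \code{outDir}, splitting scenes into train/validation subsets.
#'
#' @param scenes list of \code{MaskedScene} or \code{LabeledImage} objects.
#' @param outDir output directory (created if needed).
#' @param splitRatio train fraction (default 0.8, i.e. an 80:20 split).
#' @param seed RNG seed for the deterministic shuffle before splitting.
#' @param classNames character vector of class names for the YAML; defaults
#'   to the 15 emulated pest classes.
#' @return Invisibly, a manifest list with elements \code{yaml}, \code{train},
#'   \code{val} (file paths).
#' @export
writeDataset <- function(scenes, outDir, splitRatio = 0.8, seed = 0L,
                         classNames = ricePestClasses$name) {
  n <- length(scenes)
  if (n < 2L && splitRatio > 0 && splitRatio < 1)
    stop("need at least 2 scenes for a nontrivial split")
  for (sub in c("images/train", "images/val", "labels/train", "labels/val"))
    dir.create(file.path(outDir, sub), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  nTrain <- round(n * splitRatio)
  isTrain <- seq_len(n) %in% perm[seq_len(nTrain)]
  trainFiles <- character(0); valFiles <- character(0)
  for (i in seq_len(n)) {
    li <- if (is(scenes[[i]], "MaskedScene")) asLabeledImage(scenes[[i]])
          else scenes[[i]]
    split <- if (isTrain[i]) "train" else "val"
    stem <- sprintf("scene_%05d", i - 1L)
    imgPath <- file.path(outDir, "images", split, paste0(stem, ".png"))
    lblPath <- file.path(outDir, "labels", split, paste0(stem, ".txt"))
    png::writePNG(li@image, imgPath)
    bx <- li@boxes
    lines <- if (nrow(bx))
      sprintf("%d %.6f %.6f %.6f %.6f", as.integer(bx[, 1L]),
              bx[, 2L], bx[, 3L], bx[, 4L], bx[, 5L]) else character(0)
    writeLines(lines, lblPath)
    if (isTrain[i]) trainFiles <- c(trainFiles, imgPath)
    else valFiles <- c(valFiles, imgPath)
  }
  yml <- file.path(outDir, "dataset.yaml")
  yaml::write_yaml(list(
    path = normalizePath(outDir),
    train = "images/train",
    val = "images/val",
    names = as.list(setNames(as.character(classNames),
                             seq_along(classNames) - 1L))), yml)
  invisible(list(yaml = yml, train = trainFiles, val = valFiles))
}

#' Read a YOLO label file
#'
#' @param path label text file (\code{class cx cy w h} per line).
#' @return n x 5 numeric matrix (class, cx, cy, w, h); 0 rows if empty.
#' @export
readLabels <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    return(matrix(numeric(), 0L, 5L,
                  dimnames = list(NULL, c("class", "cx", "cy", "w", "h"))))
  m <- as.matrix(read.table(path, col.names = c("class", "cx", "cy", "w", "h")))
  m
}

#' Read a YOLO-layout dataset manifest
#'
#' @param yamlPath path to the dataset YAML written by
#'   \code{\link{writeDataset}}.
#' @return list with \code{names} (character vector) and data.frames
#'   \code{train} and \code{val} (columns \code{image}, \code{label}).
#' @export
readDataset <- function(yamlPath) {
  y <- yaml::read_yaml(yamlPath)
  root <- y$path
  splitDf <- function(sub) {
    imgs <- sort(list.files(file.path(root, sub), full.names = TRUE,
                            pattern = "\\.png$"))
    lbls <- file.path(root, sub("images", "labels", sub),
                      sub("\\.png$", ".txt", basename(imgs)))
    data.frame(image = imgs, label = lbls, stringsAsFactors = FALSE)
  }
  list(names = unlist(y$names, use.names = FALSE),
       train = splitDf(y$train), val = splitDf(y$val))
}

#' Load a dataset image with its labels
#'
#' @param imagePath PNG path.
#' @param labelPath label text path.
#' @return A \code{\link{labeledImage}}.
#' @export
readLabeledImage <- function(imagePath, labelPath) {
  img <- png::readPNG(imagePath)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  labeledImage(img, readLabels(labelPath))
}
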