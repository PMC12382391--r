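# S4 containers for the toolkit. Images are numeric arrays H x W x 3 in [0,1]
# (row = y, column = x, both 0-based in the pixel conventions of the helpers).
# Normalized boxes are n x 5 matrices: class id (0-based), cx, cy, w, h.

#' Table of annotated object counts of the emulated field survey
#'
#' Per-class labelled-object counts for the 15 rice pest categories the
#' synthetic generator emulates, used as the default class frequency weights.
#'
#' @format A data.frame with columns \code{id} (0-based class id),
#'   \code{name} (pest class name) and \code{objects} (annotated instances).
#' @export
ricePestClasses <- data.frame(
  id = 0:14,
  name = c(
    "Chilo_suppressalis_egg", "Chilo_suppressalis_Walker",
    "Chilo_suppressalis_pupa", "Sesamia_inferens_adult",
    "Erthesina_fullo_Thunberg_first_instar",
    "Nezara_viridula_Nymph_three_instar",
    "Nezara_viridula_Nymph_fourth_instar",
    "Nezara_viridula_Nymph_fifth_instar", "Nezara_viridula_adult",
    "Sesamia_inferens_Walker", "Naranga_aenescens_Moore_Walker",
    "Naranga_aenescens_Moore_adult", "Cnaphalocrocis_medinalis_Guenee_Walker",
    "Cnaphalocrocis_medinalis_Guenee_pupa", "Sesamia_inferens_pupa"),
  objects = c(714L, 797L, 31L, 23L, 16L, 321L, 51L, 258L, 306L, 280L,
              462L, 145L, 29L, 3L, 13L),
  stringsAsFactors = FALSE
)

#' SceneConfig: configuration of the synthetic pest-scene generator
#'
#' Describes the synthetic field scenes: canvas size, number of pest classes,
#' relative class frequencies, per-image object count range, and the nuisance
#' factors emulating field acquisition (foliage occlusion, motion blur,
#' illumination shifts).
#'
#' @slot imageSize integer(2), width and height in pixels (>= 32).
#' @slot nClasses integer, number of pest classes.
#' @slot classWeights numeric, relative class frequencies (length nClasses,
#'   all >= 0, not all zero).
#' @slot objectsPerImage integer(2), inclusive min/max object count.
#' @slot occlusionProb numeric, probability that a foliage stripe is drawn
#'   across an object.
#' @slot blurProb numeric, probability of applying a motion-blur kernel.
#' @slot illuminationRange numeric(2), multiplicative brightness interval.
#' @slot areaRange numeric(2), object area as a fraction of the canvas
#'   (log-uniformly sampled; default 0.002 to 0.08 spans the multi-scale
#'   regime of field imagery).
#' @slot seed integer, root RNG seed; per-scene streams are fanned out from it.
#' @export
setClass("SceneConfig", representation(
  imageSize = "integer", nClasses = "integer", classWeights = "numeric",
  objectsPerImage = "integer", occlusionProb = "numeric",
  blurProb = "numeric", illuminationRange = "numeric",
  areaRange = "numeric", seed = "integer"))

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (length(object@imageSize) != 2L || any(object@imageSize < 32L))
    msg <- c(msg, "imageSize must be two integers >= 32")
  if (length(object@classWeights) != object@nClasses)
    msg <- c(msg, "classWeights must have length nClasses")
  if (any(object@classWeights < 0) || all(object@classWeights == 0))
    msg <- c(msg, "classWeights must be >= 0 and not all zero")
  if (length(object@objectsPerImage) != 2L ||
      object@objectsPerImage[1L] < 0L ||
      object@objectsPerImage[1L] > object@objectsPerImage[2L])
    msg <- c(msg, "objectsPerImage must satisfy 0 <= min <= max")
  if (object@occlusionProb < 0 || object@occlusionProb > 1)
    msg <- c(msg, "occlusionProb must be in [0,1]")
  if (object@blurProb < 0 || object@blurProb > 1)
    msg <- c(msg, "blurProb must be in [0,1]")
  if (length(object@illuminationRange) != 2L ||
      any(object@illuminationRange <= 0) ||
      diff(object@illuminationRange) < 0)
    msg <- c(msg, "illuminationRange must be a positive increasing interval")
  if (length(object@areaRange) != 2L || any(object@areaRange <= 0) ||
      any(object@areaRange > 0.5) || diff(object@areaRange) < 0)
    msg <- c(msg, "areaRange must be an increasing interval within (0, 0.5]")
  if (length(msg)) msg else TRUE
})

#' Construct a SceneConfig
#'
#' @param imageSize canvas size in pixels, length-1 (square) or length-2.
#' @param nClasses number of pest classes.
#' @param classWeights relative class frequencies; defaults to the annotated
#'   object counts of \code{\link{ricePestClasses}} (truncated/recycled is an
#'   error: supply weights when \code{nClasses != 15}).
#' @param objectsPerImage inclusive integer range of objects per scene.
#' @param occlusionProb probability of a foliage stripe over an object.
#' @param blurProb probability of motion blur.
#' @param illuminationRange multiplicative brightness factor interval.
#' @param areaRange object area interval as a fraction of the canvas.
#' @param seed root RNG seed.
#' @return A validated \code{SceneConfig}.
#' @examples
#' cfg <- sceneConfig(imageSize = 64, objectsPerImage = c(1, 3), seed = 1)
#' @export
sceneConfig <- function(imageSize = 640L, nClasses = 15L,
                        classWeights = NULL,
                        objectsPerImage = c(1L, 6L),
                        occlusionProb = 0.3, blurProb = 0.2,
                        illuminationRange = c(0.6, 1.4),
                        areaRange = c(0.002, 0.08), seed = 0L) {
  if (length(imageSize) == 1L) imageSize <- rep(imageSize, 2L)
  if (any(imageSize < 32))
    stop("imageSize must be at least 32 pixels")
  if (is.null(classWeights)) {
    if (nClasses == 15L) classWeights <- as.numeric(ricePestClasses$objects)
    else stop("supply classWeights when nClasses != 15")
  }
  new("SceneConfig", imageSize = as.integer(imageSize),
      nClasses = as.integer(nClasses), classWeights = as.numeric(classWeights),
      objectsPerImage = as.integer(objectsPerImage),
      occlusionProb = occlusionProb, blurProb = blurProb,
      illuminationRange = as.numeric(illuminationRange),
      areaRange = as.numeric(areaRange), seed = as.integer(seed))
}

#' MaskedScene: a synthetic scene with instance masks
#'
#' @slot image numeric array H x W x 3 in [0,1].
#' @slot masks list of H x W logical instance masks recording the full object
#'   extent (including parts hidden behind occluders).
#' @slot labels integer vector of 0-based class ids, one per mask.
#' @export
setClass("MaskedScene", representation(
  image = "array", masks = "list", labels = "integer"))

setValidity("MaskedScene", function(object) {
  msg <- character()
  if (length(object@masks) != length(object@labels))
    msg <- c(msg, "masks and labels must have equal length")
  if (length(object@masks) && !all(vapply(object@masks, any, logical(1))))
    msg <- c(msg, "every mask must have at least one foreground pixel")
  if (length(msg)) msg else TRUE
})

#' LabeledImage: an RGB raster with normalized box annotations
#'
#' @slot image numeric array H x W x 3 in [0,1].
#' @slot boxes numeric matrix n x 5 with columns class (0-based), cx, cy, w, h,
#'   all coordinates normalized to [0,1].
#' @export
setClass("LabeledImage", representation(image = "array", boxes = "matrix"))

setValidity("LabeledImage", function(object) {
  msg <- character()
  if (length(dim(object@image)) != 3L || dim(object@image)[3L] != 3L)
    msg <- c(msg, "image must be an H x W x 3 array")
  if (ncol(object@boxes) != 5L)
    msg <- c(msg, "boxes must have 5 columns (class, cx, cy, w, h)")
  if (nrow(object@boxes) &&
      (any(object@boxes[, 2:5] < -1e-9) || any(object@boxes[, 2:5] > 1 + 1e-9)))
    msg <- c(msg, "box coordinates must be normalized to [0,1]")
  if (length(msg)) msg else TRUE
})

#' Construct a LabeledImage
#'
#' @param image H x W x 3 numeric array in [0,1].
#' @param boxes n x 5 matrix (class, cx, cy, w, h), normalized.
#' @return A \code{LabeledImage}.
#' @export
labeledImage <- function(image, boxes = matrix(numeric(), 0L, 5L)) {
  boxes <- as.matrix(boxes)
  if (length(boxes) == 0L) boxes <- matrix(numeric(), 0L, 5L)
  colnames(boxes) <- c("class", "cx", "cy", "w", "h")
  new("LabeledImage", image = image, boxes = boxes)
}

#' ModelConfig: declarative description of a detector variant
#'
#' Drives both the live model construction and the closed-form parameter
#' accounting. The baseline is the nano-scale topology (depth multiple 0.33,
#' width multiple 0.25, backbone widths 16-32-64-128-256); ghost replacement
#' applies to the four stride-2 backbone convolutions (0-based layer ids
#' 1, 3, 5, 7) and the optional context-aggregation block sits on the
#' 384-channel top-down neck concatenation.
#'
#' @slot nClasses integer, number of object classes.
#' @slot depthMultiple numeric depth multiple.
#' @slot widthMultiple numeric width multiple.
#' @slot maxChannels integer channel cap before width scaling.
#' @slot ghostLayers integer, subset of c(1,3,5,7): backbone convolutions
#'   replaced by ghost modules.
#' @slot caEnabled logical, insert the context-aggregation block.
#' @slot regMax integer, number of distribution-focal bins per box side.
#' @export
setClass("ModelConfig", representation(
  nClasses = "integer", depthMultiple = "numeric", widthMultiple = "numeric",
  maxChannels = "integer", ghostLayers = "integer", caEnabled = "logical",
  regMax = "integer"))

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (!all(object@ghostLayers %in% c(1L, 3L, 5L, 7L)))
    msg <- c(msg, "ghostLayers must be a subset of {1,3,5,7}")
  if (object@nClasses < 1L) msg <- c(msg, "nClasses must be >= 1")
  if (object@regMax < 2L) msg <- c(msg, "regMax must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Construct a ModelConfig
#'
#' @param nClasses number of object classes (default 15).
#' @param ghost logical or integer vector; TRUE replaces all four stride-2
#'   backbone convolutions (layers 1,3,5,7) with ghost modules, an integer
#'   vector selects a subset, FALSE keeps standard convolutions.
#' @param ca logical, insert the context-aggregation attention block on the
#'   384-channel top-down neck concatenation.
#' @param depthMultiple,widthMultiple,maxChannels scaling of the layer
#'   inventory (nano defaults).
#' @param regMax distribution-focal bin count (frozen decode projection).
#' @return A validated \code{ModelConfig}.
#' @examples
#' modelConfig(nClasses = 15, ghost = TRUE, ca = TRUE)
#' @export
modelConfig <- function(nClasses = 15L, ghost = FALSE, ca = FALSE,
                        depthMultiple = 0.33, widthMultiple = 0.25,
                        maxChannels = 1024L, regMax = 16L) {
  gl <- if (isTRUE(ghost)) c(1L, 3L, 5L, 7L)
        else if (isFALSE(ghost)) integer()
        else as.integer(ghost)
  new("ModelConfig", nClasses = as.integer(nClasses),
      depthMultiple = depthMultiple, widthMultiple = widthMultiple,
      maxChannels = as.integer(maxChannels), ghostLayers = gl,
      caEnabled = isTRUE(ca), regMax = as.integer(regMax))
}

#' ParamReport: exact parameter accounting of a model
#'
#' @slot totalParams integer total parameter count.
#' @slot trainableParams integer count of parameters receiving gradients
#'   (total minus the frozen distribution-focal decode projection).
#' @slot perLayer data.frame with columns \code{name} and \code{params}.
#' @export
setClass("ParamReport", representation(
  totalParams = "numeric", trainableParams = "numeric",
  perLayer = "data.frame"))

#' EvalReport: per-class detection evaluation
#'
#' @slot perClass data.frame with one row per evaluated class: \code{class},
#'   \code{P}, \code{R}, \code{F1}, \code{AP}, \code{TP}, \code{FP}, \code{FN}.
#' @slot map50 numeric, mean AP at IoU 0.5.
#' @slot map5095 numeric, mean AP averaged over IoU 0.5 to 0.95 step 0.05.
#' @export
setClass("EvalReport", representation(
  perClass = "data.frame", map50 = "numeric", map5095 = "numeric"))

#' TrainConfig: training hyperparameters
#'
#' Defaults follow the reference training recipe: 100 epochs, SGD with
#' momentum 0.937 and weight decay 5e-4, initial learning rate 0.01 decayed
#' to 1% of itself, 3 warmup epochs (bias learning rate starting at 0.1,
#' momentum warming from 1.5 is clamped to the nominal momentum), batch 16,
#' image size 640, mosaic disabled for the last 10 epochs, loss gains
#' 7.5 / 0.5 / 1.5 for box / classification / distribution-focal.
#'
#' @slot epochs,patience,batch,imgsz,closeMosaic,maxDet,seed integers.
#' @slot lr0,lrf,momentum,weightDecay,warmupEpochs,warmupMomentum,warmupBiasLr
#'   numerics.
#' @slot boxGain,clsGain,dflGain numeric loss gains.
#' @slot optimizer character, currently "sgd".
#' @slot pretrained logical; no bundled weights, random init unless the user
#'   supplies a checkpoint.
#' @export
setClass("TrainConfig", representation(
  epochs = "integer", patience = "integer", batch = "integer",
  imgsz = "integer", lr0 = "numeric", lrf = "numeric", momentum = "numeric",
  weightDecay = "numeric", warmupEpochs = "numeric",
  warmupMomentum = "numeric", warmupBiasLr = "numeric",
  closeMosaic = "integer", boxGain = "numeric", clsGain = "numeric",
  dflGain = "numeric", optimizer = "character", maxDet = "integer",
  seed = "integer", pretrained = "logical"))

setValidity("TrainConfig", function(object) {
  if (object@closeMosaic > object@epochs)
    "closeMosaic must not exceed epochs" else TRUE
})

#' Construct a TrainConfig
#'
#' @param epochs,patience,batch,imgsz,closeMosaic,maxDet,seed integer settings.
#' @param lr0,lrf,momentum,weightDecay,warmupEpochs,warmupMomentum,warmupBiasLr
#'   optimizer schedule settings.
#' @param boxGain,clsGain,dflGain loss component gains.
#' @param optimizer optimizer name ("sgd").
#' @param pretrained logical, load user-supplied weights if given to
#'   \code{\link{trainModel}}.
#' @return A validated \code{TrainConfig}.
#' @export
trainConfig <- function(epochs = 100L, patience = 50L, batch = 16L,
                        imgsz = 640L, lr0 = 0.01, lrf = 0.01,
                        momentum = 0.937, weightDecay = 5e-4,
                        warmupEpochs = 3.0, warmupMomentum = 1.5,
                        warmupBiasLr = 0.1, closeMosaic = 10L,
                        boxGain = 7.5, clsGain = 0.5, dflGain = 1.5,
                        optimizer = "sgd", maxDet = 300L, seed = 0L,
                        pretrained = FALSE) {
  new("TrainConfig", epochs = as.integer(epochs),
      patience = as.integer(patience), batch = as.integer(batch),
      imgsz = as.integer(imgsz), lr0 = lr0, lrf = lrf, momentum = momentum,
      weightDecay = weightDecay, warmupEpochs = warmupEpochs,
      warmupMomentum = warmupMomentum, warmupBiasLr = warmupBiasLr,
      closeMosaic = as.integer(closeMosaic), boxGain = boxGain,
      clsGain = clsGain, dflGain = dflGain, optimizer = optimizer,
      maxDet = as.integer(maxDet), seed = as.integer(seed),
      pretrained = pretrained)
}

# ---- generics and accessors -------------------------------------------------

#' Number of classes of an object
#' @param x a SceneConfig, ModelConfig or EvalReport.
#' @return integer count of classes.
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))

#' @rdname nClasses
#' @export
setMethod("nClasses", "SceneConfig", function(x) x@nClasses)

#' @rdname nClasses
#' @export
setMethod("nClasses", "ModelConfig", function(x) x@nClasses)

#' Normalized box annotations of a LabeledImage
#' @param x a \code{LabeledImage} or \code{MaskedScene}.
#' @return n x 5 matrix (class, cx, cy, w, h) for a \code{LabeledImage}; for a
#'   \code{MaskedScene}, pixel corner boxes derived from the masks (see
#'   \code{\link{maskToBbox}}) with the class in the first column.
#' @export
setGeneric("boxes", function(x) standardGeneric("boxes"))

#' @rdname boxes
#' @export
setMethod("boxes", "LabeledImage", function(x) x@boxes)

#' Raster of an image-bearing object
#' @param x a \code{LabeledImage} or \code{MaskedScene}.
#' @return H x W x 3 numeric array in [0,1].
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' @rdname imageData
#' @export
setMethod("imageData", "LabeledImage", function(x) x@image)

#' @rdname imageData
#' @export
setMethod("imageData", "MaskedScene", function(x) x@image)

#' Instance masks of a MaskedScene
#' @param x a \code{MaskedScene}.
#' @return list of logical H x W masks.
#' @export
setGeneric("instanceMasks", function(x) standardGeneric("instanceMasks"))

#' @rdname instanceMasks
#' @export
setMethod("instanceMasks", "MaskedScene", function(x) x@masks)

#' Class labels of a MaskedScene
#' @param x a \code{MaskedScene}.
#' @return integer vector of 0-based class ids.
#' @export
setGeneric("sceneLabels", function(x) standardGeneric("sceneLabels"))

#' @rdname sceneLabels
#' @export
setMethod("sceneLabels", "MaskedScene", function(x) x@labels)

#' Total parameter count
#' @param x a \code{ParamReport}.
#' @return numeric scalar.
#' @export
setGeneric("totalParams", function(x) standardGeneric("totalParams"))

#' @rdname totalParams
#' @export
setMethod("totalParams", "ParamReport", function(x) x@totalParams)

#' Trainable (gradient-carrying) parameter count
#' @param x a \code{ParamReport}.
#' @return numeric scalar.
#' @export
setGeneric("trainableParams", function(x) standardGeneric("trainableParams"))

#' @rdname trainableParams
#' @export
setMethod("trainableParams", "ParamReport", function(x) x@trainableParams)

#' Per-class evaluation table
#' @param x an \code{EvalReport}.
#' @return data.frame with one row per evaluated class.
#' @export
setGeneric("perClass", function(x) standardGeneric("perClass"))

#' @rdname perClass
#' @export
setMethod("perClass", "EvalReport", function(x) x@perClass)

#' Mean average precision at IoU 0.5
#' @param x an \code{EvalReport}.
#' @return numeric scalar in [0,1].
#' @export
setGeneric("map50", function(x) standardGeneric("map50"))

#' @rdname map50
#' @export
setMethod("map50", "EvalReport", function(x) x@map50)

#' Mean average precision averaged over IoU 0.5:0.05:0.95
#' @param x an \code{EvalReport}.
#' @return numeric scalar in [0,1].
#' @export
setGeneric("map5095", function(x) standardGeneric("map5095"))

#' @rdname map5095
#' @export
setMethod("map5095", "EvalReport", function(x) x@map5095)

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf("SceneConfig: %dx%d px, %d classes, %d-%d objects/scene, seed %d\n",
              object@imageSize[1L], object@imageSize[2L], object@nClasses,
              object@objectsPerImage[1L], object@objectsPerImage[2L],
              object@seed))
  cat(sprintf("  occlusion %.2f, blur %.2f, illumination [%.2f, %.2f]\n",
              object@occlusionProb, object@blurProb,
              object@illuminationRange[1L], object@illuminationRange[2L]))
})

setMethod("show", "MaskedScene", function(object) {
  d <- dim(object@image)
  cat(sprintf("MaskedScene: %dx%d px, %d instance(s) of %d class(es)\n",
              d[2L], d[1L], length(object@masks),
              length(unique(object@labels))))
})

setMethod("show", "LabeledImage", function(object) {
  d <- dim(object@image)
  cat(sprintf("LabeledImage: %dx%d px, %d box(es)\n",
              d[2L], d[1L], nrow(object@boxes)))
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(
    "ModelConfig: nc=%d, depth %.2f, width %.2f, ghost {%s}, CA %s, regMax %d\n",
    object@nClasses, object@depthMultiple, object@widthMultiple,
    paste(object@ghostLayers, collapse = ","),
    if (object@caEnabled) "on" else "off", object@regMax))
})

setMethod("show", "ParamReport", function(object) {
  cat(sprintf("ParamReport: %s total, %s trainable, %d layers\n",
              format(object@totalParams, big.mark = ","),
              format(object@trainableParams, big.mark = ","),
              nrow(object@perLayer)))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d class(es), mAP@0.5 = %.5f, mAP@0.5:0.95 = %.5f\n",
              nrow(object@perClass), object@map50, object@map5095))
  if (nrow(object@perClass)) {
    df <- object@perClass
    df[, c("P", "R", "F1", "AP")] <- round(df[, c("P", "R", "F1", "AP")], 5L)
    print(df, row.names = FALSE)
  }
})
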