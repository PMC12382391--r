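# Declarative construction of the nano-scale detector and its ghost /
# context-aggregation variants, with exact closed-form parameter accounting.
#
# Topology at depth 0.33 / width 0.25: backbone widths 16-32-64-128-256 with
# C2f blocks and a final SPPF; a path-aggregation neck with two upsample +
# concat stages and two downsample + concat stages; three decoupled heads at
# strides 8/16/32 with distribution-focal box regression (regMax bins, frozen
# decode projection). Ghost replacement applies to the four stride-2 backbone
# convolutions (0-based layer ids 1,3,5,7); the optional context-aggregation
# block sits on the 384-channel top-down concatenation (deepest neck stream
# upsampled and fused with the stride-16 backbone stream), before the
# following C2f.

#' Parameter count of a standard convolution block
#'
#' Bias-free convolution plus the two batch-norm affine terms per output
#' channel: \code{cin * cout * k^2 + 2 * cout}.
#'
#' @param cin,cout channel counts.
#' @param k square kernel size.
#' @return integer parameter count.
#' @examples
#' convBlockParams(16, 32, 3)  # 4672
#' @export
convBlockParams <- function(cin, cout, k) cin * cout * k^2 + 2 * cout

#' Parameter count of a ghost convolution block
#'
#' Primary branch: standard convolution to \code{cout/2} channels with kernel
#' \code{kPrimary}; cheap branch: depthwise \code{dwKernel} convolution of the
#' primary output (one \code{dwKernel^2} filter per channel) with its own
#' batch norm. The block output concatenates both halves.
#'
#' @param cin,cout channel counts (\code{cout} must be even).
#' @param kPrimary primary kernel (inherited from the replaced convolution).
#' @param dwKernel cheap-operation depthwise kernel.
#' @return integer parameter count.
#' @examples
#' ghostConvParams(16, 32)    # 2768
#' ghostConvParams(128, 256)  # 151168
#' @export
ghostConvParams <- function(cin, cout, kPrimary = 3, dwKernel = 5) {
  stopifnot(cout %% 2 == 0)
  half <- cout / 2
  convBlockParams(cin, half, kPrimary) + half * dwKernel^2 + 2 * half
}

#' Parameter count of the context-aggregation block
#'
#' Two scalar projections (1x1, c to 1, bias + 1-channel batch norm, c + 3
#' parameters each) and one value projection (1x1, c to c, bias + c-channel
#' batch norm): \code{2*(c + 3) + c^2 + 3c}.
#'
#' @param ch block channel count (384 at the top-down neck concatenation).
#' @return integer parameter count.
#' @examples
#' caBlockParams(384)  # 149382
#' @export
caBlockParams <- function(ch = 384) 2 * (ch + 3) + ch^2 + 3 * ch

#' Ghost-module compression and speed-up ratios
#'
#' Exact rational evaluation of the parameter compression ratio
#' \code{r_c = n c k^2 / (n/s c k^2 + (s-1) n/s d^2)} and the corresponding
#' speed-up ratio (identical in value once the shared spatial factor
#' cancels); both tend to \code{s} as \code{c} grows.
#'
#' @param s ghost ratio (ghost features per intrinsic feature; no ghost
#'   branch at s = 1).
#' @param c input channel count.
#' @param k primary kernel size.
#' @param d cheap-operation kernel size.
#' @return ratio as a numeric scalar.
#' @examples
#' compressionRatio(2, 256, 3, 3)  # ~1.992
#' @export
compressionRatio <- function(s, c, k, d) {
  (c * k * k) / (c * k * k / s + (s - 1) * d * d / s)
}

#' @rdname compressionRatio
#' @param hw output spatial size h' * w' (cancels; accepted for completeness).
#' @param n output channel count (cancels; accepted for completeness).
#' @export
speedupRatio <- function(s, c, k, d, hw = 1, n = 1) {
  (n * hw * c * k * k) /
    (n / s * hw * c * k * k + (s - 1) * n / s * hw * d * d)
}

# width/depth scaling of the layer inventory
#' @noRd
scaleWidth <- function(c, cfg)
  as.integer(ceiling(min(c, cfg@maxChannels) * cfg@widthMultiple / 8) * 8)

#' @noRd
scaleDepth <- function(n, cfg) max(1L, as.integer(round(n * cfg@depthMultiple)))

#' Build a detector model from a declarative configuration
#'
#' Constructs the live network (parameters initialised from the current RNG
#' state) according to a \code{\link{modelConfig}}: baseline, ghost variant,
#' context-aggregation variant, or both.
#'
#' @param cfg a \code{\link{modelConfig}}.
#' @return An opaque model object (class \code{ricePestModel}) accepted by
#'   \code{\link{countParams}}, \code{\link{forwardPass}},
#'   \code{\link{trainModel}} and \code{\link{predictModel}}.
#' @examples
#' m <- buildModel(modelConfig(nClasses = 15))
#' totalParams(countParams(m))  # 3013773
#' @export
buildModel <- function(cfg) {
  stopifnot(is(cfg, "ModelConfig"))
  validObject(cfg)
  c1 <- scaleWidth(64, cfg); c2 <- scaleWidth(128, cfg)
  c3 <- scaleWidth(256, cfg); c4 <- scaleWidth(512, cfg)
  c5 <- scaleWidth(1024, cfg)
  n3 <- scaleDepth(3, cfg); n6 <- scaleDepth(6, cfg)
  g <- function(id, cin, cout) {
    if (id %in% cfg@ghostLayers) nnGhostConv(cin, cout, 3L, 2L, 5L)
    else nnConv(cin, cout, 3L, 2L)
  }
  layers <- list(); names_ <- character(); from <- list()
  addL <- function(mod, nm, fr = -1L) {
    layers[[length(layers) + 1L]] <<- mod
    names_[length(names_) + 1L] <<- nm
    from[[length(from) + 1L]] <<- as.integer(fr)
    length(layers)
  }
  addL(nnConv(3L, c1, 3L, 2L), "conv0")
  addL(g(1L, c1, c2), if (1L %in% cfg@ghostLayers) "ghost1" else "conv1")
  addL(nnC2f(c2, c2, n3, TRUE), "c2f2")
  addL(g(3L, c2, c3), if (3L %in% cfg@ghostLayers) "ghost3" else "conv3")
  iP3 <- addL(nnC2f(c3, c3, n6, TRUE), "c2f4")
  addL(g(5L, c3, c4), if (5L %in% cfg@ghostLayers) "ghost5" else "conv5")
  iP4 <- addL(nnC2f(c4, c4, n6, TRUE), "c2f6")
  addL(g(7L, c4, c5), if (7L %in% cfg@ghostLayers) "ghost7" else "conv7")
  addL(nnC2f(c5, c5, n3, TRUE), "c2f8")
  iSppf <- addL(nnSPPF(c5, c5), "sppf9")
  addL(nnUpsample(), "up10")
  iCat <- addL(nnConcat(), "cat11", c(-1L, iP4))
  if (cfg@caEnabled) addL(nnCABlock(c5 + c4), "ca")
  iN1 <- addL(nnC2f(c5 + c4, c4, n3, FALSE), "c2f12")
  addL(nnUpsample(), "up13")
  addL(nnConcat(), "cat14", c(-1L, iP3))
  iH1 <- addL(nnC2f(c4 + c3, c3, n3, FALSE), "c2f15")
  addL(nnConv(c3, c3, 3L, 2L), "conv16")
  addL(nnConcat(), "cat17", c(-1L, iN1))
  iH2 <- addL(nnC2f(c3 + c4, c4, n3, FALSE), "c2f18")
  addL(nnConv(c4, c4, 3L, 2L), "conv19")
  addL(nnConcat(), "cat20", c(-1L, iSppf))
  iH3 <- addL(nnC2f(c4 + c5, c5, n3, FALSE), "c2f21")
  det <- nnDetect(c(c3, c4, c5), cfg@nClasses, cfg@regMax)
  addL(det, "detect", c(iH1, iH2, iH3))

  model <- new.env(parent = emptyenv())
  model$cfg <- cfg
  model$layers <- layers
  model$from <- from
  model$layerNames <- names_
  model$detect <- det
  model$strides <- c(8L, 16L, 32L)
  model$leaves <- do.call(c, lapply(layers, `[[`, "leafList"))
  class(model) <- "ricePestModel"
  model
}

#' @export
print.ricePestModel <- function(x, ...) {
  pr <- countParams(x)
  cat(sprintf("ricePestModel: nc=%d, %d layers, %s params (%s trainable)\n",
              x$cfg@nClasses, length(x$layers),
              format(pr@totalParams, big.mark = ","),
              format(pr@trainableParams, big.mark = ",")))
  invisible(x)
}

#' @noRd
leafParamCount <- function(leaf)
  sum(vapply(leaf$pnames, function(p) length(get(p, envir = leaf)),
             numeric(1L)))

#' Exact parameter accounting of a live model
#'
#' Counts every parameter array of the model. Trainable parameters exclude
#' the frozen distribution-focal decode projection (regMax entries), which is
#' registered as a fixed buffer.
#'
#' @param model a model built by \code{\link{buildModel}}.
#' @return A \code{\link{ParamReport-class}}: total, trainable, per-layer
#'   table.
#' @examples
#' countParams(buildModel(modelConfig(ghost = TRUE, ca = TRUE)))
#' @export
countParams <- function(model) {
  stopifnot(inherits(model, "ricePestModel"))
  per <- vapply(seq_along(model$layers), function(i) {
    ly <- model$layers[[i]]
    n <- sum(vapply(ly$leafList, leafParamCount, numeric(1L)))
    if (!is.null(ly$frozenParams)) n <- n + ly$frozenParams
    n
  }, numeric(1L))
  total <- sum(per)
  frozen <- sum(vapply(model$layers, function(ly)
    if (is.null(ly$frozenParams)) 0 else ly$frozenParams, numeric(1L)))
  new("ParamReport", totalParams = total, trainableParams = total - frozen,
      perLayer = data.frame(name = model$layerNames, params = per,
                            stringsAsFactors = FALSE))
}

# ---- feature-map helpers and standalone block surfaces ----------------------

#' @noRd
featureToTensor <- function(x) {
  d <- dim(x)
  newTensor(matrix(x, d[1L] * d[2L], d[3L]), d[1L], d[2L], 1L)
}

#' @noRd
tensorToFeature <- function(t) array(t$X, c(t$H, t$W, ncol(t$X)))

#' Construct a standalone ghost convolution module
#'
#' A dual-branch block: the primary branch is a standard strided convolution
#' producing the intrinsic half of the output channels; the cheap branch
#' derives the other ("ghost") half by a depthwise convolution of the
#' intrinsic features. Both halves pass through batch norm and SiLU.
#'
#' @param cin,cout input/output channels (\code{cout} even).
#' @param kPrimary,stride primary convolution kernel and stride.
#' @param dwKernel depthwise cheap-operation kernel.
#' @return An opaque module for \code{\link{ghostForward}}.
#' @export
ghostConv <- function(cin, cout, kPrimary = 3L, stride = 2L, dwKernel = 5L) {
  nnGhostConv(as.integer(cin), as.integer(cout), as.integer(kPrimary),
              as.integer(stride), as.integer(dwKernel))
}

#' Run a ghost convolution on a feature map
#'
#' @param module a \code{\link{ghostConv}} module.
#' @param x H x W x cin numeric array.
#' @param train logical; batch statistics (TRUE) or running statistics.
#' @return H' x W' x cout array: first half intrinsic features, second half
#'   their depthwise cheap transforms.
#' @export
ghostForward <- function(module, x, train = TRUE) {
  if (dim(x)[3L] != module$primary$cin)
    stop("input channel count does not match the module")
  tensorToFeature(module$fwd(featureToTensor(x), train))
}

#' Construct a standalone context-aggregation block
#'
#' @param channels block channel count (default 384).
#' @return An opaque module for \code{\link{caForward}}.
#' @export
caBlock <- function(channels = 384L) nnCABlock(as.integer(channels))

#' Run the context-aggregation block on a feature map
#'
#' Residual global-context attention: softmax over the N = H*W positions of a
#' scalar key projection aggregates the value projection into one context
#' vector, re-injected at every position modulated by the softmax of a second
#' scalar projection (the reweighting map). Output shape equals input shape.
#'
#' @param module a \code{\link{caBlock}} module.
#' @param x H x W x channels numeric array.
#' @param train logical; batch statistics (TRUE) or running statistics.
#' @return H x W x channels array.
#' @export
caForward <- function(module, x, train = TRUE) {
  if (dim(x)[3L] != module$ch)
    stop("input channel count does not match the block")
  tensorToFeature(module$fwd(featureToTensor(x), train))
}

# ---- graph executor ---------------------------------------------------------

#' @noRd
modelForwardT <- function(model, tin, train = FALSE) {
  outs <- vector("list", length(model$layers))
  x <- tin
  for (i in seq_along(model$layers)) {
    fr <- model$from[[i]]
    ins <- lapply(fr, function(f) if (f == -1L) x else outs[[f]])
    mod <- model$layers[[i]]
    x <- mod$fwd(if (mod$multi) ins else ins[[1L]], train)
    outs[[i]] <- x
  }
  model$.outs <- outs
  x
}

#' @noRd
modelBackwardT <- function(model, dLevels) {
  L <- length(model$layers)
  douts <- vector("list", L)
  douts[[L]] <- dLevels
  for (i in L:1) {
    d <- douts[[i]]
    if (is.null(d)) next
    mod <- model$layers[[i]]
    dIns <- mod$bwd(d)
    if (!mod$multi) dIns <- list(dIns)
    fr <- model$from[[i]]
    for (j in seq_along(fr)) {
      f <- fr[j]
      if (f == -1L) f <- i - 1L
      if (f == 0L) next
      douts[[f]] <- if (is.null(douts[[f]])) dIns[[j]]
                    else douts[[f]] + dIns[[j]]
    }
    douts[i] <- list(NULL)  # free memory without shifting indices
  }
  invisible(NULL)
}

#' Forward pass of a detector on a batch of images
#'
#' @param model a model from \code{\link{buildModel}}.
#' @param images list of H x W x 3 arrays (H and W divisible by 32).
#' @param train logical; use batch statistics and keep backward caches.
#' @return list of three per-scale raw prediction maps, each an array
#'   H/stride x W/stride x (4*regMax + nClasses) x N with the
#'   distribution-focal logits first and class logits last, for strides
#'   8, 16, 32.
#' @examples
#' m <- buildModel(modelConfig())
#' maps <- forwardPass(m, list(array(0.5, c(64, 64, 3))))
#' vapply(maps, function(x) dim(x)[1], numeric(1))  # 8 4 2
#' @export
forwardPass <- function(model, images, train = FALSE) {
  stopifnot(inherits(model, "ricePestModel"))
  if (!is.list(images)) images <- list(images)
  d <- dim(images[[1L]])
  if (any(d[1:2] %% 32L != 0L))
    stop("image size must be divisible by 32")
  levels <- modelForwardT(model, tensorFromImages(images), train)
  lapply(levels, function(t) {
    arr <- array(t$X, c(t$H, t$W, t$N, ncol(t$X)))
    aperm(arr, c(1L, 2L, 4L, 3L))
  })
}
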