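# Minimal CNN engine used by the architecture module. Activations are stored
# channels-last as S x C matrices, S = H*W*N with y fastest, then x, then
# image index; convolution is im2col (sparse row gather) followed by a BLAS
# matrix product, and every layer carries a hand-derived backward pass. For a
# fixed tap of a convolution kernel the output-to-input position map is
# injective, so the col2im scatter in the backward pass is a plain indexed
# add (the padding row is discarded afterwards).
#
# These internals are deliberately plain environments rather than S4: they sit
# in the training hot loop and are not part of the user-facing surface.

#' @noRd
newTensor <- function(X, H, W, N) list(X = X, H = H, W = W, N = N)

# Stack a list of H x W x 3 images into an activation tensor.
#' @noRd
tensorFromImages <- function(imgs) {
  h <- dim(imgs[[1L]])[1L]; w <- dim(imgs[[1L]])[2L]
  n <- length(imgs)
  X <- matrix(0, h * w * n, 3L)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * h * w + 1L):(i * h * w)
    for (ch in 1:3) X[rows, ch] <- as.vector(imgs[[i]][, , ch])
  }
  newTensor(X, h, w, n)
}

# im2col gather index: G[r, t] is the input row feeding tap t of output row r
# (0 for padding). Output rows ordered y, x, image.
#' @noRd
convIndex <- function(H, W, N, k, s, p) {
  Ho <- (H + 2L * p - k) %/% s + 1L
  Wo <- (W + 2L * p - k) %/% s + 1L
  yo <- rep.int(0:(Ho - 1L), Wo)
  xo <- rep(0:(Wo - 1L), each = Ho)
  nOff <- rep((0:(N - 1L)) * (H * W), each = Ho * Wo)
  G <- matrix(0L, Ho * Wo * N, k * k)
  t <- 0L
  for (kj in 0:(k - 1L)) for (ki in 0:(k - 1L)) {
    t <- t + 1L
    y <- yo * s + ki - p
    x <- xo * s + kj - p
    valid <- (y >= 0L & y < H & x >= 0L & x < W)
    base <- (y + 1L + H * x) * valid
    G[, t] <- rep.int(base, N) + nOff * rep.int(valid, N)
  }
  list(G = G, Ho = Ho, Wo = Wo)
}

#' @noRd
rowRep <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

# ---- leaf: convolution (+ optional bias, batch norm, SiLU) ------------------

#' @noRd
nnConv <- function(cin, cout, k = 1L, s = 1L, bias = FALSE, bn = TRUE,
                   act = bn, biasInit = 0) {
  e <- new.env(parent = emptyenv())
  e$type <- "conv"; e$multi <- FALSE
  e$cin <- cin; e$cout <- cout; e$k <- as.integer(k); e$s <- as.integer(s)
  e$p <- e$k %/% 2L
  e$W <- matrix(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                k * k * cin, cout)
  e$pnames <- "W"; e$decay <- "W"; e$biasP <- character(0)
  e$useBias <- bias; e$useBn <- bn; e$act <- act
  if (bias) {
    e$b <- rep(as.numeric(biasInit), length.out = cout)
    e$pnames <- c(e$pnames, "b"); e$biasP <- "b"
  }
  if (bn) {
    e$bng <- rep(1, cout); e$bnb <- numeric(cout)
    e$rm <- numeric(cout); e$rv <- rep(1, cout)
    e$bnMom <- 0.03
    e$pnames <- c(e$pnames, "bng", "bnb"); e$biasP <- c(e$biasP, "bnb")
  }
  e$leafList <- list(e)
  e$cc <- new.env(parent = emptyenv())

  gather <- function(tin) {
    if (e$k == 1L && e$s == 1L) return(tin$X)
    key <- paste(tin$H, tin$W, tin$N)
    if (is.null(e$cc$key) || e$cc$key != key) {
      e$cc$ci <- convIndex(tin$H, tin$W, tin$N, e$k, e$s, e$p)
      e$cc$key <- key
    }
    ci <- e$cc$ci
    Xz <- rbind(0, tin$X)
    kk <- e$k * e$k
    P <- matrix(0, nrow(ci$G), kk * e$cin)
    for (t in seq_len(kk))
      P[, ((t - 1L) * e$cin + 1L):(t * e$cin)] <-
        Xz[ci$G[, t] + 1L, , drop = FALSE]
    P
  }

  e$fwd <- function(tin, train) {
    P <- gather(tin)
    if (e$k == 1L && e$s == 1L) { Ho <- tin$H; Wo <- tin$W }
    else { Ho <- e$cc$ci$Ho; Wo <- e$cc$ci$Wo }
    Y <- P %*% e$W
    n <- nrow(Y)
    if (e$useBias) Y <- Y + rowRep(e$b, n)
    z <- Y
    if (e$useBn) {
      if (train) {
        mu <- colMeans(Y)
        yc <- Y - rowRep(mu, n)
        v <- colMeans(yc * yc)
        istd <- 1 / sqrt(v + 1e-3)
        xhat <- yc * rowRep(istd, n)
        e$rm <- (1 - e$bnMom) * e$rm + e$bnMom * mu
        e$rv <- (1 - e$bnMom) * e$rv + e$bnMom * v
        e$cc$xhat <- xhat; e$cc$istd <- istd
      } else {
        xhat <- (Y - rowRep(e$rm, n)) * rowRep(1 / sqrt(e$rv + 1e-3), n)
      }
      z <- xhat * rowRep(e$bng, n) + rowRep(e$bnb, n)
    }
    out <- z
    if (e$act) {
      sig <- 1 / (1 + exp(-z))
      out <- z * sig
      if (train) { e$cc$sig <- sig; e$cc$z <- z }
    }
    if (train) {
      e$cc$P <- P; e$cc$tin <- tin
    }
    newTensor(out, Ho, Wo, tin$N)
  }

  e$bwd <- function(dY) {
    n <- nrow(dY)
    d <- dY
    if (e$act) {
      sig <- e$cc$sig
      d <- d * (sig * (1 + e$cc$z * (1 - sig)))
    }
    if (e$useBn) {
      xhat <- e$cc$xhat; istd <- e$cc$istd
      e$g_bng <- e$g_bng + colSums(d * xhat)
      e$g_bnb <- e$g_bnb + colSums(d)
      dxh <- d * rowRep(e$bng, n)
      m1 <- colMeans(dxh)
      m2 <- colMeans(dxh * xhat)
      d <- (dxh - rowRep(m1, n) - xhat * rowRep(m2, n)) * rowRep(istd, n)
    }
    if (e$useBias) e$g_b <- e$g_b + colSums(d)
    P <- e$cc$P
    e$g_W <- e$g_W + crossprod(P, d)
    dP <- d %*% t(e$W)
    if (e$k == 1L && e$s == 1L) return(dP)
    tin <- e$cc$tin
    ci <- e$cc$ci
    dXz <- matrix(0, nrow(tin$X) + 1L, e$cin)
    kk <- e$k * e$k
    for (t in seq_len(kk)) {
      idx <- ci$G[, t] + 1L
      dXz[idx, ] <- dXz[idx, ] +
        dP[, ((t - 1L) * e$cin + 1L):(t * e$cin), drop = FALSE]
    }
    dXz[-1L, , drop = FALSE]
  }
  e
}

# ---- leaf: depthwise convolution (+ batch norm + SiLU) ----------------------

#' @noRd
nnDwConv <- function(ch, k = 5L) {
  e <- new.env(parent = emptyenv())
  e$type <- "dwconv"; e$multi <- FALSE
  e$ch <- ch; e$k <- as.integer(k); e$p <- e$k %/% 2L
  e$Wd <- matrix(rnorm(k * k * ch, 0, sqrt(2 / (k * k))), k * k, ch)
  e$bng <- rep(1, ch); e$bnb <- numeric(ch)
  e$rm <- numeric(ch); e$rv <- rep(1, ch)
  e$bnMom <- 0.03
  e$act <- TRUE
  e$pnames <- c("Wd", "bng", "bnb"); e$decay <- "Wd"; e$biasP <- "bnb"
  e$leafList <- list(e)
  e$cc <- new.env(parent = emptyenv())

  e$fwd <- function(tin, train) {
    key <- paste(tin$H, tin$W, tin$N)
    if (is.null(e$cc$key) || e$cc$key != key) {
      e$cc$ci <- convIndex(tin$H, tin$W, tin$N, e$k, 1L, e$p)
      e$cc$key <- key
    }
    G <- e$cc$ci$G
    Xz <- rbind(0, tin$X)
    n <- nrow(tin$X)
    Y <- matrix(0, n, e$ch)
    for (t in seq_len(e$k^2))
      Y <- Y + Xz[G[, t] + 1L, , drop = FALSE] * rowRep(e$Wd[t, ], n)
    if (train) { mu <- colMeans(Y); yc <- Y - rowRep(mu, n)
      v <- colMeans(yc * yc); istd <- 1 / sqrt(v + 1e-3)
      xhat <- yc * rowRep(istd, n)
      e$rm <- (1 - e$bnMom) * e$rm + e$bnMom * mu
      e$rv <- (1 - e$bnMom) * e$rv + e$bnMom * v
      e$cc$xhat <- xhat; e$cc$istd <- istd
    } else {
      xhat <- (Y - rowRep(e$rm, n)) * rowRep(1 / sqrt(e$rv + 1e-3), n)
    }
    z <- xhat * rowRep(e$bng, n) + rowRep(e$bnb, n)
    out <- z
    if (e$act) {
      sig <- 1 / (1 + exp(-z))
      out <- z * sig
      if (train) { e$cc$sig <- sig }
    }
    if (train) { e$cc$Xz <- Xz; e$cc$z <- z }
    newTensor(out, tin$H, tin$W, tin$N)
  }

  e$bwd <- function(dY) {
    n <- nrow(dY)
    d <- if (e$act) {
      sig <- e$cc$sig
      dY * (sig * (1 + e$cc$z * (1 - sig)))
    } else dY
    xhat <- e$cc$xhat; istd <- e$cc$istd
    e$g_bng <- e$g_bng + colSums(d * xhat)
    e$g_bnb <- e$g_bnb + colSums(d)
    dxh <- d * rowRep(e$bng, n)
    m1 <- colMeans(dxh); m2 <- colMeans(dxh * xhat)
    d <- (dxh - rowRep(m1, n) - xhat * rowRep(m2, n)) * rowRep(istd, n)
    G <- e$cc$ci$G; Xz <- e$cc$Xz
    dXz <- matrix(0, nrow(Xz), e$ch)
    for (t in seq_len(e$k^2)) {
      idx <- G[, t] + 1L
      Xt <- Xz[idx, , drop = FALSE]
      e$g_Wd[t, ] <- e$g_Wd[t, ] + colSums(d * Xt)
      dXz[idx, ] <- dXz[idx, ] + d * rowRep(e$Wd[t, ], n)
    }
    dXz[-1L, , drop = FALSE]
  }
  e
}

# ---- leaf: 5x5 stride-1 max pooling -----------------------------------------

#' @noRd
nnMaxPool <- function(k = 5L) {
  e <- new.env(parent = emptyenv())
  e$type <- "maxpool"; e$multi <- FALSE
  e$k <- as.integer(k); e$p <- e$k %/% 2L
  e$pnames <- character(0); e$decay <- character(0); e$biasP <- character(0)
  e$leafList <- list()
  e$cc <- new.env(parent = emptyenv())
  e$fwd <- function(tin, train) {
    key <- paste(tin$H, tin$W, tin$N)
    if (is.null(e$cc$key) || e$cc$key != key) {
      e$cc$ci <- convIndex(tin$H, tin$W, tin$N, e$k, 1L, e$p)
      e$cc$key <- key
    }
    G <- e$cc$ci$G
    C <- ncol(tin$X)
    Xz <- rbind(-Inf, tin$X)
    n <- nrow(tin$X)
    Y <- matrix(-Inf, n, C)
    A <- matrix(1L, n, C)
    for (t in seq_len(e$k^2)) {
      cand <- Xz[G[, t] + 1L, , drop = FALSE]
      upd <- cand > Y
      Y[upd] <- cand[upd]
      A[upd] <- t
    }
    if (train) { e$cc$A <- A; e$cc$n <- n; e$cc$C <- C }
    newTensor(Y, tin$H, tin$W, tin$N)
  }
  e$bwd <- function(dY) {
    A <- e$cc$A; G <- e$cc$ci$G
    dXz <- matrix(0, e$cc$n + 1L, e$cc$C)
    for (t in seq_len(e$k^2)) {
      m <- A == t
      if (!any(m)) next
      idx <- G[, t] + 1L
      dXz[idx, ] <- dXz[idx, ] + dY * m
    }
    dXz[-1L, , drop = FALSE]
  }
  e
}

# ---- leaf: nearest-neighbour 2x upsampling ----------------------------------

#' @noRd
nnUpsample <- function() {
  e <- new.env(parent = emptyenv())
  e$type <- "upsample"; e$multi <- FALSE
  e$pnames <- character(0); e$decay <- character(0); e$biasP <- character(0)
  e$leafList <- list()
  e$cc <- new.env(parent = emptyenv())
  e$fwd <- function(tin, train) {
    key <- paste(tin$H, tin$W, tin$N)
    if (is.null(e$cc$key) || e$cc$key != key) {
      H <- tin$H; W <- tin$W; N <- tin$N
      Ho <- 2L * H; Wo <- 2L * W
      yo <- rep.int(0:(Ho - 1L), Wo)
      xo <- rep(0:(Wo - 1L), each = Ho)
      base <- (yo %/% 2L) + 1L + H * (xo %/% 2L)
      m <- rep.int(base, N) + rep((0:(N - 1L)) * (H * W), each = Ho * Wo)
      e$cc$m <- m; e$cc$key <- key
    }
    newTensor(tin$X[e$cc$m, , drop = FALSE], 2L * tin$H, 2L * tin$W, tin$N)
  }
  e$bwd <- function(dY) {
    d <- rowsum(dY, e$cc$m)
    dimnames(d) <- NULL
    d
  }
  e
}

# ---- leaf: channel concatenation --------------------------------------------

#' @noRd
nnConcat <- function() {
  e <- new.env(parent = emptyenv())
  e$type <- "concat"; e$multi <- TRUE
  e$pnames <- character(0); e$decay <- character(0); e$biasP <- character(0)
  e$leafList <- list()
  e$cc <- new.env(parent = emptyenv())
  e$fwd <- function(tins, train) {
    e$cc$widths <- vapply(tins, function(t) ncol(t$X), integer(1L))
    newTensor(do.call(cbind, lapply(tins, `[[`, "X")),
              tins[[1L]]$H, tins[[1L]]$W, tins[[1L]]$N)
  }
  e$bwd <- function(dY) {
    w <- e$cc$widths
    ends <- cumsum(w); starts <- ends - w + 1L
    lapply(seq_along(w), function(i) dY[, starts[i]:ends[i], drop = FALSE])
  }
  e
}

# ---- composite: ghost convolution -------------------------------------------

#' @noRd
nnGhostConv <- function(cin, cout, k = 3L, s = 2L, dw = 5L) {
  stopifnot(cout %% 2L == 0L)
  e <- new.env(parent = emptyenv())
  e$type <- "ghost"; e$multi <- FALSE
  half <- cout %/% 2L
  e$primary <- nnConv(cin, half, k, s)
  e$cheap <- nnDwConv(half, dw)
  e$leafList <- c(e$primary$leafList, e$cheap$leafList)
  e$half <- half
  e$cc <- new.env(parent = emptyenv())
  e$fwd <- function(tin, train) {
    y1 <- e$primary$fwd(tin, train)
    y2 <- e$cheap$fwd(y1, train)
    newTensor(cbind(y1$X, y2$X), y1$H, y1$W, y1$N)
  }
  e$bwd <- function(dY) {
    h <- e$half
    d1 <- dY[, seq_len(h), drop = FALSE]
    d2 <- dY[, h + seq_len(h), drop = FALSE]
    e$primary$bwd(e$cheap$bwd(d2) + d1)
  }
  e
}

# ---- composite: bottleneck and C2f ------------------------------------------

#' @noRd
nnBottleneck <- function(ch, shortcut = TRUE) {
  e <- new.env(parent = emptyenv())
  e$type <- "bottleneck"; e$multi <- FALSE
  e$cv1 <- nnConv(ch, ch, 3L, 1L)
  e$cv2 <- nnConv(ch, ch, 3L, 1L)
  e$shortcut <- shortcut
  e$leafList <- c(e$cv1$leafList, e$cv2$leafList)
  e$fwd <- function(tin, train) {
    y <- e$cv2$fwd(e$cv1$fwd(tin, train), train)
    if (e$shortcut) y$X <- y$X + tin$X
    y
  }
  e$bwd <- function(dY) {
    d <- e$cv1$bwd(e$cv2$bwd(dY))
    if (e$shortcut) d <- d + dY
    d
  }
  e
}

#' @noRd
nnC2f <- function(cin, cout, n = 1L, shortcut = FALSE) {
  e <- new.env(parent = emptyenv())
  e$type <- "c2f"; e$multi <- FALSE
  ch <- cout %/% 2L
  e$ch <- ch; e$n <- n
  e$cv1 <- nnConv(cin, 2L * ch, 1L, 1L)
  e$blocks <- lapply(seq_len(n), function(i) nnBottleneck(ch, shortcut))
  e$cv2 <- nnConv((2L + n) * ch, cout, 1L, 1L)
  e$leafList <- c(e$cv1$leafList,
                  do.call(c, lapply(e$blocks, `[[`, "leafList")),
                  e$cv2$leafList)
  e$fwd <- function(tin, train) {
    y <- e$cv1$fwd(tin, train)
    parts <- list(newTensor(y$X[, seq_len(e$ch), drop = FALSE], y$H, y$W, y$N),
                  newTensor(y$X[, e$ch + seq_len(e$ch), drop = FALSE],
                            y$H, y$W, y$N))
    cur <- parts[[2L]]
    for (b in e$blocks) {
      cur <- b$fwd(cur, train)
      parts <- c(parts, list(cur))
    }
    cat_ <- do.call(cbind, lapply(parts, `[[`, "X"))
    e$cv2$fwd(newTensor(cat_, y$H, y$W, y$N), train)
  }
  e$bwd <- function(dY) {
    d <- e$cv2$bwd(dY)
    np <- 2L + e$n
    dparts <- lapply(seq_len(np), function(i)
      d[, ((i - 1L) * e$ch + 1L):(i * e$ch), drop = FALSE])
    g <- dparts[[np]]
    for (i in rev(seq_len(e$n))) {
      g <- e$blocks[[i]]$bwd(g)
      g <- g + dparts[[i + 1L]]
    }
    e$cv1$bwd(cbind(dparts[[1L]], g))
  }
  e
}

# ---- composite: SPPF --------------------------------------------------------

#' @noRd
nnSPPF <- function(cin, cout, k = 5L) {
  e <- new.env(parent = emptyenv())
  e$type <- "sppf"; e$multi <- FALSE
  ch <- cin %/% 2L
  e$cv1 <- nnConv(cin, ch, 1L, 1L)
  e$mp <- lapply(1:3, function(i) nnMaxPool(k))
  e$cv2 <- nnConv(4L * ch, cout, 1L, 1L)
  e$ch <- ch
  e$leafList <- c(e$cv1$leafList, e$cv2$leafList)
  e$fwd <- function(tin, train) {
    a <- e$cv1$fwd(tin, train)
    m1 <- e$mp[[1L]]$fwd(a, train)
    m2 <- e$mp[[2L]]$fwd(m1, train)
    m3 <- e$mp[[3L]]$fwd(m2, train)
    e$cv2$fwd(newTensor(cbind(a$X, m1$X, m2$X, m3$X), a$H, a$W, a$N), train)
  }
  e$bwd <- function(dY) {
    d <- e$cv2$bwd(dY)
    ch <- e$ch
    dp <- lapply(0:3, function(i) d[, i * ch + seq_len(ch), drop = FALSE])
    d3 <- e$mp[[3L]]$bwd(dp[[4L]])
    d2 <- e$mp[[2L]]$bwd(dp[[3L]] + d3)
    d1 <- e$mp[[1L]]$bwd(dp[[2L]] + d2)
    e$cv1$bwd(dp[[1L]] + d1)
  }
  e
}

# ---- composite: context-aggregation block -----------------------------------

# Simplified non-local attention: a spatial softmax over a 1-channel key
# projection aggregates the value projection into one global context vector
# per image, which is re-injected residually, modulated per position by a
# second spatial softmax (the reweighting map). Projections are 1x1
# convolutions with bias followed by batch norm (1-channel norm for the two
# scalar projections, c-channel norm for the value projection).
#' @noRd
nnCABlock <- function(ch) {
  e <- new.env(parent = emptyenv())
  e$type <- "ca"; e$multi <- FALSE
  e$ch <- ch
  e$pk <- nnConv(ch, 1L, 1L, 1L, bias = TRUE, bn = TRUE, act = FALSE)
  e$pa <- nnConv(ch, 1L, 1L, 1L, bias = TRUE, bn = TRUE, act = FALSE)
  e$pv <- nnConv(ch, ch, 1L, 1L, bias = TRUE, bn = TRUE, act = FALSE)
  e$leafList <- c(e$pk$leafList, e$pa$leafList, e$pv$leafList)
  e$cc <- new.env(parent = emptyenv())
  softmaxCol <- function(v) {
    z <- exp(v - max(v)); z / sum(z)
  }
  e$fwd <- function(tin, train) {
    kk <- e$pk$fwd(tin, train)$X[, 1L]
    aa <- e$pa$fwd(tin, train)$X[, 1L]
    V <- e$pv$fwd(tin, train)$X
    hw <- tin$H * tin$W
    Y <- tin$X
    sAll <- numeric(length(kk)); aAll <- numeric(length(aa))
    gAll <- matrix(0, tin$N, e$ch)
    for (nI in seq_len(tin$N)) {
      rows <- ((nI - 1L) * hw + 1L):(nI * hw)
      s <- softmaxCol(kk[rows])
      a <- softmaxCol(aa[rows])
      g <- colSums(V[rows, , drop = FALSE] * s)
      Y[rows, ] <- Y[rows, ] + a %o% g
      sAll[rows] <- s; aAll[rows] <- a; gAll[nI, ] <- g
    }
    if (train) {
      e$cc$s <- sAll; e$cc$a <- aAll; e$cc$g <- gAll; e$cc$V <- V
      e$cc$hw <- hw; e$cc$N <- tin$N
    }
    newTensor(Y, tin$H, tin$W, tin$N)
  }
  e$bwd <- function(dY) {
    hw <- e$cc$hw
    dkk <- numeric(hw * e$cc$N); daa <- numeric(hw * e$cc$N)
    dV <- matrix(0, hw * e$cc$N, e$ch)
    for (nI in seq_len(e$cc$N)) {
      rows <- ((nI - 1L) * hw + 1L):(nI * hw)
      s <- e$cc$s[rows]; a <- e$cc$a[rows]; g <- e$cc$g[nI, ]
      dYn <- dY[rows, , drop = FALSE]
      da <- as.vector(dYn %*% g)
      dg <- as.vector(crossprod(dYn, a))
      dV[rows, ] <- s %o% dg
      ds <- as.vector(e$cc$V[rows, , drop = FALSE] %*% dg)
      dkk[rows] <- s * (ds - sum(s * ds))
      daa[rows] <- a * (da - sum(a * da))
    }
    dY + e$pk$bwd(matrix(dkk, ncol = 1L)) +
      e$pa$bwd(matrix(daa, ncol = 1L)) + e$pv$bwd(dV)
  }
  e
}

# ---- composite: decoupled detection head ------------------------------------

# Three per-scale heads, each with a box branch (two 3x3 conv blocks into a
# 4*regMax linear map, distribution-focal bins) and a classification branch
# (hidden width max(ch_P3, min(nc, 100))). The regMax-element decode
# projection (bin expectation weights 0..regMax-1) is a frozen parameter.
#' @noRd
nnDetect <- function(chs, nc, regMax = 16L) {
  e <- new.env(parent = emptyenv())
  e$type <- "detect"; e$multi <- TRUE
  e$nc <- nc; e$regMax <- regMax
  c2 <- max(16L, chs[1L] %/% 4L, regMax * 4L)
  c3 <- max(chs[1L], min(nc, 100L))
  e$box <- lapply(chs, function(ch) list(
    nnConv(ch, c2, 3L, 1L), nnConv(c2, c2, 3L, 1L),
    nnConv(c2, 4L * regMax, 1L, 1L, bias = TRUE, bn = FALSE, act = FALSE,
           biasInit = 1)))
  e$cls <- lapply(chs, function(ch) list(
    nnConv(ch, c3, 3L, 1L), nnConv(c3, c3, 3L, 1L),
    nnConv(c3, nc, 1L, 1L, bias = TRUE, bn = FALSE, act = FALSE,
           biasInit = -4.595)))
  e$dflW <- seq(0L, regMax - 1L)   # frozen expectation projection
  e$frozenParams <- regMax
  e$leafList <- do.call(c, lapply(c(e$box, e$cls), function(branch)
    do.call(c, lapply(branch, `[[`, "leafList"))))
  e$fwd <- function(tins, train) {
    lapply(seq_along(tins), function(i) {
      b <- tins[[i]]
      for (m in e$box[[i]]) b <- m$fwd(b, train)
      cl <- tins[[i]]
      for (m in e$cls[[i]]) cl <- m$fwd(cl, train)
      newTensor(cbind(b$X, cl$X), b$H, b$W, b$N)
    })
  }
  e$bwd <- function(dLevels) {
    nb <- 4L * e$regMax
    lapply(seq_along(dLevels), function(i) {
      d <- dLevels[[i]]
      db <- d[, seq_len(nb), drop = FALSE]
      dc <- d[, nb + seq_len(e$nc), drop = FALSE]
      for (m in rev(e$box[[i]])) db <- m$bwd(db)
      for (m in rev(e$cls[[i]])) dc <- m$bwd(dc)
      db + dc
    })
  }
  e
}

# ---- optimizer helpers ------------------------------------------------------

#' @noRd
zeroGrads <- function(model) {
  for (leaf in model$leaves)
    for (p in leaf$pnames)
      assign(paste0("g_", p), get(p, envir = leaf) * 0, envir = leaf)
  invisible(model)
}

# SGD with momentum; weight decay on convolution weights only, separate
# learning rate for the bias group (biases + batch-norm shifts).
#' @noRd
sgdStep <- function(model, lr, lrBias = lr, momentum = 0.937, wd = 5e-4) {
  for (leaf in model$leaves) {
    for (p in leaf$pnames) {
      g <- get(paste0("g_", p), envir = leaf)
      w <- get(p, envir = leaf)
      if (p %in% leaf$decay) g <- g + wd * w
      mname <- paste0("m_", p)
      mbuf <- if (exists(mname, envir = leaf, inherits = FALSE))
        get(mname, envir = leaf) else g * 0
      mbuf <- momentum * mbuf + g
      assign(mname, mbuf, envir = leaf)
      useLr <- if (p %in% leaf$biasP) lrBias else lr
      assign(p, w - useLr * mbuf, envir = leaf)
    }
  }
  invisible(model)
}

# Flatten / restore all parameters (checkpointing as a plain numeric vector).
#' @noRd
getParamVector <- function(model) {
  unlist(lapply(model$leaves, function(leaf)
    lapply(c(leaf$pnames,
             intersect(c("rm", "rv"), ls(leaf))), function(p)
               as.numeric(get(p, envir = leaf)))))
}

#' @noRd
setParamVector <- function(model, v) {
  i <- 0L
  for (leaf in model$leaves) {
    for (p in c(leaf$pnames, intersect(c("rm", "rv"), ls(leaf)))) {
      cur <- get(p, envir = leaf)
      n <- length(cur)
      newv <- v[(i + 1L):(i + n)]
      if (is.matrix(cur)) newv <- matrix(newv, nrow(cur), ncol(cur))
      assign(p, newv, envir = leaf)
      i <- i + n
    }
  }
  if (i != length(v)) stop("checkpoint length mismatch")
  invisible(model)
}
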