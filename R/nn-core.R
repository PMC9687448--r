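# Minimal CNN engine. Activations are 4-D arrays (H, W, C, N); convolution
# is im2col + BLAS matrix multiplication; every layer provides an exact
# hand-derived backward pass, so training is plain reverse-mode
# differentiation with ADAM. 'same' zero padding throughout; strides,
# dilations and depthwise (separable) convolutions are supported — that is
# all the atrous/ASPP segmenter and the shallow classifier need.

conv_geometry <- function(H, W, kh, kw, stride, dilation) {
  Ho <- ceiling(H / stride); Wo <- ceiling(W / stride)
  eh <- (kh - 1L) * dilation + 1L
  ew <- (kw - 1L) * dilation + 1L
  pad_h <- max((Ho - 1L) * stride + eh - H, 0L)
  pad_w <- max((Wo - 1L) * stride + ew - W, 0L)
  list(H = H, W = W, Ho = Ho, Wo = Wo, kh = kh, kw = kw,
       stride = stride, dilation = dilation,
       pad_h = pad_h, pad_w = pad_w,
       ph0 = pad_h %/% 2L, pw0 = pad_w %/% 2L)
}

# Patch matrix (Ho*Wo) x (kh*kw*C); column blocks of width C per kernel
# position, positions ordered row-fastest.
im2col <- function(x3, g) {
  C <- dim(x3)[3]
  Hp <- g$H + g$pad_h; Wp <- g$W + g$pad_w
  xp <- array(0, c(Hp, Wp, C))
  xp[g$ph0 + seq_len(g$H), g$pw0 + seq_len(g$W), ] <- x3
  r0 <- seq(1L, by = g$stride, length.out = g$Ho)
  c0 <- seq(1L, by = g$stride, length.out = g$Wo)
  M <- g$Ho * g$Wo
  P <- matrix(0, M, g$kh * g$kw * C)
  k <- 0L
  for (j in seq_len(g$kw)) for (i in seq_len(g$kh)) {
    # column-major (h, w, c) order of the slice matches the (M, C) block
    P[, k * C + seq_len(C)] <-
      xp[r0 + (i - 1L) * g$dilation, c0 + (j - 1L) * g$dilation, ,
         drop = FALSE]
    k <- k + 1L
  }
  P
}

col2im <- function(dP, g, C) {
  Hp <- g$H + g$pad_h; Wp <- g$W + g$pad_w
  dxp <- array(0, c(Hp, Wp, C))
  r0 <- seq(1L, by = g$stride, length.out = g$Ho)
  c0 <- seq(1L, by = g$stride, length.out = g$Wo)
  M <- g$Ho * g$Wo
  k <- 0L
  for (j in seq_len(g$kw)) for (i in seq_len(g$kh)) {
    rows <- r0 + (i - 1L) * g$dilation
    cols <- c0 + (j - 1L) * g$dilation
    blk <- dP[, k * C + seq_len(C)]
    dim(blk) <- c(g$Ho, g$Wo, C)
    dxp[rows, cols, ] <- dxp[rows, cols, , drop = FALSE] + blk
    k <- k + 1L
  }
  dxp[g$ph0 + seq_len(g$H), g$pw0 + seq_len(g$W), , drop = FALSE]
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

nn_conv <- function(kh, kw, cin, cout, stride = 1L, dilation = 1L,
                    bias = FALSE) {
  l <- list(type = "conv", kh = kh, kw = kw, cin = cin, cout = cout,
            stride = stride, dilation = dilation,
            params = list(W = he_init(c(kh * kw * cin, cout),
                                      kh * kw * cin)),
            decay = c(W = TRUE))
  if (bias) {
    l$params$b <- numeric(cout)
    l$decay <- c(l$decay, b = FALSE)
  }
  l
}

nn_dwconv <- function(k, c, stride = 1L, dilation = 1L) {
  list(type = "dwconv", kh = k, kw = k, cin = c, cout = c,
       stride = stride, dilation = dilation,
       params = list(W = he_init(c(k * k, c), k * k)),
       decay = c(W = TRUE))
}

nn_bn <- function(c, momentum = 0.1) {
  list(type = "bn", cin = c, momentum = momentum,
       params = list(gamma = rep(1, c), beta = rep(0, c)),
       decay = c(gamma = FALSE, beta = FALSE),
       state = list(mean = rep(0, c), var = rep(1, c)))
}

nn_relu <- function() list(type = "relu", params = list(), decay = logical(0))
nn_maxpool <- function() list(type = "maxpool", params = list(),
                              decay = logical(0))
nn_flatten <- function() list(type = "flatten", params = list(),
                              decay = logical(0))

nn_fc <- function(din, dout) {
  list(type = "fc", din = din, dout = dout,
       params = list(W = he_init(c(din, dout), din), b = numeric(dout)),
       decay = c(W = TRUE, b = FALSE))
}

# Image-level pooling branch: global average pool -> 1x1 conv -> ReLU ->
# broadcast back to the input raster.
nn_imgpool <- function(cin, cout) {
  list(type = "imgpool", cin = cin, cout = cout,
       params = list(W = he_init(c(cin, cout), cin), b = numeric(cout)),
       decay = c(W = TRUE, b = FALSE))
}

nn_forward <- function(layer, x, train = FALSE) {
  switch(layer$type,
    conv = {
      d <- dim(x); N <- d[4]
      g <- conv_geometry(d[1], d[2], layer$kh, layer$kw, layer$stride,
                         layer$dilation)
      y <- array(0, c(g$Ho, g$Wo, layer$cout, N))
      Ps <- vector("list", N)
      for (n in seq_len(N)) {
        xs <- x[, , , n, drop = FALSE]
        dim(xs) <- d[1:3]
        P <- im2col(xs, g)
        Ym <- P %*% layer$params$W
        if (!is.null(layer$params$b))
          Ym <- sweep(Ym, 2L, layer$params$b, "+")
        y[, , , n] <- Ym
        Ps[[n]] <- P
      }
      list(y = y, cache = list(g = g, Ps = Ps, cin = d[3]))
    },
    dwconv = {
      d <- dim(x); N <- d[4]; C <- d[3]
      g <- conv_geometry(d[1], d[2], layer$kh, layer$kw, layer$stride,
                         layer$dilation)
      KK <- layer$kh * layer$kw
      M <- g$Ho * g$Wo
      y <- array(0, c(g$Ho, g$Wo, C, N))
      Ps <- vector("list", N)
      wrep <- lapply(seq_len(KK), function(k)
        rep(layer$params$W[k, ], each = M))
      for (n in seq_len(N)) {
        xs <- x[, , , n, drop = FALSE]
        dim(xs) <- d[1:3]
        P <- im2col(xs, g)
        Ym <- matrix(0, M, C)
        for (k in seq_len(KK)) {
          Pk <- P[, (k - 1L) * C + seq_len(C), drop = FALSE]
          Ym <- Ym + Pk * wrep[[k]]
        }
        y[, , , n] <- Ym
        Ps[[n]] <- P
      }
      list(y = y, cache = list(g = g, Ps = Ps))
    },
    bn = {
      d <- dim(x); C <- d[3]; HW <- d[1] * d[2]; N <- d[4]
      x2 <- x; dim(x2) <- c(HW, C * N)
      if (train) {
        cs <- .colMeans(x2, HW, C * N)
        cs2 <- .colMeans(x2 * x2, HW, C * N)
        mu <- rowMeans(matrix(cs, C, N))
        v <- rowMeans(matrix(cs2, C, N)) - mu^2
        layer$state$mean <- (1 - layer$momentum) * layer$state$mean +
          layer$momentum * mu
        layer$state$var <- (1 - layer$momentum) * layer$state$var +
          layer$momentum * v
      } else {
        mu <- layer$state$mean
        v <- layer$state$var
      }
      invstd <- 1 / sqrt(v + 1e-5)
      a <- layer$params$gamma * invstd
      b <- layer$params$beta - mu * a
      y <- x * rep(rep(a, each = HW), N) + rep(rep(b, each = HW), N)
      list(y = y, cache = list(x = x, mu = mu, invstd = invstd, d = d,
                               train = train),
           state = layer$state)
    },
    relu = list(y = pmax(x, 0), cache = x > 0),
    maxpool = {
      d <- dim(x)
      Ho <- d[1] %/% 2L; Wo <- d[2] %/% 2L
      ri <- seq_len(2L * Ho); ci <- seq_len(2L * Wo)
      a11 <- x[ri[c(TRUE, FALSE)], ci[c(TRUE, FALSE)], , , drop = FALSE]
      a21 <- x[ri[c(FALSE, TRUE)], ci[c(TRUE, FALSE)], , , drop = FALSE]
      a12 <- x[ri[c(TRUE, FALSE)], ci[c(FALSE, TRUE)], , , drop = FALSE]
      a22 <- x[ri[c(FALSE, TRUE)], ci[c(FALSE, TRUE)], , , drop = FALSE]
      y <- pmax(a11, a21, a12, a22)
      w11 <- a11 == y
      w21 <- (a21 == y) & !w11
      w12 <- (a12 == y) & !w11 & !w21
      w22 <- (a22 == y) & !w11 & !w21 & !w12
      list(y = y, cache = list(w = list(w11, w21, w12, w22), d = d,
                               Ho = Ho, Wo = Wo))
    },
    flatten = {
      d <- dim(x)
      list(y = matrix(x, prod(d[1:3]), d[4]), cache = d)
    },
    fc = {
      list(y = sweep(crossprod(layer$params$W, x), 1L, layer$params$b, "+"),
           cache = x)
    },
    imgpool = {
      d <- dim(x); C <- d[3]; N <- d[4]
      gmat <- apply(x, c(3, 4), mean)
      gmat <- matrix(gmat, C, N)
      z <- sweep(crossprod(layer$params$W, gmat), 1L, layer$params$b, "+")
      zr <- pmax(z, 0)
      y <- array(0, c(d[1], d[2], layer$cout, N))
      for (n in seq_len(N))
        y[, , , n] <- rep(zr[, n], each = d[1] * d[2])
      list(y = y, cache = list(g = gmat, mask = z > 0, d = d))
    },
    stop("unknown layer type ", layer$type))
}

nn_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      g <- cache$g; N <- length(cache$Ps)
      dW <- array(0, dim(layer$params$W))
      db <- if (!is.null(layer$params$b)) numeric(layer$cout) else NULL
      dx <- array(0, c(g$H, g$W, cache$cin, N))
      for (n in seq_len(N)) {
        dYm <- dy[, , , n, drop = FALSE]
        dim(dYm) <- c(g$Ho * g$Wo, layer$cout)
        dW <- dW + crossprod(cache$Ps[[n]], dYm)
        if (!is.null(db)) db <- db + colSums(dYm)
        dP <- tcrossprod(dYm, layer$params$W)
        dx[, , , n] <- col2im(dP, g, cache$cin)
      }
      grads <- list(W = dW)
      if (!is.null(db)) grads$b <- db
      list(dx = dx, grads = grads)
    },
    dwconv = {
      g <- cache$g; N <- length(cache$Ps)
      C <- layer$cin; KK <- layer$kh * layer$kw
      M <- g$Ho * g$Wo
      dW <- matrix(0, KK, C)
      dx <- array(0, c(g$H, g$W, C, N))
      wrep <- lapply(seq_len(KK), function(k)
        rep(layer$params$W[k, ], each = M))
      for (n in seq_len(N)) {
        dYm <- dy[, , , n, drop = FALSE]
        dim(dYm) <- c(M, C)
        P <- cache$Ps[[n]]
        dP <- matrix(0, M, KK * C)
        for (k in seq_len(KK)) {
          cols <- (k - 1L) * C + seq_len(C)
          dW[k, ] <- dW[k, ] + colSums(P[, cols, drop = FALSE] * dYm)
          dP[, cols] <- dYm * wrep[[k]]
        }
        dx[, , , n] <- col2im(dP, g, C)
      }
      list(dx = dx, grads = list(W = dW))
    },
    bn = {
      d <- cache$d; C <- d[3]; HW <- d[1] * d[2]; N <- d[4]
      M <- HW * N
      murep <- rep(rep(cache$mu, each = HW), N)
      invrep <- rep(rep(cache$invstd, each = HW), N)
      xhat <- (cache$x - murep) * invrep
      t1 <- dy * xhat; dim(t1) <- c(HW, C * N)
      dgamma <- rowSums(matrix(.colSums(t1, HW, C * N), C, N))
      dy2 <- dy; dim(dy2) <- c(HW, C * N)
      dbeta <- rowSums(matrix(.colSums(dy2, HW, C * N), C, N))
      gam <- layer$params$gamma
      if (cache$train) {
        m1 <- gam * dbeta / M
        m2 <- gam * dgamma / M
        dx <- invrep * (dy * rep(rep(gam, each = HW), N) -
                          rep(rep(m1, each = HW), N) -
                          xhat * rep(rep(m2, each = HW), N))
      } else {
        dx <- dy * rep(rep(gam * cache$invstd, each = HW), N)
        dim(dx) <- d
      }
      dim(dx) <- d
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dx = dy * cache, grads = NULL),
    maxpool = {
      d <- cache$d
      dx <- array(0, d)
      ri1 <- seq(1L, 2L * cache$Ho, by = 2L)
      ci1 <- seq(1L, 2L * cache$Wo, by = 2L)
      dx[ri1, ci1, , ] <- dy * cache$w[[1]]
      dx[ri1 + 1L, ci1, , ] <- dy * cache$w[[2]]
      dx[ri1, ci1 + 1L, , ] <- dy * cache$w[[3]]
      dx[ri1 + 1L, ci1 + 1L, , ] <- dy * cache$w[[4]]
      list(dx = dx, grads = NULL)
    },
    flatten = list(dx = array(dy, cache), grads = NULL),
    fc = {
      list(dx = layer$params$W %*% dy,
           grads = list(W = tcrossprod(cache, dy), b = rowSums(dy)))
    },
    imgpool = {
      d <- cache$d; N <- d[4]
      dz <- apply(dy, c(3, 4), sum)
      dz <- matrix(dz, layer$cout, N) * cache$mask
      dW <- tcrossprod(cache$g, dz)
      db <- rowSums(dz)
      dg <- layer$params$W %*% dz
      dx <- array(0, d)
      for (n in seq_len(N))
        dx[, , , n] <- rep(dg[, n] / (d[1] * d[2]), each = d[1] * d[2])
      list(dx = dx, grads = list(W = dW, b = db))
    },
    stop("unknown layer type ", layer$type))
}

# Bilinear up/down-sampling to explicit output dims; the backward pass is
# the exact adjoint of the interpolation matrices.
nn_resize <- function(x, out_h, out_w) {
  d <- dim(x)
  Ar <- interp_matrix(out_h, d[1]); Ac <- interp_matrix(out_w, d[2])
  y <- array(0, c(out_h, out_w, d[3], d[4]))
  for (n in seq_len(d[4])) for (c in seq_len(d[3]))
    y[, , c, n] <- Ar %*% x[, , c, n] %*% t(Ac)
  list(y = y, Ar = Ar, Ac = Ac, d = d)
}

nn_resize_backward <- function(cache, dy) {
  d <- cache$d
  dx <- array(0, d)
  for (n in seq_len(d[4])) for (c in seq_len(d[3]))
    dx[, , c, n] <- t(cache$Ar) %*% dy[, , c, n] %*% cache$Ac
  dx
}

concat_channels <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[3], numeric(1))
  y <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (x in xs) {
    y[, , at + seq_len(dim(x)[3]), ] <- x
    at <- at + dim(x)[3]
  }
  y
}

split_channels <- function(dy, cs) {
  at <- 0L
  out <- vector("list", length(cs))
  for (i in seq_along(cs)) {
    out[[i]] <- dy[, , at + seq_len(cs[i]), , drop = FALSE]
    at <- at + cs[i]
  }
  out
}

# --- sequential execution (the classifier, and linear sub-chains of the
# segmenter) ------------------------------------------------------------

seq_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  states <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- nn_forward(layers[[i]], x, train)
    x <- r$y
    caches[[i]] <- r$cache
    if (!is.null(r$state)) states[[i]] <- r$state
  }
  list(y = x, caches = caches, states = states)
}

seq_backward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- nn_backward(layers[[i]], caches[[i]], dy)
    dy <- r$dx
    if (!is.null(r$grads)) grads[[i]] <- r$grads  # keep positions aligned
  }
  list(dx = dy, grads = grads)
}

apply_states <- function(layers, states) {
  for (i in seq_along(layers))
    if (!is.null(states[[i]])) layers[[i]]$state <- states[[i]]
  layers
}

# --- losses -------------------------------------------------------------

softmax2 <- function(z1, z2) {
  m <- pmax(z1, z2)
  e1 <- exp(z1 - m); e2 <- exp(z2 - m)
  s <- e1 + e2
  list(p1 = e1 / s, p2 = e2 / s)
}

# Class-weighted masked pixel cross-entropy. logits (H,W,2,N); labels
# (H,W,N) in {0,1} (1 = vessel); mask (H,W,N) logical. Returns the loss and
# its gradient w.r.t. the logits.
seg_loss <- function(logits, labels, mask, class_wts = c(1, 1)) {
  dspat <- dim(logits)[c(1, 2, 4)]
  z1 <- array(logits[, , 1, ], dspat); z2 <- array(logits[, , 2, ], dspat)
  p <- softmax2(z1, z2)
  w <- (class_wts[1] + (class_wts[2] - class_wts[1]) * labels) * mask
  norm <- sum(w)
  if (norm == 0) stop("no valid pixels in the loss")
  py <- p$p1 + (p$p2 - p$p1) * labels
  loss <- -sum(w * log(pmax(py, 1e-12))) / norm
  d <- dim(logits)
  dlog <- array(0, d)
  dlog[, , 1, ] <- w * (p$p1 - (1 - labels)) / norm
  dlog[, , 2, ] <- w * (p$p2 - labels) / norm
  list(loss = loss, dlogits = dlog)
}

# Cross-entropy on (2, N) logits; y in {1, 2}.
clf_loss <- function(logits, y) {
  p <- softmax2(logits[1, ], logits[2, ])
  py <- ifelse(y == 1, p$p1, p$p2)
  n <- length(y)
  loss <- -mean(log(pmax(py, 1e-12)))
  dlog <- rbind(p$p1 - (y == 1), p$p2 - (y == 2)) / n
  list(loss = loss, dlogits = dlog)
}

# --- ADAM ---------------------------------------------------------------

adam_init <- function(layers) {
  zeros <- function(p) if (is.null(dim(p))) numeric(length(p))
                       else array(0, dim(p))
  lapply(layers, function(l)
    lapply(l$params, function(p) list(m = zeros(p), v = zeros(p))))
}

adam_step <- function(layers, grads, state, lr, t, l2 = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  nm_lookup <- !is.null(names(grads)) && !is.null(names(layers))
  for (i in seq_along(layers)) {
    g <- if (nm_lookup) grads[[names(layers)[i]]] else grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      gv <- g[[nm]]
      if (l2 > 0 && isTRUE(layers[[i]]$decay[[nm]]))
        gv <- gv + l2 * layers[[i]]$params[[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * gv
      st$v <- beta2 * st$v + (1 - beta2) * gv^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]]$params[[nm]] <- layers[[i]]$params[[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}

#' Learning rate at a given (fractional) epoch
#'
#' The initial rate is multiplied by `drop_factor` once per `drop_period`
#' epochs; `drop_period` may be fractional (e.g. 0.5 drops twice per epoch).
#'
#' @param tc a [train_config()].
#' @param epoch fractional epochs completed (0 at the first iteration).
#' @return learning rate.
#' @export
lr_at <- function(tc, epoch) {
  tc$lr0 * tc$drop_factor^floor(epoch / tc$drop_period)
}

#' Early-stopping tracker
#'
#' Training halts when the validation loss has not improved by more than
#' `min_rel_improve` (relative, default 0.01%) over `patience` consecutive
#' epochs. `es_update()` returns the updated tracker with `$stop` set once
#' the rule fires.
#'
#' @param patience consecutive non-improving epochs tolerated.
#' @param min_rel_improve minimum relative improvement that counts.
#' @return an early-stopping tracker list.
#' @export
es_tracker <- function(patience = 5L, min_rel_improve = 1e-4) {
  list(best = Inf, bad = 0L, patience = patience,
       min_rel_improve = min_rel_improve, stop = FALSE)
}

#' @rdname es_tracker
#' @param tr tracker from [es_tracker()].
#' @param val_loss validation loss of the epoch just finished.
#' @export
es_update <- function(tr, val_loss) {
  improved <- is.finite(tr$best) &&
    (tr$best - val_loss) / abs(tr$best) > tr$min_rel_improve ||
    !is.finite(tr$best)
  if (improved) {
    tr$best <- val_loss
    tr$bad <- 0L
  } else {
    tr$bad <- tr$bad + 1L
    if (tr$bad >= tr$patience) tr$stop <- TRUE
  }
  tr
}
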