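# Minimal neural-network engine used by the brain-age regressors.
#
# Layers operate on batches stored as R arrays with the sample index FIRST:
#   2D feature maps: (N, H, W, C);  3D feature maps: (N, D, H, W, C);
#   vectors: (N, C) matrices.
# Convolutions use TensorFlow-style "same" padding with ceiling division,
# so a stride-2 layer maps H -> ceiling(H/2); five stride-2 stages give the
# 32-fold reduction of the canonical 138 x 176 slice to 5 x 6.
# All heavy lifting is im2col + BLAS matrix multiplication; gradients are
# exact (verified against finite differences in the test suite) and are
# propagated all the way to the input, which is what gradient saliency needs.

#' @noRd
nn_he_init <- function(fan_in, n) {
  stats::rnorm(n, sd = sqrt(2 / fan_in))
}

nn_conv2d <- function(c_in, c_out, k = 3L, stride = 1L, bias = TRUE) {
  W <- matrix(nn_he_init(k * k * c_in, k * k * c_in * c_out), k * k * c_in, c_out)
  list(type = "conv2d", k = as.integer(k), stride = as.integer(stride),
       c_in = as.integer(c_in), c_out = as.integer(c_out),
       params = list(W = W, b = if (bias) numeric(c_out) else NULL))
}

nn_conv3d <- function(c_in, c_out, k = c(3L, 3L, 3L), stride = c(1L, 1L, 1L),
                      bias = TRUE) {
  k <- as.integer(rep_len(k, 3L)); stride <- as.integer(rep_len(stride, 3L))
  kk <- prod(k) * c_in
  W <- matrix(nn_he_init(kk, kk * c_out), kk, c_out)
  list(type = "conv3d", k = k, stride = stride,
       c_in = as.integer(c_in), c_out = as.integer(c_out),
       params = list(W = W, b = if (bias) numeric(c_out) else NULL))
}

nn_bn <- function(c, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", c = as.integer(c), momentum = momentum, eps = eps,
       params = list(gamma = rep(1, c), beta = numeric(c)),
       state = list(mean = numeric(c), var = rep(1, c)))
}

nn_relu <- function() list(type = "relu", params = list())

nn_maxpool2d <- function(k = 3L, stride = 2L) {
  list(type = "maxpool2d", k = as.integer(k), stride = as.integer(stride),
       params = list())
}

nn_gap <- function() list(type = "gap", params = list())

nn_dropout <- function(rate = 0.3) list(type = "dropout", rate = rate, params = list())

nn_dense <- function(c_in, c_out) {
  list(type = "dense",
       params = list(W = matrix(nn_he_init(c_in, c_in * c_out), c_in, c_out),
                     b = numeric(c_out)))
}

# Pre-activation residual block (BN -> ReLU -> Conv), basic (two 3x3) or
# bottleneck (1x1 -> 3x3 -> 1x1) form. The projection shortcut, when needed,
# is taken from the shared pre-activation as in the v2 residual design.
nn_resblock2d <- function(c_in, c_out, stride = 1L, bottleneck = FALSE) {
  sub <- if (bottleneck) {
    c_mid <- c_out %/% 4L
    list(bn1 = nn_bn(c_in),
         conv1 = nn_conv2d(c_in, c_mid, k = 1L, stride = 1L),
         bn2 = nn_bn(c_mid),
         conv2 = nn_conv2d(c_mid, c_mid, k = 3L, stride = stride),
         bn3 = nn_bn(c_mid),
         conv3 = nn_conv2d(c_mid, c_out, k = 1L, stride = 1L))
  } else {
    list(bn1 = nn_bn(c_in),
         conv1 = nn_conv2d(c_in, c_out, k = 3L, stride = stride),
         bn2 = nn_bn(c_out),
         conv2 = nn_conv2d(c_out, c_out, k = 3L, stride = 1L))
  }
  proj <- (stride != 1L) || (c_in != c_out)
  if (proj) sub$conv_sc <- nn_conv2d(c_in, c_out, k = 1L, stride = stride)
  list(type = "resblock2d", proj = proj, bottleneck = bottleneck, sub = sub,
       params = list())
}

nn_resblock3d <- function(c_in, c_out, stride = c(1L, 1L, 1L)) {
  stride <- as.integer(rep_len(stride, 3L))
  sub <- list(bn1 = nn_bn(c_in),
              conv1 = nn_conv3d(c_in, c_out, k = 3L, stride = stride),
              bn2 = nn_bn(c_out),
              conv2 = nn_conv3d(c_out, c_out, k = 3L, stride = 1L))
  proj <- any(stride != 1L) || (c_in != c_out)
  if (proj) sub$conv_sc <- nn_conv3d(c_in, c_out, k = 1L, stride = stride)
  list(type = "resblock3d", proj = proj, sub = sub, params = list())
}

# ---- im2col machinery ------------------------------------------------------

# Index matrix mapping (output position, patch element) -> flat index into a
# padded (Hp, Wp, C) sample. Cached per geometry in a session environment.
.nn_cache <- new.env(parent = emptyenv())

nn_same_pad <- function(len, k, stride) {
  out <- as.integer(ceiling(len / stride))
  tot <- max(0L, (out - 1L) * stride + k - len)
  c(out = out, lo = tot %/% 2L, hi = tot - tot %/% 2L)
}

nn_im2col_idx2d <- function(H, W, C, k, stride) {
  key <- paste("2d", H, W, C, k, stride, sep = "_")
  got <- .nn_cache[[key]]
  if (!is.null(got)) return(got)
  ph <- nn_same_pad(H, k, stride); pw <- nn_same_pad(W, k, stride)
  Ho <- ph["out"]; Wo <- pw["out"]
  Hp <- H + ph["lo"] + ph["hi"]; Wp <- W + pw["lo"] + pw["hi"]
  i <- rep(seq_len(Ho), times = Wo)        # output row, fastest
  j <- rep(seq_len(Wo), each = Ho)
  di <- rep(seq_len(k), times = k); dj <- rep(seq_len(k), each = k)
  # rows: output pixel o; cols: (di, dj, c)
  r0 <- (i - 1L) * stride            # top-left of patch in padded coords - 1
  s0 <- (j - 1L) * stride
  base <- outer(r0, di, "+") + Hp * (outer(s0, dj, "+") - 1L)  # (HoWo, k*k)
  idx <- matrix(0L, Ho * Wo, k * k * C)
  for (cc in seq_len(C)) {
    idx[, (cc - 1L) * k * k + seq_len(k * k)] <- base + (cc - 1L) * Hp * Wp
  }
  out <- list(idx = idx, Ho = as.integer(Ho), Wo = as.integer(Wo),
              Hp = as.integer(Hp), Wp = as.integer(Wp),
              plo = as.integer(ph["lo"]), qlo = as.integer(pw["lo"]))
  .nn_cache[[key]] <- out
  out
}

nn_im2col_idx3d <- function(D, H, W, C, k, stride) {
  key <- paste("3d", D, H, W, C, paste(k, collapse = "x"),
               paste(stride, collapse = "x"), sep = "_")
  got <- .nn_cache[[key]]
  if (!is.null(got)) return(got)
  pd <- nn_same_pad(D, k[1], stride[1])
  ph <- nn_same_pad(H, k[2], stride[2])
  pw <- nn_same_pad(W, k[3], stride[3])
  Do <- pd["out"]; Ho <- ph["out"]; Wo <- pw["out"]
  Dp <- D + pd["lo"] + pd["hi"]; Hp <- H + ph["lo"] + ph["hi"]
  Wp <- W + pw["lo"] + pw["hi"]
  no <- Do * Ho * Wo
  # output order (d, h, w) with d fastest (matches array dim (N, Do, Ho, Wo, C))
  d <- rep(seq_len(Do), times = Ho * Wo)
  h <- rep(rep(seq_len(Ho), each = Do), times = Wo)
  w <- rep(seq_len(Wo), each = Do * Ho)
  d0 <- (d - 1L) * stride[1]; h0 <- (h - 1L) * stride[2]; w0 <- (w - 1L) * stride[3]
  kd <- k[1]; kh <- k[2]; kw <- k[3]
  dd <- rep(seq_len(kd), times = kh * kw)
  dh <- rep(rep(seq_len(kh), each = kd), times = kw)
  dw <- rep(seq_len(kw), each = kd * kh)
  nk <- kd * kh * kw
  base <- matrix(0L, no, nk)
  for (jj in seq_len(nk)) {
    base[, jj] <- (d0 + dd[jj]) + Dp * (h0 + dh[jj] - 1L) +
      Dp * Hp * (w0 + dw[jj] - 1L)
  }
  idx <- matrix(0L, no, nk * C)
  for (cc in seq_len(C)) idx[, (cc - 1L) * nk + seq_len(nk)] <- base + (cc - 1L) * Dp * Hp * Wp
  out <- list(idx = idx, Do = as.integer(Do), Ho = as.integer(Ho),
              Wo = as.integer(Wo), Dp = as.integer(Dp), Hp = as.integer(Hp),
              Wp = as.integer(Wp), plo = as.integer(pd["lo"]),
              qlo = as.integer(ph["lo"]), rlo = as.integer(pw["lo"]))
  .nn_cache[[key]] <- out
  out
}

nn_pad2d <- function(x, Hp, Wp, plo, qlo) {
  d <- dim(x)  # (N, H, W, C)
  xp <- array(0, c(d[1], Hp, Wp, d[4]))
  xp[, plo + seq_len(d[2]), qlo + seq_len(d[3]), ] <- x
  xp
}

nn_pad3d <- function(x, Dp, Hp, Wp, plo, qlo, rlo) {
  d <- dim(x)  # (N, D, H, W, C)
  xp <- array(0, c(d[1], Dp, Hp, Wp, d[5]))
  xp[, plo + seq_len(d[2]), qlo + seq_len(d[3]), rlo + seq_len(d[4]), ] <- x
  xp
}

# ---- forward/backward per layer -------------------------------------------

nn_forward_conv2d <- function(layer, x) {
  d <- dim(x); N <- d[1]
  g <- nn_im2col_idx2d(d[2], d[3], d[4], layer$k, layer$stride)
  xp <- nn_pad2d(x, g$Hp, g$Wp, g$plo, g$qlo)
  dim(xp) <- c(N, g$Hp * g$Wp * d[4])
  P <- xp[, as.vector(g$idx), drop = FALSE]
  dim(P) <- c(N * g$Ho * g$Wo, layer$k * layer$k * d[4])
  Y <- P %*% layer$params$W
  if (!is.null(layer$params$b)) Y <- sweep(Y, 2L, layer$params$b, "+")
  dim(Y) <- c(N, g$Ho, g$Wo, layer$c_out)
  list(out = Y, cache = list(P = P, g = g, din = d))
}

nn_backward_conv2d <- function(layer, cache, dout) {
  d <- cache$din; N <- d[1]; g <- cache$g
  kkC <- layer$k * layer$k * d[4]
  dim(dout) <- c(N * g$Ho * g$Wo, layer$c_out)
  dW <- crossprod(cache$P, dout)
  db <- if (!is.null(layer$params$b)) colSums(dout) else NULL
  dP <- dout %*% t(layer$params$W)        # (N*HoWo, kkC)
  dim(dP) <- c(N, g$Ho * g$Wo, kkC)
  dxp <- matrix(0, N, g$Hp * g$Wp * d[4])
  for (jj in seq_len(kkC)) {
    cols <- g$idx[, jj]
    dxp[, cols] <- dxp[, cols] + dP[, , jj]
  }
  dim(dxp) <- c(N, g$Hp, g$Wp, d[4])
  dx <- dxp[, g$plo + seq_len(d[2]), g$qlo + seq_len(d[3]), , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db))
}

nn_forward_conv3d <- function(layer, x) {
  d <- dim(x); N <- d[1]
  g <- nn_im2col_idx3d(d[2], d[3], d[4], d[5], layer$k, layer$stride)
  xp <- nn_pad3d(x, g$Dp, g$Hp, g$Wp, g$plo, g$qlo, g$rlo)
  dim(xp) <- c(N, g$Dp * g$Hp * g$Wp * d[5])
  P <- xp[, as.vector(g$idx), drop = FALSE]
  nk <- prod(layer$k) * d[5]
  dim(P) <- c(N * g$Do * g$Ho * g$Wo, nk)
  Y <- P %*% layer$params$W
  if (!is.null(layer$params$b)) Y <- sweep(Y, 2L, layer$params$b, "+")
  dim(Y) <- c(N, g$Do, g$Ho, g$Wo, layer$c_out)
  list(out = Y, cache = list(P = P, g = g, din = d))
}

nn_backward_conv3d <- function(layer, cache, dout) {
  d <- cache$din; N <- d[1]; g <- cache$g
  nk <- prod(layer$k) * d[5]
  no <- g$Do * g$Ho * g$Wo
  dim(dout) <- c(N * no, layer$c_out)
  dW <- crossprod(cache$P, dout)
  db <- if (!is.null(layer$params$b)) colSums(dout) else NULL
  dP <- dout %*% t(layer$params$W)
  dim(dP) <- c(N, no, nk)
  dxp <- matrix(0, N, g$Dp * g$Hp * g$Wp * d[5])
  for (jj in seq_len(nk)) {
    cols <- g$idx[, jj]
    dxp[, cols] <- dxp[, cols] + dP[, , jj]
  }
  dim(dxp) <- c(N, g$Dp, g$Hp, g$Wp, d[5])
  dx <- dxp[, g$plo + seq_len(d[2]), g$qlo + seq_len(d[3]),
            g$rlo + seq_len(d[4]), , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db))
}

nn_forward_bn <- function(layer, x, training) {
  d <- dim(x); C <- layer$c
  m <- matrix(x, ncol = C)
  if (training) {
    mu <- colMeans(m)
    xc <- sweep(m, 2L, mu, "-")
    v <- colMeans(xc * xc)
    istd <- 1 / sqrt(v + layer$eps)
    xhat <- sweep(xc, 2L, istd, "*")
    state <- list(mean = layer$momentum * layer$state$mean + (1 - layer$momentum) * mu,
                  var = layer$momentum * layer$state$var + (1 - layer$momentum) * v)
  } else {
    istd <- 1 / sqrt(layer$state$var + layer$eps)
    xhat <- sweep(sweep(m, 2L, layer$state$mean, "-"), 2L, istd, "*")
    state <- NULL
  }
  y <- sweep(sweep(xhat, 2L, layer$params$gamma, "*"), 2L, layer$params$beta, "+")
  dim(y) <- d
  list(out = y, cache = list(xhat = xhat, istd = istd, d = d, training = training),
       state = state)
}

nn_backward_bn <- function(layer, cache, dout) {
  d <- cache$d; C <- layer$c
  dm <- matrix(dout, ncol = C)
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  if (cache$training) {
    M <- nrow(dm)
    t1 <- sweep(dm, 2L, layer$params$gamma * cache$istd, "*")
    dx <- t1 - sweep(cache$xhat, 2L, colSums(t1 * cache$xhat) / M, "*") -
      matrix(colSums(t1) / M, M, C, byrow = TRUE)
  } else {
    dx <- sweep(dm, 2L, layer$params$gamma * cache$istd, "*")
  }
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

nn_forward_relu <- function(x) {
  keep <- x > 0
  list(out = x * keep, cache = keep)
}

nn_forward_maxpool2d <- function(layer, x) {
  d <- dim(x); N <- d[1]; C <- d[4]
  g <- nn_im2col_idx2d(d[2], d[3], 1L, layer$k, layer$stride)
  xp <- nn_pad2d(x, g$Hp, g$Wp, g$plo, g$qlo)
  # treat channels like extra batch: (N, Hp, Wp, C) -> (N*C over channel loop)
  kk <- layer$k * layer$k
  no <- g$Ho * g$Wo
  out <- array(0, c(N, g$Ho, g$Wo, C))
  amax <- array(0L, c(N, no, C))
  for (cc in seq_len(C)) {
    xf <- xp[, , , cc]
    dim(xf) <- c(N, g$Hp * g$Wp)
    # padded zeros can win over negative activations; acceptable after ReLU
    P <- xf[, as.vector(g$idx), drop = FALSE]
    dim(P) <- c(N, no, kk)
    o <- P[, , 1]; a <- matrix(1L, N, no)
    for (jj in 2:kk) {
      pj <- P[, , jj]
      better <- pj > o
      o[better] <- pj[better]
      a[better] <- jj
    }
    out[, , , cc] <- array(o, c(N, g$Ho, g$Wo))
    amax[, , cc] <- a
  }
  list(out = out, cache = list(g = g, amax = amax, din = d))
}

nn_backward_maxpool2d <- function(layer, cache, dout) {
  d <- cache$din; N <- d[1]; C <- d[4]; g <- cache$g
  no <- g$Ho * g$Wo
  dxp <- array(0, c(N, g$Hp * g$Wp, C))
  dof <- dout; dim(dof) <- c(N, no, C)
  for (cc in seq_len(C)) {
    a <- cache$amax[, , cc]
    for (jj in seq_len(layer$k * layer$k)) {
      sel <- a == jj
      if (!any(sel)) next
      w <- which(sel, arr.ind = TRUE)          # (n, o)
      cols <- g$idx[w[, 2], jj]
      ii <- cbind(w[, 1], cols, rep(cc, nrow(w)))
      dxp[ii] <- dxp[ii] + dof[, , cc][w]
    }
  }
  dim(dxp) <- c(N, g$Hp, g$Wp, C)
  dx <- dxp[, g$plo + seq_len(d[2]), g$qlo + seq_len(d[3]), , drop = FALSE]
  list(dx = dx, grads = list())
}

nn_forward_gap <- function(x) {
  d <- dim(x); N <- d[1]; C <- d[length(d)]
  sp <- prod(d[-c(1, length(d))])
  m <- matrix(x, N * sp, C)
  grp <- rep_len(seq_len(N), N * sp)
  out <- rowsum(m, grp, reorder = TRUE) / sp
  list(out = out, cache = list(d = d, sp = sp))
}

nn_backward_gap <- function(cache, dout) {
  d <- cache$d; N <- d[1]
  grp <- rep_len(seq_len(N), N * cache$sp)
  dx <- dout[grp, , drop = FALSE] / cache$sp
  dim(dx) <- d
  list(dx = dx, grads = list())
}

nn_forward_dropout <- function(layer, x, training) {
  if (!training || layer$rate <= 0) return(list(out = x, cache = NULL))
  keep <- array(stats::runif(length(x)) >= layer$rate, dim(x))
  list(out = x * keep / (1 - layer$rate), cache = keep)
}

nn_forward_dense <- function(layer, x) {
  y <- x %*% layer$params$W
  y <- sweep(y, 2L, layer$params$b, "+")
  list(out = y, cache = x)
}

nn_backward_dense <- function(layer, cache, dout) {
  list(dx = dout %*% t(layer$params$W),
       grads = list(W = crossprod(cache, dout), b = colSums(dout)))
}

# ---- layer dispatch (handles composites recursively) ------------------------

nn_layer_forward <- function(layer, x, training) {
  switch(layer$type,
    conv2d = c(nn_forward_conv2d(layer, x), list(layer = NULL)),
    conv3d = c(nn_forward_conv3d(layer, x), list(layer = NULL)),
    bn = {
      r <- nn_forward_bn(layer, x, training)
      if (!is.null(r$state)) layer$state <- r$state
      list(out = r$out, cache = r$cache, layer = layer)
    },
    relu = { r <- nn_forward_relu(x); list(out = r$out, cache = r$cache, layer = NULL) },
    maxpool2d = c(nn_forward_maxpool2d(layer, x), list(layer = NULL)),
    gap = { r <- nn_forward_gap(x); list(out = r$out, cache = r$cache, layer = NULL) },
    dropout = { r <- nn_forward_dropout(layer, x, training)
                list(out = r$out, cache = r$cache, layer = NULL) },
    dense = { r <- nn_forward_dense(layer, x); list(out = r$out, cache = r$cache, layer = NULL) },
    resblock2d = nn_forward_resblock(layer, x, training),
    resblock3d = nn_forward_resblock(layer, x, training),
    stop("unknown layer type: ", layer$type)
  )
}

nn_forward_resblock <- function(layer, x, training) {
  sub <- layer$sub
  caches <- list()
  f1 <- nn_layer_forward(sub$bn1, x, training)
  if (!is.null(f1$layer)) sub$bn1 <- f1$layer
  caches$bn1 <- f1$cache
  r1 <- nn_forward_relu(f1$out); caches$relu1 <- r1$cache
  a <- r1$out
  if (layer$proj) {
    fs <- nn_layer_forward(sub$conv_sc, a, training)
    caches$conv_sc <- fs$cache
    shortcut <- fs$out
  } else shortcut <- x
  f2 <- nn_layer_forward(sub$conv1, a, training); caches$conv1 <- f2$cache
  y <- f2$out
  f3 <- nn_layer_forward(sub$bn2, y, training)
  if (!is.null(f3$layer)) sub$bn2 <- f3$layer
  caches$bn2 <- f3$cache
  r2 <- nn_forward_relu(f3$out); caches$relu2 <- r2$cache
  f4 <- nn_layer_forward(sub$conv2, r2$out, training); caches$conv2 <- f4$cache
  y <- f4$out
  if (isTRUE(layer$bottleneck)) {
    f5 <- nn_layer_forward(sub$bn3, y, training)
    if (!is.null(f5$layer)) sub$bn3 <- f5$layer
    caches$bn3 <- f5$cache
    r3 <- nn_forward_relu(f5$out); caches$relu3 <- r3$cache
    f6 <- nn_layer_forward(sub$conv3, r3$out, training); caches$conv3 <- f6$cache
    y <- f6$out
  }
  layer$sub <- sub
  list(out = y + shortcut, cache = caches, layer = layer)
}

nn_layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv2d = nn_backward_conv2d(layer, cache, dout),
    conv3d = nn_backward_conv3d(layer, cache, dout),
    bn = nn_backward_bn(layer, cache, dout),
    relu = list(dx = dout * cache, grads = list()),
    maxpool2d = nn_backward_maxpool2d(layer, cache, dout),
    gap = nn_backward_gap(cache, dout),
    dropout = {
      if (is.null(cache)) list(dx = dout, grads = list())
      else list(dx = dout * cache / (1 - layer$rate), grads = list())
    },
    dense = nn_backward_dense(layer, cache, dout),
    resblock2d = nn_backward_resblock(layer, cache, dout),
    resblock3d = nn_backward_resblock(layer, cache, dout),
    stop("unknown layer type: ", layer$type)
  )
}

nn_backward_resblock <- function(layer, cache, dout) {
  sub <- layer$sub
  grads <- list()
  dy <- dout
  if (isTRUE(layer$bottleneck)) {
    b6 <- nn_layer_backward(sub$conv3, cache$conv3, dy); grads$conv3 <- b6$grads
    dy <- b6$dx * cache$relu3
    b5 <- nn_layer_backward(sub$bn3, cache$bn3, dy); grads$bn3 <- b5$grads
    dy <- b5$dx
  }
  b4 <- nn_layer_backward(sub$conv2, cache$conv2, dy); grads$conv2 <- b4$grads
  dy <- b4$dx * cache$relu2
  b3 <- nn_layer_backward(sub$bn2, cache$bn2, dy); grads$bn2 <- b3$grads
  b2 <- nn_layer_backward(sub$conv1, cache$conv1, b3$dx); grads$conv1 <- b2$grads
  da <- b2$dx
  if (layer$proj) {
    bs <- nn_layer_backward(sub$conv_sc, cache$conv_sc, dout)
    grads$conv_sc <- bs$grads
    da <- da + bs$dx
    dx_direct <- 0
  } else dx_direct <- dout
  da <- da * cache$relu1
  b1 <- nn_layer_backward(sub$bn1, cache$bn1, da); grads$bn1 <- b1$grads
  dx <- b1$dx
  if (!identical(dx_direct, 0)) dx <- dx + dx_direct
  list(dx = dx, grads = grads)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- network-level API -----------------------------------------------------

nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    r <- nn_layer_forward(net$layers[[i]], x, training)
    x <- r$out
    caches[[i]] <- r$cache
    if (!is.null(r$layer)) net$layers[[i]] <- r$layer  # updated BN running stats
  }
  list(out = x, caches = caches, net = net)
}

nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    b <- nn_layer_backward(net$layers[[i]], caches[[i]], dout)
    grads[[i]] <- b$grads
    dout <- b$dx
  }
  list(grads = grads, dx = dout)
}

# Recursively collect / update parameters, mirroring the layer tree.
nn_param_tree <- function(layer) {
  if (layer$type %in% c("resblock2d", "resblock3d")) {
    lapply(layer$sub, nn_param_tree)
  } else layer$params
}

nn_count_params <- function(net) {
  cnt <- function(x) if (is.list(x)) sum(vapply(x, cnt, numeric(1))) else length(x)
  sum(vapply(net$layers, function(l) cnt(nn_param_tree(l)), numeric(1)))
}

# Adam: state and updates mirror the grads tree layer-by-layer.
nn_adam_init <- function() list(t = 0L)

nn_adam_update <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8, decay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  if (decay > 0) lr <- lr / (1 + decay * (t - 1))
  bc <- sqrt(1 - beta2^t) / (1 - beta1^t)
  upd_leaf <- function(p, g, m, v) {
    if (is.null(g)) return(list(p = p, m = m, v = v))
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * bc * m / (sqrt(v) + eps)
    list(p = p, m = m, v = v)
  }
  upd_layer <- function(layer, g, ms, vs) {
    if (layer$type %in% c("resblock2d", "resblock3d")) {
      for (nm in names(layer$sub)) {
        r <- upd_layer(layer$sub[[nm]], g[[nm]], ms[[nm]], vs[[nm]])
        layer$sub[[nm]] <- r$layer; ms[[nm]] <- r$m; vs[[nm]] <- r$v
      }
      return(list(layer = layer, m = ms, v = vs))
    }
    if (length(layer$params)) {
      if (is.null(ms)) { ms <- list(); vs <- list() }
      for (nm in names(layer$params)) {
        r <- upd_leaf(layer$params[[nm]], g[[nm]], ms[[nm]], vs[[nm]])
        layer$params[[nm]] <- r$p; ms[[nm]] <- r$m; vs[[nm]] <- r$v
      }
    }
    list(layer = layer, m = ms, v = vs)
  }
  if (is.null(state$m)) { state$m <- vector("list", length(net$layers))
                          state$v <- vector("list", length(net$layers)) }
  for (i in seq_along(net$layers)) {
    r <- upd_layer(net$layers[[i]], grads[[i]], state$m[[i]], state$v[[i]])
    net$layers[[i]] <- r$layer
    state$m[i] <- list(r$m); state$v[i] <- list(r$v)   # keep NULLs in place
  }
  list(net = net, state = state)
}
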