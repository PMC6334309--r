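# Minimal CPU training engine for the networks in this package.
#
# Activation tensors are 4-d arrays with dim = c(H, W, N, C): height, width,
# batch, channel. With R's column-major layout this makes a [H*W*N, C]
# matrix view of the same memory give one column per channel, so batch-norm
# and bias addition are plain column operations, and the im2col product
# `cols %*% W` reshapes directly to c(oh, ow, N, F).
#
# A network is a list of layers; each layer is list(def, params, buffers).
# Forward returns (possibly updated) running statistics, per-layer caches
# for the backward pass, and the output. All randomness (weight init,
# dropout) draws from R's RNG so runs are reproducible from set.seed().

convOutSize <- function(insize, k, stride, pad) (insize + 2L * pad - k) %/% stride + 1L

# ---- layer definitions -----------------------------------------------------

nnConv <- function(cin, cout, k, stride = 1L, pad = 0L, wsd = 0.02) {
  list(type = "conv", cin = cin, cout = cout, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad), wsd = wsd)
}

nnTConv <- function(cin, cout, k, stride = 2L, pad = 2L, outpad = 1L, wsd = 0.02) {
  list(type = "tconv", cin = cin, cout = cout, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad),
       outpad = as.integer(outpad), wsd = wsd)
}

nnBN <- function(c, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", c = c, momentum = momentum, eps = eps)
}

nnReLU <- function() list(type = "relu")
nnLeakyReLU <- function(alpha = 0.2) list(type = "lrelu", alpha = alpha)
nnTanh <- function() list(type = "tanh")
nnPool <- function(k = 2L, stride = k) {
  list(type = "pool", k = as.integer(k), stride = as.integer(stride))
}
nnFlatten <- function() list(type = "flatten")
nnUnflatten <- function(h, w, c) list(type = "unflatten", h = h, w = w, c = c)
nnDense <- function(din, dout, wsd = 0.02) {
  list(type = "dense", din = din, dout = dout, wsd = wsd)
}
nnDropout <- function(p = 0.5) list(type = "dropout", p = p)

# ---- construction ----------------------------------------------------------

nnBuild <- function(defs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  layers <- lapply(defs, function(d) {
    params <- list(); buffers <- list()
    if (d$type == "conv") {
      params$W <- matrix(stats::rnorm(d$k * d$k * d$cin * d$cout, sd = d$wsd),
                         d$k * d$k * d$cin, d$cout)
      params$b <- numeric(d$cout)
    } else if (d$type == "tconv") {
      params$W <- matrix(stats::rnorm(d$k * d$k * d$cout * d$cin, sd = d$wsd),
                         d$k * d$k * d$cout, d$cin)
      params$b <- numeric(d$cout)
    } else if (d$type == "dense") {
      params$W <- matrix(stats::rnorm(d$dout * d$din, sd = d$wsd), d$dout, d$din)
      params$b <- numeric(d$dout)
    } else if (d$type == "bn") {
      params$gamma <- rep(1, d$c)
      params$beta <- rep(0, d$c)
      buffers$rmean <- rep(0, d$c)
      buffers$rvar <- rep(1, d$c)
    }
    list(def = d, params = params, buffers = buffers)
  })
  structure(list(layers = layers), class = "nnNet")
}

addColBias <- function(m, b) {
  for (f in seq_along(b)) m[, f] <- m[, f] + b[f]
  m
}

# ---- forward ---------------------------------------------------------------

layerForward <- function(layer, x, train, retain) {
  d <- layer$def
  cache <- NULL
  switch(d$type,
    conv = {
      dm <- dim(x)
      oh <- convOutSize(dm[1], d$k, d$stride, d$pad)
      ow <- convOutSize(dm[2], d$k, d$stride, d$pad)
      cols <- ng_im2col(x, dm[1], dm[2], dm[3], dm[4], d$k, d$stride, d$pad, oh, ow)
      y <- addColBias(cols %*% layer$params$W, layer$params$b)
      dim(y) <- c(oh, ow, dm[3], d$cout)
      if (retain) cache <- list(cols = cols, indim = dm, oh = oh, ow = ow)
      list(layer = layer, out = y, cache = cache)
    },
    tconv = {
      dm <- dim(x)
      H <- (dm[1] - 1L) * d$stride - 2L * d$pad + d$k + d$outpad
      W <- (dm[2] - 1L) * d$stride - 2L * d$pad + d$k + d$outpad
      xm <- x; dim(xm) <- c(dm[1] * dm[2] * dm[3], dm[4])
      dcols <- tcrossprod(xm, layer$params$W)
      y <- ng_col2im(dcols, H, W, dm[3], d$cout, d$k, d$stride, d$pad, dm[1], dm[2])
      ym <- y; dim(ym) <- c(H * W * dm[3], d$cout)
      ym <- addColBias(ym, layer$params$b)
      dim(ym) <- c(H, W, dm[3], d$cout)
      if (retain) cache <- list(xm = xm, indim = dm, H = H, W = W)
      list(layer = layer, out = ym, cache = cache)
    },
    bn = {
      dm <- dim(x); M <- prod(dm[-length(dm)])
      xm <- x; dim(xm) <- c(M, d$c)
      if (train) {
        mu <- colMeans(xm)
        v <- colMeans(xm^2) - mu^2
        layer$buffers$rmean <- d$momentum * layer$buffers$rmean + (1 - d$momentum) * mu
        layer$buffers$rvar <- d$momentum * layer$buffers$rvar + (1 - d$momentum) * v
      } else {
        mu <- layer$buffers$rmean
        v <- layer$buffers$rvar
      }
      invstd <- 1 / sqrt(v + d$eps)
      xhat <- (xm - rep(mu, each = M)) * rep(invstd, each = M)
      y <- xhat * rep(layer$params$gamma, each = M) +
        rep(layer$params$beta, each = M)
      dim(y) <- dm
      if (retain) cache <- list(xhat = xhat, invstd = invstd, dm = dm, M = M)
      list(layer = layer, out = y, cache = cache)
    },
    relu = {
      y <- pmax(x, 0); dim(y) <- dim(x)
      if (retain) cache <- list(mask = x > 0)
      list(layer = layer, out = y, cache = cache)
    },
    lrelu = {
      slope <- d$alpha + (1 - d$alpha) * (x > 0)
      y <- x * slope; dim(y) <- dim(x)
      if (retain) cache <- list(slope = slope)
      list(layer = layer, out = y, cache = cache)
    },
    tanh = {
      y <- tanh(x)
      if (retain) cache <- list(y = y)
      list(layer = layer, out = y, cache = cache)
    },
    pool = {
      dm <- dim(x)
      r <- ng_maxpool(x, dm[1], dm[2], dm[3], dm[4], d$k, d$stride)
      if (retain) cache <- list(argmax = r$argmax, indim = dm)
      list(layer = layer, out = r$out, cache = cache)
    },
    flatten = {
      dm <- dim(x)
      y <- aperm(x, c(1, 2, 4, 3))
      dim(y) <- c(dm[1] * dm[2] * dm[4], dm[3])
      if (retain) cache <- list(indim = dm)
      list(layer = layer, out = y, cache = cache)
    },
    unflatten = {
      N <- ncol(x)
      y <- x; dim(y) <- c(d$h, d$w, d$c, N)
      y <- aperm(y, c(1, 2, 4, 3))
      if (retain) cache <- list(N = N)
      list(layer = layer, out = y, cache = cache)
    },
    dense = {
      y <- layer$params$W %*% x + layer$params$b
      if (retain) cache <- list(x = x)
      list(layer = layer, out = y, cache = cache)
    },
    dropout = {
      if (train) {
        mask <- (stats::runif(length(x)) >= d$p) / (1 - d$p)
        y <- x * mask; dim(y) <- dim(x)
        if (retain) cache <- list(mask = mask)
      } else {
        y <- x
        if (retain) cache <- list(mask = NULL)
      }
      list(layer = layer, out = y, cache = cache)
    },
    stop("unknown layer type: ", d$type)
  )
}

nnForward <- function(net, x, train = FALSE, retain = train) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    r <- layerForward(net$layers[[i]], x, train, retain)
    net$layers[[i]] <- r$layer
    caches[[i]] <- r$cache
    x <- r$out
  }
  list(net = net, out = x, caches = caches)
}

# ---- backward --------------------------------------------------------------

layerBackward <- function(layer, cache, dy) {
  d <- layer$def
  switch(d$type,
    conv = {
      dm <- cache$indim
      dym <- dy; dim(dym) <- c(cache$oh * cache$ow * dm[3], d$cout)
      grads <- list(W = crossprod(cache$cols, dym), b = colSums(dym))
      dcols <- tcrossprod(dym, layer$params$W)
      dx <- ng_col2im(dcols, dm[1], dm[2], dm[3], dm[4], d$k, d$stride, d$pad,
                      cache$oh, cache$ow)
      list(dx = dx, grads = grads)
    },
    tconv = {
      dm <- cache$indim
      colsdy <- ng_im2col(dy, cache$H, cache$W, dm[3], d$cout, d$k, d$stride,
                          d$pad, dm[1], dm[2])
      dxm <- colsdy %*% layer$params$W
      dim(dxm) <- dm
      dym <- dy; dim(dym) <- c(cache$H * cache$W * dm[3], d$cout)
      grads <- list(W = crossprod(colsdy, cache$xm), b = colSums(dym))
      list(dx = dxm, grads = grads)
    },
    bn = {
      M <- cache$M
      dym <- dy; dim(dym) <- c(M, d$c)
      dgamma <- colSums(dym * cache$xhat)
      dbeta <- colSums(dym)
      dxhat <- dym * rep(layer$params$gamma, each = M)
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * cache$xhat)
      dx <- (dxhat - rep(s1 / M, each = M) -
               cache$xhat * rep(s2 / M, each = M)) * rep(cache$invstd, each = M)
      dim(dx) <- cache$dm
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = {
      dx <- dy * cache$mask; dim(dx) <- dim(dy)
      list(dx = dx, grads = list())
    },
    lrelu = {
      dx <- dy * cache$slope; dim(dx) <- dim(dy)
      list(dx = dx, grads = list())
    },
    tanh = {
      list(dx = dy * (1 - cache$y^2), grads = list())
    },
    pool = {
      dm <- cache$indim
      dx <- ng_maxpool_backward(dy, cache$argmax, dm[1], dm[2], dm[3], dm[4])
      list(dx = dx, grads = list())
    },
    flatten = {
      dm <- cache$indim
      dx <- dy; dim(dx) <- c(dm[1], dm[2], dm[4], dm[3])
      dx <- aperm(dx, c(1, 2, 4, 3))
      list(dx = dx, grads = list())
    },
    unflatten = {
      dx <- aperm(dy, c(1, 2, 4, 3))
      dim(dx) <- c(d$h * d$w * d$c, cache$N)
      list(dx = dx, grads = list())
    },
    dense = {
      grads <- list(W = tcrossprod(dy, cache$x), b = rowSums(dy))
      list(dx = crossprod(layer$params$W, dy), grads = grads)
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dy, grads = list())
      else { dx <- dy * cache$mask; dim(dx) <- dim(dy); list(dx = dx, grads = list()) }
    },
    stop("unknown layer type: ", d$type)
  )
}

nnBackward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  dy <- dout
  for (i in rev(seq_along(net$layers))) {
    r <- layerBackward(net$layers[[i]], caches[[i]], dy)
    grads[[i]] <- r$grads
    dy <- r$dx
  }
  list(dx = dy, grads = grads)
}

# ---- losses ----------------------------------------------------------------

# logits: [K, N]; y: integer class index 1..K per sample.
softmaxCrossEntropy <- function(logits, y) {
  K <- nrow(logits); N <- ncol(logits)
  m <- apply(logits, 2, max)
  e <- exp(logits - matrix(m, K, N, byrow = TRUE))
  p <- e / matrix(colSums(e), K, N, byrow = TRUE)
  idx <- cbind(y, seq_len(N))
  loss <- -mean(log(pmax(p[cbind(y, seq_len(N))], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / N
  list(loss = loss, dlogits = dlogits, probs = p)
}

# ---- optimizers ------------------------------------------------------------

optInitLike <- function(net) {
  lapply(net$layers, function(l) lapply(l$params, function(p) p * 0))
}

sgdStep <- function(net, grads, state, lr, momentum = 0.9) {
  for (i in seq_along(net$layers)) {
    for (nm in names(net$layers[[i]]$params)) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      v <- momentum * state[[i]][[nm]] + g
      state[[i]][[nm]] <- v
      net$layers[[i]]$params[[nm]] <- net$layers[[i]]$params[[nm]] - lr * v
    }
  }
  list(net = net, state = state)
}

rmspropStep <- function(net, grads, state, lr, rho = 0.9, eps = 1e-8) {
  for (i in seq_along(net$layers)) {
    for (nm in names(net$layers[[i]]$params)) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      v <- rho * state[[i]][[nm]] + (1 - rho) * g^2
      state[[i]][[nm]] <- v
      net$layers[[i]]$params[[nm]] <- net$layers[[i]]$params[[nm]] -
        lr * g / (sqrt(v) + eps)
    }
  }
  list(net = net, state = state)
}

# Clip every parameter of the network into [-clip, clip] (Wasserstein critic
# Lipschitz constraint).
nnClip <- function(net, clip) {
  for (i in seq_along(net$layers)) {
    for (nm in names(net$layers[[i]]$params)) {
      p <- net$layers[[i]]$params[[nm]]
      net$layers[[i]]$params[[nm]] <- pmin(pmax(p, -clip), clip)
    }
  }
  net
}

nnMaxAbsParam <- function(net) {
  m <- 0
  for (l in net$layers) for (p in l$params) m <- max(m, max(abs(p)))
  m
}

# Copy parameters and buffers of layer range `idx` from `src` into `dst`
# (shape-checked).
nnCopyLayers <- function(dst, src, idx) {
  for (i in idx) {
    for (nm in names(src$layers[[i]]$params)) {
      stopifnot(length(dst$layers[[i]]$params[[nm]]) ==
                  length(src$layers[[i]]$params[[nm]]))
      dst$layers[[i]]$params[[nm]] <- src$layers[[i]]$params[[nm]]
    }
    dst$layers[[i]]$buffers <- src$layers[[i]]$buffers
  }
  dst
}
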