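# Minimal CNN engine used by both classifier profiles.
#
# Tensors are numeric arrays in (H, W, C, N) layout; fully-connected parts use
# (features, N) matrices. Every layer is a plain list with a `type`, a `par`
# list of learnable arrays, and layer-specific config; `nn_forward()` /
# `nn_backward()` walk the layer list (recursively for residual blocks) and
# Adam updates mirror the nested parameter structure. Convolution and max
# pooling call the compiled im2col/GEMM kernels in src/.

channel_index <- function(C, N) rep(seq_len(C), times = N)

## ---- layer constructors -----------------------------------------------------

nn_conv <- function(kh, kw, cin, cout, stride = 1L, pad = NULL, groups = 1L,
                    bias = TRUE) {
  if (is.null(pad)) pad <- (kh - 1L) %/% 2L
  fan_in <- kh * kw * cin / groups
  w <- array(stats::rnorm(kh * kw * (cin / groups) * cout, sd = sqrt(2 / fan_in)),
             dim = c(kh, kw, cin / groups, cout))
  par <- list(w = w)
  if (bias) par$b <- numeric(cout)
  list(type = "conv", par = par, stride = as.integer(stride),
       pad = as.integer(pad), groups = as.integer(groups), bias = bias)
}

nn_bn <- function(C, eps = 1e-3, momentum = 0.1) {
  list(type = "bn", par = list(gamma = rep(1, C), beta = numeric(C)),
       buf = list(mean = numeric(C), var = rep(1, C)), eps = eps,
       momentum = momentum)
}

nn_act <- function(fun = c("relu", "swish")) {
  list(type = "act", fun = match.arg(fun), par = list())
}

nn_maxpool <- function(size = 2L, stride = size) {
  list(type = "maxpool", size = as.integer(size), stride = as.integer(stride),
       par = list())
}

nn_gap <- function() list(type = "gap", par = list())

nn_flatten <- function() list(type = "flatten", par = list())

nn_dense <- function(nin, nout) {
  list(type = "dense",
       par = list(w = matrix(stats::rnorm(nout * nin, sd = sqrt(2 / nin)),
                             nout, nin),
                  b = numeric(nout)))
}

# Squeeze-and-excitation: channel-wise gating by a 2-layer bottleneck on the
# globally pooled activations.
nn_se <- function(C, reduced) {
  list(type = "se",
       par = list(w1 = matrix(stats::rnorm(reduced * C, sd = sqrt(2 / C)),
                              reduced, C),
                  b1 = numeric(reduced),
                  w2 = matrix(stats::rnorm(C * reduced, sd = sqrt(2 / reduced)),
                              C, reduced),
                  b2 = numeric(C)))
}

# Residual block: sequential sub-layers, identity skip when `skip` is TRUE.
nn_block <- function(layers, skip = FALSE) {
  list(type = "block", layers = layers, skip = skip, par = list())
}

## ---- forward / backward -----------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    conv = {
      y <- .conv2d_fw(x, dim(x), layer$par$w, dim(layer$par$w),
                      if (layer$bias) layer$par$b else numeric(0),
                      layer$stride, layer$pad, layer$groups)
      list(y = y, cache = list(x = x))
    },
    bn = {
      d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
      xm <- matrix(x, HW, C * N)
      if (training) {
        cs <- .colMeans(xm, HW, C * N)
        cs2 <- .colMeans(xm * xm, HW, C * N)
        mu <- .rowMeans(matrix(cs, C, N), C, N)
        m2 <- .rowMeans(matrix(cs2, C, N), C, N)
        v <- pmax(m2 - mu^2, 0)
      } else {
        mu <- layer$buf$mean; v <- layer$buf$var
      }
      invstd <- 1 / sqrt(v + layer$eps)
      ch <- channel_index(C, N)
      xhat <- (xm - rep(mu[ch], each = HW)) * rep(invstd[ch], each = HW)
      y <- xhat * rep(layer$par$gamma[ch], each = HW) +
        rep(layer$par$beta[ch], each = HW)
      dim(y) <- d
      cache <- list(xhat = xhat, invstd = invstd, dims = d,
                    batch_mean = if (training) mu else NULL,
                    batch_var = if (training) v else NULL)
      list(y = y, cache = cache)
    },
    act = {
      if (layer$fun == "relu") {
        y <- pmax(x, 0); dim(y) <- dim(x)
        list(y = y, cache = list(pos = x > 0))
      } else { # swish
        s <- sigmoid(x)
        y <- x * s; dim(y) <- dim(x)
        list(y = y, cache = list(x = x, s = s))
      }
    },
    maxpool = {
      r <- .maxpool_fw(x, dim(x), layer$size, layer$stride)
      list(y = r$y, cache = list(argmax = r$argmax, xdim = dim(x)))
    },
    gap = {
      d <- dim(x)
      cm <- .colMeans(matrix(x, d[1] * d[2], d[3] * d[4]), d[1] * d[2],
                      d[3] * d[4])
      list(y = matrix(cm, d[3], d[4]), cache = list(xdim = d))
    },
    flatten = {
      d <- dim(x)
      list(y = matrix(x, d[1] * d[2] * d[3], d[4]), cache = list(xdim = d))
    },
    dense = {
      list(y = layer$par$w %*% x + layer$par$b, cache = list(x = x))
    },
    se = {
      d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
      z <- matrix(.colMeans(matrix(x, HW, C * N), HW, C * N), C, N)
      h <- pmax(layer$par$w1 %*% z + layer$par$b1, 0)
      s <- sigmoid(layer$par$w2 %*% h + layer$par$b2)
      ch <- channel_index(C, N)
      y <- matrix(x, HW, C * N) * rep(as.vector(s)[seq_len(C * N)], each = HW)
      dim(y) <- d
      list(y = y, cache = list(x = x, z = z, h = h, s = s))
    },
    block = {
      r <- nn_forward_layers(layer$layers, x, training)
      y <- r$y
      if (layer$skip) y <- y + x
      list(y = y, cache = list(inner = r$caches, layers = r$layers))
    },
    stop("unknown layer type: ", layer$type)
  )
}

# Returns y, per-layer caches, and (in training) layers with refreshed BN
# running statistics.
nn_forward_layers <- function(layers, x, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, training)
    x <- r$y
    caches[[i]] <- r$cache
    if (training && layers[[i]]$type == "bn") {
      m <- layers[[i]]$momentum
      layers[[i]]$buf$mean <- (1 - m) * layers[[i]]$buf$mean +
        m * r$cache$batch_mean
      layers[[i]]$buf$var <- (1 - m) * layers[[i]]$buf$var +
        m * r$cache$batch_var
    }
    if (training && layers[[i]]$type == "block") {
      layers[[i]]$layers <- r$cache$layers
    }
  }
  list(y = x, caches = caches, layers = layers)
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      r <- .conv2d_bw(cache$x, dim(cache$x), layer$par$w, dim(layer$par$w),
                      dy, layer$stride, layer$pad, layer$groups, TRUE)
      g <- list(w = r$dw)
      if (layer$bias) g$b <- r$db
      list(dx = r$dx, grads = g)
    },
    bn = {
      d <- cache$dims; HW <- d[1] * d[2]; C <- d[3]; N <- d[4]; M <- HW * N
      ch <- channel_index(C, N)
      dym <- matrix(dy, HW, C * N)
      sum_dy_cn <- .colSums(dym, HW, C * N)
      sum_dy <- .rowSums(matrix(sum_dy_cn, C, N), C, N)
      sum_dyx_cn <- .colSums(dym * cache$xhat, HW, C * N)
      sum_dyx <- .rowSums(matrix(sum_dyx_cn, C, N), C, N)
      g <- list(gamma = sum_dyx, beta = sum_dy)
      coef <- layer$par$gamma * cache$invstd / M
      dx <- rep(coef[ch], each = HW) *
        (M * dym - rep(sum_dy[ch], each = HW) -
           cache$xhat * rep(sum_dyx[ch], each = HW))
      dim(dx) <- d
      list(dx = dx, grads = g)
    },
    act = {
      if (layer$fun == "relu") {
        dx <- dy * cache$pos; dim(dx) <- dim(dy)
      } else {
        dx <- dy * (cache$s + cache$x * cache$s * (1 - cache$s))
        dim(dx) <- dim(dy)
      }
      list(dx = dx, grads = list())
    },
    maxpool = {
      list(dx = .maxpool_bw(dy, cache$argmax, cache$xdim), grads = list())
    },
    gap = {
      d <- cache$xdim; HW <- d[1] * d[2]
      dx <- rep(as.vector(dy) / HW, each = HW)
      dim(dx) <- d
      list(dx = dx, grads = list())
    },
    flatten = {
      dx <- dy; dim(dx) <- cache$xdim
      list(dx = dx, grads = list())
    },
    dense = {
      list(dx = crossprod(layer$par$w, dy),
           grads = list(w = tcrossprod(dy, cache$x), b = .rowSums(dy, nrow(dy), ncol(dy))))
    },
    se = {
      d <- dim(cache$x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
      ch <- channel_index(C, N)
      dym <- matrix(dy, HW, C * N)
      xm <- matrix(cache$x, HW, C * N)
      sv <- as.vector(cache$s)
      dx <- dym * rep(sv, each = HW)
      ds <- matrix(.colSums(dym * xm, HW, C * N), C, N)
      dpre2 <- ds * cache$s * (1 - cache$s)
      dh <- crossprod(layer$par$w2, dpre2) * (cache$h > 0)
      dz <- crossprod(layer$par$w1, dh)
      dx <- dx + rep(as.vector(dz) / HW, each = HW)
      dim(dx) <- d
      list(dx = dx,
           grads = list(w1 = tcrossprod(dh, cache$z),
                        b1 = .rowSums(dh, nrow(dh), ncol(dh)),
                        w2 = tcrossprod(dpre2, cache$h),
                        b2 = .rowSums(dpre2, nrow(dpre2), ncol(dpre2))))
    },
    block = {
      r <- nn_backward_layers(layer$layers, cache$inner, dy)
      dx <- r$dx
      if (layer$skip) dx <- dx + dy
      list(dx = dx, grads = list(layers = r$grads))
    },
    stop("unknown layer type")
  )
}

nn_backward_layers <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = dy, grads = grads)
}

## ---- optimiser --------------------------------------------------------------

adam_init_layers <- function(layers) {
  lapply(layers, function(l) {
    st <- lapply(l$par, function(p) list(m = p * 0, v = p * 0))
    if (l$type == "block") st$layers <- adam_init_layers(l$layers)
    st
  })
}

adam_step_layers <- function(layers, grads, state, lr, t, beta1 = 0.9,
                             beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "block") {
      r <- adam_step_layers(l$layers, grads[[i]]$layers, state[[i]]$layers,
                            lr, t, beta1, beta2, eps)
      layers[[i]]$layers <- r$layers
      state[[i]]$layers <- r$state
      next
    }
    for (nm in names(l$par)) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      layers[[i]]$par[[nm]] <- l$par[[nm]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}

nn_count_params_layers <- function(layers) {
  sum(vapply(layers, function(l) {
    n <- sum(vapply(l$par, length, integer(1)))
    if (l$type == "bn") n <- n + length(l$buf$mean) + length(l$buf$var)
    if (l$type == "block") n <- n + nn_count_params_layers(l$layers)
    n
  }, numeric(1)))
}

## ---- loss -------------------------------------------------------------------

# logits: (K, N); labels: integer 0-based classes. Returns mean cross-entropy,
# probabilities, and the gradient w.r.t. logits.
softmax_xent <- function(logits, labels) {
  K <- nrow(logits); N <- ncol(logits)
  mx <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, mx))
  p <- sweep(e, 2, colSums(e), "/")
  idx <- cbind(labels + 1L, seq_len(N))
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / N
  list(loss = loss, probs = p, dlogits = dlogits)
}
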