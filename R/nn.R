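# Minimal neural-network engine: dense / convolutional / transposed-
# convolutional layers with hand-written backpropagation and an Adam
# optimizer. Feature maps are arrays of dim (channels, height, width, batch);
# dense activations are (features, batch) matrices. Convolutions are computed
# as one matrix product per kernel offset, which keeps everything inside
# BLAS-backed base R.
#
# Internal: none of this is exported; the GAN suite and the style-transfer
# feature extractor are built on top of it.

nn_layer <- function(type, params = list(), ...) {
  c(list(type = type, params = params), list(...))
}

# --- layer constructors (weights drawn from the *current* RNG stream) -------

layer_dense <- function(n_in, n_out, w_sd = 0.02) {
  nn_layer("dense", params = list(
    W = matrix(stats::rnorm(n_out * n_in, sd = w_sd), n_out, n_in),
    b = numeric(n_out)
  ))
}

layer_conv <- function(c_in, c_out, k = 4L, stride = 1L, pad = 0L,
                       w_sd = 0.02) {
  nn_layer("conv",
    params = list(
      W = array(stats::rnorm(c_out * c_in * k * k, sd = w_sd),
                c(c_out, c_in, k, k)),
      b = numeric(c_out)
    ),
    k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad)
  )
}

layer_tconv <- function(c_in, c_out, k = 4L, stride = 2L, pad = 1L,
                        w_sd = 0.02) {
  nn_layer("tconv",
    params = list(
      W = array(stats::rnorm(c_out * c_in * k * k, sd = w_sd),
                c(c_out, c_in, k, k)),
      b = numeric(c_out)
    ),
    k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad)
  )
}

layer_batchnorm <- function(n_ch, momentum = 0.1, eps = 1e-5) {
  nn_layer("batchnorm",
    params = list(
      gamma = 1 + stats::rnorm(n_ch, sd = 0.02),
      beta  = numeric(n_ch)
    ),
    running_mean = numeric(n_ch), running_var = rep(1, n_ch),
    momentum = momentum, eps = eps
  )
}

layer_lrelu   <- function(alpha = 0.2) nn_layer("lrelu", alpha = alpha)
layer_relu    <- function() nn_layer("relu")
layer_tanh    <- function() nn_layer("tanh")
layer_sigmoid <- function() nn_layer("sigmoid")
layer_dropout <- function(rate = 0.25) nn_layer("dropout", rate = rate)
layer_flatten <- function() nn_layer("flatten")
layer_reshape <- function(shape) nn_layer("reshape", shape = as.integer(shape))
layer_upsample2 <- function() nn_layer("upsample2")
layer_avgpool2  <- function() nn_layer("avgpool2")
layer_crop_br   <- function(n = 1L) nn_layer("crop_br", n = as.integer(n))

# --- padding helpers ---------------------------------------------------------

pad_chw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2L * p, d[3] + 2L * p, d[4]))
  out[, p + seq_len(d[2]), p + seq_len(d[3]), ] <- x
  out
}

unpad_chw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  x[, (p + 1L):(d[2] - p), (p + 1L):(d[3] - p), , drop = FALSE]
}

# --- forward -----------------------------------------------------------------

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    dense = {
      out <- layer$params$W %*% x + layer$params$b
      list(out = out, cache = list(x = x), layer = layer)
    },
    conv = {
      k <- layer$k; s <- layer$stride; p <- layer$pad
      W <- layer$params$W
      cout <- dim(W)[1]; cin <- dim(W)[2]
      xp <- pad_chw(x, p)
      d <- dim(xp)
      oh <- (d[2] - k) %/% s + 1L; ow <- (d[3] - k) %/% s + 1L
      stopifnot((d[2] - k) %% s == 0L, (d[3] - k) %% s == 0L)
      M <- oh * ow * d[4]
      acc <- matrix(0, cout, M)
      for (a in seq_len(k)) {
        rows <- seq.int(a, by = s, length.out = oh)
        for (b in seq_len(k)) {
          cols <- seq.int(b, by = s, length.out = ow)
          xs <- xp[, rows, cols, , drop = FALSE]
          dim(xs) <- c(cin, M)
          acc <- acc + matrix(W[, , a, b], cout, cin) %*% xs
        }
      }
      acc <- acc + layer$params$b
      dim(acc) <- c(cout, oh, ow, d[4])
      list(out = acc, cache = list(xp = xp, oh = oh, ow = ow), layer = layer)
    },
    tconv = {
      k <- layer$k; s <- layer$stride; p <- layer$pad
      W <- layer$params$W
      cout <- dim(W)[1]; cin <- dim(W)[2]
      d <- dim(x)
      ohf <- (d[2] - 1L) * s + k; owf <- (d[3] - 1L) * s + k
      y <- array(0, c(cout, ohf, owf, d[4]))
      xm <- x; dim(xm) <- c(cin, d[2] * d[3] * d[4])
      for (a in seq_len(k)) {
        rows <- seq.int(a, by = s, length.out = d[2])
        for (b in seq_len(k)) {
          cols <- seq.int(b, by = s, length.out = d[3])
          contrib <- matrix(W[, , a, b], cout, cin) %*% xm
          dim(contrib) <- c(cout, d[2], d[3], d[4])
          y[, rows, cols, ] <- y[, rows, cols, , drop = FALSE] + contrib
        }
      }
      y <- unpad_chw(y, p)
      y <- y + layer$params$b   # recycles over the channel-first layout
      list(out = y, cache = list(x = x), layer = layer)
    },
    batchnorm = {
      d <- dim(x)
      xm <- x; dim(xm) <- c(d[1], prod(d[-1]))
      eps <- layer$eps
      if (training) {
        mu <- rowMeans(xm)
        va <- rowMeans(xm * xm) - mu^2
        mom <- layer$momentum
        layer$running_mean <- (1 - mom) * layer$running_mean + mom * mu
        layer$running_var  <- (1 - mom) * layer$running_var + mom * va
      } else {
        mu <- layer$running_mean
        va <- layer$running_var
      }
      inv_std <- 1 / sqrt(va + eps)
      xhat <- (xm - mu) * inv_std
      out <- layer$params$gamma * xhat + layer$params$beta
      dim(out) <- d
      list(out = out,
           cache = list(xhat = xhat, inv_std = inv_std, dims = d,
                        training = training),
           layer = layer)
    },
    lrelu = {
      mask <- ifelse(x > 0, 1, layer$alpha)
      list(out = x * mask, cache = list(mask = mask), layer = layer)
    },
    relu = {
      mask <- (x > 0) * 1
      list(out = x * mask, cache = list(mask = mask), layer = layer)
    },
    tanh = {
      out <- tanh(x)
      list(out = out, cache = list(out = out), layer = layer)
    },
    sigmoid = {
      out <- 1 / (1 + exp(-x))
      list(out = out, cache = list(out = out), layer = layer)
    },
    dropout = {
      if (training && layer$rate > 0) {
        keep <- 1 - layer$rate
        mask <- (array(stats::runif(length(x)), dim(x)) < keep) / keep
        list(out = x * mask, cache = list(mask = mask), layer = layer)
      } else {
        list(out = x, cache = list(mask = NULL), layer = layer)
      }
    },
    flatten = {
      d <- dim(x)
      out <- x; dim(out) <- c(prod(d[-length(d)]), d[length(d)])
      list(out = out, cache = list(dims = d), layer = layer)
    },
    reshape = {
      d <- dim(x)
      out <- x; dim(out) <- c(layer$shape, d[2])
      list(out = out, cache = list(dims = d), layer = layer)
    },
    upsample2 = {
      d <- dim(x)
      out <- x[, rep(seq_len(d[2]), each = 2L),
                 rep(seq_len(d[3]), each = 2L), , drop = FALSE]
      list(out = out, cache = list(dims = d), layer = layer)
    },
    avgpool2 = {
      d <- dim(x)
      r1 <- seq.int(1L, d[2], 2L); r2 <- r1 + 1L
      c1 <- seq.int(1L, d[3], 2L); c2 <- c1 + 1L
      out <- 0.25 * (x[, r1, c1, , drop = FALSE] + x[, r2, c1, , drop = FALSE] +
                     x[, r1, c2, , drop = FALSE] + x[, r2, c2, , drop = FALSE])
      list(out = out, cache = list(dims = d), layer = layer)
    },
    crop_br = {
      d <- dim(x); n <- layer$n
      out <- x[, seq_len(d[2] - n), seq_len(d[3] - n), , drop = FALSE]
      list(out = out, cache = list(dims = d), layer = layer)
    },
    stop("unknown layer type: ", layer$type)
  )
}

# forward pass through the whole network
# returns out, per-layer caches, and the (possibly updated) network
nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net))
  for (i in seq_along(net)) {
    step <- layer_forward(net[[i]], x, training)
    x <- step$out
    caches[[i]] <- step$cache
    net[[i]] <- step$layer
  }
  list(out = x, caches = caches, net = net)
}

# --- backward ----------------------------------------------------------------

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    dense = {
      list(dx = crossprod(layer$params$W, dout),
           grads = list(W = dout %*% t(cache$x), b = rowSums(dout)))
    },
    conv = {
      k <- layer$k; s <- layer$stride; p <- layer$pad
      W <- layer$params$W
      cout <- dim(W)[1]; cin <- dim(W)[2]
      xp <- cache$xp; oh <- cache$oh; ow <- cache$ow
      d <- dim(xp)
      M <- oh * ow * d[4]
      dm <- dout; dim(dm) <- c(cout, M)
      dW <- array(0, dim(W))
      dxp <- array(0, d)
      for (a in seq_len(k)) {
        rows <- seq.int(a, by = s, length.out = oh)
        for (b in seq_len(k)) {
          cols <- seq.int(b, by = s, length.out = ow)
          xs <- xp[, rows, cols, , drop = FALSE]
          dim(xs) <- c(cin, M)
          dW[, , a, b] <- dm %*% t(xs)
          dxs <- crossprod(matrix(W[, , a, b], cout, cin), dm)
          dim(dxs) <- c(cin, oh, ow, d[4])
          dxp[, rows, cols, ] <- dxp[, rows, cols, , drop = FALSE] + dxs
        }
      }
      list(dx = unpad_chw(dxp, p), grads = list(W = dW, b = rowSums(dm)))
    },
    tconv = {
      k <- layer$k; s <- layer$stride; p <- layer$pad
      W <- layer$params$W
      cout <- dim(W)[1]; cin <- dim(W)[2]
      x <- cache$x
      d <- dim(x)
      ohf <- (d[2] - 1L) * s + k; owf <- (d[3] - 1L) * s + k
      dyf <- array(0, c(cout, ohf, owf, d[4]))
      dyf[, (p + 1L):(ohf - p), (p + 1L):(owf - p), ] <- dout
      xm <- x; dim(xm) <- c(cin, d[2] * d[3] * d[4])
      dW <- array(0, dim(W))
      dx <- matrix(0, cin, d[2] * d[3] * d[4])
      for (a in seq_len(k)) {
        rows <- seq.int(a, by = s, length.out = d[2])
        for (b in seq_len(k)) {
          cols <- seq.int(b, by = s, length.out = d[3])
          dys <- dyf[, rows, cols, , drop = FALSE]
          dim(dys) <- c(cout, d[2] * d[3] * d[4])
          dW[, , a, b] <- dys %*% t(xm)
          dx <- dx + crossprod(matrix(W[, , a, b], cout, cin), dys)
        }
      }
      dim(dx) <- d
      db <- dout; dim(db) <- c(cout, length(dout) %/% cout)
      list(dx = dx, grads = list(W = dW, b = rowSums(db)))
    },
    batchnorm = {
      d <- cache$dims
      dm <- dout; dim(dm) <- c(d[1], prod(d[-1]))
      xhat <- cache$xhat
      gamma <- layer$params$gamma
      dgamma <- rowSums(dm * xhat)
      dbeta <- rowSums(dm)
      if (cache$training) {
        M <- ncol(dm)
        dxhat <- dm * gamma
        dx <- (cache$inv_std / M) *
          (M * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
      } else {
        dx <- dm * (gamma * cache$inv_std)
      }
      dim(dx) <- d
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    lrelu = list(dx = dout * cache$mask, grads = NULL),
    relu  = list(dx = dout * cache$mask, grads = NULL),
    tanh  = list(dx = dout * (1 - cache$out^2), grads = NULL),
    sigmoid = list(dx = dout * cache$out * (1 - cache$out), grads = NULL),
    dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache$mask, grads = NULL)
    },
    flatten = { dim(dout) <- cache$dims; list(dx = dout, grads = NULL) },
    reshape = { dim(dout) <- cache$dims; list(dx = dout, grads = NULL) },
    upsample2 = {
      d <- cache$dims
      r1 <- seq.int(1L, 2L * d[2], 2L); c1 <- seq.int(1L, 2L * d[3], 2L)
      dx <- dout[, r1, c1, , drop = FALSE] + dout[, r1 + 1L, c1, , drop = FALSE] +
            dout[, r1, c1 + 1L, , drop = FALSE] +
            dout[, r1 + 1L, c1 + 1L, , drop = FALSE]
      list(dx = dx, grads = NULL)
    },
    avgpool2 = {
      d <- cache$dims
      dx <- array(0, d)
      r1 <- seq.int(1L, d[2], 2L); c1 <- seq.int(1L, d[3], 2L)
      q <- 0.25 * dout
      dx[, r1, c1, ] <- q; dx[, r1 + 1L, c1, ] <- q
      dx[, r1, c1 + 1L, ] <- q; dx[, r1 + 1L, c1 + 1L, ] <- q
      list(dx = dx, grads = NULL)
    },
    crop_br = {
      d <- cache$dims
      dx <- array(0, d)
      dx[, seq_len(d[2] - layer$n), seq_len(d[3] - layer$n), ] <- dout
      list(dx = dx, grads = NULL)
    },
    stop("unknown layer type: ", layer$type)
  )
}

# full backward pass; returns gradient lists (one per layer, NULL where the
# layer has no parameters) and the gradient w.r.t. the network input
nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    step <- layer_backward(net[[i]], caches[[i]], dout)
    dout <- step$dx
    grads[i] <- list(step$grads)   # [[<- would drop NULLs and shrink the list
  }
  list(dx = dout, grads = grads)
}

# element-wise sum of two per-layer gradient lists
nn_add_grads <- function(g1, g2) {
  if (is.null(g1)) return(g2)
  for (i in seq_along(g1)) {
    if (!is.null(g2[[i]])) {
      for (nm in names(g2[[i]])) {
        g1[[i]][[nm]] <- (g1[[i]][[nm]] %||% 0) + g2[[i]][[nm]]
      }
    }
  }
  g1
}

# --- Adam --------------------------------------------------------------------

adam_init <- function(net) {
  lapply(net, function(layer) {
    if (length(layer$params) == 0) return(NULL)
    lapply(layer$params, function(p) list(m = p * 0, v = p * 0))
  })
}

adam_step <- function(net, grads, state, lr, t,
                      beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(net)) {
    if (is.null(grads[[i]])) next
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      net[[i]]$params[[nm]] <- net[[i]]$params[[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(net = net, state = state)
}

# total number of trainable parameters
nn_n_params <- function(net) {
  sum(vapply(net, function(l) sum(vapply(l$params, length, 1L)), 1L))
}
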