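# Convolutional layer engine with explicit backpropagation.
#
# A layer couples one (transposed) convolution with optional batch
# normalization, an activation, and optional dropout, in that order.
# Feature batches are (H, W, C, N) arrays; weights are stored as the
# (k*k*C_in) x C_out GEMM matrix the C++ kernels consume (transposed
# convolutions store (k*k*C_out) x C_in, i.e. the matrix of the convolution
# they are the adjoint of).

new_layer <- function(type = c("conv", "tconv"), in_ch, out_ch,
                      k = 4L, stride = 2L, pad = 1L,
                      bn = TRUE, act = "lrelu", dropout = 0,
                      lrelu_slope = 0.2, init_sd = 0.02) {
  type <- match.arg(type)
  kk <- k * k
  wdim <- if (type == "conv") c(kk * in_ch, out_ch) else c(kk * out_ch, in_ch)
  layer <- list(
    type = type, in_ch = in_ch, out_ch = out_ch,
    k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad),
    W = matrix(rnorm(prod(wdim), sd = init_sd), wdim[1], wdim[2]),
    b = numeric(out_ch),
    bn = isTRUE(bn), act = act, dropout = dropout, lrelu_slope = lrelu_slope
  )
  if (layer$bn) {
    layer$gamma <- rnorm(out_ch, mean = 1, sd = 0.02)
    layer$beta <- numeric(out_ch)
    layer$run_mean <- numeric(out_ch)
    layer$run_var <- rep(1, out_ch)
    layer$bn_momentum <- 0.1
    layer$bn_eps <- 1e-5
  }
  layer
}

# ---- batch normalization ----------------------------------------------------

bn_forward <- function(layer, x, training) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]
  xm <- x; dim(xm) <- c(HW, C, d[4])
  if (training) {
    mu <- numeric(C); v <- numeric(C)
    for (c in seq_len(C)) {
      s <- xm[, c, ]
      mu[c] <- mean(s)
      v[c] <- mean((s - mu[c])^2) # population variance
    }
  } else {
    mu <- layer$run_mean; v <- layer$run_var
  }
  istd <- 1 / sqrt(v + layer$bn_eps)
  xhat <- xm; out <- xm
  for (c in seq_len(C)) {
    xhat[, c, ] <- (xm[, c, ] - mu[c]) * istd[c]
    out[, c, ] <- layer$gamma[c] * xhat[, c, ] + layer$beta[c]
  }
  dim(out) <- d
  list(out = out, xhat = xhat, mu = mu, var = v, istd = istd)
}

bn_backward <- function(layer, cache, dout) {
  d <- dim(dout); HW <- d[1] * d[2]; C <- d[3]
  dm <- dout; dim(dm) <- c(HW, C, d[4])
  M <- HW * d[4]
  dx <- dm
  dgamma <- numeric(C); dbeta <- numeric(C)
  for (c in seq_len(C)) {
    g <- dm[, c, ]
    xh <- cache$xhat[, c, ]
    dgamma[c] <- sum(g * xh)
    dbeta[c] <- sum(g)
    dxhat <- g * layer$gamma[c]
    # dvar and dmu terms of the standard batch-norm backward pass
    s1 <- sum(dxhat)
    s2 <- sum(dxhat * xh)
    dx[, c, ] <- cache$istd[c] * (dxhat - s1 / M - xh * s2 / M)
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- activations ------------------------------------------------------------

act_forward <- function(act, a, slope) {
  switch(act,
    lrelu = ifelse(a > 0, a, slope * a),
    relu = pmax(a, 0),
    tanh = tanh(a),
    sigmoid = 1 / (1 + exp(-a)),
    none = a,
    stop("unknown activation: ", act)
  )
}

act_backward <- function(act, a, y, dy, slope) {
  switch(act,
    lrelu = dy * ifelse(a > 0, 1, slope),
    relu = dy * (a > 0),
    tanh = dy * (1 - y^2),
    sigmoid = dy * y * (1 - y),
    none = dy
  )
}

# ---- layer forward / backward ----------------------------------------------

layer_forward <- function(layer, x, training = FALSE) {
  d <- dim(x)
  if (d[3] != layer$in_ch)
    stop(sprintf(paste0(
      "channel mismatch: layer expects %d input channels, got %d",
      if (layer$in_ch == 6L)
        " (the conditional discriminator takes the corrupted image concatenated with the candidate)"
      else ""), layer$in_ch, d[3]), call. = FALSE)
  if (layer$type == "conv") {
    z <- cpp_conv_fwd(x, layer$W, layer$b, layer$k, layer$stride, layer$pad)
  } else {
    Hin <- d[1] * layer$stride
    Win <- d[2] * layer$stride
    z <- cpp_conv_bwd_data(x, layer$W, layer$k, layer$stride, layer$pad,
                           Hin, Win)
    dz <- dim(z)
    for (c in seq_len(layer$out_ch))
      z[, , c, ] <- z[, , c, ] + layer$b[c]
  }
  cache <- list(x = x, z = z)
  h <- z
  use_bn <- layer$bn && dim(z)[1] * dim(z)[2] > 1 # skip BN on 1x1 maps
  cache$use_bn <- use_bn
  if (use_bn) {
    bnc <- bn_forward(layer, h, training)
    cache$bn <- bnc
    h <- bnc$out
  }
  cache$a <- h
  h <- act_forward(layer$act, h, layer$lrelu_slope)
  cache$y <- h
  if (training && layer$dropout > 0) {
    keep <- 1 - layer$dropout
    mask <- array((runif(length(h)) < keep) / keep, dim(h))
    cache$mask <- mask
    h <- h * mask
  }
  list(out = h, cache = cache)
}

layer_backward <- function(layer, cache, dout, need_dx = TRUE) {
  if (!is.null(cache$mask)) dout <- dout * cache$mask
  da <- act_backward(layer$act, cache$a, cache$y, dout, layer$lrelu_slope)
  grads <- list()
  if (cache$use_bn) {
    bb <- bn_backward(layer, cache$bn, da)
    da <- bb$dx
    grads$gamma <- bb$dgamma
    grads$beta <- bb$dbeta
  } else if (layer$bn) {
    grads$gamma <- numeric(layer$out_ch)
    grads$beta <- numeric(layer$out_ch)
  }
  if (layer$type == "conv") {
    res <- cpp_conv_bwd(cache$x, da, layer$W, layer$k, layer$stride,
                        layer$pad, need_dx)
    grads$W <- res$dW
    grads$b <- res$db
    dx <- if (need_dx) res$dx else NULL
  } else {
    # transposed conv: weight grad swaps the roles of input and upstream grad
    res <- cpp_conv_bwd(da, cache$x, layer$W, layer$k, layer$stride,
                        layer$pad, FALSE)
    grads$W <- res$dW
    db <- numeric(layer$out_ch)
    for (c in seq_len(layer$out_ch)) db[c] <- sum(da[, , c, ])
    grads$b <- db
    dx <- if (need_dx)
      cpp_conv_fwd(da, layer$W, numeric(layer$in_ch), layer$k,
                   layer$stride, layer$pad)
    else NULL
  }
  list(dx = dx, grads = grads)
}

# update running BN statistics from a training-mode forward cache
layer_update_running <- function(layer, cache) {
  if (cache$use_bn) {
    m <- layer$bn_momentum
    layer$run_mean <- (1 - m) * layer$run_mean + m * cache$bn$mu
    layer$run_var <- (1 - m) * layer$run_var + m * cache$bn$var
  }
  layer
}

layer_param_names <- function(layer) {
  c("W", "b", if (layer$bn) c("gamma", "beta"))
}
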