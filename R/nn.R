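# Minimal 1D convolutional network engine.
#
# Activations are arrays of dim (length, channels, batch). Convolutions are
# computed as im2col patch matrices times a (kernel*channels_in x
# channels_out) weight matrix so the heavy lifting stays in BLAS; the same
# patch matrix is reused for the weight and input gradients. Everything is
# deterministic given the R RNG state, and gradients propagate all the way
# to the input (needed for integrated gradients).
#
# Internal: none of this is exported directly; qc_fit() and
# integrated_gradients() are the public surface.

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

nn_layer_conv <- function(k, c_in, c_out) {
  list(type = "conv", k = k, c_in = c_in, c_out = c_out,
       params = list(W = he_init(k * c_in, c_out, k * c_in),
                     b = numeric(c_out)))
}

nn_layer_relu <- function() list(type = "relu", params = NULL)

nn_layer_pool2 <- function() list(type = "pool2", params = NULL)

nn_layer_flatten <- function() list(type = "flatten", params = NULL)

nn_layer_dense <- function(f_in, f_out) {
  list(type = "dense", f_in = f_in, f_out = f_out,
       params = list(W = he_init(f_in, f_out, f_in), b = numeric(f_out)))
}

# inception block: parallel conv branches (kernels 1/3/5) plus a width-3
# same-padded max-pool branch projected by a 1x1 conv; channel-concatenated
nn_layer_inception <- function(c_in, c_branch) {
  list(type = "inception", c_in = c_in, c_branch = c_branch,
       params = list(
         b1 = nn_layer_conv(1L, c_in, c_branch)$params,
         b3 = nn_layer_conv(3L, c_in, c_branch)$params,
         b5 = nn_layer_conv(5L, c_in, c_branch)$params,
         bp = nn_layer_conv(1L, c_in, c_branch)$params))
}

# ---- primitive forward/backward ----

conv_fwd <- function(X, W, b, k) {
  d <- dim(X); L <- d[1L]; C <- d[2L]; B <- d[3L]
  if (k == 1L) {
    M <- matrix(aperm(X, c(1L, 3L, 2L)), L * B, C)
  } else {
    pad <- (k - 1L) %/% 2L
    Xp <- array(0, c(L + 2L * pad, C, B))
    Xp[pad + seq_len(L), , ] <- X
    P <- array(0, c(L, C, B, k))
    for (kk in seq_len(k))
      P[, , , kk] <- Xp[(kk - 1L) + seq_len(L), , , drop = FALSE]
    M <- aperm(P, c(1L, 3L, 2L, 4L))
    dim(M) <- c(L * B, C * k)
  }
  Y <- M %*% W
  Y <- Y + rep(b, each = nrow(Y))
  c_out <- length(b)
  dim(Y) <- c(L, B, c_out)
  list(out = aperm(Y, c(1L, 3L, 2L)),
       cache = list(M = M, L = L, C = C, B = B, k = k))
}

conv_bwd <- function(dY, cache, W) {
  L <- cache$L; C <- cache$C; B <- cache$B; k <- cache$k
  c_out <- ncol(W)
  dYm <- matrix(aperm(dY, c(1L, 3L, 2L)), L * B, c_out)
  dW <- crossprod(cache$M, dYm)
  db <- colSums(dYm)
  dM <- tcrossprod(dYm, W)
  if (k == 1L) {
    dim(dM) <- c(L, B, C)
    dX <- aperm(dM, c(1L, 3L, 2L))
  } else {
    pad <- (k - 1L) %/% 2L
    dim(dM) <- c(L, B, C, k)
    dP <- aperm(dM, c(1L, 3L, 2L, 4L))     # (L, C, B, k)
    dXp <- array(0, c(L + 2L * pad, C, B))
    for (kk in seq_len(k)) {
      idx <- (kk - 1L) + seq_len(L)
      dP_k <- dP[, , , kk, drop = FALSE]
      dim(dP_k) <- c(L, C, B)
      dXp[idx, , ] <- dXp[idx, , , drop = FALSE] + dP_k
    }
    dX <- dXp[pad + seq_len(L), , , drop = FALSE]
  }
  list(dX = dX, grads = list(W = dW, b = db))
}

pool2_fwd <- function(X) {
  d <- dim(X); L <- d[1L]
  L2 <- L %/% 2L
  i1 <- seq.int(1L, 2L * L2, by = 2L)
  A <- X[i1, , , drop = FALSE]
  B2 <- X[i1 + 1L, , , drop = FALSE]
  mask <- A >= B2
  list(out = pmax(A, B2), cache = list(mask = mask, L = L, i1 = i1))
}

pool2_bwd <- function(dY, cache, dims_in) {
  dX <- array(0, dims_in)
  dX[cache$i1, , ] <- dY * cache$mask
  dX[cache$i1 + 1L, , ] <- dY * !cache$mask
  dX
}

pool3same_fwd <- function(X) {
  d <- dim(X); L <- d[1L]
  Xp <- array(-Inf, c(L + 2L, d[2L], d[3L]))
  Xp[1L + seq_len(L), , ] <- X
  s1 <- Xp[seq_len(L), , , drop = FALSE]
  s2 <- Xp[1L + seq_len(L), , , drop = FALSE]
  s3 <- Xp[2L + seq_len(L), , , drop = FALSE]
  m1 <- (s1 >= s2) & (s1 >= s3)
  m2 <- !m1 & (s2 >= s3)
  list(out = pmax(s1, s2, s3),
       cache = list(m1 = m1, m2 = m2, L = L))
}

pool3same_bwd <- function(dY, cache, dims_in) {
  L <- cache$L
  dXp <- array(0, c(L + 2L, dims_in[2L], dims_in[3L]))
  m3 <- !(cache$m1 | cache$m2)
  dXp[seq_len(L), , ] <- dY * cache$m1
  idx2 <- 1L + seq_len(L)
  dXp[idx2, , ] <- dXp[idx2, , , drop = FALSE] + dY * cache$m2
  idx3 <- 2L + seq_len(L)
  dXp[idx3, , ] <- dXp[idx3, , , drop = FALSE] + dY * m3
  dXp[1L + seq_len(L), , , drop = FALSE]
}

# ---- layer dispatch ----

layer_fwd <- function(layer, X) {
  switch(layer$type,
    conv = conv_fwd(X, layer$params$W, layer$params$b, layer$k),
    relu = {
      mask <- X > 0
      list(out = X * mask, cache = list(mask = mask))
    },
    pool2 = pool2_fwd(X),
    flatten = {
      d <- dim(X)
      Y <- aperm(X, c(3L, 1L, 2L))
      dim(Y) <- c(d[3L], d[1L] * d[2L])
      list(out = Y, cache = list(dims = d))
    },
    dense = {
      Y <- X %*% layer$params$W
      Y <- Y + rep(layer$params$b, each = nrow(Y))
      list(out = Y, cache = list(X = X))
    },
    inception = {
      p1 <- conv_fwd(X, layer$params$b1$W, layer$params$b1$b, 1L)
      p3 <- conv_fwd(X, layer$params$b3$W, layer$params$b3$b, 3L)
      p5 <- conv_fwd(X, layer$params$b5$W, layer$params$b5$b, 5L)
      pool <- pool3same_fwd(X)
      pp <- conv_fwd(pool$out, layer$params$bp$W, layer$params$bp$b, 1L)
      cb <- layer$c_branch
      d <- dim(X)
      Y <- array(0, c(d[1L], 4L * cb, d[3L]))
      masks <- vector("list", 4L)
      branch_outs <- list(p1$out, p3$out, p5$out, pp$out)
      for (i in 1:4) {
        m <- branch_outs[[i]] > 0
        Y[, (i - 1L) * cb + seq_len(cb), ] <- branch_outs[[i]] * m
        masks[[i]] <- m
      }
      list(out = Y,
           cache = list(c1 = p1$cache, c3 = p3$cache, c5 = p5$cache,
                        cp = pp$cache, cpool = pool$cache,
                        masks = masks, dims_in = d))
    },
    stop("unknown layer type: ", layer$type))
}

layer_bwd <- function(layer, dY, cache, dims_in) {
  switch(layer$type,
    conv = conv_bwd(dY, cache, layer$params$W),
    relu = list(dX = dY * cache$mask, grads = NULL),
    pool2 = list(dX = pool2_bwd(dY, cache, dims_in), grads = NULL),
    flatten = {
      dX <- dY
      d <- cache$dims
      dim(dX) <- c(d[3L], d[1L], d[2L])
      list(dX = aperm(dX, c(2L, 3L, 1L)), grads = NULL)
    },
    dense = list(
      dX = tcrossprod(dY, layer$params$W),
      grads = list(W = crossprod(cache$X, dY), b = colSums(dY))),
    inception = {
      cb <- layer$c_branch
      parts <- lapply(1:4, function(i)
        dY[, (i - 1L) * cb + seq_len(cb), , drop = FALSE] *
          cache$masks[[i]])
      g1 <- conv_bwd(parts[[1L]], cache$c1, layer$params$b1$W)
      g3 <- conv_bwd(parts[[2L]], cache$c3, layer$params$b3$W)
      g5 <- conv_bwd(parts[[3L]], cache$c5, layer$params$b5$W)
      gp <- conv_bwd(parts[[4L]], cache$cp, layer$params$bp$W)
      dX_pool <- pool3same_bwd(gp$dX, cache$cpool, dims_in)
      list(dX = g1$dX + g3$dX + g5$dX + dX_pool,
           grads = list(W1 = g1$grads, W3 = g3$grads, W5 = g5$grads,
                        Wp = gp$grads))
    },
    stop("unknown layer type: ", layer$type))
}

# ---- network assembly ----

# 6 x (conv -> relu -> maxpool) then FC(256) -> relu -> FC(64) -> relu ->
# FC(2); the post-activation 64-node layer is the penultimate feature block
build_cnn_net <- function(spec) {
  layers <- list()
  c_in <- 1L
  L <- spec$input_length
  for (i in seq_len(spec$cnn_conv_layers)) {
    layers <- c(layers,
                list(nn_layer_conv(spec$kernel_size, c_in,
                                   spec$cnn_channels[i]),
                     nn_layer_relu(), nn_layer_pool2()))
    c_in <- spec$cnn_channels[i]
    L <- L %/% 2L
  }
  layers <- c(layers, list(
    nn_layer_flatten(),
    nn_layer_dense(L * c_in, spec$fc_widths[1L]), nn_layer_relu(),
    nn_layer_dense(spec$fc_widths[1L], spec$penultimate_width),
    nn_layer_relu(),
    nn_layer_dense(spec$penultimate_width, spec$n_classes)))
  list(layers = layers, input_length = spec$input_length,
       n_classes = spec$n_classes)
}

# 2 x (conv -> relu -> maxpool), 2 x (inception -> maxpool), then the same
# fully connected tail as the CNN
build_icnn_net <- function(spec) {
  layers <- list()
  c_in <- 1L
  L <- spec$input_length
  for (i in seq_len(spec$icnn_conv_layers)) {
    layers <- c(layers,
                list(nn_layer_conv(spec$kernel_size, c_in,
                                   spec$icnn_channels[i]),
                     nn_layer_relu(), nn_layer_pool2()))
    c_in <- spec$icnn_channels[i]
    L <- L %/% 2L
  }
  for (i in seq_len(spec$icnn_inception_modules)) {
    layers <- c(layers,
                list(nn_layer_inception(c_in, spec$inception_branch_channels),
                     nn_layer_pool2()))
    c_in <- 4L * spec$inception_branch_channels
    L <- L %/% 2L
  }
  layers <- c(layers, list(
    nn_layer_flatten(),
    nn_layer_dense(L * c_in, spec$fc_widths[1L]), nn_layer_relu(),
    nn_layer_dense(spec$fc_widths[1L], spec$penultimate_width),
    nn_layer_relu(),
    nn_layer_dense(spec$penultimate_width, spec$n_classes)))
  list(layers = layers, input_length = spec$input_length,
       n_classes = spec$n_classes)
}

# X: batch x length matrix of preprocessed spectra
nn_forward <- function(net, X, keep_cache = FALSE) {
  B <- nrow(X)
  A <- array(t(X), dim = c(ncol(X), 1L, B))
  n <- length(net$layers)
  caches <- if (keep_cache) vector("list", n) else NULL
  dims <- if (keep_cache) vector("list", n) else NULL
  penult <- NULL
  for (i in seq_len(n)) {
    if (i == n) penult <- A   # input to the final output layer (64 nodes)
    if (keep_cache) dims[[i]] <- dim(A)
    step <- layer_fwd(net$layers[[i]], A)
    if (keep_cache) caches[[i]] <- step$cache
    A <- step$out
  }
  list(logits = A, penult = penult, caches = caches, dims = dims)
}

# dlogits: batch x n_classes; returns parameter grads and (optionally) the
# gradient with respect to the input spectra
nn_backward <- function(net, fwd, dlogits, need_dx = FALSE) {
  n <- length(net$layers)
  grads <- vector("list", n)
  dA <- dlogits
  for (i in rev(seq_len(n))) {
    step <- layer_bwd(net$layers[[i]], dA, fwd$caches[[i]], fwd$dims[[i]])
    grads[i] <- list(step$grads)   # keep NULL placeholders for no-param layers
    dA <- step$dX
  }
  dX <- NULL
  if (need_dx) {
    d <- dim(dA)               # (L, 1, B)
    dX <- t(matrix(dA, d[1L], d[3L]))
  }
  list(grads = grads, dX = dX)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# categorical cross-entropy; y_idx in 1..n_classes
ce_loss_grad <- function(logits, y_idx) {
  p <- softmax_rows(logits)
  B <- nrow(p)
  eps <- 1e-12
  loss <- -mean(log(pmax(p[cbind(seq_len(B), y_idx)], eps)))
  dZ <- p
  dZ[cbind(seq_len(B), y_idx)] <- dZ[cbind(seq_len(B), y_idx)] - 1
  list(loss = loss, dZ = dZ / B, p = p)
}

# ---- Adam over the nested parameter/gradient trees ----

zero_like_tree <- function(x) {
  if (is.list(x)) lapply(x, zero_like_tree)
  else if (is.numeric(x)) x * 0
  else NULL
}

adam_init <- function(net) {
  params <- lapply(net$layers, function(l) l$params)
  list(m = zero_like_tree(params), v = zero_like_tree(params), t = 0L)
}

adam_apply <- function(p, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  if (is.null(g)) return(list(p = p, m = m, v = v))
  if (is.list(p)) {
    out_p <- p; out_m <- m; out_v <- v
    for (nm in names(p)) {
      r <- adam_apply(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t, beta1,
                      beta2, eps)
      out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
    }
    return(list(p = out_p, m = out_m, v = out_v))
  }
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g * g
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

adam_step <- function(net, grads, state, lr) {
  state$t <- state$t + 1L
  # inception grads come back named W1/W3/W5/Wp, params named b1/b3/b5/bp
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    if (net$layers[[i]]$type == "inception")
      names(g) <- c("b1", "b3", "b5", "bp")
    r <- adam_apply(net$layers[[i]]$params, g, state$m[[i]], state$v[[i]],
                    lr, state$t)
    net$layers[[i]]$params <- r$p
    state$m[[i]] <- r$m
    state$v[[i]] <- r$v
  }
  list(net = net, state = state)
}
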