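# Minimal fully-convolutional layer framework: conv / relu / maxpool /
# bilinear upsample / spatial batch-norm / residual block, with forward and
# backward passes. Activations are H x W x C arrays; convolutions are
# im2col + BLAS matrix products, with the gather/scatter index vectors
# cached per shape. This is the engine behind every backbone; training is
# plain SGD with momentum and weight decay (the optimizer family the
# stated momentum/weight-decay hyperparameters presuppose).

# ---- im2col index cache -------------------------------------------------

im2col_index <- function(h, w, ch, k, stride, pad) {
  key <- sprintf("i2c_%d_%d_%d_%d_%d_%d", h, w, ch, k, stride, pad)
  cached <- .earcount_cache[[key]]
  if (!is.null(cached)) return(cached)
  hp <- h + 2 * pad; wp <- w + 2 * pad
  ho <- (hp - k) %/% stride + 1L
  wo <- (wp - k) %/% stride + 1L
  or_ <- rep(seq_len(ho), times = wo)              # output row, fast
  oc_ <- rep(seq_len(wo), each = ho)
  base_r <- (or_ - 1L) * stride                     # top-left of patch - 1
  base_c <- (oc_ - 1L) * stride
  n_out <- ho * wo
  idx <- integer(n_out * k * k * ch)
  col <- 0L
  for (c_ in seq_len(ch)) for (kj in seq_len(k)) for (ki in seq_len(k)) {
    rows <- base_r + ki
    cols <- base_c + kj
    lin <- rows + (cols - 1L) * hp + (c_ - 1L) * hp * wp
    idx[col * n_out + seq_len(n_out)] <- lin
    col <- col + 1L
  }
  # spatial (single-plane) indices of the k*k kernel offsets, used by the
  # backward scatter: identical across channels up to a plane offset
  sp <- matrix(idx[seq_len(n_out * k * k)], n_out, k * k)
  out <- list(idx = idx, sp = sp, ho = ho, wo = wo, hp = hp, wp = wp,
              n_out = n_out)
  .earcount_cache[[key]] <- out
  out
}

pad_array <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  out
}

# ---- layer constructors -------------------------------------------------

nn_conv <- function(in_ch, out_ch, k = 3, stride = 1, pad = (k - 1) %/% 2) {
  # He initialisation; weights are filled later by init_params (seeded)
  list(type = "conv", in_ch = in_ch, out_ch = out_ch, k = k,
       stride = stride, pad = pad,
       W = matrix(0, k * k * in_ch, out_ch), b = numeric(out_ch))
}
nn_relu <- function() list(type = "relu")
nn_maxpool <- function() list(type = "maxpool")           # 2 x 2, stride 2
nn_upsample <- function(factor = 2) list(type = "upsample", factor = factor)
nn_bn <- function(ch, eps = 1e-5)
  list(type = "bn", ch = ch, eps = eps, gamma = rep(1, ch), beta = rep(0, ch))
nn_block <- function(layers, projection = NULL)
  list(type = "block", layers = layers, projection = projection)

# ---- forward ------------------------------------------------------------

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = {
      d <- dim(x)
      ii <- im2col_index(d[1], d[2], d[3], layer$k, layer$stride, layer$pad)
      xp <- pad_array(x, layer$pad)
      X2 <- xp[ii$idx]
      dim(X2) <- c(ii$n_out, layer$k^2 * d[3])
      Y <- X2 %*% layer$W + rep(layer$b, each = ii$n_out)
      dim(Y) <- c(ii$ho, ii$wo, layer$out_ch)
      list(out = Y, cache = list(X2 = X2, in_dim = d, ii = ii))
    },
    relu = list(out = pmax(x, 0), cache = list(mask = x > 0)),
    maxpool = {
      d <- dim(x)
      xr <- x; dim(xr) <- c(2, d[1] / 2, 2, d[2] / 2, d[3])
      m4 <- cbind(as.vector(xr[1, , 1, , ]), as.vector(xr[2, , 1, , ]),
                  as.vector(xr[1, , 2, , ]), as.vector(xr[2, , 2, , ]))
      pick <- max.col(m4, ties.method = "first")
      y <- m4[cbind(seq_along(pick), pick)]
      dim(y) <- c(d[1] / 2, d[2] / 2, d[3])
      list(out = y, cache = list(pick = pick, in_dim = d))
    },
    upsample = {
      d <- dim(x)
      f <- layer$factor
      R <- interp_matrix(d[1], d[1] * f); C <- interp_matrix(d[2], d[2] * f)
      y <- array(0, c(d[1] * f, d[2] * f, d[3]))
      for (k in seq_len(d[3])) y[, , k] <- R %*% x[, , k] %*% t(C)
      list(out = y, cache = list(R = R, C = C, in_dim = d))
    },
    bn = {
      d <- dim(x); n <- d[1] * d[2]
      xm <- matrix(x, n, d[3])
      mu <- colMeans(xm)
      xc <- sweep(xm, 2, mu)
      v <- colMeans(xc^2)
      inv <- 1 / sqrt(v + layer$eps)
      xhat <- sweep(xc, 2, inv, "*")
      ym <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
      list(out = array(ym, d),
           cache = list(xhat = xhat, inv = inv, d = d))
    },
    block = {
      caches <- vector("list", length(layer$layers))
      h <- x
      for (i in seq_along(layer$layers)) {
        f <- layer_forward(layer$layers[[i]], h)
        h <- f$out; caches[[i]] <- f$cache
      }
      if (!is.null(layer$projection)) {
        pf <- layer_forward(layer$projection, x)
        sc <- pf$out; pcache <- pf$cache
      } else { sc <- x; pcache <- NULL }
      list(out = pmax(h + sc, 0),   # residual add + relu
           cache = list(caches = caches, pcache = pcache,
                        mask = (h + sc) > 0))
    },
    stopf("unknown layer type %s", layer$type))
}

# ---- backward -----------------------------------------------------------

# Returns list(dx = ..., grads = list(W=, b=) or NULL)
layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      ii <- cache$ii; d <- cache$in_dim
      dY2 <- dy; dim(dY2) <- c(ii$n_out, layer$out_ch)
      dW <- crossprod(cache$X2, dY2)
      db <- colSums(dY2)
      dX2 <- tcrossprod(dY2, layer$W)
      # scatter-add back to the padded input; within one kernel-offset
      # column the target indices are distinct, so a plain indexed add per
      # column is exact (and much faster than any grouped sum)
      k2 <- layer$k^2
      dxp <- matrix(0, ii$hp * ii$wp, d[3])
      for (o in seq_len(k2)) {
        j <- ii$sp[, o]
        dxp[j, ] <- dxp[j, ] + dX2[, seq(o, by = k2, length.out = d[3]), drop = FALSE]
      }
      dxp <- array(dxp, c(ii$hp, ii$wp, d[3]))
      p <- layer$pad
      dx <- dxp[p + seq_len(d[1]), p + seq_len(d[2]), , drop = FALSE]
      list(dx = dx, grads = list(W = dW, b = db))
    },
    relu = list(dx = dy * cache$mask, grads = NULL),
    maxpool = {
      d <- cache$in_dim
      n <- length(cache$pick)
      dm4 <- matrix(0, n, 4)
      dm4[cbind(seq_len(n), cache$pick)] <- as.vector(dy)
      dxr <- array(0, c(2, d[1] / 2, 2, d[2] / 2, d[3]))
      half <- c(d[1] / 2, d[2] / 2, d[3])
      dxr[1, , 1, , ] <- array(dm4[, 1], half)
      dxr[2, , 1, , ] <- array(dm4[, 2], half)
      dxr[1, , 2, , ] <- array(dm4[, 3], half)
      dxr[2, , 2, , ] <- array(dm4[, 4], half)
      dim(dxr) <- d
      list(dx = dxr, grads = NULL)
    },
    upsample = {
      d <- cache$in_dim
      dx <- array(0, d)
      for (k in seq_len(d[3]))
        dx[, , k] <- t(cache$R) %*% dy[, , k] %*% cache$C
      list(dx = dx, grads = NULL)
    },
    bn = {
      d <- cache$d; n <- d[1] * d[2]
      dym <- matrix(dy, n, d[3])
      dgamma <- colSums(dym * cache$xhat)
      dbeta <- colSums(dym)
      dxhat <- sweep(dym, 2, layer$gamma, "*")
      t1 <- sweep(dxhat, 2, colMeans(dxhat))
      t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
      dxm <- sweep(t1 - t2, 2, cache$inv, "*")
      list(dx = array(dxm, d), grads = list(gamma = dgamma, beta = dbeta))
    },
    block = {
      dsum <- dy * cache$mask
      dh <- dsum
      grads <- vector("list", length(layer$layers))
      for (i in rev(seq_along(layer$layers))) {
        bk <- layer_backward(layer$layers[[i]], cache$caches[[i]], dh)
        dh <- bk$dx; grads[i] <- list(bk$grads)
      }
      if (!is.null(layer$projection)) {
        pk <- layer_backward(layer$projection, cache$pcache, dsum)
        dx <- dh + pk$dx
        list(dx = dx, grads = list(inner = grads, projection = pk$grads))
      } else {
        list(dx = dh + dsum, grads = list(inner = grads, projection = NULL))
      }
    },
    stopf("unknown layer type %s", layer$type))
}

# ---- model-level helpers ------------------------------------------------

model_forward <- function(model, x, keep_caches = FALSE) {
  caches <- if (keep_caches) vector("list", length(model$layers)) else NULL
  h <- x
  for (i in seq_along(model$layers)) {
    f <- layer_forward(model$layers[[i]], h)
    h <- f$out
    if (keep_caches) caches[[i]] <- f$cache
  }
  list(logits = h, caches = caches)
}

model_backward <- function(model, caches, dZ) {
  grads <- vector("list", length(model$layers))
  dh <- dZ
  for (i in rev(seq_along(model$layers))) {
    bk <- layer_backward(model$layers[[i]], caches[[i]], dh)
    dh <- bk$dx; grads[i] <- list(bk$grads)
  }
  grads
}

softmax2 <- function(Z) {
  m <- pmax(Z[, , 1], Z[, , 2])
  e1 <- exp(Z[, , 1] - m); e2 <- exp(Z[, , 2] - m)
  tot <- e1 + e2
  S <- array(0, dim(Z))
  S[, , 1] <- e1 / tot; S[, , 2] <- e2 / tot
  probability_map(S)
}

# Seeded He initialisation of every conv weight in place (recursive).
init_params <- function(layers) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      fan_in <- nrow(l$W)
      layers[[i]]$W <- matrix(stats::rnorm(length(l$W), 0, sqrt(2 / fan_in)),
                              nrow(l$W), ncol(l$W))
    } else if (l$type == "block") {
      layers[[i]]$layers <- init_params(l$layers)
      if (!is.null(l$projection))
        layers[[i]]$projection <- init_params(list(l$projection))[[1]]
    }
  }
  layers
}

# Flatten all trainable parameters to a named numeric vector (coef method).
collect_params <- function(layers, prefix = "layer") {
  out <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    nm <- sprintf("%s%d", prefix, i)
    if (l$type == "conv") {
      out[[paste0(nm, ".W")]] <- as.vector(l$W)
      out[[paste0(nm, ".b")]] <- l$b
    } else if (l$type == "bn") {
      out[[paste0(nm, ".gamma")]] <- l$gamma
      out[[paste0(nm, ".beta")]] <- l$beta
    } else if (l$type == "block") {
      out <- c(out, collect_params(l$layers, paste0(nm, ".")))
      if (!is.null(l$projection))
        out <- c(out, collect_params(list(l$projection), paste0(nm, ".proj")))
    }
  }
  out
}

# SGD with momentum + weight decay, applied recursively over layers.
# velocity has the same nesting as grads.
sgd_update <- function(layers, grads, velocity, lr, momentum, weight_decay) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]; g <- grads[[i]]
    if (is.null(g)) next
    if (l$type == "conv") {
      if (is.null(velocity[[i]])) velocity[[i]] <- list(W = 0 * l$W, b = 0 * l$b)
      velocity[[i]]$W <- momentum * velocity[[i]]$W - lr * (g$W + weight_decay * l$W)
      velocity[[i]]$b <- momentum * velocity[[i]]$b - lr * g$b
      layers[[i]]$W <- l$W + velocity[[i]]$W
      layers[[i]]$b <- l$b + velocity[[i]]$b
    } else if (l$type == "bn") {
      if (is.null(velocity[[i]])) velocity[[i]] <- list(gamma = 0 * l$gamma, beta = 0 * l$beta)
      velocity[[i]]$gamma <- momentum * velocity[[i]]$gamma - lr * g$gamma
      velocity[[i]]$beta <- momentum * velocity[[i]]$beta - lr * g$beta
      layers[[i]]$gamma <- l$gamma + velocity[[i]]$gamma
      layers[[i]]$beta <- l$beta + velocity[[i]]$beta
    } else if (l$type == "block") {
      if (is.null(velocity[[i]])) velocity[[i]] <- list(inner = vector("list", length(l$layers)),
                                                        projection = NULL)
      upd <- sgd_update(l$layers, g$inner, velocity[[i]]$inner, lr, momentum, weight_decay)
      layers[[i]]$layers <- upd$layers
      velocity[[i]]$inner <- upd$velocity
      if (!is.null(l$projection)) {
        updp <- sgd_update(list(l$projection), list(g$projection),
                           list(velocity[[i]]$projection), lr, momentum, weight_decay)
        layers[[i]]$projection <- updp$layers[[1]]
        velocity[[i]]$projection <- updp$velocity[[1]]
      }
    }
  }
  list(layers = layers, velocity = velocity)
}
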