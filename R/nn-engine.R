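# Minimal convolutional network engine.
#
# A batch of images is a numeric matrix with `H*W*C` rows (h fastest, then w,
# then channel) and one column per sample.  Convolutions are evaluated by
# im2col: patch-gather indices are precomputed per layer at build time (input
# geometry is static), so a forward/backward pass is a handful of gathers,
# matrix products and scatter-adds.  Everything is plain double-precision
# base R, which keeps training bit-reproducible for a fixed seed.

conv_plan <- function(in_shape, kh, kw, stride = 1L, pad = 0L) {
  H <- in_shape[1L]; W <- in_shape[2L]; C <- in_shape[3L]
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  if (Hp < kh || Wp < kw) {
    stop("input ", H, "x", W, " too small for ", kh, "x", kw,
         " kernel (needs at least ", kh - 2L * pad, "x", kw - 2L * pad, ")")
  }
  oh <- (Hp - kh) %/% stride + 1L
  ow <- (Wp - kw) %/% stride + 1L
  ki <- rep.int(seq_len(kh), kw)
  kj <- rep(seq_len(kw), each = kh)
  base_hw <- (ki - 1L) + (kj - 1L) * Hp
  base <- as.vector(outer(base_hw, (seq_len(C) - 1L) * (Hp * Wp), "+"))
  oi <- rep.int(seq_len(oh), ow)
  oj <- rep(seq_len(ow), each = oh)
  start <- (oi - 1L) * stride + (oj - 1L) * stride * Hp + 1L
  idx <- as.vector(outer(base, start, "+"))
  inner <- NULL
  if (pad > 0L) {
    h <- rep.int(seq_len(H), W * C)
    w <- rep(rep(seq_len(W), each = H), C)
    ch <- rep(seq_len(C), each = H * W)
    inner <- (h + pad - 1L) + (w + pad - 1L) * Hp + (ch - 1L) * Hp * Wp + 1L
  }
  list(idx = idx, L = kh * kw * C, P = oh * ow, oh = oh, ow = ow,
       inner = inner, padded_len = Hp * Wp * C, in_shape = in_shape)
}

pad_batch <- function(X, plan, fill = 0) {
  if (is.null(plan$inner)) return(X)
  Xp <- matrix(fill, plan$padded_len, ncol(X))
  Xp[plan$inner, ] <- X
  Xp
}

unpad_batch <- function(Xp, plan) {
  if (is.null(plan$inner)) Xp else Xp[plan$inner, , drop = FALSE]
}

# scatter-add of a (L*P) x M gradient back through the gather indices
scatter_cols <- function(dcols, plan, ncols) {
  rs <- rowsum(dcols, group = plan$idx)
  dXp <- matrix(0, plan$padded_len, ncols)
  dXp[as.integer(rownames(rs)), ] <- rs
  dXp
}

conv_forward <- function(X, plan, W, b) {
  N <- ncol(X)
  Xp <- pad_batch(X, plan)
  cols <- Xp[plan$idx, , drop = FALSE]
  dim(cols) <- c(plan$L, plan$P * N)
  out <- crossprod(W, cols) + b
  nf <- ncol(W)
  dim(out) <- c(nf, plan$P, N)
  out <- aperm(out, c(2L, 1L, 3L))
  dim(out) <- c(plan$P * nf, N)
  list(out = out, cols = cols)
}

conv_backward <- function(dout, cache, plan, W) {
  nf <- ncol(W)
  N <- ncol(dout)
  dim(dout) <- c(plan$P, nf, N)
  dout <- aperm(dout, c(2L, 1L, 3L))
  dim(dout) <- c(nf, plan$P * N)
  dW <- cache$cols %*% t(dout)
  db <- rowSums(dout)
  dcols <- W %*% dout
  dim(dcols) <- c(plan$L * plan$P, N)
  dX <- unpad_batch(scatter_cols(dcols, plan, N), plan)
  list(dX = dX, dW = dW, db = db)
}

# max pooling is a C=1 im2col over each channel plane; channels ride along
# with the batch dimension
maxpool_forward <- function(X, plan, C) {
  N <- ncol(X)
  dim(X) <- c(length(X) / (C * N), C * N)
  Xp <- pad_batch(X, plan, fill = -Inf)
  cols <- Xp[plan$idx, , drop = FALSE]
  dim(cols) <- c(plan$L, plan$P * C * N)
  mx <- cols[1L, ]
  am <- rep.int(1L, length(mx))
  for (l in seq_len(plan$L)[-1L]) {
    sel <- cols[l, ] > mx
    mx[sel] <- cols[l, sel]
    am[sel] <- l
  }
  out <- mx
  dim(out) <- c(plan$P * C, N)
  list(out = out, am = am)
}

maxpool_backward <- function(dout, cache, plan, C, in_len) {
  N <- ncol(dout)
  M <- plan$P * C * N
  dcols <- matrix(0, plan$L, M)
  dcols[cbind(cache$am, seq_len(M))] <- as.vector(dout)
  dim(dcols) <- c(plan$L * plan$P, C * N)
  dXp <- scatter_cols(dcols, plan, C * N)
  dX <- unpad_batch(dXp, plan)
  dim(dX) <- c(in_len, N)
  dX
}

global_avgpool_forward <- function(X, hw, C) {
  N <- ncol(X)
  dim(X) <- c(hw, C * N)
  out <- colMeans(X)
  dim(out) <- c(C, N)
  out
}

global_avgpool_backward <- function(dout, hw, C) {
  N <- ncol(dout)
  dX <- matrix(rep(as.vector(dout), each = hw) / hw, hw * C, N)
  dX
}

dense_forward <- function(X, W, b) crossprod(W, X) + b

dense_backward <- function(dout, X, W) {
  list(dX = W %*% dout, dW = X %*% t(dout), db = rowSums(dout))
}

# ---- layer construction -----------------------------------------------------

he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

new_conv_layer <- function(in_shape, kh, kw, out_ch, stride = 1L, pad = 0L) {
  plan <- conv_plan(in_shape, kh, kw, stride, pad)
  list(type = "conv", plan = plan,
       W = he_init(plan$L, out_ch), b = numeric(out_ch),
       in_shape = in_shape, out_shape = c(plan$oh, plan$ow, out_ch))
}

new_relu_layer <- function(in_shape) {
  list(type = "relu", in_shape = in_shape, out_shape = in_shape)
}

new_maxpool_layer <- function(in_shape, kh, kw, stride, pad = 0L) {
  plan <- conv_plan(c(in_shape[1L], in_shape[2L], 1L), kh, kw, stride, pad)
  list(type = "maxpool", plan = plan, C = in_shape[3L],
       in_shape = in_shape, out_shape = c(plan$oh, plan$ow, in_shape[3L]))
}

new_gap_layer <- function(in_shape) {
  list(type = "gap", hw = in_shape[1L] * in_shape[2L], C = in_shape[3L],
       in_shape = in_shape, out_shape = c(1L, 1L, in_shape[3L]))
}

new_dense_layer <- function(in_shape, units) {
  nin <- prod(in_shape)
  list(type = "dense", W = he_init(nin, units), b = numeric(units),
       in_shape = in_shape, out_shape = c(1L, 1L, units))
}

# inception block: four parallel branches over the same input, channel-concat.
# branch widths: b1 (1x1), b3r->b3 (1x1 reduce then 3x3), b5r->b5 (1x1 reduce
# then 5x5), pp (3x3 maxpool then 1x1 projection)
new_inception_layer <- function(in_shape, b1, b3r, b3, b5r, b5, pp) {
  branch <- function(specs) {
    layers <- list()
    shape <- in_shape
    for (s in specs) {
      lay <- switch(s$what,
        conv = new_conv_layer(shape, s$k, s$k, s$ch, 1L, (s$k - 1L) %/% 2L),
        relu = new_relu_layer(shape),
        pool = new_maxpool_layer(shape, 3L, 3L, 1L, 1L))
      layers[[length(layers) + 1L]] <- lay
      shape <- lay$out_shape
    }
    layers
  }
  branches <- list(
    branch(list(list(what = "conv", k = 1L, ch = b1), list(what = "relu"))),
    branch(list(list(what = "conv", k = 1L, ch = b3r), list(what = "relu"),
                list(what = "conv", k = 3L, ch = b3), list(what = "relu"))),
    branch(list(list(what = "conv", k = 1L, ch = b5r), list(what = "relu"),
                list(what = "conv", k = 5L, ch = b5), list(what = "relu"))),
    branch(list(list(what = "pool"),
                list(what = "conv", k = 1L, ch = pp), list(what = "relu"))))
  out_ch <- b1 + b3 + b5 + pp
  list(type = "inception", branches = branches,
       in_shape = in_shape,
       out_shape = c(in_shape[1L], in_shape[2L], out_ch))
}

# ---- forward / backward over a layer list -----------------------------------

layer_forward <- function(layer, X) {
  switch(layer$type,
    conv = {
      r <- conv_forward(X, layer$plan, layer$W, layer$b)
      list(out = r$out, cache = list(cols = r$cols))
    },
    relu = list(out = pmax(X, 0), cache = list(mask = X > 0)),
    maxpool = {
      r <- maxpool_forward(X, layer$plan, layer$C)
      list(out = r$out, cache = list(am = r$am, in_len = nrow(X)))
    },
    gap = list(out = global_avgpool_forward(X, layer$hw, layer$C),
               cache = NULL),
    dense = list(out = dense_forward(X, layer$W, layer$b),
                 cache = list(X = X)),
    inception = {
      outs <- vector("list", length(layer$branches))
      caches <- vector("list", length(layer$branches))
      for (i in seq_along(layer$branches)) {
        cur <- X
        bc <- vector("list", length(layer$branches[[i]]))
        for (j in seq_along(layer$branches[[i]])) {
          r <- layer_forward(layer$branches[[i]][[j]], cur)
          cur <- r$out
          bc[[j]] <- r$cache
        }
        outs[[i]] <- cur
        caches[[i]] <- bc
      }
      list(out = do.call(rbind, outs),
           cache = list(branch = caches,
                        rows = vapply(outs, nrow, integer(1))))
    },
    stop("unknown layer type: ", layer$type))
}

# returns list(dX, grads) where grads mirrors the layer's parameter slots
layer_backward <- function(layer, dout, cache) {
  switch(layer$type,
    conv = {
      r <- conv_backward(dout, cache, layer$plan, layer$W)
      list(dX = r$dX, grads = list(W = r$dW, b = r$db))
    },
    relu = list(dX = dout * cache$mask, grads = NULL),
    maxpool = list(
      dX = maxpool_backward(dout, cache, layer$plan, layer$C, cache$in_len),
      grads = NULL),
    gap = list(dX = global_avgpool_backward(dout, layer$hw, layer$C),
               grads = NULL),
    dense = {
      r <- dense_backward(dout, cache$X, layer$W)
      list(dX = r$dX, grads = list(W = r$dW, b = r$db))
    },
    inception = {
      offsets <- cumsum(c(0L, cache$rows))
      dX <- NULL
      grads <- vector("list", length(layer$branches))
      for (i in seq_along(layer$branches)) {
        dcur <- dout[(offsets[i] + 1L):offsets[i + 1L], , drop = FALSE]
        bg <- vector("list", length(layer$branches[[i]]))
        for (j in rev(seq_along(layer$branches[[i]]))) {
          r <- layer_backward(layer$branches[[i]][[j]], dcur,
                              cache$branch[[i]][[j]])
          dcur <- r$dX
          bg[j] <- list(r$grads)
        }
        grads[[i]] <- bg
        dX <- if (is.null(dX)) dcur else dX + dcur
      }
      list(dX = dX, grads = grads)
    })
}

net_forward <- function(layers, X, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], X)
    X <- r$out
    if (keep_cache) caches[[i]] <- r$cache
  }
  list(out = X, caches = caches)
}

net_backward <- function(layers, dout, caches) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], dout, caches[[i]])
    dout <- r$dX
    grads[i] <- list(r$grads)   # keep NULL slots (grads[[i]] <- NULL deletes)
  }
  grads
}

softmax_cols <- function(logits) {
  m <- apply(logits, 2L, max)
  e <- exp(sweep(logits, 2L, m))
  sweep(e, 2L, colSums(e), "/")
}

# cross-entropy loss and gradient for one-hot Y (K x N)
softmax_xent <- function(logits, Y) {
  p <- softmax_cols(logits)
  n <- ncol(logits)
  loss <- -sum(Y * log(pmax(p, 1e-300))) / n
  list(loss = loss, dlogits = (p - Y) / n, probs = p)
}

# flatten/restore parameters for SGD state and save/load
collect_params <- function(layers, fn) {
  walk <- function(lay, path) {
    if (lay$type %in% c("conv", "dense")) fn(lay, path)
    if (lay$type == "inception") {
      for (i in seq_along(lay$branches))
        for (j in seq_along(lay$branches[[i]]))
          walk(lay$branches[[i]][[j]], c(path, i, j))
    }
    invisible(NULL)
  }
  for (k in seq_along(layers)) walk(layers[[k]], k)
}

count_params <- function(layers) {
  total <- 0L
  collect_params(layers, function(lay, path) {
    total <<- total + length(lay$W) + length(lay$b)
  })
  total
}

# apply SGD + momentum update in place over (layers, velocity, grads)
sgd_update <- function(layers, grads, velocity, lr, momentum) {
  upd <- function(lay, g, v) {
    if (is.null(v)) v <- list(W = 0 * lay$W, b = 0 * lay$b)
    v$W <- momentum * v$W - lr * g$W
    v$b <- momentum * v$b - lr * g$b
    lay$W <- lay$W + v$W
    lay$b <- lay$b + v$b
    list(lay = lay, v = v)
  }
  rec <- function(lay, g, v) {
    if (lay$type %in% c("conv", "dense")) {
      r <- upd(lay, g, v)
      return(r)
    }
    if (lay$type == "inception") {
      if (is.null(v)) v <- vector("list", length(lay$branches))
      for (i in seq_along(lay$branches)) {
        if (is.null(v[[i]])) v[[i]] <- vector("list", length(lay$branches[[i]]))
        for (j in seq_along(lay$branches[[i]])) {
          sub <- rec(lay$branches[[i]][[j]], g[[i]][[j]], v[[i]][[j]])
          if (!is.null(sub)) {
            lay$branches[[i]][[j]] <- sub$lay
            v[[i]][[j]] <- sub$v
          }
        }
      }
      return(list(lay = lay, v = v))
    }
    NULL
  }
  for (k in seq_along(layers)) {
    if (!is.null(grads[[k]])) {
      r <- rec(layers[[k]], grads[[k]], velocity[[k]])
      layers[[k]] <- r$lay
      velocity[[k]] <- r$v
    }
  }
  list(layers = layers, velocity = velocity)
}
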