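# Minimal neural-network engine: 3x3 same-padding convolution via im2col and
# BLAS matmuls, 2x2 max pooling, average-pool downsampling, dense layers, and
# SGD with momentum. Activations for the conv stack are (H, W, C) arrays per
# sample; the dense stack is batched as (B x D) matrices. Internal only.

.he_init <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
}

.shifts3 <- as.matrix(expand.grid(dy = -1:1, dx = -1:1))

# ---- conv 3x3, stride 1, pad 1, fused ReLU ----

conv_forward <- function(x, W, b, relu = TRUE) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]
  xp <- array(0, c(H + 2, Wd + 2, C))
  xp[2:(H + 1), 2:(Wd + 1), ] <- x
  col <- matrix(0, C * 9, H * Wd)
  for (s in 1:9) {
    dy <- .shifts3[s, 1]; dx <- .shifts3[s, 2]
    v <- xp[(1:H) + 1 + dy, (1:Wd) + 1 + dx, , drop = FALSE]
    col[((s - 1) * C + 1):(s * C), ] <- t(matrix(v, H * Wd, C))
  }
  y <- W %*% col + b
  mask <- NULL
  if (relu) {
    mask <- y > 0
    y <- y * mask
  }
  list(out = array(t(y), c(H, Wd, nrow(W))),
       cache = list(col = col, mask = mask, dims = c(H, Wd, C)))
}

conv_backward <- function(dy, W, cache) {
  H <- cache$dims[1]; Wd <- cache$dims[2]; C <- cache$dims[3]
  Cout <- nrow(W)
  dym <- t(matrix(dy, H * Wd, Cout))
  if (!is.null(cache$mask)) dym <- dym * cache$mask
  dW <- dym %*% t(cache$col)
  db <- rowSums(dym)
  dcol <- crossprod(W, dym)                      # (C*9) x (H*W)
  dxp <- array(0, c(H + 2, Wd + 2, C))
  for (s in 1:9) {
    dy_ <- .shifts3[s, 1]; dx_ <- .shifts3[s, 2]
    blk <- array(t(dcol[((s - 1) * C + 1):(s * C), , drop = FALSE]),
                 c(H, Wd, C))
    dxp[(1:H) + 1 + dy_, (1:Wd) + 1 + dx_, ] <-
      dxp[(1:H) + 1 + dy_, (1:Wd) + 1 + dx_, , drop = FALSE] + blk
  }
  list(dx = dxp[2:(H + 1), 2:(Wd + 1), , drop = FALSE], dW = dW, db = db)
}

# ---- 2x2 max pool (floor crop on odd dims); ties route to the first view ----

maxpool_forward <- function(x) {
  d <- dim(x); H2 <- d[1] %/% 2; W2 <- d[2] %/% 2; C <- d[3]
  i1 <- seq(1, 2 * H2, 2); j1 <- seq(1, 2 * W2, 2)
  v <- list(x[i1, j1, , drop = FALSE], x[i1 + 1, j1, , drop = FALSE],
            x[i1, j1 + 1, , drop = FALSE], x[i1 + 1, j1 + 1, , drop = FALSE])
  m <- pmax(v[[1]], v[[2]], v[[3]], v[[4]])
  taken <- array(FALSE, dim(m))
  masks <- vector("list", 4)
  for (k in 1:4) {
    mk <- (v[[k]] == m) & !taken
    taken <- taken | mk
    masks[[k]] <- mk
  }
  list(out = m, cache = list(masks = masks, dims = d, H2 = H2, W2 = W2))
}

maxpool_backward <- function(dy, cache) {
  d <- cache$dims; H2 <- cache$H2; W2 <- cache$W2
  i1 <- seq(1, 2 * H2, 2); j1 <- seq(1, 2 * W2, 2)
  dx <- array(0, d)
  dx[i1, j1, ] <- dy * cache$masks[[1]]
  dx[i1 + 1, j1, ] <- dx[i1 + 1, j1, , drop = FALSE] + dy * cache$masks[[2]]
  dx[i1, j1 + 1, ] <- dx[i1, j1 + 1, , drop = FALSE] + dy * cache$masks[[3]]
  dx[i1 + 1, j1 + 1, ] <- dx[i1 + 1, j1 + 1, , drop = FALSE] + dy * cache$masks[[4]]
  dx
}

# ---- average-pool downsample by integer factor (fixed, no parameters) ----

avgpool_forward <- function(x, f) {
  d <- dim(x); H2 <- d[1] %/% f; W2 <- d[2] %/% f; C <- d[3]
  out <- array(0, c(H2, W2, C))
  for (c in seq_len(C)) {
    m <- x[seq_len(H2 * f), seq_len(W2 * f), c]
    m <- rowsum(m, rep(seq_len(H2), each = f)) # sums over row blocks
    m <- t(rowsum(t(m), rep(seq_len(W2), each = f)))
    out[, , c] <- m / (f * f)
  }
  out
}

# ---- batched dense layer ----

dense_forward <- function(X, W, b, relu = TRUE) {
  Y <- X %*% t(W)
  Y <- sweep(Y, 2, b, `+`)
  mask <- NULL
  if (relu) {
    mask <- Y > 0
    Y <- Y * mask
  }
  list(out = Y, cache = list(X = X, mask = mask))
}

dense_backward <- function(dY, W, cache) {
  if (!is.null(cache$mask)) dY <- dY * cache$mask
  list(dX = dY %*% W, dW = crossprod(dY, cache$X), db = colSums(dY))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# ---- multilayer perceptron (dense stack, ReLU hidden, linear output) ----

mlp_init <- function(sizes, seed = 1L) {
  with_seed(seed, {
    L <- length(sizes) - 1
    layers <- vector("list", L)
    for (l in seq_len(L)) {
      layers[[l]] <- list(W = .he_init(sizes[l + 1], sizes[l]),
                          b = numeric(sizes[l + 1]))
    }
    structure(list(layers = layers, sizes = sizes), class = "gradenav_mlp")
  })
}

mlp_forward <- function(net, X, keep_cache = FALSE) {
  L <- length(net$layers)
  caches <- if (keep_cache) vector("list", L) else NULL
  for (l in seq_len(L)) {
    f <- dense_forward(X, net$layers[[l]]$W, net$layers[[l]]$b, relu = l < L)
    X <- f$out
    if (keep_cache) caches[[l]] <- f$cache
  }
  list(out = X, caches = caches)
}

mlp_backward <- function(net, caches, dOut) {
  L <- length(net$layers)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    g <- dense_backward(dOut, net$layers[[l]]$W, caches[[l]])
    grads[[l]] <- list(dW = g$dW, db = g$db)
    dOut <- g$dX
  }
  grads
}

# SGD with momentum; `state` carries velocity buffers shaped like the params.
sgd_momentum_step <- function(net, grads, state, lr, momentum = 0.9) {
  for (l in seq_along(net$layers)) {
    if (is.null(state[[l]])) {
      state[[l]] <- list(vW = net$layers[[l]]$W * 0,
                         vb = net$layers[[l]]$b * 0)
    }
    state[[l]]$vW <- momentum * state[[l]]$vW - lr * grads[[l]]$dW
    state[[l]]$vb <- momentum * state[[l]]$vb - lr * grads[[l]]$db
    net$layers[[l]]$W <- net$layers[[l]]$W + state[[l]]$vW
    net$layers[[l]]$b <- net$layers[[l]]$b + state[[l]]$vb
  }
  list(net = net, state = state)
}

# ---- small convolutional backbone ----
#
# avgpool(pool_factor) -> [conv3x3+ReLU, maxpool2] x length(channels)
#   -> flatten -> dense(feature_dim, ReLU) -> dense(n_classes, linear)
# The penultimate dense activations are the feature vector handed to the
# navigation agent.

# global first-order statistics of the network input, concatenated to the
# conv features: upper quantiles carry the lesion-contrast cue directly
.input_stats <- function(x) {
  as.numeric(stats::quantile(x, c(0.05, 0.1, 0.25, 0.5, 0.75,
                                  0.9, 0.95, 0.99)))
}

cnn_init <- function(input_size, channels = c(8, 16, 16, 32, 32),
                     feature_dim = 4320, n_classes = 5, pool_factor = 1,
                     in_channels = 1, head = "flatten",
                     input_stats = TRUE, seed = 1L) {
  h <- input_size %/% pool_factor
  cin <- in_channels
  conv <- vector("list", length(channels))
  with_seed(seed, {
    for (i in seq_along(channels)) {
      conv[[i]] <- list(W = .he_init(channels[i], cin * 9),
                        b = numeric(channels[i]))
      cin <- channels[i]
      h <- h %/% 2
    }
    flat_dim <- if (head == "gap") cin else h * h * cin
    n_stats <- if (input_stats) 8L else 0L
    flat_dim <- flat_dim + n_stats
    stop_if_not(flat_dim >= 1, "input_size too small for %d conv blocks",
                length(channels))
    fc1 <- list(W = .he_init(feature_dim, flat_dim), b = numeric(feature_dim))
    # near-zero output layer: initial logits ~ 0 so the softmax starts at the
    # uniform distribution instead of a saturated one
    fc2 <- list(W = 0.01 * .he_init(n_classes, feature_dim),
                b = numeric(n_classes))
    structure(list(conv = conv, fc1 = fc1, fc2 = fc2,
                   input_size = input_size, pool_factor = pool_factor,
                   channels = channels, flat_dim = flat_dim,
                   feature_dim = feature_dim, n_classes = n_classes,
                   in_channels = in_channels, head = head,
                   input_stats = input_stats, n_stats = n_stats),
              class = "gradenav_cnn")
  })
}

# xs: list of (H, W) matrices (single channel) at input_size resolution.
cnn_forward <- function(net, xs, keep_cache = FALSE, dropout = 0) {
  B <- length(xs)
  flat <- matrix(0, B, net$flat_dim)
  conv_caches <- if (keep_cache) vector("list", B) else NULL
  for (b in seq_len(B)) {
    x <- xs[[b]]
    if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
    if (net$pool_factor > 1) x <- avgpool_forward(x, net$pool_factor)
    stats_b <- if (isTRUE(net$input_stats)) .input_stats(x) else NULL
    caches_b <- if (keep_cache) vector("list", 2 * length(net$conv)) else NULL
    for (i in seq_along(net$conv)) {
      cf <- conv_forward(x, net$conv[[i]]$W, net$conv[[i]]$b)
      pf <- maxpool_forward(cf$out)
      x <- pf$out
      if (keep_cache) {
        caches_b[[2 * i - 1]] <- cf$cache
        caches_b[[2 * i]] <- pf$cache
      }
    }
    conv_feat <- if (identical(net$head, "gap")) {
      apply(x, 3, mean)              # global average pooling per channel
    } else as.vector(x)
    flat[b, ] <- c(conv_feat, stats_b)
    if (keep_cache) conv_caches[[b]] <- caches_b
  }
  f1 <- dense_forward(flat, net$fc1$W, net$fc1$b, relu = TRUE)
  feats <- f1$out
  drop_mask <- NULL
  if (dropout > 0) {
    # inverted dropout on the feature layer (training only)
    drop_mask <- matrix(stats::runif(length(feats)) >= dropout,
                        nrow(feats), ncol(feats)) / (1 - dropout)
    feats <- feats * drop_mask
  }
  f2 <- dense_forward(feats, net$fc2$W, net$fc2$b, relu = FALSE)
  list(logits = f2$out, features = f1$out,
       caches = if (keep_cache) list(conv = conv_caches, f1 = f1$cache,
                                     f2 = f2$cache,
                                     drop_mask = drop_mask) else NULL)
}

cnn_backward <- function(net, caches, dlogits) {
  g2 <- dense_backward(dlogits, net$fc2$W, caches$f2)
  dfeat <- g2$dX
  if (!is.null(caches$drop_mask)) dfeat <- dfeat * caches$drop_mask
  g1 <- dense_backward(dfeat, net$fc1$W, caches$f1)
  B <- nrow(dlogits)
  nconv <- length(net$conv)
  conv_grads <- lapply(net$conv, function(l)
    list(dW = l$W * 0, db = l$b * 0))
  for (b in seq_len(B)) {
    cb <- caches$conv[[b]]
    # reshape the flat gradient back to the last pooled activation; the
    # input-statistics tail has no parameters below it
    dflat_b <- g1$dX[b, ]
    if (net$n_stats > 0) dflat_b <- dflat_b[seq_len(length(dflat_b) - net$n_stats)]
    last_dims <- dim(cb[[2 * nconv]]$masks[[1]])
    dx <- if (identical(net$head, "gap")) {
      # each channel mean distributes its gradient uniformly over the map
      array(rep(dflat_b, each = prod(last_dims[1:2])) /
              prod(last_dims[1:2]), last_dims)
    } else array(dflat_b, last_dims)
    for (i in rev(seq_len(nconv))) {
      dx <- maxpool_backward(dx, cb[[2 * i]])
      gc_ <- conv_backward(dx, net$conv[[i]]$W, cb[[2 * i - 1]])
      conv_grads[[i]]$dW <- conv_grads[[i]]$dW + gc_$dW
      conv_grads[[i]]$db <- conv_grads[[i]]$db + gc_$db
      dx <- gc_$dx
    }
  }
  list(conv = conv_grads,
       fc1 = list(dW = g1$dW, db = g1$db),
       fc2 = list(dW = g2$dW, db = g2$db))
}

# Data-dependent init calibration (LSUV-style): forward a probe batch and
# rescale each convolution and the feature layer to unit output RMS, so SGD
# sees comparable gradient scales in every layer. The positive-mean ReLU
# chain otherwise inflates activations multiplicatively with depth.
cnn_calibrate <- function(net, xs) {
  probe <- lapply(xs, function(x) {
    if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
    if (net$pool_factor > 1) x <- avgpool_forward(x, net$pool_factor)
    x
  })
  stats_m <- if (isTRUE(net$input_stats)) {
    do.call(rbind, lapply(probe, .input_stats))
  } else NULL
  acts <- probe
  for (i in seq_along(net$conv)) {
    outs <- lapply(acts, function(a)
      conv_forward(a, net$conv[[i]]$W, net$conv[[i]]$b)$out)
    r <- sqrt(mean(unlist(outs)^2))
    if (r > 1e-8) {
      net$conv[[i]]$W <- net$conv[[i]]$W / r
      outs <- lapply(outs, function(o) o / r)
    }
    acts <- lapply(outs, function(o) maxpool_forward(o)$out)
  }
  flat <- if (identical(net$head, "gap")) {
    do.call(rbind, lapply(acts, function(a) apply(a, 3, mean)))
  } else do.call(rbind, lapply(acts, as.vector))
  if (!is.null(stats_m)) flat <- cbind(flat, stats_m)
  f1 <- dense_forward(flat, net$fc1$W, net$fc1$b, relu = TRUE)
  r <- sqrt(mean(f1$out^2))
  if (r > 1e-8) {
    net$fc1$W <- net$fc1$W / r
    f1$out <- f1$out / r
  }
  # output layer to moderate logit scale (rms 0.5): large enough that
  # gradients reach the body from the first step, small enough that the
  # softmax starts near uniform
  f2 <- dense_forward(f1$out, net$fc2$W, net$fc2$b, relu = FALSE)
  r <- sqrt(mean(f2$out^2))
  if (r > 1e-8) net$fc2$W <- net$fc2$W * (0.5 / r)
  net
}

# global-norm gradient clipping: preserves direction, caps step size; the
# first few from-scratch steps otherwise blow up under momentum
cnn_clip_grads <- function(g, max_norm) {
  if (!is.finite(max_norm) || max_norm <= 0) return(g)
  gn <- sqrt(sum(unlist(lapply(g$conv, function(z) sum(z$dW^2) + sum(z$db^2)))) +
               sum(g$fc1$dW^2) + sum(g$fc1$db^2) +
               sum(g$fc2$dW^2) + sum(g$fc2$db^2))
  if (gn > max_norm) {
    sc <- max_norm / gn
    g$conv <- lapply(g$conv, function(z) list(dW = z$dW * sc, db = z$db * sc))
    g$fc1 <- list(dW = g$fc1$dW * sc, db = g$fc1$db * sc)
    g$fc2 <- list(dW = g$fc2$dW * sc, db = g$fc2$db * sc)
  }
  g
}

cnn_sgd_step <- function(net, grads, state, lr, momentum = 0.9,
                         optimizer = "sgd", weight_decay = 0) {
  if (is.null(state)) state <- list(conv = vector("list", length(net$conv)),
                                    fc1 = NULL, fc2 = NULL, t = 0L)
  state$t <- state$t + 1L
  upd <- if (optimizer == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- state$t
    function(p, g, v) {
      if (is.null(v)) v <- list(mW = p$W * 0, vW = p$W * 0,
                                mb = p$b * 0, vb = p$b * 0)
      v$mW <- b1 * v$mW + (1 - b1) * g$dW
      v$vW <- b2 * v$vW + (1 - b2) * g$dW^2
      v$mb <- b1 * v$mb + (1 - b1) * g$db
      v$vb <- b2 * v$vb + (1 - b2) * g$db^2
      corr <- sqrt(1 - b2^t) / (1 - b1^t)
      p$W <- p$W - lr * corr * v$mW / (sqrt(v$vW) + eps) -
        lr * weight_decay * p$W      # decoupled weight decay
      p$b <- p$b - lr * corr * v$mb / (sqrt(v$vb) + eps)
      list(p = p, v = v)
    }
  } else {
    function(p, g, v) {
      if (is.null(v)) v <- list(vW = p$W * 0, vb = p$b * 0)
      v$vW <- momentum * v$vW - lr * (g$dW + weight_decay * p$W)
      v$vb <- momentum * v$vb - lr * g$db
      p$W <- p$W + v$vW
      p$b <- p$b + v$vb
      list(p = p, v = v)
    }
  }
  for (i in seq_along(net$conv)) {
    r <- upd(net$conv[[i]], grads$conv[[i]], state$conv[[i]])
    net$conv[[i]] <- r$p; state$conv[[i]] <- r$v
  }
  r <- upd(net$fc1, grads$fc1, state$fc1); net$fc1 <- r$p; state$fc1 <- r$v
  r <- upd(net$fc2, grads$fc2, state$fc2); net$fc2 <- r$p; state$fc2 <- r$v
  list(net = net, state = state)
}

# Polyak averaging of two networks with identical structure:
# decay * a + (1 - decay) * b
cnn_blend <- function(a, b, decay) {
  for (i in seq_along(a$conv)) {
    a$conv[[i]]$W <- decay * a$conv[[i]]$W + (1 - decay) * b$conv[[i]]$W
    a$conv[[i]]$b <- decay * a$conv[[i]]$b + (1 - decay) * b$conv[[i]]$b
  }
  a$fc1$W <- decay * a$fc1$W + (1 - decay) * b$fc1$W
  a$fc1$b <- decay * a$fc1$b + (1 - decay) * b$fc1$b
  a$fc2$W <- decay * a$fc2$W + (1 - decay) * b$fc2$W
  a$fc2$b <- decay * a$fc2$b + (1 - decay) * b$fc2$b
  a
}
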