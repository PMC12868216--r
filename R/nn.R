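# Compact U-Net implemented directly on top of the compiled conv/pool/
# upsample primitives. Tensor convention: dim(x) = c(H, W, C, N).
#
# Two encoder levels, two decoder levels, nearest-neighbour upsampling and
# channel-concatenated skip connections, 1x1 classification head. Input
# spatial dims must be divisible by 4.

.relu <- function(z) pmax(z, 0)

.cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# layer table: name, kernel, in/out channels, spatial downsampling factor
# relative to the input (used for analytic FLOP counting)
.unet_layer_table <- function(base = 16L, in_channels = 1L,
                              n_classes = 3L) {
  b <- as.integer(base)
  defs <- list(
    list("enc1a", 3L, in_channels, b,      1L),
    list("enc1b", 3L, b,           b,      1L),
    list("enc2a", 3L, b,           2L * b, 2L),
    list("enc2b", 3L, 2L * b,      2L * b, 2L),
    list("bota",  3L, 2L * b,      4L * b, 4L),
    list("botb",  3L, 4L * b,      4L * b, 4L),
    list("dec1a", 3L, 6L * b,      2L * b, 2L),
    list("dec1b", 3L, 2L * b,      2L * b, 2L),
    list("dec2a", 3L, 3L * b,      b,      1L),
    list("dec2b", 3L, b,           b,      1L),
    list("head",  1L, b,           n_classes, 1L)
  )
  do.call(rbind, lapply(defs, function(d) {
    data.frame(name = d[[1]], k = d[[2]], cin = d[[3]], cout = d[[4]],
               downsample = d[[5]], stringsAsFactors = FALSE)
  }))
}

# He-normal initialization; draws from the current R RNG stream so that
# deterministic mode controls weight init through set.seed(). All conv
# layers except the 1x1 head carry batch normalization (gamma/beta
# learnable, rm/rv running statistics used at inference).
.unet_init <- function(base = 16L, in_channels = 1L, n_classes = 3L) {
  tab <- .unet_layer_table(base, in_channels, n_classes)
  params <- list()
  for (i in seq_len(nrow(tab))) {
    k <- tab$k[i]; cin <- tab$cin[i]; cout <- tab$cout[i]
    sd <- sqrt(2 / (k * k * cin))
    l <- list(
      w = array(stats::rnorm(k * k * cin * cout, sd = sd),
                dim = c(k, k, cin, cout)),
      b = numeric(cout)
    )
    if (tab$name[i] != "head") {
      l$gamma <- rep(1, cout)
      l$beta <- numeric(cout)
      l$rm <- numeric(cout)
      l$rv <- rep(1, cout)
    }
    params[[tab$name[i]]] <- l
  }
  params
}

# ---- batch normalization over (H, W, N) per channel ----

.bn_eps <- 1e-5
.bn_momentum <- 0.1

# z: (H, W, C, N). Returns list(y, cache?, rm, rv).
.bn_fwd <- function(z, layer, training, want_cache = FALSE) {
  d <- dim(z)
  zp <- aperm(z, c(1, 2, 4, 3))
  dim(zp) <- c(d[1] * d[2] * d[4], d[3])
  if (training) {
    mu <- colMeans(zp)
    centered <- sweep(zp, 2, mu)
    v <- colMeans(centered^2)
    rm <- (1 - .bn_momentum) * layer$rm + .bn_momentum * mu
    rv <- (1 - .bn_momentum) * layer$rv + .bn_momentum * v
  } else {
    mu <- layer$rm
    v <- layer$rv
    centered <- sweep(zp, 2, mu)
    rm <- layer$rm
    rv <- layer$rv
  }
  invstd <- 1 / sqrt(v + .bn_eps)
  xhat <- sweep(centered, 2, invstd, `*`)
  y <- sweep(sweep(xhat, 2, layer$gamma, `*`), 2, layer$beta, `+`)
  dim(y) <- c(d[1], d[2], d[4], d[3])
  out <- list(y = aperm(y, c(1, 2, 4, 3)), rm = rm, rv = rv)
  if (want_cache) {
    out$cache <- list(xhat = xhat, invstd = invstd, dims = d,
                      training = training)
  }
  out
}

# dy: (H, W, C, N); returns dz plus dgamma/dbeta
.bn_bwd <- function(dy, layer, cache) {
  d <- cache$dims
  dyp <- aperm(dy, c(1, 2, 4, 3))
  dim(dyp) <- c(d[1] * d[2] * d[4], d[3])
  dgamma <- colSums(dyp * cache$xhat)
  dbeta <- colSums(dyp)
  dxhat <- sweep(dyp, 2, layer$gamma, `*`)
  if (cache$training) {
    m <- nrow(dyp)
    dz <- sweep(dxhat -
                  matrix(colMeans(dxhat), m, d[3], byrow = TRUE) -
                  sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`),
                2, cache$invstd, `*`)
  } else {
    dz <- sweep(dxhat, 2, cache$invstd, `*`)
  }
  dim(dz) <- c(d[1], d[2], d[4], d[3])
  list(dz = aperm(dz, c(1, 2, 4, 3)), dgamma = dgamma, dbeta = dbeta)
}

.unet_forward <- function(params, x, want_cache = FALSE,
                          training = FALSE) {
  cache <- if (want_cache) new.env(parent = emptyenv()) else NULL
  conv <- function(name, inp, relu = TRUE) {
    z <- cpp_conv_fwd(inp, params[[name]]$w, params[[name]]$b)
    bn <- NULL
    if (!is.null(params[[name]]$gamma)) {
      bn <- .bn_fwd(z, params[[name]], training, want_cache)
      out <- bn$y
    } else {
      out <- z
    }
    if (want_cache) {
      assign(name, list(x = inp, z = out, bn_cache = bn$cache,
                        rm = bn$rm, rv = bn$rv), envir = cache)
    }
    if (relu) .relu(out) else out
  }
  e1 <- conv("enc1b", conv("enc1a", x))
  p1 <- cpp_maxpool_fwd(e1)
  e2 <- conv("enc2b", conv("enc2a", p1$y))
  p2 <- cpp_maxpool_fwd(e2)
  bb <- conv("botb", conv("bota", p2$y))
  d1 <- conv("dec1b", conv("dec1a", .cat_channels(cpp_upsample_fwd(bb), e2)))
  d2 <- conv("dec2b", conv("dec2a", .cat_channels(cpp_upsample_fwd(d1), e1)))
  logits <- conv("head", d2, relu = FALSE)
  if (want_cache) {
    assign("pool1", p1, envir = cache)
    assign("pool2", p2, envir = cache)
    assign("dim_e1", dim(e1), envir = cache)
    assign("dim_e2", dim(e2), envir = cache)
  }
  list(logits = logits, cache = cache)
}

# backward through one conv (+ its preceding ReLU when relu = TRUE);
# accumulates parameter gradients into `grads`, returns gradient w.r.t.
# the conv input.
.unet_backward <- function(params, cache, dlogits) {
  grads <- list()
  back <- function(name, dout, relu = TRUE) {
    layer <- get(name, envir = cache)
    if (relu) dout <- dout * (layer$z > 0)
    gl <- list()
    if (!is.null(layer$bn_cache)) {
      bb <- .bn_bwd(dout, params[[name]], layer$bn_cache)
      dout <- bb$dz
      gl$gamma <- bb$dgamma
      gl$beta <- bb$dbeta
    }
    g <- cpp_conv_bwd(layer$x, params[[name]]$w, dout)
    gl$w <- g$dw
    gl$b <- g$db
    grads[[name]] <<- gl
    g$dx
  }
  split_skip <- function(dcat, n_up) {
    list(up = dcat[, , seq_len(n_up), , drop = FALSE],
         skip = dcat[, , -seq_len(n_up), , drop = FALSE])
  }
  dd2 <- back("head", dlogits, relu = FALSE)
  dc2 <- back("dec2a", back("dec2b", dd2))
  s2 <- split_skip(dc2, dim(dc2)[3] - get("dim_e1", envir = cache)[3])
  dd1 <- cpp_upsample_bwd(s2$up)
  dc1 <- back("dec1a", back("dec1b", dd1))
  s1 <- split_skip(dc1, dim(dc1)[3] - get("dim_e2", envir = cache)[3])
  dbb <- cpp_upsample_bwd(s1$up)
  dp2 <- back("bota", back("botb", dbb))
  de2 <- cpp_maxpool_bwd(get("pool2", envir = cache)$idx, dp2,
                         get("dim_e2", envir = cache)) + s1$skip
  dp1 <- back("enc2a", back("enc2b", de2))
  de1 <- cpp_maxpool_bwd(get("pool1", envir = cache)$idx, dp1,
                         get("dim_e1", envir = cache)) + s2$skip
  back("enc1a", back("enc1b", de1))
  grads
}

# ---- softmax / one-hot over the channel dimension ----

.softmax_channels <- function(z) {
  d <- dim(z)
  zp <- aperm(z, c(1, 2, 4, 3))
  dim(zp) <- c(d[1] * d[2] * d[4], d[3])
  m <- do.call(pmax, lapply(seq_len(d[3]), function(j) zp[, j]))
  e <- exp(zp - m)
  p <- e / rowSums(e)
  dim(p) <- c(d[1], d[2], d[4], d[3])
  aperm(p, c(1, 2, 4, 3))
}

# labels: (H, W, N) integer array of class codes 0..C-1
.one_hot <- function(labels, n_classes = 3L) {
  d <- dim(labels)
  out <- array(0, c(d[1], d[2], n_classes, d[3]))
  for (c in seq_len(n_classes)) {
    out[, , c, ] <- as.numeric(labels == (c - 1L))
  }
  out
}

#' Soft Jaccard (IoU) loss
#'
#' One minus the mean over classes of the soft Jaccard index
#' `(<p,t> + s) / (sum(p) + sum(t) - <p,t> + s + eps)`, with
#' intersections and unions pooled over the whole batch per class. Zero
#' (up to `eps`) for an exact hard match; one for fully disjoint hard
#' predictions.
#'
#' The defaults `smooth = 0`, `eps = 1e-7` follow the reference
#' segmentation-loss implementations. A positive `smooth` makes batches
#' that lack a class actively push that class's probabilities toward
#' zero (the `(I+s)/(U+s)` term then rewards shrinking the union), which
#' can irreversibly silence rare classes such as pores; with
#' `smooth = 0` an absent class contributes no gradient.
#'
#' @param probs Array `(H, W, C, N)` of class probabilities (each pixel's
#'   class vector sums to 1).
#' @param target One-hot array with the same shape.
#' @param smooth Smoothing constant added to numerator and denominator
#'   (default 0).
#' @param eps Denominator guard (default 1e-7).
#' @return Scalar loss.
#' @export
soft_jaccard_loss <- function(probs, target, smooth = 0, eps = 1e-7) {
  if (!identical(dim(probs), dim(target))) {
    stop("`probs` and `target` must have identical shapes")
  }
  .jaccard_loss_grad(probs, target, smooth, eps, want_grad = FALSE)$loss
}

.jaccard_loss_grad <- function(p, t, smooth = 0, eps = 1e-7,
                               want_grad = TRUE) {
  d <- dim(p)
  C <- d[3]
  loss_terms <- numeric(C)
  grad <- if (want_grad) array(0, d) else NULL
  for (c in seq_len(C)) {
    pc <- p[, , c, , drop = FALSE]
    tc <- t[, , c, , drop = FALSE]
    I <- sum(pc * tc)
    U <- sum(pc) + sum(tc) - I
    den <- U + smooth + eps
    loss_terms[c] <- (I + smooth) / den
    if (want_grad) {
      # d/dp of (I+s)/(U+s+eps):  (t*den - (I+s)*(1-t)) / den^2
      grad[, , c, ] <- -(tc * den - (I + smooth) * (1 - tc)) /
        (den^2 * C)
    }
  }
  list(loss = 1 - mean(loss_terms), grad = grad)
}

# gradient of loss w.r.t. logits given probs = softmax(logits) and
# dL/dprobs
.softmax_backward <- function(p, dp) {
  d <- dim(p)
  pp <- aperm(p, c(1, 2, 4, 3))
  dim(pp) <- c(d[1] * d[2] * d[4], d[3])
  dpp <- aperm(dp, c(1, 2, 4, 3))
  dim(dpp) <- c(d[1] * d[2] * d[4], d[3])
  dz <- pp * (dpp - rowSums(pp * dpp))
  dim(dz) <- c(d[1], d[2], d[4], d[3])
  aperm(dz, c(1, 2, 4, 3))
}

# ---- Adam ----

.trainable_fields <- c("w", "b", "gamma", "beta")

.adam_init <- function(params) {
  lapply(params, function(l) {
    s <- list(t = 0L)
    for (f in intersect(.trainable_fields, names(l))) {
      s[[paste0("m_", f)]] <- array(0, dim(l[[f]]) %||% length(l[[f]]))
      s[[paste0("v_", f)]] <- array(0, dim(l[[f]]) %||% length(l[[f]]))
    }
    s
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  for (name in names(params)) {
    s <- state[[name]]
    g <- grads[[name]]
    s$t <- s$t + 1L
    bc1 <- 1 - beta1^s$t
    bc2 <- 1 - beta2^s$t
    for (f in intersect(.trainable_fields, names(params[[name]]))) {
      m <- beta1 * s[[paste0("m_", f)]] + (1 - beta1) * g[[f]]
      v <- beta2 * s[[paste0("v_", f)]] + (1 - beta2) * g[[f]]^2
      s[[paste0("m_", f)]] <- m
      s[[paste0("v_", f)]] <- v
      # decoupled (AdamW-style) decay applies to conv weights only
      decay <- if (f == "w") (1 - lr * weight_decay) else 1
      params[[name]][[f]] <- params[[name]][[f]] * decay -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
    state[[name]] <- s
  }
  list(params = params, state = state)
}
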