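# Internal numerical engine: im2col convolution, forward/backward pass, Adam.
#
# Weight layout. For a branch with filter height h and out_channels filters,
# W is a (4*h) x out_channels matrix whose column f holds the filter weights
# in offset-major order: entry (j-1)*4 + k is the weight applied to channel k
# (A, T/U, G, C) at offset j within the window. Dense weights are fan_in x
# fan_out. All biases are vectors.

#' Initialize CNN weights
#'
#' Glorot-uniform initialization (limit `sqrt(6 / (fan_in + fan_out))`, with
#' the convolutional fans counting the full receptive field) and zero biases,
#' reproducible from `seed`.
#'
#' @param spec A `cnn_model_spec`.
#' @param seed Integer seed.
#' @return A weight list: `conv` (per branch, `W` and `b`), `W1`, `b1`,
#'   `W2`, `b2`.
#' @export
init_cnn_weights <- function(spec, seed = 1L) {
  withr::with_seed(seed, {
    conv <- lapply(spec$branches, function(br) {
      fan_in <- br$filter_height * br$filter_width * br$in_channels
      fan_out <- br$filter_height * br$filter_width * br$out_channels
      lim <- sqrt(6 / (fan_in + fan_out))
      list(W = matrix(stats::runif(fan_in * br$out_channels, -lim, lim),
                      nrow = fan_in, ncol = br$out_channels),
           b = numeric(br$out_channels))
    })
    nf <- feature_length(spec)
    lim1 <- sqrt(6 / (nf + spec$dense_width))
    lim2 <- sqrt(6 / (spec$dense_width + spec$n_classes))
    list(
      conv = conv,
      W1 = matrix(stats::runif(nf * spec$dense_width, -lim1, lim1),
                  nrow = nf, ncol = spec$dense_width),
      b1 = numeric(spec$dense_width),
      W2 = matrix(stats::runif(spec$dense_width * spec$n_classes,
                               -lim2, lim2),
                  nrow = spec$dense_width, ncol = spec$n_classes),
      b2 = numeric(spec$n_classes)
    )
  })
}

n_weight_values <- function(weights) {
  sum(vapply(weights$conv, function(cw) length(cw$W) + length(cw$b),
             numeric(1))) +
    length(weights$W1) + length(weights$b1) +
    length(weights$W2) + length(weights$b2)
}

# Sliding-window (im2col) view of an encoded matrix for one filter height:
# row p of the result is the flattened h x 4 window starting at position p.
im2col <- function(x, h) {
  P <- nrow(x) - h + 1
  out <- matrix(0, nrow = P, ncol = 4 * h)
  for (j in seq_len(h)) {
    out[, ((j - 1) * 4 + 1):((j - 1) * 4 + 4)] <- x[j:(j + P - 1), ,
                                                    drop = FALSE]
  }
  out
}

# Precompute per-record im2col matrices for every branch height in the spec.
prepare_inputs <- function(spec, x_list) {
  heights <- vapply(spec$branches, function(b) b$filter_height, integer(1))
  for (x in x_list) {
    if (nrow(x) != spec$input_length) {
      stop("encoded input length ", nrow(x), " does not match model input ",
           spec$input_length, call. = FALSE)
    }
  }
  lapply(x_list, function(x) lapply(heights, function(h) im2col(x, h)))
}

# Forward through conv branches + global max pool for a set of prepared
# records. Returns pooled feature matrix (n x nf) and, if requested, the
# argmax bookkeeping needed for backprop.
conv_pool_forward <- function(spec, weights, prepared, keep_argmax = FALSE) {
  n <- length(prepared)
  nb <- length(spec$branches)
  pooled <- matrix(0, nrow = n, ncol = feature_length(spec))
  argmax <- if (keep_argmax) vector("list", n) else NULL
  col0 <- cumsum(c(0, vapply(spec$branches, function(b) b$out_channels,
                             integer(1))))
  for (i in seq_len(n)) {
    if (keep_argmax) argmax[[i]] <- vector("list", nb)
    for (k in seq_len(nb)) {
      cw <- weights$conv[[k]]
      fm <- prepared[[i]][[k]] %*% cw$W
      fm <- fm + rep(cw$b, each = nrow(fm))
      fm[fm < 0] <- 0 # relu
      idx <- max.col(t(fm), ties.method = "first")
      oc <- spec$branches[[k]]$out_channels
      vals <- fm[cbind(idx, seq_len(oc))]
      pooled[i, (col0[k] + 1):(col0[k] + oc)] <- vals
      if (keep_argmax) argmax[[i]][[k]] <- idx
    }
  }
  list(pooled = pooled, argmax = argmax, col0 = col0)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Full forward pass. dropout_mask (n x dense_width, already inverted-scaled)
# is NULL at inference. Returns intermediates for backprop.
nn_forward <- function(spec, weights, prepared, dropout_mask = NULL,
                       keep_argmax = FALSE) {
  cp <- conv_pool_forward(spec, weights, prepared, keep_argmax = keep_argmax)
  z1 <- cp$pooled %*% weights$W1
  z1 <- z1 + rep(weights$b1, each = nrow(z1))
  h1 <- z1
  h1[h1 < 0] <- 0
  hd <- if (is.null(dropout_mask)) h1 else h1 * dropout_mask
  z2 <- hd %*% weights$W2
  z2 <- z2 + rep(weights$b2, each = nrow(z2))
  probs <- softmax_rows(z2)
  list(probs = probs, z1 = z1, h1 = h1, hd = hd, cp = cp)
}

# Mean cross-entropy of a probability matrix against 0/1 class indices
# (1-based column of the true class), with clipping before the log.
mean_nll <- function(probs, y_idx) {
  p <- probs[cbind(seq_len(nrow(probs)), y_idx)]
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(log(p))
}

# Backward pass; returns gradients with the same structure as the weights.
nn_backward <- function(spec, weights, prepared, fwd, y_idx, dropout_mask) {
  n <- nrow(fwd$probs)
  dz2 <- fwd$probs
  dz2[cbind(seq_len(n), y_idx)] <- dz2[cbind(seq_len(n), y_idx)] - 1
  dz2 <- dz2 / n
  gW2 <- crossprod(fwd$hd, dz2)
  gb2 <- colSums(dz2)
  dhd <- tcrossprod(dz2, weights$W2)
  dh1 <- if (is.null(dropout_mask)) dhd else dhd * dropout_mask
  dz1 <- dh1 * (fwd$z1 > 0)
  gW1 <- crossprod(fwd$cp$pooled, dz1)
  gb1 <- colSums(dz1)
  dpool <- tcrossprod(dz1, weights$W1)

  col0 <- fwd$cp$col0
  gconv <- lapply(spec$branches, function(b) {
    list(W = matrix(0, nrow = 4 * b$filter_height, ncol = b$out_channels),
         b = numeric(b$out_channels))
  })
  for (i in seq_len(n)) {
    for (k in seq_along(spec$branches)) {
      oc <- spec$branches[[k]]$out_channels
      g <- dpool[i, (col0[k] + 1):(col0[k] + oc)]
      # relu gate: pooled value 0 means every window response was <= 0
      active <- fwd$cp$pooled[i, (col0[k] + 1):(col0[k] + oc)] > 0
      g <- g * active
      if (any(g != 0)) {
        idx <- fwd$cp$argmax[[i]][[k]]
        M <- prepared[[i]][[k]][idx, , drop = FALSE] # oc x 4h
        gconv[[k]]$W <- gconv[[k]]$W + t(M * g)
        gconv[[k]]$b <- gconv[[k]]$b + g
      }
    }
  }
  list(conv = gconv, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

adam_init <- function(weights) {
  zero_like <- function(w) {
    if (is.list(w)) lapply(w, zero_like) else w * 0
  }
  list(m = zero_like(weights), v = zero_like(weights), t = 0L)
}

adam_step <- function(weights, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(w, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    w <- w - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(w = w, m = m, v = v)
  }
  walk <- function(w, g, m, v) {
    if (is.list(w)) {
      out <- Map(walk, w, g, m, v)
      list(w = lapply(out, `[[`, "w"),
           m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      upd(w, g, m, v)
    }
  }
  out <- walk(weights, grads, state$m, state$v)
  list(weights = out$w, state = list(m = out$m, v = out$v, t = state$t))
}
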