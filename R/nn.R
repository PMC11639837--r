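# Minimal neural-network engine: 1-D/2-D convolutions (same padding,
# stride 1) via im2col matrix products, 2x max pooling, ReLU, dense
# layers, softmax cross-entropy, and Adam. Everything is plain R arrays
# and matrices, seeded through R's RNG, so training is bit-reproducible
# single-threaded. This scale (tens of bands / 64 px scenes, thousands
# of samples) does not justify compiled code.

nn_layer <- function(type, ...) c(list(type = type), list(...))

nn_init_dense <- function(d_in, d_out) {
  list(W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
       b = rep(0, d_out))
}

# Builds parameter tensors for a layer plan. `input_shape` is c(L, C)
# for 1-D streams or c(H, W, C) for 2-D; updated as layers are added.
nn_build <- function(plan, input_shape) {
  layers <- list()
  shape <- input_shape
  for (spec in plan) {
    l <- spec
    if (l$type == "conv1d") {
      k <- l$k %||% 3
      p <- nn_init_dense(k * shape[2], l$channels)
      l$W <- p$W; l$b <- p$b; l$k <- k
      shape <- c(shape[1], l$channels)
    } else if (l$type == "conv2d") {
      k <- l$k %||% 3
      p <- nn_init_dense(k * k * shape[3], l$channels)
      l$W <- p$W; l$b <- p$b; l$k <- k
      shape <- c(shape[1], shape[2], l$channels)
    } else if (l$type == "pool1d") {
      shape <- c(shape[1] %/% 2, shape[2])
    } else if (l$type == "pool2d") {
      shape <- c(shape[1] %/% 2, shape[2] %/% 2, shape[3])
    } else if (l$type == "flatten") {
      shape <- prod(shape)
    } else if (l$type == "dense") {
      p <- nn_init_dense(shape[1], l$units)
      l$W <- p$W; l$b <- p$b
      shape <- l$units
    } else if (l$type != "relu") {
      abort_hsd(sprintf("unknown layer type '%s'", l$type), "hsd_config_error")
    }
    l$out_shape <- shape
    layers[[length(layers) + 1]] <- l
  }
  list(layers = layers, input_shape = input_shape, out_shape = shape)
}

im2col1d <- function(X, k) {
  d <- dim(X); N <- d[1]; L <- d[2]; C <- d[3]
  p <- (k - 1) %/% 2
  Xp <- array(0, dim = c(N, L + 2 * p, C))
  Xp[, p + seq_len(L), ] <- X
  M <- matrix(0, N * L, k * C)
  for (o in seq_len(k)) for (c in seq_len(C))
    M[, (o - 1) * C + c] <- Xp[, o:(o + L - 1), c]
  M
}

col2im1d <- function(dM, k, d) {
  N <- d[1]; L <- d[2]; C <- d[3]
  p <- (k - 1) %/% 2
  dXp <- array(0, dim = c(N, L + 2 * p, C))
  for (o in seq_len(k)) for (c in seq_len(C))
    dXp[, o:(o + L - 1), c] <- dXp[, o:(o + L - 1), c] +
      matrix(dM[, (o - 1) * C + c], N, L)
  dXp[, p + seq_len(L), , drop = FALSE]
}

im2col2d <- function(X, k) {
  d <- dim(X); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  p <- (k - 1) %/% 2
  Xp <- array(0, dim = c(N, H + 2 * p, W + 2 * p, C))
  Xp[, p + seq_len(H), p + seq_len(W), ] <- X
  M <- matrix(0, N * H * W, k * k * C)
  col <- 0
  for (ox in seq_len(k)) for (oy in seq_len(k)) for (c in seq_len(C)) {
    col <- col + 1
    M[, col] <- Xp[, oy:(oy + H - 1), ox:(ox + W - 1), c, drop = FALSE]
  }
  M
}

col2im2d <- function(dM, k, d) {
  N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  p <- (k - 1) %/% 2
  dXp <- array(0, dim = c(N, H + 2 * p, W + 2 * p, C))
  col <- 0
  for (ox in seq_len(k)) for (oy in seq_len(k)) for (c in seq_len(C)) {
    col <- col + 1
    cur <- dXp[, oy:(oy + H - 1), ox:(ox + W - 1), c, drop = FALSE]
    dXp[, oy:(oy + H - 1), ox:(ox + W - 1), c] <-
      cur + array(dM[, col], dim = c(N, H, W, 1))
  }
  dXp[, p + seq_len(H), p + seq_len(W), , drop = FALSE]
}

nn_forward <- function(net, X, keep_cache = TRUE) {
  caches <- vector("list", length(net$layers))
  out <- X
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "conv1d") {
      d <- dim(out)
      M <- im2col1d(out, l$k)
      Y <- sweep(M %*% l$W, 2, l$b, `+`)
      if (keep_cache) caches[[i]] <- list(M = M, d = d)
      out <- array(Y, dim = c(d[1], d[2], ncol(l$W)))
    } else if (l$type == "conv2d") {
      d <- dim(out)
      M <- im2col2d(out, l$k)
      Y <- sweep(M %*% l$W, 2, l$b, `+`)
      if (keep_cache) caches[[i]] <- list(M = M, d = d)
      out <- array(Y, dim = c(d[1], d[2], d[3], ncol(l$W)))
    } else if (l$type == "relu") {
      if (keep_cache) caches[[i]] <- list(mask = out > 0)
      out <- pmax(out, 0)
    } else if (l$type == "pool1d") {
      d <- dim(out); L2 <- d[2] %/% 2
      a <- out[, 2 * seq_len(L2) - 1, , drop = FALSE]
      b <- out[, 2 * seq_len(L2), , drop = FALSE]
      take_a <- a >= b  # ties go to the earlier position
      if (keep_cache) caches[[i]] <- list(take_a = take_a, d = d)
      out <- ifelse(take_a, a, b)
      dim(out) <- c(d[1], L2, d[3])
    } else if (l$type == "pool2d") {
      d <- dim(out); H2 <- d[2] %/% 2; W2 <- d[3] %/% 2
      s <- list(out[, 2 * seq_len(H2) - 1, 2 * seq_len(W2) - 1, , drop = FALSE],
                out[, 2 * seq_len(H2),     2 * seq_len(W2) - 1, , drop = FALSE],
                out[, 2 * seq_len(H2) - 1, 2 * seq_len(W2),     , drop = FALSE],
                out[, 2 * seq_len(H2),     2 * seq_len(W2),     , drop = FALSE])
      mx <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
      sel <- vector("list", 4)
      taken <- array(FALSE, dim = dim(mx))
      for (j in 1:4) {
        sel[[j]] <- (s[[j]] == mx) & !taken
        taken <- taken | sel[[j]]
      }
      if (keep_cache) caches[[i]] <- list(sel = sel, d = d)
      out <- mx
      dim(out) <- c(d[1], H2, W2, d[4])
    } else if (l$type == "flatten") {
      d <- dim(out)
      if (keep_cache) caches[[i]] <- list(d = d)
      # flatten so feature order is (spatial..., channel) row-major per sample
      out <- matrix(out, nrow = d[1])
    } else if (l$type == "dense") {
      if (keep_cache) caches[[i]] <- list(X = out)
      out <- sweep(out %*% l$W, 2, l$b, `+`)
    }
  }
  list(out = out, caches = caches)
}

nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  d <- dout
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]; ca <- caches[[i]]
    if (l$type == "conv1d") {
      dm <- matrix(d, nrow = nrow(ca$M))
      grads[[i]] <- list(W = crossprod(ca$M, dm), b = colSums(dm))
      d <- col2im1d(dm %*% t(l$W), l$k, ca$d)
    } else if (l$type == "conv2d") {
      dm <- matrix(d, nrow = nrow(ca$M))
      grads[[i]] <- list(W = crossprod(ca$M, dm), b = colSums(dm))
      d <- col2im2d(dm %*% t(l$W), l$k, ca$d)
    } else if (l$type == "relu") {
      d <- d * ca$mask
    } else if (l$type == "pool1d") {
      dd <- ca$d; L2 <- dd[2] %/% 2
      dX <- array(0, dim = dd)
      da <- array(d, dim = c(dd[1], L2, dd[3]))
      dX[, 2 * seq_len(L2) - 1, ] <- da * ca$take_a
      dX[, 2 * seq_len(L2), ] <- da * !ca$take_a
      d <- dX
    } else if (l$type == "pool2d") {
      dd <- ca$d; H2 <- dd[2] %/% 2; W2 <- dd[3] %/% 2
      dX <- array(0, dim = dd)
      dm <- array(d, dim = c(dd[1], H2, W2, dd[4]))
      dX[, 2 * seq_len(H2) - 1, 2 * seq_len(W2) - 1, ] <- dm * ca$sel[[1]]
      dX[, 2 * seq_len(H2),     2 * seq_len(W2) - 1, ] <- dm * ca$sel[[2]]
      dX[, 2 * seq_len(H2) - 1, 2 * seq_len(W2),     ] <- dm * ca$sel[[3]]
      dX[, 2 * seq_len(H2),     2 * seq_len(W2),     ] <- dm * ca$sel[[4]]
      d <- dX
    } else if (l$type == "flatten") {
      d <- array(d, dim = ca$d)
    } else if (l$type == "dense") {
      grads[[i]] <- list(W = crossprod(ca$X, d), b = colSums(d))
      d <- d %*% t(l$W)
    }
  }
  list(grads = grads, dX = d)
}

nn_softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Returns list(loss, dlogits) for integer labels in 1..K.
nn_softmax_xent <- function(logits, labels) {
  p <- nn_softmax(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dl <- p
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / n, probs = p)
}

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

nn_adam_init <- function(net) {
  lapply(net$layers, function(l) {
    if (!is.null(l$W)) list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    else NULL
  })
}

nn_adam_step <- function(net, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
    net$layers[[i]]$W <- net$layers[[i]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    net$layers[[i]]$b <- net$layers[[i]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[i]] <- s
  }
  list(net = net, state = state)
}
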