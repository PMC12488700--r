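# Compact feed-forward / 1-D convolutional regression engine.
#
# A small, fully deterministic (seeded) network trainer sufficient for the
# feature-vector regression models this toolkit fits: dense and valid-mode
# 1-D convolution layers, ReLU activations, global average pooling, mean
# squared error loss, Adam updates, mini-batches and early stopping on a
# validation partition with best-weight restoration. Gradients are exact
# backpropagation (checked against finite differences in the test suite).

relu <- function(z) pmax(z, 0)

# He-scaled Gaussian initialization.
init_dense <- function(n_in, n_out) {
  list(type = "dense",
       W = matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

init_conv <- function(k, ch_in, ch_out) {
  fan_in <- k * ch_in
  list(type = "conv", k = k, ch_in = ch_in, ch_out = ch_out,
       W = matrix(stats::rnorm(fan_in * ch_out, 0, sqrt(2 / fan_in)),
                  fan_in, ch_out),
       b = numeric(ch_out))
}

# im2col for valid-mode 1-D convolution. a: array (n, len, ch_in).
# Returns matrix (n * len_out) x (k * ch_in); rows ordered sample-fastest
# within each output position block.
conv_im2col <- function(a, k) {
  n <- dim(a)[1]; len <- dim(a)[2]; ch <- dim(a)[3]
  len_out <- len - k + 1L
  M <- matrix(0, n * len_out, k * ch)
  for (dk in seq_len(k)) {
    slab <- a[, dk:(dk + len_out - 1L), , drop = FALSE]
    M[, (seq_len(ch) - 1L) * k + dk] <- matrix(slab, n * len_out, ch)
  }
  M
}

net_forward <- function(layers, x, keep_cache = FALSE) {
  n <- nrow(x)
  act <- x                   # matrix for dense stages, 3-D array for conv
  cache <- list()
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    if (l$type == "conv") {
      if (is.matrix(act)) act <- array(act, c(nrow(act), ncol(act), 1L))
      M <- conv_im2col(act, l$k)
      z <- sweep(M %*% l$W, 2, l$b, "+")
      len_out <- dim(act)[2] - l$k + 1L
      out <- array(z, c(n, len_out, l$ch_out))
      if (keep_cache) cache[[li]] <- list(M = M, z = z, in_dim = dim(act))
      act <- relu(out)
    } else if (l$type == "gap") {
      # global average pool (n, len, ch) -> (n, ch)
      if (keep_cache) cache[[li]] <- list(in_dim = dim(act))
      act <- apply(act, c(1, 3), mean)
      if (!is.matrix(act)) act <- matrix(act, n)
    } else if (l$type == "dense") {
      if (!is.matrix(act)) act <- matrix(act, n)
      z <- sweep(act %*% l$W, 2, l$b, "+")
      if (keep_cache) cache[[li]] <- list(a_in = act, z = z)
      act <- if (li == length(layers)) z else relu(z)   # linear output layer
    }
  }
  list(out = act, cache = cache)
}

# Backprop of the MSE loss 0.5 * mean((out - y)^2); returns per-layer
# gradients aligned with `layers`.
net_backward <- function(layers, x, y, fwd) {
  n <- nrow(x)
  grads <- vector("list", length(layers))
  delta <- (fwd$out - y) / n           # (n x 1) for regression
  for (li in rev(seq_along(layers))) {
    l <- layers[[li]]
    cc <- fwd$cache[[li]]
    if (l$type == "dense") {
      if (li < length(layers)) delta <- delta * (cc$z > 0)
      grads[[li]] <- list(W = crossprod(cc$a_in, delta), b = colSums(delta))
      delta <- delta %*% t(l$W)
    } else if (l$type == "gap") {
      din <- cc$in_dim                 # (n, len, ch)
      delta <- array(rep(delta / din[2], each = 1), c(din[1], din[3]))
      delta <- aperm(array(delta, c(din[1], din[3], din[2])), c(1, 3, 2))
    } else if (l$type == "conv") {
      # delta arrives as array (n, len_out, ch_out)
      dz <- matrix(delta, prod(dim(delta)[1:2]), dim(delta)[3]) * (cc$z > 0)
      grads[[li]] <- list(W = crossprod(cc$M, dz), b = colSums(dz))
      dM <- dz %*% t(l$W)
      din <- cc$in_dim
      len_out <- din[2] - l$k + 1L
      dA <- array(0, din)
      for (dk in seq_len(l$k)) {
        dA[, dk:(dk + len_out - 1L), ] <-
          dA[, dk:(dk + len_out - 1L), , drop = FALSE] +
          array(dM[, (seq_len(din[3]) - 1L) * l$k + dk], c(din[1], len_out, din[3]))
      }
      delta <- dA
    }
  }
  grads
}

# Adam step; state holds first/second moments per parameter tensor.
adam_step <- function(layers, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (li in seq_along(layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    for (nm in c("W", "b")) {
      key <- paste0(li, nm)
      if (is.null(state[[key]])) {
        state[[key]] <- list(m = g[[nm]] * 0, v = g[[nm]] * 0)
      }
      st <- state[[key]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[nm]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[nm]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[li]][[nm]] <- layers[[li]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[key]] <- st
    }
  }
  list(layers = layers, state = state)
}

# Build the layer stack for a given architecture.
net_build <- function(arch, n_in) {
  layers <- list()
  if (identical(arch$kind, "cnn")) {
    # two valid-mode convs need n_in - 2(k - 1) >= 1
    k <- max(1L, min(arch$kernel, (n_in + 1L) %/% 2L))
    layers <- c(layers, list(init_conv(k, 1L, arch$channels[1])))
    len <- n_in - k + 1L
    layers <- c(layers, list(init_conv(k, arch$channels[1], arch$channels[2])))
    len <- len - k + 1L
    layers <- c(layers, list(list(type = "gap")))
    n_flat <- arch$channels[2]
  } else {
    n_flat <- n_in
  }
  for (h in arch$hidden) {
    layers <- c(layers, list(init_dense(n_flat, h)))
    n_flat <- h
  }
  c(layers, list(init_dense(n_flat, 1L)))
}

# Train a network on standardized inputs with early stopping.
# x/y are already normalized by the caller.
net_train <- function(x_train, y_train, x_val, y_val, arch,
                      epochs = 500L, lr = 1e-3, batch_size = 32L,
                      patience = 30L, seed = 1L) {
  n <- nrow(x_train)
  with_seed(seed, {
    layers <- net_build(arch, ncol(x_train))
    state <- list()
    best <- list(loss = Inf, layers = layers)
    wait <- 0L
    step <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        if (length(idx) < 2L) next
        xb <- x_train[idx, , drop = FALSE]
        yb <- matrix(y_train[idx], ncol = 1)
        fwd <- net_forward(layers, xb, keep_cache = TRUE)
        grads <- net_backward(layers, xb, yb, fwd)
        step <- step + 1L
        upd <- adam_step(layers, grads, state, lr, step)
        layers <- upd$layers
        state <- upd$state
      }
      val_pred <- net_forward(layers, x_val)$out
      val_loss <- mean((val_pred - y_val)^2)
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, layers = layers)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    best
  })
}

net_predict <- function(layers, x) as.vector(net_forward(layers, x)$out)
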