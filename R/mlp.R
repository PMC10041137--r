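# Minimal seeded multi-layer perceptron with sigmoid outputs and weighted
# binary cross-entropy, trained with Adam. All randomness (initialization,
# validation split, batch order) flows from the caller's RNG state, so a
# single set.seed() upstream makes training bit-reproducible.

mlp_init <- function(layer_sizes) {
  L <- length(layer_sizes) - 1
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- layer_sizes[l]
    W[[l]] <- matrix(stats::rnorm(fan_in * layer_sizes[l + 1], sd = sqrt(2 / fan_in)),
                     nrow = fan_in)
    b[[l]] <- rep(0, layer_sizes[l + 1])
  }
  list(W = W, b = b, layer_sizes = layer_sizes)
}

# Forward pass; returns output probabilities and, optionally, hidden
# activations for backprop. ReLU hidden units, sigmoid output.
mlp_forward <- function(params, X, keep = FALSE) {
  L <- length(params$W)
  A <- X
  acts <- if (keep) vector("list", L + 1) else NULL
  if (keep) acts[[1]] <- A
  for (l in seq_len(L)) {
    Z <- sweep(A %*% params$W[[l]], 2, params$b[[l]], "+")
    A <- if (l < L) pmax(Z, 0) else 1 / (1 + exp(-Z))
    if (keep) acts[[l + 1]] <- A
  }
  if (keep) list(out = A, acts = acts) else A
}

# Mean weighted BCE; pos_weight is a per-output vector applied to the
# positive term (class-imbalance correction). An optional 0/1 mask marks
# cells whose label is unknown (excluded from loss and gradient).
mlp_loss <- function(P, Y, pos_weight, mask = NULL) {
  eps <- 1e-12
  Pc <- pmin(pmax(P, eps), 1 - eps)
  pw <- matrix(pos_weight, nrow(Y), ncol(Y), byrow = TRUE)
  cell <- pw * Y * log(Pc) + (1 - Y) * log(1 - Pc)
  if (!is.null(mask)) cell <- cell * mask
  -mean(cell)
}

mlp_train <- function(X, Y, hidden, pos_weight = rep(1, ncol(Y)),
                      lr = 1e-3, batch_size = 64L, epochs = 100L,
                      patience = 15L, val_fraction = 0.1, mask = NULL,
                      weight_decay = 0, restore_best = TRUE, verbose = FALSE) {
  n <- nrow(X)
  layer_sizes <- c(ncol(X), hidden, ncol(Y))
  params <- mlp_init(layer_sizes)
  L <- length(params$W)

  n_val <- max(1L, floor(val_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xt <- X[tr_idx, , drop = FALSE]; Yt <- Y[tr_idx, , drop = FALSE]
  Xv <- X[val_idx, , drop = FALSE]; Yv <- Y[val_idx, , drop = FALSE]
  Mt <- if (is.null(mask)) NULL else mask[tr_idx, , drop = FALSE]
  Mv <- if (is.null(mask)) NULL else mask[val_idx, , drop = FALSE]

  adam <- list(mW = lapply(params$W, function(w) w * 0),
               vW = lapply(params$W, function(w) w * 0),
               mb = lapply(params$b, function(bb) bb * 0),
               vb = lapply(params$b, function(bb) bb * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0

  best <- list(loss = Inf, params = params, epoch = 0L)
  stale <- 0L
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(nrow(Xt))
    starts <- seq(1, nrow(Xt), by = batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1, nrow(Xt))]
      Xb <- Xt[idx, , drop = FALSE]; Yb <- Yt[idx, , drop = FALSE]
      fw <- mlp_forward(params, Xb, keep = TRUE)
      P <- fw$out
      pw <- matrix(pos_weight, nrow(Yb), ncol(Yb), byrow = TRUE)
      # d(loss)/d(logit) for weighted BCE with sigmoid output
      G <- ((1 - Yb) * P - pw * Yb * (1 - P)) / nrow(Yb)
      if (!is.null(Mt)) G <- G * Mt[idx, , drop = FALSE]
      t <- t + 1
      for (l in rev(seq_len(L))) {
        A_prev <- fw$acts[[l]]
        gW <- crossprod(A_prev, G)
        gb <- colSums(G)
        if (l > 1) {
          G <- tcrossprod(G, params$W[[l]])
          G <- G * (fw$acts[[l]] > 0)   # ReLU mask of layer l's activation
        }
        adam$mW[[l]] <- beta1 * adam$mW[[l]] + (1 - beta1) * gW
        adam$vW[[l]] <- beta2 * adam$vW[[l]] + (1 - beta2) * gW^2
        adam$mb[[l]] <- beta1 * adam$mb[[l]] + (1 - beta1) * gb
        adam$vb[[l]] <- beta2 * adam$vb[[l]] + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
        # decoupled (AdamW-style) weight decay, applied to weights only
        if (weight_decay > 0) params$W[[l]] <- params$W[[l]] * (1 - lr * weight_decay)
        params$W[[l]] <- params$W[[l]] - lr * (adam$mW[[l]] / corr1) /
          (sqrt(adam$vW[[l]] / corr2) + eps)
        params$b[[l]] <- params$b[[l]] - lr * (adam$mb[[l]] / corr1) /
          (sqrt(adam$vb[[l]] / corr2) + eps)
      }
    }
    vloss <- mlp_loss(mlp_forward(params, Xv), Yv, pos_weight, Mv)
    if (verbose) message(sprintf("epoch %d: val loss %.5f", epoch, vloss))
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, params = params, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  final <- if (restore_best) best$params else params
  list(params = final, val_loss = best$loss, best_epoch = best$epoch,
       layer_sizes = layer_sizes)
}
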