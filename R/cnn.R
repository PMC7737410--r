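# Compact convolutional network for direction classification, implemented
# directly on matrix primitives (im2col): one 3x3 convolution with 32
# filters and ReLU over the channels x 25 trial image, 2x2 max pooling, a
# 64-unit dense ReLU layer, and softmax over the 8 directions; trained with
# Adam, cross-entropy loss, and early stopping on a held-out validation
# split of the training data.

#' CNN training configuration
#'
#' @param kernel Convolution kernel size (default 3).
#' @param n_filters Number of convolution filters (default 32).
#' @param folds Cross-validation folds (default 5).
#' @param epochs Maximum training epochs (default 30).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param hidden Dense hidden units (default 64).
#' @param val_fraction Fraction of training trials held out for early
#'   stopping (default 0.1).
#' @param patience Epochs without validation improvement before stopping
#'   (default 6).
#' @param seed Integer seed controlling initialization, minibatch order and
#'   fold splits.
#' @return List of class `cnn_config`.
#' @export
cnn_config <- function(kernel = 3, n_filters = 32, folds = 5, epochs = 30,
                       batch_size = 32, learning_rate = 1e-3, hidden = 64,
                       val_fraction = 0.1, patience = 6, seed = 1) {
  stopifnot(folds >= 2)
  structure(list(kernel = kernel, n_filters = n_filters, folds = folds,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, hidden = hidden,
                 val_fraction = val_fraction, patience = patience,
                 seed = as.integer(seed)),
            class = "cnn_config")
}

# Geometry and gather indices for im2col convolution + 2x2 pooling over a
# C x T image (column-major flattening: (r, c) -> (c - 1) * C + r).
cnn_geometry <- function(C, T_, k, n_filters) {
  if (C < k || T_ < k) stop("input image smaller than the convolution kernel")
  Hc <- C - k + 1; Wc <- T_ - k + 1
  P <- Hc * Wc
  # patch index matrix: P x k^2, entry = flat index of kernel tap
  idx <- matrix(0L, P, k * k)
  p <- 1
  for (cc in seq_len(Wc)) {
    for (rr in seq_len(Hc)) {
      tap <- 1
      for (dc in 0:(k - 1)) {
        for (dr in 0:(k - 1)) {
          idx[p, tap] <- (cc + dc - 1L) * C + (rr + dr)
          tap <- tap + 1
        }
      }
      p <- p + 1
    }
  }
  # 2x2 max pooling, degrading to 1x2 / 2x1 when a feature-map dimension
  # has a single position (small synergy-count inputs)
  ph <- if (Hc >= 2) 2L else 1L
  pw <- if (Wc >= 2) 2L else 1L
  Hp <- Hc %/% ph; Wp <- Wc %/% pw
  Q <- Hp * Wp
  ntaps <- ph * pw
  pool <- matrix(0L, Q, ntaps)
  q <- 1
  for (cc in seq_len(Wp)) {
    for (rr in seq_len(Hp)) {
      r0 <- ph * (rr - 1) + 1; c0 <- pw * (cc - 1) + 1
      tap <- 1
      for (dc in 0:(pw - 1)) {
        for (dr in 0:(ph - 1)) {
          pool[q, tap] <- (c0 + dc - 1L) * Hc + (r0 + dr)
          tap <- tap + 1
        }
      }
      q <- q + 1
    }
  }
  list(C = C, T_ = T_, k = k, P = P, Q = Q, idx = idx, pool = pool,
       ntaps = ntaps, n_feat = Q * n_filters)
}

cnn_init <- function(geom, n_filters, hidden, n_classes, seed) {
  with_seed(seed, {
    k2 <- geom$k^2
    list(
      Wc = matrix(stats::rnorm(k2 * n_filters, sd = sqrt(2 / k2)), k2),
      bc = rep(0, n_filters),
      W1 = matrix(stats::rnorm(geom$n_feat * hidden,
                               sd = sqrt(2 / geom$n_feat)), geom$n_feat),
      b1 = rep(0, hidden),
      W2 = matrix(stats::rnorm(hidden * n_classes, sd = sqrt(2 / hidden)),
                  hidden),
      b2 = rep(0, n_classes)
    )
  })
}

# Forward pass on a batch. Xb: B x (C*T_) flattened images. Returns the
# cached intermediates needed for backprop when `cache = TRUE`.
cnn_forward <- function(Xb, par, geom, n_filters, cache = FALSE) {
  B <- nrow(Xb)
  Pm <- matrix(0, B * geom$P, geom$k^2)
  for (tap in seq_len(geom$k^2)) {
    Pm[, tap] <- as.vector(Xb[, geom$idx[, tap]])
  }
  Conv <- Pm %*% par$Wc + rep(par$bc, each = B * geom$P)
  relu_mask <- Conv > 0
  Conv[!relu_mask] <- 0
  # 2x2 max pooling over non-overlapping cells
  gather <- lapply(seq_len(geom$ntaps), function(j) {
    rep((geom$pool[, j] - 1L) * B, each = B) + seq_len(B)
  })
  Pool <- Conv[gather[[1]], , drop = FALSE]
  argj <- matrix(1L, nrow(Pool), ncol(Pool))
  if (geom$ntaps > 1) {
    for (j in 2:geom$ntaps) {
      Cj <- Conv[gather[[j]], , drop = FALSE]
      upd <- Cj > Pool
      Pool[upd] <- Cj[upd]
      argj[upd] <- j
    }
  }
  Flat <- matrix(array(Pool, c(B, geom$Q, n_filters)), B, geom$n_feat)
  H1 <- Flat %*% par$W1 + rep(par$b1, each = B)
  h1_mask <- H1 > 0
  H1[!h1_mask] <- 0
  logits <- H1 %*% par$W2 + rep(par$b2, each = B)
  logits <- logits - apply(logits, 1, max)
  expz <- exp(logits)
  probs <- expz / rowSums(expz)
  out <- list(probs = probs)
  if (cache) {
    out <- c(out, list(Pm = Pm, relu_mask = relu_mask, gather = gather,
                       argj = argj, Flat = Flat, H1 = H1, h1_mask = h1_mask,
                       B = B))
  }
  out
}

cnn_backward <- function(fw, y_onehot, par, geom, n_filters) {
  B <- fw$B
  dlog <- (fw$probs - y_onehot) / B
  dW2 <- crossprod(fw$H1, dlog)
  db2 <- colSums(dlog)
  dH1 <- dlog %*% t(par$W2)
  dH1[!fw$h1_mask] <- 0
  dW1 <- crossprod(fw$Flat, dH1)
  db1 <- colSums(dH1)
  dFlat <- dH1 %*% t(par$W1)
  dPool <- matrix(array(dFlat, c(B, geom$Q, n_filters)),
                  B * geom$Q, n_filters)
  dConv <- matrix(0, B * geom$P, n_filters)
  for (j in seq_len(geom$ntaps)) {
    Mj <- dPool * (fw$argj == j)
    dConv[fw$gather[[j]], ] <- dConv[fw$gather[[j]], , drop = FALSE] + Mj
  }
  dConv[!fw$relu_mask] <- 0
  dWc <- crossprod(fw$Pm, dConv)
  dbc <- colSums(dConv)
  list(Wc = dWc, bc = dbc, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

adam_step <- function(par, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

#' Train the compact CNN on trial images
#'
#' @param X Trials x channels x time array (standardized by the caller).
#' @param y Integer class labels (1..n_classes).
#' @param config A [cnn_config()].
#' @param n_classes Number of classes (default 8).
#' @return Fitted model list (`par`, `geom`, `n_filters`) usable with
#'   [cnn_predict()].
#' @export
cnn_train <- function(X, y, config = cnn_config(), n_classes = 8) {
  stopifnot(length(dim(X)) == 3, dim(X)[1] == length(y))
  B_all <- dim(X)[1]; C <- dim(X)[2]; T_ <- dim(X)[3]
  geom <- cnn_geometry(C, T_, config$kernel, config$n_filters)
  Xmat <- matrix(X, B_all, C * T_)  # column-major (channel fastest) flatten
  epochs <- config$epochs
  if (min(table(y)) < 20 && B_all / n_classes < 20) {
    warning("fewer than 20 trials per class: epochs capped at 20")
    epochs <- min(epochs, 20)
  }
  split <- with_seed(config$seed, {
    nv <- max(n_classes, round(config$val_fraction * B_all))
    val <- sample(B_all, nv)
    list(val = val, tr = setdiff(seq_len(B_all), val))
  })
  Xtr <- Xmat[split$tr, , drop = FALSE]; ytr <- y[split$tr]
  Xval <- Xmat[split$val, , drop = FALSE]; yval <- y[split$val]
  par <- cnn_init(geom, config$n_filters, config$hidden, n_classes,
                  config$seed)
  state <- list(m = lapply(par, function(p) p * 0),
                v = lapply(par, function(p) p * 0))
  onehot <- function(yy) {
    Y <- matrix(0, length(yy), n_classes)
    Y[cbind(seq_along(yy), yy)] <- 1
    Y
  }
  best <- list(loss = Inf, par = par, stale = 0)
  t_step <- 0
  for (ep in seq_len(epochs)) {
    ord <- with_seed(config$seed + 1000L + ep, sample(length(ytr)))
    for (b0 in seq(1, length(ord), by = config$batch_size)) {
      bi <- ord[b0:min(b0 + config$batch_size - 1, length(ord))]
      fw <- cnn_forward(Xtr[bi, , drop = FALSE], par, geom,
                        config$n_filters, cache = TRUE)
      gr <- cnn_backward(fw, onehot(ytr[bi]), par, geom, config$n_filters)
      t_step <- t_step + 1
      up <- adam_step(par, gr, state, config$learning_rate, t_step)
      par <- up$par; state <- up$state
    }
    pv <- cnn_forward(Xval, par, geom, config$n_filters)$probs
    vloss <- -mean(log(pmax(pv[cbind(seq_along(yval), yval)], 1e-12)))
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, par = par, stale = 0)
    } else {
      best$stale <- best$stale + 1
      if (best$stale >= config$patience) break
    }
  }
  list(par = best$par, geom = geom, n_filters = config$n_filters,
       n_classes = n_classes, val_loss = best$loss)
}

#' Predict classes with a fitted CNN
#'
#' @param model Fit from [cnn_train()].
#' @param X Trials x channels x time array.
#' @return Integer predicted classes.
#' @export
cnn_predict <- function(model, X) {
  Xmat <- matrix(X, dim(X)[1], dim(X)[2] * dim(X)[3])
  out <- integer(nrow(Xmat))
  for (b0 in seq(1, nrow(Xmat), by = 256)) {
    bi <- b0:min(b0 + 255, nrow(Xmat))
    p <- cnn_forward(Xmat[bi, , drop = FALSE], model$par, model$geom,
                     model$n_filters)$probs
    out[bi] <- max.col(p, ties.method = "first")
  }
  out
}
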