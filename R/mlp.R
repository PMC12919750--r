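# Multilayer-perceptron internals: dense layers with batch normalization
# (dense -> batch-norm -> ReLU -> dropout), softmax output, categorical
# cross-entropy with L2 weight penalty, Adam optimizer, mini-batch training
# with early stopping on validation loss and best-weight restoration.
#
# Written in plain R matrix code; the network sizes involved (15 inputs,
# three 64-unit hidden layers, 3 outputs) make BLAS-backed matrix products
# fast enough that no compiled code is needed.

#' Network hyperparameter specification
#'
#' Defaults mirror the kiosk's triage network: three hidden layers of 64
#' rectified-linear units with batch normalization and dropout 0.3, a
#' three-unit softmax output, Adam (learning rate 0.001), categorical
#' cross-entropy with L2 penalty, early stopping on validation loss with
#' patience 10 within a 100-epoch budget.
#'
#' @param hidden integer vector of hidden-layer sizes.
#' @param batch_norm apply batch normalization after each hidden dense layer.
#' @param dropout_rate dropout probability in \[0, 1).
#' @param l2_lambda L2 penalty weight on dense-layer weights.
#' @param learning_rate Adam step size (> 0).
#' @param max_epochs epoch budget.
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping.
#' @param batch_size mini-batch size.
#' @param lr_reduce_factor multiplier applied to the learning rate when the
#'   validation loss has not improved for `lr_reduce_patience` epochs
#'   (plateau schedule; set to 1 to disable).
#' @param lr_reduce_patience plateau length in epochs before reducing.
#' @param seed integer seed for weight initialization, shuffling and dropout.
#' @return list of class `"mlp_spec"`.
#' @export
mlp_spec <- function(hidden = c(64, 64, 64), batch_norm = TRUE,
                     dropout_rate = 0.3, l2_lambda = 1e-4,
                     learning_rate = 0.001, max_epochs = 100,
                     early_stop_patience = 10, batch_size = 32,
                     lr_reduce_factor = 0.5, lr_reduce_patience = 4,
                     seed = 42) {
  stopifnot(all(hidden > 0), dropout_rate >= 0, dropout_rate < 1,
            learning_rate > 0, max_epochs >= 1, batch_size >= 1,
            lr_reduce_factor > 0, lr_reduce_factor <= 1)
  structure(list(hidden = as.integer(hidden), batch_norm = isTRUE(batch_norm),
                 dropout_rate = dropout_rate, l2_lambda = l2_lambda,
                 learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 batch_size = as.integer(batch_size),
                 lr_reduce_factor = lr_reduce_factor,
                 lr_reduce_patience = as.integer(lr_reduce_patience),
                 seed = as.integer(seed)),
            class = "mlp_spec")
}

.bn_eps <- 1e-5
.bn_momentum <- 0.9

# He-normal initialization; one parameter list per layer.
.mlp_init <- function(input_dim, hidden, output_dim, batch_norm) {
  dims <- c(input_dim, hidden, output_dim)
  layers <- vector("list", length(dims) - 1)
  for (l in seq_along(layers)) {
    fan_in <- dims[l]
    W <- matrix(stats::rnorm(fan_in * dims[l + 1], 0, sqrt(2 / fan_in)),
                fan_in, dims[l + 1])
    b <- numeric(dims[l + 1])
    layer <- list(W = W, b = b)
    if (batch_norm && l < length(layers)) {
      layer$gamma <- rep(1, dims[l + 1])
      layer$beta <- numeric(dims[l + 1])
      layer$run_mean <- numeric(dims[l + 1])
      layer$run_var <- rep(1, dims[l + 1])
    }
    layers[[l]] <- layer
  }
  layers
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass. training=TRUE uses batch statistics, samples dropout masks
# and returns the caches needed for backprop (and updated running stats).
.mlp_forward <- function(layers, x, spec, training = FALSE) {
  n_hidden <- length(layers) - 1
  caches <- vector("list", n_hidden)
  h <- x
  for (l in seq_len(n_hidden)) {
    ly <- layers[[l]]
    z <- sweep(h %*% ly$W, 2, ly$b, `+`)
    if (spec$batch_norm) {
      if (training) {
        mu <- colMeans(z)
        zc <- sweep(z, 2, mu)
        v <- colMeans(zc * zc)        # biased (MLE) batch variance
        inv_sd <- 1 / sqrt(v + .bn_eps)
        zhat <- sweep(zc, 2, inv_sd, `*`)
        layers[[l]]$run_mean <- .bn_momentum * ly$run_mean + (1 - .bn_momentum) * mu
        layers[[l]]$run_var <- .bn_momentum * ly$run_var + (1 - .bn_momentum) * v
      } else {
        inv_sd <- 1 / sqrt(ly$run_var + .bn_eps)
        zhat <- sweep(sweep(z, 2, ly$run_mean), 2, inv_sd, `*`)
      }
      a_pre <- sweep(sweep(zhat, 2, ly$gamma, `*`), 2, ly$beta, `+`)
    } else {
      zhat <- NULL; inv_sd <- NULL
      a_pre <- z
    }
    a <- pmax(a_pre, 0)
    if (training && spec$dropout_rate > 0) {
      mask <- matrix(stats::runif(length(a)) >= spec$dropout_rate,
                     nrow(a), ncol(a)) / (1 - spec$dropout_rate)
      a_drop <- a * mask
    } else {
      mask <- NULL
      a_drop <- a
    }
    caches[[l]] <- list(input = h, zhat = zhat, inv_sd = inv_sd,
                        a_pre = a_pre, mask = mask)
    h <- a_drop
  }
  out <- layers[[length(layers)]]
  logits <- sweep(h %*% out$W, 2, out$b, `+`)
  list(probs = .softmax(logits), hidden_out = h, caches = caches,
       layers = layers)
}

# Backward pass; y is the one-hot matrix. Returns per-layer gradients.
.mlp_backward <- function(layers, fwd, y, spec) {
  n <- nrow(y)
  n_hidden <- length(layers) - 1
  grads <- vector("list", length(layers))
  delta <- (fwd$probs - y) / n
  out <- layers[[length(layers)]]
  grads[[length(layers)]] <- list(
    W = crossprod(fwd$hidden_out, delta) + 2 * spec$l2_lambda * out$W,
    b = colSums(delta))
  dh <- tcrossprod(delta, out$W)  # gradient wrt dropped activation
  for (l in rev(seq_len(n_hidden))) {
    ly <- layers[[l]]
    ca <- fwd$caches[[l]]
    if (!is.null(ca$mask)) dh <- dh * ca$mask
    da <- dh * (ca$a_pre > 0)
    if (spec$batch_norm) {
      dgamma <- colSums(da * ca$zhat)
      dbeta <- colSums(da)
      dzhat <- sweep(da, 2, ly$gamma, `*`)
      # batch-norm backward (means over the batch):
      # dz = inv_sd * (dzhat - mean(dzhat) - zhat * mean(dzhat * zhat))
      m1 <- colMeans(dzhat)
      m2 <- colMeans(dzhat * ca$zhat)
      dz <- sweep(dzhat, 2, m1) - sweep(ca$zhat, 2, m2, `*`)
      dz <- sweep(dz, 2, ca$inv_sd, `*`)
      grads[[l]] <- list(W = crossprod(ca$input, dz) + 2 * spec$l2_lambda * ly$W,
                         b = colSums(dz), gamma = dgamma, beta = dbeta)
    } else {
      dz <- da
      grads[[l]] <- list(W = crossprod(ca$input, dz) + 2 * spec$l2_lambda * ly$W,
                         b = colSums(dz))
    }
    if (l > 1) dh <- tcrossprod(dz, ly$W)
  }
  grads
}

.adam_init <- function(layers) {
  lapply(layers, function(ly) {
    params <- intersect(names(ly), c("W", "b", "gamma", "beta"))
    stats::setNames(lapply(params, function(p)
      list(m = ly[[p]] * 0, v = ly[[p]] * 0)), params)
  })
}

.adam_step <- function(layers, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  for (l in seq_along(layers)) {
    for (p in names(state[[l]])) {
      g <- grads[[l]][[p]]
      st <- state[[l]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      state[[l]][[p]] <- st
      layers[[l]][[p]] <- layers[[l]][[p]] -
        lr * (st$m / corr1) / (sqrt(st$v / corr2) + eps)
    }
  }
  list(layers = layers, state = state)
}

.ce_loss <- function(probs, y, layers, l2_lambda) {
  ce <- -mean(log(pmax(rowSums(probs * y), 1e-12)))
  l2 <- l2_lambda * sum(vapply(layers, function(ly) sum(ly$W^2), 0))
  ce + l2
}

# Core training loop on already-encoded matrices.
# x: n x p matrix; y_idx: integer class index 1..k.
.mlp_fit <- function(x, y_idx, k, spec, x_val = NULL, y_val_idx = NULL) {
  onehot <- function(idx) {
    m <- matrix(0, length(idx), k)
    m[cbind(seq_along(idx), idx)] <- 1
    m
  }
  y <- onehot(y_idx)
  y_val <- if (!is.null(y_val_idx)) onehot(y_val_idx)
  n <- nrow(x)
  layers <- .mlp_init(ncol(x), spec$hidden, k, spec$batch_norm)
  state <- .adam_init(layers)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_acc = numeric(0), val_loss = numeric(0),
                        val_acc = numeric(0))
  best <- list(loss = Inf, layers = layers, epoch = 0)
  wait <- 0
  lr_wait <- 0
  lr <- spec$learning_rate
  t <- 0
  n_batches <- ceiling(n / spec$batch_size)
  for (epoch in seq_len(spec$max_epochs)) {
    ord <- sample.int(n)
    for (bi in seq_len(n_batches)) {
      idx <- ord[((bi - 1) * spec$batch_size + 1):min(bi * spec$batch_size, n)]
      if (length(idx) < 2 && spec$batch_norm) next  # batch stats undefined
      fwd <- .mlp_forward(layers, x[idx, , drop = FALSE], spec, training = TRUE)
      layers <- fwd$layers  # running stats updated
      grads <- .mlp_backward(layers, fwd, y[idx, , drop = FALSE], spec)
      t <- t + 1
      upd <- .adam_step(layers, grads, state, lr, t)
      layers <- upd$layers
      state <- upd$state
    }
    ev_tr <- .mlp_forward(layers, x, spec, training = FALSE)
    train_loss <- .ce_loss(ev_tr$probs, y, layers, spec$l2_lambda)
    train_acc <- mean(max.col(ev_tr$probs, ties.method = "first") == y_idx)
    if (!is.null(x_val)) {
      ev_v <- .mlp_forward(layers, x_val, spec, training = FALSE)
      val_loss <- .ce_loss(ev_v$probs, y_val, layers, spec$l2_lambda)
      val_acc <- mean(max.col(ev_v$probs, ties.method = "first") == y_val_idx)
    } else {
      val_loss <- train_loss
      val_acc <- train_acc
    }
    history[epoch, ] <- list(epoch, train_loss, train_acc, val_loss, val_acc)
    if (val_loss < best$loss - 1e-6) {
      best <- list(loss = val_loss, layers = layers, epoch = epoch)
      wait <- 0
      lr_wait <- 0
    } else {
      wait <- wait + 1
      lr_wait <- lr_wait + 1
      if (wait >= spec$early_stop_patience) break
      if (spec$lr_reduce_factor < 1 && lr_wait >= spec$lr_reduce_patience) {
        lr <- lr * spec$lr_reduce_factor
        lr_wait <- 0
      }
    }
  }
  list(layers = best$layers, history = history, best_epoch = best$epoch,
       stopped_epoch = nrow(history))
}
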