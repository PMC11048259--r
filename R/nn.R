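# Small CNN engine: stride-1 "same" convolutions + ReLU + 2x2 max pooling
# blocks, a 2-output fully connected head, optional logit dropout, and a
# softmax or softplus final activation.  Convolution and pooling kernels
# live in src/conv_ops.cpp; parameter updates and the training loop are R.
# Tensors use (h, w, channels, n) layout.  Class order on the output axis is
# fixed as c("negative", "positive").

.CLASS_LEVELS <- c("negative", "positive")

# output spatial size after the conv/pool ladder
pooled_sizes <- function(input_size, n_layers) {
  sizes <- integer(n_layers)
  s <- input_size
  for (l in seq_len(n_layers)) {
    s <- s %/% 2L
    if (s < 1) stop_with("efastcnn_invalid_argument",
                         "input too small for this many pooling stages")
    sizes[l] <- s
  }
  sizes
}

# He-initialized parameter set for a conv ladder + fc head
nn_init <- function(filters, filter_size, input_size, in_channels = 1,
                    seed = NULL) {
  build <- function() {
    params <- list()
    cin <- in_channels
    k <- filter_size
    for (l in seq_along(filters)) {
      cout <- filters[l]
      params[[paste0("conv", l, ".W")]] <-
        array(rnorm(k * k * cin * cout) * sqrt(2 / (k * k * cin)),
              dim = c(k, k, cin, cout))
      params[[paste0("conv", l, ".b")]] <- rep(0, cout)
      cin <- cout
    }
    sizes <- pooled_sizes(input_size, length(filters))
    din <- sizes[length(filters)]^2 * filters[length(filters)]
    params[["fc.W"]] <- matrix(rnorm(2 * din) * sqrt(2 / din), 2, din)
    params[["fc.b"]] <- rep(0, 2)
    params
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

new_cnn_model <- function(name, filters, filter_size, input_size, activator,
                          dropout = 0, spec = NULL, in_channels = 1,
                          seed = NULL) {
  activator <- match.arg(activator, c("softmax", "softplus"))
  params <- nn_init(filters, filter_size, input_size, in_channels, seed)
  structure(list(
    name = name, filters = filters, filter_size = filter_size,
    input_size = as.integer(input_size), in_channels = in_channels,
    activator = activator, dropout = dropout, spec = spec,
    params = params,
    n_params = sum(vapply(params, length, integer(1)))
  ), class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(
    "<cnn_model %s: %d conv layers [%s], %dx%d kernels, input %d, %s head%s, %d params>\n",
    x$name, length(x$filters), paste(x$filters, collapse = ","),
    x$filter_size, x$filter_size, x$input_size, x$activator,
    if (x$dropout > 0) sprintf(", dropout %.1f", x$dropout) else "",
    x$n_params))
  invisible(x)
}

# Forward pass.  x: (h, w, cin, n).  Returns raw scores (2 x n); with
# retain = TRUE also the per-layer caches needed for backward / Grad-CAM.
# Dropout (inverted scaling on the two logits) is active only when
# training = TRUE; inference is deterministic.
nn_forward <- function(model, x, training = FALSE, retain = FALSE) {
  caches <- if (retain) vector("list", length(model$filters))
  a <- x
  for (l in seq_along(model$filters)) {
    W <- model$params[[paste0("conv", l, ".W")]]
    b <- model$params[[paste0("conv", l, ".b")]]
    z <- .conv2d_forward(a, W, b)
    r <- z
    r[r < 0] <- 0
    mp <- .maxpool_forward(r)
    if (retain) caches[[l]] <- list(x = a, z = z, r = r, idx = mp$idx)
    a <- mp$y
  }
  d <- dim(a)
  flat <- matrix(a, nrow = d[1] * d[2] * d[3], ncol = d[4])
  scores <- model$params$fc.W %*% flat + model$params$fc.b
  drop_mask <- NULL
  if (training && model$dropout > 0) {
    keep <- 1 - model$dropout
    drop_mask <- matrix(runif(length(scores)) < keep, 2, ncol(scores)) / keep
    scores <- scores * drop_mask
  }
  if (retain) {
    list(scores = scores, flat = flat, pooled_dim = d, caches = caches,
         drop_mask = drop_mask)
  } else {
    list(scores = scores)
  }
}

softplus_stable <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

#' Final activation of the two-class head
#'
#' `softmax`: `y_r = exp(a_r) / sum_j exp(a_j)`, computed with
#' log-sum-exp stabilization so it is invariant to adding a constant to both
#' scores. `softplus`: element-wise `log(1 + exp(x))`, deliberately not
#' normalized (probabilities for AUROC are obtained downstream by L1
#' normalization of the two outputs).
#'
#' @param scores length-2 numeric vector, or 2-row matrix (one column per
#'   example)
#' @param kind "softmax" or "softplus"
#' @return same shape as `scores`
#' @export
final_activation <- function(scores, kind = c("softmax", "softplus")) {
  kind <- match.arg(kind)
  if (!all(is.finite(scores))) {
    stop_with("efastcnn_invalid_argument", "scores must be finite")
  }
  m <- if (is.matrix(scores)) scores else matrix(scores, ncol = 1)
  out <- if (kind == "softmax") {
    mx <- apply(m, 2, max)
    e <- exp(sweep(m, 2, mx))
    sweep(e, 2, colSums(e), "/")
  } else {
    softplus_stable(m)
  }
  if (is.matrix(scores)) out else as.vector(out)
}

# class probabilities for a raw score matrix (2 x n): softmax directly,
# softplus via L1 normalization of the two positive outputs
scores_to_probs <- function(scores, activator) {
  act <- final_activation(scores, activator)
  if (activator == "softplus") {
    tot <- colSums(act)
    act <- sweep(act, 2, ifelse(tot > 0, tot, 1), "/")
  }
  rownames(act) <- .CLASS_LEVELS
  act
}

#' Predict classes and probabilities for an image tensor
#'
#' @param object a `cnn_model`
#' @param x image tensor `(h, w, channels, n)` or a single `h x w` matrix
#' @param ... unused
#' @return list with `scores` (raw 2 x n), `probs` (2 x n, rows
#'   negative/positive), and `labels` (predicted classes; exact score ties
#'   predict "negative")
#' @export
predict.cnn_model <- function(object, x, ...) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1, 1))
  fwd <- nn_forward(object, x, training = FALSE)
  probs <- scores_to_probs(fwd$scores, object$activator)
  labels <- ifelse(fwd$scores[2, ] > fwd$scores[1, ], "positive", "negative")
  list(scores = fwd$scores, probs = probs, labels = labels)
}

# Loss and gradients on one batch.  y: integer vector (1 = negative,
# 2 = positive).  Cross-entropy on the head's class probabilities
# (softmax directly; softplus through L1 normalization).
nn_loss_grad <- function(model, x, y, training = TRUE) {
  fwd <- nn_forward(model, x, training = training, retain = TRUE)
  s <- fwd$scores
  n <- ncol(s)
  eps <- 1e-12
  if (model$activator == "softmax") {
    mx <- apply(s, 2, max)
    e <- exp(sweep(s, 2, mx))
    p <- sweep(e, 2, colSums(e), "/")
    loss <- -mean(log(p[cbind(y, seq_len(n))] + eps))
    dscores <- p
    dscores[cbind(y, seq_len(n))] <- dscores[cbind(y, seq_len(n))] - 1
    dscores <- dscores / n
  } else {
    sp <- softplus_stable(s)
    tot <- colSums(sp)
    pt <- sp[cbind(y, seq_len(n))] / tot
    loss <- -mean(log(pt + eps))
    # dL/dsp_i = 1/tot - 1{i = y}/sp_y, then chain through sigmoid
    dsp <- matrix(rep(1 / tot, each = 2), 2, n)
    dsp[cbind(y, seq_len(n))] <- dsp[cbind(y, seq_len(n))] -
      1 / pmax(sp[cbind(y, seq_len(n))], eps)
    dscores <- dsp * (1 / (1 + exp(-s))) / n
  }
  if (!is.null(fwd$drop_mask)) dscores <- dscores * fwd$drop_mask
  grads <- list()
  grads[["fc.W"]] <- dscores %*% t(fwd$flat)
  grads[["fc.b"]] <- rowSums(dscores)
  dflat <- t(model$params$fc.W) %*% dscores
  da <- array(dflat, dim = fwd$pooled_dim)
  for (l in rev(seq_along(model$filters))) {
    cache <- fwd$caches[[l]]
    dr <- .maxpool_backward(cache$idx, da, nrow(cache$r), ncol(cache$r))
    dz <- dr * (cache$z > 0)
    bk <- .conv2d_backward(cache$x, model$params[[paste0("conv", l, ".W")]], dz)
    grads[[paste0("conv", l, ".W")]] <- bk$dw
    grads[[paste0("conv", l, ".b")]] <- bk$db
    da <- bk$dx
  }
  list(loss = loss, grads = grads)
}

# mean loss over a dataset without gradient bookkeeping (validation)
nn_eval_loss <- function(model, x, y, batch = 64) {
  n <- dim(x)[4]
  tot <- 0
  i <- 1
  while (i <= n) {
    j <- min(n, i + batch - 1)
    xb <- x[, , , i:j, drop = FALSE]
    fwd <- nn_forward(model, xb, training = FALSE)
    p <- scores_to_probs(fwd$scores, model$activator)
    tot <- tot + sum(-log(p[cbind(y[i:j], seq_len(j - i + 1))] + 1e-12))
    i <- j + 1
  }
  tot / n
}

# ---- optimizers ------------------------------------------------------------
# Conventional defaults: RMSprop decay 0.9; ADAM beta1 0.9, beta2 0.999;
# SGDM momentum 0.9; epsilon 1e-8.

opt_init <- function(optimizer, params) {
  zero <- lapply(params, function(p) p * 0)  # preserves each shape exactly
  switch(optimizer,
         RMSprop = list(s = zero),
         ADAM = list(m = zero, v = zero, t = 0),
         SGDM = list(v = zero),
         stop_with("efastcnn_invalid_argument",
                   paste0("unknown optimizer: ", optimizer)))
}

opt_step <- function(optimizer, params, grads, state, lr) {
  eps <- 1e-8
  if (optimizer == "RMSprop") {
    for (k in names(params)) {
      state$s[[k]] <- 0.9 * state$s[[k]] + 0.1 * grads[[k]]^2
      params[[k]] <- params[[k]] - lr * grads[[k]] / (sqrt(state$s[[k]]) + eps)
    }
  } else if (optimizer == "ADAM") {
    state$t <- state$t + 1
    bc1 <- 1 - 0.9^state$t
    bc2 <- 1 - 0.999^state$t
    for (k in names(params)) {
      state$m[[k]] <- 0.9 * state$m[[k]] + 0.1 * grads[[k]]
      state$v[[k]] <- 0.999 * state$v[[k]] + 0.001 * grads[[k]]^2
      params[[k]] <- params[[k]] -
        lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
    }
  } else {  # SGDM
    for (k in names(params)) {
      state$v[[k]] <- 0.9 * state$v[[k]] - lr * grads[[k]]
      params[[k]] <- params[[k]] + state$v[[k]]
    }
  }
  list(params = params, state = state)
}

#' Early-stopping trace over a validation-loss sequence
#'
#' Pure implementation of the validation-patience rule used by the trainer:
#' an epoch improves when its loss is strictly below the best loss so far;
#' training stops once `patience` consecutive epochs fail to improve, and
#' the best epoch's weights are the ones restored.
#'
#' @param val_losses numeric vector, one loss per epoch, in order
#' @param patience consecutive non-improving epochs tolerated (default 5)
#' @return list with `stop_epoch` (last epoch run), `best_epoch`, and
#'   `stopped_early`
#' @export
early_stop_trace <- function(val_losses, patience = 5) {
  best <- Inf
  best_epoch <- 0L
  bad <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      best_epoch <- e
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) {
        return(list(stop_epoch = e, best_epoch = best_epoch,
                    stopped_early = TRUE))
      }
    }
  }
  list(stop_epoch = length(val_losses), best_epoch = best_epoch,
       stopped_early = FALSE)
}

# labels -> integer class index (1 = negative, 2 = positive)
label_index <- function(labels) {
  y <- match(as.character(labels), .CLASS_LEVELS)
  if (anyNA(y)) stop_with("efastcnn_invalid_argument",
                          "labels must be 'positive'/'negative'")
  y
}

#' Train a model with validation-patience early stopping
#'
#' Mini-batch training with the configured optimizer, learning rate and
#' batch size, up to `config$max_epochs` epochs. After each epoch the
#' validation loss is evaluated; if it fails to improve on the best loss so
#' far for `config$patience` consecutive epochs, training stops and the
#' best-epoch weights are restored. On-the-fly augmentation is applied to
#' each training image when a policy is given. A non-finite training loss
#' aborts the run and is reported via `diverged = TRUE`.
#'
#' @param model a `cnn_model` (its activator should match `config$activator`)
#' @param config a [train_config()]
#' @param train,val lists with `x` (tensor `(h, w, 1, n)`) and `y`
#'   (positive/negative labels); see [frames_to_tensor()]
#' @param augment optional [augment_policy()]
#' @param seed integer seed controlling shuffling, augmentation and dropout
#' @return list: `model` (best weights), `history` (per-epoch losses),
#'   `epochs_run`, `best_epoch`, `best_val_loss`, `stopped_early`,
#'   `diverged`
#' @export
train_with_early_stopping <- function(model, config, train, val,
                                      augment = NULL, seed = 1L) {
  if (is.null(train$x) || dim(train$x)[4] == 0 || is.null(val$x) ||
      dim(val$x)[4] == 0) {
    stop_with("efastcnn_insufficient_data",
              "training and validation datasets must be non-empty")
  }
  ytr <- label_index(train$y)
  yva <- label_index(val$y)
  n <- dim(train$x)[4]
  state <- opt_init(config$optimizer, model$params)
  best_params <- model$params
  best_loss <- Inf
  best_epoch <- 0L
  bad <- 0L
  hist <- data.frame(epoch = integer(), train_loss = double(),
                     val_loss = double())
  diverged <- FALSE
  with_seed(seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      i <- 1
      while (i <= n) {
        j <- min(n, i + config$batch_size - 1)
        ids <- ord[i:j]
        xb <- train$x[, , , ids, drop = FALSE]
        if (!is.null(augment)) {
          for (q in seq_along(ids)) {
            xb[, , 1, q] <- augment_matrix(xb[, , 1, q], augment)
          }
        }
        lg <- nn_loss_grad(model, xb, ytr[ids], training = TRUE)
        if (!is.finite(lg$loss)) {
          diverged <- TRUE
          break
        }
        upd <- opt_step(config$optimizer, model$params, lg$grads, state,
                        config$learning_rate)
        model$params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + lg$loss
        nb <- nb + 1L
        i <- j + 1
      }
      if (diverged) break
      vl <- nn_eval_loss(model, val$x, yva)
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = ep_loss / max(nb, 1),
                                     val_loss = vl))
      if (vl < best_loss) {
        best_loss <- vl
        best_epoch <- epoch
        best_params <- model$params
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= config$patience) break
      }
    }
  })
  model$params <- best_params
  list(model = model, history = hist, epochs_run = nrow(hist),
       best_epoch = best_epoch, best_val_loss = best_loss,
       stopped_early = bad >= config$patience, diverged = diverged)
}

#' Stack frames into a model-input tensor
#'
#' @param frames list of `us_frame`s with equal extents
#' @param target optional square resize applied first
#' @return list with `x` (tensor `(h, w, 1, n)`) and `y` (label vector)
#' @export
frames_to_tensor <- function(frames, target = NULL) {
  if (length(frames) == 0) {
    return(list(x = array(0, dim = c(0, 0, 1, 0)), y = character(0)))
  }
  if (!is.null(target)) {
    frames <- lapply(frames, resize_frame, target = target)
  }
  h <- nrow(frames[[1]]$pixels)
  w <- ncol(frames[[1]]$pixels)
  x <- array(0, dim = c(h, w, 1, length(frames)))
  for (i in seq_along(frames)) x[, , 1, i] <- frames[[i]]$pixels
  list(x = x, y = vapply(frames, function(f) f$label, character(1)))
}

# blind-test accuracy of a model on a tensor dataset
blind_accuracy <- function(model, test) {
  pred <- predict(model, test$x)
  mean(pred$labels == test$y)
}
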