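#' Training hyperparameters
#'
#' Field-for-field the training recipe: initial learning rate 0.001 with an
#' inverse-time decay of 0.0016 per epoch, momentum 0.9, minibatch 20,
#' dropout 0.5, at most 150 epochs, and early stopping once the validation
#' cost has not decreased for 20 epochs.
#'
#' @param lr initial learning rate (> 0).
#' @param decay per-epoch learning-rate decay (see [lr_schedule()]).
#' @param momentum momentum coefficient in `[0, 1)`.
#' @param batch_size minibatch size (>= 1).
#' @param max_epochs maximum training epochs.
#' @param dropout dropout rate for the head layers.
#' @param patience early-stopping patience, epochs (>= 1).
#' @param seed seed for shuffling, dropout and any weight draws.
#' @param lr_kind `"inverse_time"` (default) or `"multiplicative"`.
#' @return List of class `hyperparams`.
#' @export
hyperparams <- function(lr = 0.001, decay = 0.0016, momentum = 0.9,
                        batch_size = 20L, max_epochs = 150L, dropout = 0.5,
                        patience = 20L, seed = 1L,
                        lr_kind = c("inverse_time", "multiplicative")) {
  if (lr <= 0) stop_("learning rate must be > 0")
  if (momentum < 0 || momentum >= 1) stop_("momentum must be in [0, 1)")
  if (patience < 1) stop_("patience must be >= 1")
  if (batch_size < 1) stop_("batch size must be >= 1")
  structure(list(lr = lr, decay = decay, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), dropout = dropout,
                 patience = as.integer(patience), seed = as.integer(seed),
                 lr_kind = match.arg(lr_kind)),
            class = "hyperparams")
}

#' Pixelwise cross-entropy cost
#'
#' Mean over all pixels (and images) of the negative log probability the
#' prediction assigns to the true class, in nats. Probabilities are clipped
#' to `[eps, 1 - eps]` before the log, so a perfect prediction costs about
#' `-log(1 - eps)` and a confidently wrong one stays finite.
#'
#' @param probabilities `(h, w, cl)` array on the per-pixel probability
#'   simplex, or a list of such arrays.
#' @param targets matching [binary_mask] (values `0 .. cl-1`), or list.
#' @param eps clipping constant.
#' @return Non-negative scalar cost.
#' @export
cross_entropy <- function(probabilities, targets, eps = 1e-7) {
  if (!is.list(probabilities)) {
    probabilities <- list(probabilities); targets <- list(targets)
  }
  tot <- 0; npix <- 0
  for (i in seq_along(probabilities)) {
    p <- probabilities[[i]]; t <- unclass(targets[[i]])
    d <- dim(p)
    if (!all(dim(t) == d[1:2])) stop_("probability/target shape mismatch")
    ptrue <- p[cbind(c(row(t)), c(col(t)), c(t) + 1L)]
    tot <- tot + sum(-log(pmin(pmax(ptrue, eps), 1 - eps)))
    npix <- npix + length(t)
  }
  tot / npix
}

#' One momentum-SGD update
#'
#' Implements the classical momentum recurrence: `v <- momentum * v +
#' lr * g` followed by `theta <- theta - v`, elementwise over every
#' parameter tensor. With momentum 0 this reduces to plain gradient
#' descent; under a constant gradient `g` the velocity obeys the closed
#' form `v_k = lr * g * (1 - momentum^k) / (1 - momentum)`.
#'
#' @param state list with `params` (named list of `list(W, b)`) and `v`
#'   (velocities of identical shape; created as zeros if `NULL`).
#' @param gradients named list of `list(W, b)` matching `params`.
#' @param lr learning rate for this step.
#' @param momentum momentum coefficient.
#' @return Updated state (same structure).
#' @export
sgd_momentum_step <- function(state, gradients, lr, momentum) {
  if (is.null(state$v))
    state$v <- lapply(state$params, function(p)
      list(W = array(0, dim(p$W)), b = numeric(length(p$b))))
  for (nm in names(gradients)) {
    p <- state$params[[nm]]; v <- state$v[[nm]]; g <- gradients[[nm]]
    if (is.null(p)) stop_("gradient for unknown parameter '%s'", nm)
    if (!identical(dim(g$W), dim(p$W)) || length(g$b) != length(p$b))
      stop_("gradient shape mismatch for '%s'", nm)
    if (!all(is.finite(g$W)) || !all(is.finite(g$b)))
      stop_("non-finite gradient in '%s': training halted", nm)
    v$W <- momentum * v$W + lr * g$W
    v$b <- momentum * v$b + lr * g$b
    p$W <- p$W - v$W
    p$b <- p$b - v$b
    state$params[[nm]] <- p; state$v[[nm]] <- v
  }
  state
}

#' Learning-rate schedule
#'
#' Inverse-time decay indexed by epoch: `lr_e = lr0 / (1 + decay * e)`
#' (epoch 0 gives `lr0`; decay 0 gives a constant rate). A multiplicative
#' alternative `lr0 * (1 - decay)^e` is available via `kind`.
#'
#' @param lr0 initial rate.
#' @param decay per-epoch decay constant.
#' @param epoch 0-based epoch index.
#' @param kind `"inverse_time"` or `"multiplicative"`.
#' @return Learning rate for the epoch.
#' @export
lr_schedule <- function(lr0, decay, epoch,
                        kind = c("inverse_time", "multiplicative")) {
  if (epoch < 0) stop_("epoch must be >= 0")
  switch(match.arg(kind),
         inverse_time = lr0 / (1 + decay * epoch),
         multiplicative = lr0 * (1 - decay)^epoch)
}

# Normalise a list of samples in place: subtract channel means.
apply_channel_means <- function(samples, means) {
  lapply(samples, function(s) {
    for (k in 1:3) s$x[, , k] <- s$x[, , k] - means[k]
    s
  })
}

channel_means <- function(samples) {
  sums <- c(0, 0, 0); n <- 0
  for (s in samples) {
    for (k in 1:3) sums[k] <- sums[k] + sum(s$x[, , k])
    n <- n + length(s$x) / 3
  }
  sums / n
}

as_sample_list <- function(set) {
  if (inherits(set, "subimage_set")) {
    if (is.null(set$samples))
      stop_("subimage set was built with pixels = FALSE; re-sample with \
pixels = TRUE for training")
    set$samples
  } else set
}

#' Train an FCN-8 segmentation model
#'
#' Minibatch momentum-SGD training with pixelwise cross-entropy, dropout
#' active only in training forward passes, a per-epoch learning-rate decay,
#' and early stopping on validation cost: if the validation cost has not
#' decreased for `patience` epochs, training stops and the weights from the
#' lowest-validation-cost epoch are restored. Channel means computed on the
#' training set are subtracted from every input (and stored for use at
#' prediction time).
#'
#' @param network an initialized `fcn8_net` (see [he_initialise()],
#'   [load_pretrained_encoder()]).
#' @param train_set,val_set materialized [sample_subimages()] sets (or plain
#'   lists of `list(x, y)` samples).
#' @param hp a [hyperparams()].
#' @param val_cost_fn optional `function(epoch)` overriding the measured
#'   validation cost - used to script the early-stopping rule in controlled
#'   experiments.
#' @param freeze_encoder keep the 13 encoder convolution layers fixed
#'   (useful after [load_pretrained_encoder()]); default trains everything.
#' @param verbose print a one-line summary per epoch.
#' @return Object of class `fcn8_fit`: the best network, `history` (one row
#'   per epoch: `epoch, lr, train_cost, val_cost, param_norm`),
#'   `best_epoch`, `stop_reason`, `channel_means`, `hp`.
#' @export
train_fcn8 <- function(network, train_set, val_set, hp = hyperparams(),
                       val_cost_fn = NULL, freeze_encoder = FALSE,
                       verbose = FALSE) {
  train_samples <- as_sample_list(train_set)
  val_samples <- as_sample_list(val_set)
  if (length(train_samples) == 0L || length(val_samples) == 0L)
    stop_("empty training or validation set")
  means <- channel_means(train_samples)
  train_samples <- apply_channel_means(train_samples, means)
  val_samples <- apply_channel_means(val_samples, means)
  network$config$dropout <- hp$dropout

  state <- list(params = network$params, v = NULL)
  frozen <- if (freeze_encoder) encoder_layer_names() else character()

  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_cost = numeric(), val_cost = numeric(),
                        param_norm = numeric())
  best_cost <- Inf; best_params <- state$params; best_epoch <- 0L
  bad_epochs <- 0L; stop_reason <- "max_epochs"

  with_seed(hp$seed, {
    for (epoch in seq_len(hp$max_epochs)) {
      lr_e <- lr_schedule(hp$lr, hp$decay, epoch - 1L, hp$lr_kind)
      ord <- sample.int(length(train_samples))
      epoch_cost <- 0; nb <- 0
      for (start in seq(1, length(ord), by = hp$batch_size)) {
        batch <- ord[start:min(start + hp$batch_size - 1L, length(ord))]
        acc <- NULL
        bcost <- 0
        for (i in batch) {
          s <- train_samples[[i]]
          network$params <- state$params
          fw <- fcn8_forward(network, s$x, train = hp$dropout > 0,
                             want_cache = TRUE)
          npix <- length(s$y)
          onehot_idx <- cbind(c(row(s$y)), c(col(s$y)), c(s$y) + 1L)
          bcost <- bcost + cross_entropy(fw$probs, s$y)
          dlogits <- fw$probs
          dlogits[onehot_idx] <- dlogits[onehot_idx] - 1
          dlogits <- dlogits / (npix * length(batch))
          g <- fcn8_backward(network, fw$cache, dlogits)
          acc <- if (is.null(acc)) g else
            mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                   acc, g[names(acc)], SIMPLIFY = FALSE)
        }
        if (length(frozen)) acc[frozen] <- NULL
        state <- sgd_momentum_step(state, acc, lr_e, hp$momentum)
        epoch_cost <- epoch_cost + bcost / length(batch)
        nb <- nb + 1
      }
      epoch_cost <- epoch_cost / nb

      val_cost <- if (!is.null(val_cost_fn)) val_cost_fn(epoch) else {
        network$params <- state$params
        vc <- 0
        for (s in val_samples)
          vc <- vc + cross_entropy(fcn8_forward(network, s$x)$probs, s$y)
        vc / length(val_samples)
      }
      if (!is.finite(val_cost) || !is.finite(epoch_cost))
        stop_("non-finite cost at epoch %d", epoch)
      pnorm <- sum(vapply(state$params,
                          function(p) sum(abs(p$W)) + sum(abs(p$b)), 0))
      history[nrow(history) + 1L, ] <- list(epoch, lr_e, epoch_cost,
                                            val_cost, pnorm)
      if (verbose)
        message(sprintf("epoch %3d lr %.3e train %.4f val %.4f best %.4f",
                        epoch, lr_e, epoch_cost, val_cost,
                        min(best_cost, val_cost)))
      if (val_cost < best_cost) {
        best_cost <- val_cost; best_params <- state$params
        best_epoch <- epoch; bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= hp$patience) { stop_reason <- "early_stop"; break }
      }
    }
  })
  network$params <- best_params
  structure(list(network = network, history = history,
                 best_epoch = best_epoch, stop_reason = stop_reason,
                 channel_means = means, hp = hp),
            class = "fcn8_fit")
}

#' @export
print.fcn8_fit <- function(x, ...) {
  cat(sprintf(
    "<fcn8_fit: %d epochs (%s), best epoch %d, val cost %.4f>\n",
    nrow(x$history), x$stop_reason, x$best_epoch,
    x$history$val_cost[x$best_epoch]))
  print(x$network)
  invisible(x)
}

#' @export
summary.fcn8_fit <- function(object, ...) {
  h <- object$history
  cat("FCN-8 segmentation fit\n")
  print(object$network)
  cat(sprintf("  epochs run: %d (stop: %s)\n", nrow(h), object$stop_reason))
  cat(sprintf("  best epoch: %d  val cost %.4f  train cost %.4f\n",
              object$best_epoch, h$val_cost[object$best_epoch],
              h$train_cost[object$best_epoch]))
  cat(sprintf("  channel means: %.3f %.3f %.3f\n",
              object$channel_means[1], object$channel_means[2],
              object$channel_means[3]))
  invisible(object)
}

#' @export
coef.fcn8_fit <- function(object, ...) object$network$params

#' Plot training and validation cost curves
#' @param x an `fcn8_fit`.
#' @param ... passed to [plot()].
#' @export
plot.fcn8_fit <- function(x, ...) {
  h <- x$history
  plot(h$epoch, h$train_cost, type = "l", xlab = "epoch",
       ylab = "cross-entropy (nats)", ylim = range(h$train_cost, h$val_cost),
       ...)
  lines(h$epoch, h$val_cost, lty = 2)
  graphics::abline(v = x$best_epoch, col = "grey60", lty = 3)
  legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  invisible(x)
}

#' @export
forward.fcn8_fit <- function(object, x, ...) {
  if (inherits(x, "plot_image")) x <- x$pixels
  for (k in 1:3) x[, , k] <- x[, , k] - object$channel_means[k]
  forward(object$network, x, ...)
}

#' Predict spike masks for new images
#'
#' Runs sliding-window inference with the fitted network (channel means
#' subtracted as at training time) and returns the thresholded mask, or the
#' full class-probability map.
#'
#' @param object an `fcn8_fit`.
#' @param image a [plot_image] or `(h, w, 3)` array.
#' @param window,stride tiling parameters (see [tile_positions()]).
#' @param type `"mask"` (argmax decision) or `"prob"` (a `prediction_map`).
#' @param ... unused.
#' @export
predict.fcn8_fit <- function(object, image, window = 512L, stride = window,
                             type = c("mask", "prob"), ...) {
  type <- match.arg(type)
  d <- if (inherits(image, "plot_image")) dim(image$pixels) else dim(image)
  window <- min(window, d[1], d[2])
  map <- sliding_window_predict(object, image, window, stride)
  if (type == "mask") prediction_to_mask(map) else map
}
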