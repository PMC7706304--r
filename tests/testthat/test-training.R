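uniform_probs <- function(h, w) array(0.5, c(h, w, 2))

test_that("cross-entropy matches closed forms", {
  t0 <- binary_mask(matrix(c(0L, 1L, 1L, 0L), 2, 2))
  # uniform prediction costs ln 2 regardless of targets
  expect_equal(cross_entropy(uniform_probs(2, 2), t0), log(2),
               tolerance = 1e-12)
  # true-class probability 0.9 everywhere
  p9 <- array(0, c(2, 2, 2))
  p9[, , 1] <- ifelse(unclass(t0) == 0L, 0.9, 0.1)
  p9[, , 2] <- 1 - p9[, , 1]
  expect_equal(cross_entropy(p9, t0), -log(0.9), tolerance = 1e-12)
  # perfect one-hot prediction is capped by the clip floor
  ph <- array(0, c(2, 2, 2))
  ph[, , 2] <- unclass(t0); ph[, , 1] <- 1 - unclass(t0)
  expect_lte(cross_entropy(ph, t0), 1.2e-7)
  expect_error(cross_entropy(uniform_probs(3, 3), t0), "mismatch")
})

test_that("momentum update follows the velocity recurrence", {
  mkstate <- function(theta) list(
    params = list(layer = list(W = array(theta, c(1, 1, 1, 1)), b = 0)),
    v = NULL)
  g1 <- list(layer = list(W = array(1, c(1, 1, 1, 1)), b = 0))

  # momentum 0: plain gradient descent
  s <- sgd_momentum_step(mkstate(0.5), g1, lr = 0.1, momentum = 0)
  expect_equal(as.numeric(s$params$layer$W), 0.4)

  # first step: v1 = lr * g
  s <- sgd_momentum_step(mkstate(0), g1, lr = 0.001, momentum = 0.9)
  expect_equal(as.numeric(s$v$layer$W), 0.001)

  # three constant-gradient steps: v3 = 0.001 * (1 + 0.9 + 0.81)
  s <- mkstate(0)
  for (k in 1:3) s <- sgd_momentum_step(s, g1, lr = 0.001, momentum = 0.9)
  expect_equal(as.numeric(s$v$layer$W), 0.00271, tolerance = 1e-12)

  # closed form v_k = lr*g*(1-m^k)/(1-m) for k <= 10 (standard rate/momentum)
  s <- mkstate(0)
  for (k in 1:10) {
    s <- sgd_momentum_step(s, g1, lr = 0.001, momentum = 0.9)
    expect_equal(as.numeric(s$v$layer$W),
                 0.001 * (1 - 0.9^k) / (1 - 0.9), tolerance = 1e-12)
  }

  bad <- list(layer = list(W = array(NaN, c(1, 1, 1, 1)), b = 0))
  expect_error(sgd_momentum_step(mkstate(0), bad, 0.1, 0.9), "non-finite")
  wrong <- list(layer = list(W = array(1, c(2, 1, 1, 1)), b = 0))
  expect_error(sgd_momentum_step(mkstate(0), wrong, 0.1, 0.9), "shape")
})

test_that("learning-rate schedule is inverse-time in the epoch index", {
  expect_equal(lr_schedule(0.001, 0.0016, 0), 0.001)
  expect_equal(lr_schedule(0.001, 0, 57), 0.001)
  expect_equal(lr_schedule(0.001, 0.0016, 100), 0.001 / 1.16,
               tolerance = 1e-12)
  expect_lt(lr_schedule(0.001, 0.0016, 100, "multiplicative"), 0.001)
  expect_error(lr_schedule(0.001, 0.0016, -1), ">= 0")
})

tiny_sets <- function(n_train = 4, n_val = 2, size = 32, seed = 31) {
  withr::local_seed(seed, .local_envir = parent.frame())
  mk <- function(n) lapply(seq_len(n), function(i) {
    y <- matrix(0L, size, size)
    y[sample(size^2, size)] <- 1L
    x <- array(runif(size * size * 3) * 0.2, c(size, size, 3))
    x[, , 1] <- x[, , 1] + y * 0.7  # spikes are red-shifted: learnable
    list(x = x, y = y)
  })
  list(train = mk(n_train), val = mk(n_val))
}

test_that("early stopping halts on patience and restores the best weights", {
  sets <- tiny_sets()
  net <- he_initialise(build_fcn8(arch_config(width = 1 / 32)), seed = 1)

  # scripted validation costs [3.0, 2.0, 2.1, 2.2, 2.3], patience 2:
  # stop after epoch 4, best epoch 2
  costs <- c(3.0, 2.0, 2.1, 2.2, 2.3, 1.0)
  fit <- train_fcn8(net, sets$train, sets$val,
                    hyperparams(batch_size = 4, max_epochs = 10, patience = 2,
                                dropout = 0, seed = 2),
                    val_cost_fn = function(e) costs[e])
  expect_equal(nrow(fit$history), 4L)
  expect_equal(fit$best_epoch, 2L)
  expect_equal(fit$stop_reason, "early_stop")
  # restored weights are the epoch-2 snapshot, not the last state
  pnorm_returned <- sum(sapply(fit$network$params,
                               function(p) sum(abs(p$W)) + sum(abs(p$b))))
  expect_equal(pnorm_returned, fit$history$param_norm[2])
  expect_false(isTRUE(all.equal(pnorm_returned, fit$history$param_norm[4])))

  # flat cost from epoch 1 with patience 20: stop at epoch 21
  fit2 <- train_fcn8(net, sets$train, sets$val,
                     hyperparams(batch_size = 4, max_epochs = 40,
                                 dropout = 0, seed = 2),
                     val_cost_fn = function(e) 1.0)
  expect_equal(nrow(fit2$history), 21L)
  expect_equal(fit2$best_epoch, 1L)

  # strictly decreasing cost: runs to max epochs, best = last
  fit3 <- train_fcn8(net, sets$train, sets$val,
                     hyperparams(batch_size = 4, max_epochs = 5,
                                 dropout = 0, seed = 2),
                     val_cost_fn = function(e) 1 / e)
  expect_equal(nrow(fit3$history), 5L)
  expect_equal(fit3$best_epoch, 5L)
  expect_equal(fit3$stop_reason, "max_epochs")
})

test_that("best epoch always has the minimal recorded validation cost", {
  sets <- tiny_sets()
  net <- he_initialise(build_fcn8(arch_config(width = 1 / 32)), seed = 1)
  withr::local_seed(77)
  for (rep in 1:3) {
    costs <- runif(8, 1, 2)
    fit <- train_fcn8(net, sets$train, sets$val,
                      hyperparams(batch_size = 4, max_epochs = 8,
                                  patience = 3, dropout = 0, seed = rep),
                      val_cost_fn = function(e) costs[e])
    expect_equal(fit$history$val_cost[fit$best_epoch],
                 min(fit$history$val_cost))
  }
})

test_that("training is reproducible with dropout off and momentum 0", {
  sets <- tiny_sets()
  net <- he_initialise(build_fcn8(arch_config(width = 1 / 32)), seed = 1)
  hp <- hyperparams(batch_size = 2, max_epochs = 2, dropout = 0,
                    momentum = 0, seed = 5)
  f1 <- train_fcn8(net, sets$train, sets$val, hp)
  f2 <- train_fcn8(net, sets$train, sets$val, hp)
  expect_identical(f1$network$params, f2$network$params)
  expect_identical(f1$history, f2$history)
})

test_that("a short training run reduces the training cost", {
  sets <- tiny_sets(n_train = 20, n_val = 5, size = 64, seed = 13)
  net <- he_initialise(build_fcn8(arch_config(width = 1 / 8)), seed = 3)
  fit <- train_fcn8(net, sets$train, sets$val,
                    hyperparams(batch_size = 5, max_epochs = 5, seed = 11))
  expect_lt(fit$history$train_cost[5], fit$history$train_cost[1])
})

test_that("frozen encoders do not move during training", {
  sets <- tiny_sets()
  net <- he_initialise(build_fcn8(arch_config(width = 1 / 32)), seed = 1)
  fit <- train_fcn8(net, sets$train, sets$val,
                    hyperparams(batch_size = 4, max_epochs = 2, dropout = 0,
                                seed = 2),
                    freeze_encoder = TRUE)
  for (nm in spikeseg:::encoder_layer_names())
    expect_identical(fit$network$params[[nm]], net$params[[nm]])
  expect_false(identical(fit$network$params$score_fr, net$params$score_fr))
})
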