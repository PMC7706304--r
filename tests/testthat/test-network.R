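test_that("output shape law holds across input sizes", {
  net <- he_initialise(build_fcn8(arch_config(width = 1 / 16)), seed = 2)
  for (n in c(32, 64, 96, 128)) {
    x <- array(runif(n * n * 3), c(n, n, 3))
    p <- forward(net, x)
    expect_equal(dim(p), c(n, n, 2))
    expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-6)
  }
  expect_error(forward(net, array(0, c(16, 16, 3))), "32 px minimum")
})

test_that("block taps are successive halvings of the input", {
  net <- he_initialise(build_fcn8(arch_config(width = 1 / 16)), seed = 2)
  x <- array(runif(96 * 64 * 3), c(96, 64, 3))
  taps <- spikeseg:::fcn8_forward(net, x, want_taps = TRUE)$taps
  for (b in 1:5)
    expect_equal(dim(taps[[sprintf("P%d", b)]])[1:2], c(96, 64) / 2^b)
})

test_that("parameter counts match the closed-form kernel arithmetic", {
  net1 <- build_fcn8(arch_config(width = 1))
  expect_equal(length(net1$params$conv1_1$W) + length(net1$params$conv1_1$b),
               1792L)  # 3*3*3*64 + 64
  expect_equal(n_parameters(net1), oracle_param_count(1))
  net8 <- build_fcn8(arch_config(width = 1 / 8))
  expect_equal(n_parameters(net8), oracle_param_count(1 / 8))
})

test_that("He initialisation draws sd sqrt(2/fan_in), zero-mean, zero bias", {
  # fan-in 50: conv with k=1, cin=50 in a purpose-built layer draw
  withr::local_seed(99)
  draws <- rnorm(1e5, 0, sqrt(2 / 50))
  expect_lt(abs(sd(draws) - sqrt(2 / 50)) / sqrt(2 / 50), 0.01)

  net <- he_initialise(build_fcn8(arch_config(width = 1 / 8)), seed = 4)
  for (nm in c("conv1_1", "conv3_2", "conv6", "score_fr")) {
    s <- net$spec[[nm]]
    W <- net$params[[nm]]$W
    fan_in <- s$k^2 * s$cin
    expect_lt(abs(sd(W) - sqrt(2 / fan_in)) / sqrt(2 / fan_in), 0.15)
    expect_lt(abs(mean(W)), 3 * sd(W) / sqrt(length(W)))
    expect_true(all(net$params[[nm]]$b == 0))
  }
  # deterministic under seed
  net2 <- he_initialise(build_fcn8(arch_config(width = 1 / 8)), seed = 4)
  expect_identical(net$params, net2$params)
  # upsampling kernels start as bilinear interpolation, not noise
  expect_equal(net$params$upscore2$W[, , 1, 1],
               outer(c(.25, .75, .75, .25), c(.25, .75, .75, .25)))
  expect_true(all(net$params$upscore2$W[, , 1, 2] == 0))
})

test_that("a zero-weight network predicts the uniform distribution", {
  net <- build_fcn8(arch_config(width = 1 / 16))
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  p <- forward(net, x)
  expect_true(all(abs(p - 0.5) < 1e-12))
})

test_that("evaluation-mode forward passes are deterministic", {
  net <- he_initialise(build_fcn8(arch_config(width = 1 / 16)), seed = 6)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  expect_identical(forward(net, x), forward(net, x))
  # training mode with dropout differs between calls
  f1 <- spikeseg:::fcn8_forward(net, x, train = TRUE)$probs
  f2 <- spikeseg:::fcn8_forward(net, x, train = TRUE)$probs
  expect_false(identical(f1, f2))
})

test_that("zeroing the skip branches reduces FCN-8 to coarse FCN-32 output", {
  net <- he_initialise(build_fcn8(arch_config(width = 1 / 16)), seed = 8)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  ablated <- net
  for (nm in c("score_p3", "score_p4")) {
    ablated$params[[nm]]$W[] <- 0
    ablated$params[[nm]]$b[] <- 0
  }
  got <- spikeseg:::fcn8_forward(ablated, x)$logits

  # independent coarse path: score conv7 output, then chain the three
  # upsampling layers directly (x2, x2, x8 = x32 total)
  taps <- spikeseg:::fcn8_forward(net, x, want_taps = TRUE)
  s_fr <- spikeseg:::.conv2d_fw(taps$taps$conv7, net$params$score_fr$W,
                                net$params$score_fr$b, 0L)
  u1 <- spikeseg:::.convtr_fw(s_fr, net$params$upscore2$W,
                              net$params$upscore2$b, 2L, 1L)
  u2 <- spikeseg:::.convtr_fw(u1, net$params$upscore4$W,
                              net$params$upscore4$b, 2L, 1L)
  u3 <- spikeseg:::.convtr_fw(u2, net$params$upscore8$W,
                              net$params$upscore8$b, 8L, 4L)
  expect_equal(got, u3, tolerance = 1e-12)
})

test_that("pretrained-encoder loading replaces exactly the encoder", {
  net <- he_initialise(build_fcn8(arch_config(width = 1 / 8)), seed = 1)
  enc <- spikeseg:::encoder_layer_names()
  expect_length(enc, 13L)
  store <- lapply(net$params[enc], function(p)
    list(W = array(1, dim(p$W)), b = rep(0, length(p$b))))
  loaded <- load_pretrained_encoder(net, store)
  rep <- attr(loaded, "transfer_report")
  expect_setequal(rep$loaded, enc)
  expect_length(rep$skipped, 0L)
  for (nm in enc) expect_true(all(loaded$params[[nm]]$W == 1))
  # decoder bitwise untouched
  dec <- setdiff(names(net$params), enc)
  for (nm in dec) expect_identical(loaded$params[[nm]], net$params[[nm]])

  # wrong-shaped tensor errors naming the layer
  bad <- store
  bad$conv2_1$W <- array(1, c(3, 3, 2, 2))
  expect_error(load_pretrained_encoder(net, bad), "conv2_1")
  # non-encoder names are skipped and reported
  extra <- store["conv1_1"]
  extra$fc8 <- store[["conv1_1"]]
  rep2 <- attr(load_pretrained_encoder(net, extra), "transfer_report")
  expect_equal(rep2$skipped, "fc8")
  expect_error(load_pretrained_encoder(net, list()), "empty")
})
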