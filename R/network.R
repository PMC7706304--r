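#' FCN-8 architecture configuration
#'
#' Describes the VGG16-style encoder (five blocks of 3x3 stride-1
#' convolutions - 2, 2, 3, 3, 3 per block - each followed by ReLU, with a
#' 2x2 stride-2 max-pool after every block), the fully convolutional head
#' (conv6, 7x7, and conv7, 1x1, each followed by ReLU and dropout; the
#' 1000-class classifier layer of the original network is omitted), and the
#' skip decoder (1x1 score layers on conv7, pool4 and pool3; learned x2
#' upsampling twice with element-wise-sum fusion, then a final learned x8
#' upsampling to input size and a per-pixel softmax over `classes`).
#'
#' `width` scales every filter count (e.g. 1/8 for desk-scale training);
#' width 1 reproduces the full architecture with encoder depths
#' 64/128/256/512/512 and a 4096-filter head.
#'
#' @param width filter-count multiplier (> 0; each layer keeps >= 1 filter).
#' @param classes number of output classes `cl` (>= 2; 2 = background/spike).
#' @param in_channels input channels (3 for RGB).
#' @param dropout dropout rate applied after conv6 and conv7 in training.
#' @return List of class `arch_config`.
#' @export
arch_config <- function(width = 1, classes = 2L, in_channels = 3L,
                        dropout = 0.5) {
  if (width <= 0) stop_("width multiplier must be > 0")
  if (classes < 2) stop_("need at least 2 classes")
  filters <- pmax(1L, as.integer(round(c(64, 128, 256, 512, 512) * width)))
  head <- max(1L, as.integer(round(4096 * width)))
  structure(list(width = width, classes = as.integer(classes),
                 in_channels = as.integer(in_channels),
                 filters = filters, convs_per_block = c(2L, 2L, 3L, 3L, 3L),
                 head = head, dropout = dropout),
            class = "arch_config")
}

# Full ordered layer table: one row per parameterised layer.
# kind: conv (stride-1 same convolution) or upconv (transposed convolution).
layer_table <- function(config) {
  f <- config$filters; cl <- config$classes
  rows <- list()
  cin <- config$in_channels
  for (b in 1:5) {
    for (j in seq_len(config$convs_per_block[b])) {
      rows[[length(rows) + 1L]] <-
        list(name = sprintf("conv%d_%d", b, j), kind = "conv", k = 3L,
             cin = cin, cout = f[b], pad = 1L, stride = 1L)
      cin <- f[b]
    }
  }
  rows[[length(rows) + 1L]] <- list(name = "conv6", kind = "conv", k = 7L,
                                    cin = f[5], cout = config$head, pad = 3L,
                                    stride = 1L)
  rows[[length(rows) + 1L]] <- list(name = "conv7", kind = "conv", k = 1L,
                                    cin = config$head, cout = config$head,
                                    pad = 0L, stride = 1L)
  rows[[length(rows) + 1L]] <- list(name = "score_fr", kind = "conv", k = 1L,
                                    cin = config$head, cout = cl, pad = 0L,
                                    stride = 1L)
  rows[[length(rows) + 1L]] <- list(name = "score_p4", kind = "conv", k = 1L,
                                    cin = f[4], cout = cl, pad = 0L,
                                    stride = 1L)
  rows[[length(rows) + 1L]] <- list(name = "score_p3", kind = "conv", k = 1L,
                                    cin = f[3], cout = cl, pad = 0L,
                                    stride = 1L)
  rows[[length(rows) + 1L]] <- list(name = "upscore2", kind = "upconv",
                                    k = 4L, cin = cl, cout = cl, pad = 1L,
                                    stride = 2L)
  rows[[length(rows) + 1L]] <- list(name = "upscore4", kind = "upconv",
                                    k = 4L, cin = cl, cout = cl, pad = 1L,
                                    stride = 2L)
  rows[[length(rows) + 1L]] <- list(name = "upscore8", kind = "upconv",
                                    k = 16L, cin = cl, cout = cl, pad = 4L,
                                    stride = 8L)
  names(rows) <- vapply(rows, `[[`, "", "name")
  rows
}

encoder_layer_names <- function() {
  c(sprintf("conv1_%d", 1:2), sprintf("conv2_%d", 1:2),
    sprintf("conv3_%d", 1:3), sprintf("conv4_%d", 1:3),
    sprintf("conv5_%d", 1:3))
}

#' Build an (uninitialized) FCN-8 network
#'
#' Constructs the layer graph and zero-filled parameter tensors for the
#' architecture described by an [arch_config()]. Weights are all zero until
#' [he_initialise()] (or [load_pretrained_encoder()]) is applied; a
#' zero-weight network outputs the uniform class distribution everywhere.
#'
#' @param config an [arch_config()].
#' @return Object of class `fcn8_net` with elements `config`, `spec` (layer
#'   table) and `params` (named list of `list(W, b)` tensors; `W` has dim
#'   `(k, k, cin, cout)`).
#' @export
build_fcn8 <- function(config = arch_config()) {
  spec <- layer_table(config)
  params <- lapply(spec, function(s)
    list(W = array(0, c(s$k, s$k, s$cin, s$cout)), b = numeric(s$cout)))
  structure(list(config = config, spec = spec, params = params),
            class = "fcn8_net")
}

#' Number of parameters of a network
#' @param network an `fcn8_net`.
#' @return Integer count of weights plus biases over all layers.
#' @export
n_parameters <- function(network) {
  sum(vapply(network$params, function(p) length(p$W) + length(p$b), 0))
}

#' @export
print.fcn8_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<fcn8_net: width %s, %d classes, %s parameters>\n",
              format(cfg$width), cfg$classes,
              format(n_parameters(x), big.mark = ",")))
  cat(sprintf("  encoder filters: %s | head: %d\n",
              paste(cfg$filters, collapse = "/"), cfg$head))
  invisible(x)
}

# 1-d bilinear interpolation weights for a transposed-conv kernel of size k
# (k = 2 * stride): w[i] = 1 - |i - (k-1)/2| / (k/2).
bilinear_weights <- function(k) {
  i <- 0:(k - 1)
  1 - abs(i - (k - 1) / 2) / (k / 2)
}

#' He initialisation
#'
#' Draws every convolution weight from a zero-mean normal with standard
#' deviation `sqrt(2 / n_l)`, where `n_l` is the layer fan-in
#' (`k * k * cin`), and sets every bias to 0. The learned upsampling
#' (transposed-convolution) kernels are initialized to bilinear
#' interpolation (channel-wise identity) rather than random values, the
#' standard starting point for skip-decoder upsampling. Deterministic under
#' `seed`.
#'
#' @param network a freshly built `fcn8_net`.
#' @param seed integer seed.
#' @return The initialized network.
#' @export
he_initialise <- function(network, seed = 1) {
  with_seed(seed, {
    for (nm in names(network$params)) {
      s <- network$spec[[nm]]
      p <- network$params[[nm]]
      if (s$kind == "upconv") {
        w1 <- bilinear_weights(s$k)
        k2 <- outer(w1, w1)
        W <- array(0, dim(p$W))
        for (ci in seq_len(s$cin)) W[, , ci, ci] <- k2
        p$W <- W
      } else {
        fan_in <- s$k * s$k * s$cin
        p$W <- array(rnorm(length(p$W), 0, sqrt(2 / fan_in)), dim(p$W))
      }
      p$b <- numeric(s$cout)
      network$params[[nm]] <- p
    }
  })
  network
}

#' Load pretrained encoder weights (transfer-learning hook)
#'
#' Replaces the parameters of the 13 encoder convolution layers
#' (`conv1_1` ... `conv5_3`) with tensors from a named weight store, leaving
#' the head, score and upsampling layers untouched. Store entries whose
#' names do not match an encoder layer are skipped and listed in the
#' attached report; a matched name with an incompatible shape is an error
#' naming the layer.
#'
#' @param network an `fcn8_net` (typically at width 1, matching the store).
#' @param store named list; each element `list(W, b)` with `W` of dim
#'   `(k, k, cin, cout)`.
#' @return The network with replaced encoder weights; attribute
#'   `transfer_report` holds `list(loaded =, skipped =)` character vectors.
#' @export
load_pretrained_encoder <- function(network, store) {
  if (length(store) == 0L) stop_("empty weight store")
  enc <- encoder_layer_names()
  loaded <- character(); skipped <- character()
  for (nm in names(store)) {
    if (!nm %in% enc) { skipped <- c(skipped, nm); next }
    tgt <- network$params[[nm]]
    src <- store[[nm]]
    if (!identical(dim(src$W), dim(tgt$W)))
      stop_("shape conflict for layer '%s': store %s vs network %s", nm,
            paste(dim(src$W), collapse = "x"),
            paste(dim(tgt$W), collapse = "x"))
    if (!is.null(src$b) && length(src$b) != length(tgt$b))
      stop_("bias length conflict for layer '%s'", nm)
    tgt$W <- src$W
    if (!is.null(src$b)) tgt$b <- as.numeric(src$b)
    network$params[[nm]] <- tgt
    loaded <- c(loaded, nm)
  }
  attr(network, "transfer_report") <- list(loaded = loaded, skipped = skipped)
  network
}

# Center-crop an (h, w, c) array to (th, tw); returns value + offsets used.
crop_center <- function(x, th, tw) {
  d <- dim(x)
  ro <- (d[1] - th) %/% 2L
  co <- (d[2] - tw) %/% 2L
  list(y = x[(ro + 1):(ro + th), (co + 1):(co + tw), , drop = FALSE],
       ro = ro, co = co, h = d[1], w = d[2])
}

uncrop <- function(dy, info, channels) {
  dx <- array(0, c(info$h, info$w, channels))
  d <- dim(dy)
  dx[(info$ro + 1):(info$ro + d[1]), (info$co + 1):(info$co + d[2]), ] <- dy
  dx
}

check_input_size <- function(h, w) {
  if (h < 32 || w < 32)
    stop_("input %dx%d is below the 32 px minimum that survives 5 poolings",
          h, w)
  if (h %% 32 != 0 || w %% 32 != 0)
    stop_("input extents must be multiples of 32 (got %dx%d): pooling and \
x8 upsampling cannot otherwise restore the input size without padding", h, w)
}

dropout_mask <- function(n, p) {
  # inverted dropout: surviving units scaled by 1/(1-p) so evaluation mode
  # needs no rescaling
  (runif(n) >= p) / (1 - p)
}

# Single forward pass over one (h, w, 3) array. Returns probs/logits and,
# on request, the cache needed by fcn8_backward and the block taps P1..P5.
fcn8_forward <- function(net, x, train = FALSE, want_cache = FALSE,
                         want_taps = FALSE) {
  if (inherits(x, "plot_image")) x <- x$pixels
  d <- dim(x)
  if (length(d) != 3L || d[3] != net$config$in_channels)
    stop_("input must be (h, w, %d)", net$config$in_channels)
  check_input_size(d[1], d[2])
  P <- net$params; spec <- net$spec
  cache <- if (want_cache) new.env(parent = emptyenv()) else NULL
  taps <- list()
  a <- x
  for (b in 1:5) {
    for (j in seq_len(net$config$convs_per_block[b])) {
      nm <- sprintf("conv%d_%d", b, j)
      z <- .conv2d_fw(a, P[[nm]]$W, P[[nm]]$b, spec[[nm]]$pad)
      if (want_cache) assign(nm, list(x = a, z = z), envir = cache)
      a <- .relu_fw(z)
    }
    pl <- .maxpool2_fw(a)
    if (want_cache) assign(sprintf("pool%d", b),
                           list(idx = pl$idx, dim = dim(a)), envir = cache)
    a <- pl$y
    if (want_taps || b %in% 3:4) taps[[sprintf("P%d", b)]] <- a
  }
  for (nm in c("conv6", "conv7")) {
    z <- .conv2d_fw(a, P[[nm]]$W, P[[nm]]$b, spec[[nm]]$pad)
    r <- .relu_fw(z)
    if (train) {
      m <- array(dropout_mask(length(r), net$config$dropout), dim(r))
      a2 <- r * m
    } else {
      m <- NULL
      a2 <- r
    }
    if (want_cache) assign(nm, list(x = a, z = z, mask = m), envir = cache)
    a <- a2
  }
  if (want_taps) taps$conv7 <- a
  s_fr <- .conv2d_fw(a, P$score_fr$W, P$score_fr$b, 0L)
  if (want_cache) assign("score_fr", list(x = a), envir = cache)

  up2a <- .convtr_fw(s_fr, P$upscore2$W, P$upscore2$b, 2L, 1L)
  s_p4 <- .conv2d_fw(taps$P4, P$score_p4$W, P$score_p4$b, 0L)
  cr1 <- crop_center(up2a, dim(s_p4)[1], dim(s_p4)[2])
  f1 <- cr1$y + s_p4

  up2b <- .convtr_fw(f1, P$upscore4$W, P$upscore4$b, 2L, 1L)
  s_p3 <- .conv2d_fw(taps$P3, P$score_p3$W, P$score_p3$b, 0L)
  cr2 <- crop_center(up2b, dim(s_p3)[1], dim(s_p3)[2])
  f2 <- cr2$y + s_p3

  up8 <- .convtr_fw(f2, P$upscore8$W, P$upscore8$b, 8L, 4L)
  cr3 <- crop_center(up8, d[1], d[2])
  logits <- cr3$y
  if (want_cache) {
    assign("decoder", list(s_fr = s_fr, f1 = f1, f2 = f2, P3 = taps$P3,
                           P4 = taps$P4, cr1 = cr1, cr2 = cr2, cr3 = cr3),
           envir = cache)
  }
  probs <- .softmax_channels(logits)
  list(probs = probs, logits = logits, cache = cache,
       taps = if (want_taps) taps else NULL)
}

# Backward pass: dlogits (h, w, cl) -> named list of list(W, b) gradients.
fcn8_backward <- function(net, cache, dlogits) {
  P <- net$params; spec <- net$spec; cl <- net$config$classes
  g <- list()
  dec <- get("decoder", envir = cache)
  dup8 <- uncrop(dlogits, dec$cr3, cl)
  bw <- .convtr_bw(dec$f2, P$upscore8$W, dup8, 8L, 4L)
  g$upscore8 <- list(W = bw$dW, b = bw$db)
  df2 <- bw$dx

  cbw <- .conv2d_bw(dec$P3, P$score_p3$W, df2, 0L)
  g$score_p3 <- list(W = cbw$dW, b = cbw$db)
  dP3_score <- cbw$dx

  dup2b <- uncrop(df2, dec$cr2, cl)
  bw <- .convtr_bw(dec$f1, P$upscore4$W, dup2b, 2L, 1L)
  g$upscore4 <- list(W = bw$dW, b = bw$db)
  df1 <- bw$dx

  cbw <- .conv2d_bw(dec$P4, P$score_p4$W, df1, 0L)
  g$score_p4 <- list(W = cbw$dW, b = cbw$db)
  dP4_score <- cbw$dx

  dup2a <- uncrop(df1, dec$cr1, cl)
  bw <- .convtr_bw(dec$s_fr, P$upscore2$W, dup2a, 2L, 1L)
  g$upscore2 <- list(W = bw$dW, b = bw$db)
  ds_fr <- bw$dx

  sc <- get("score_fr", envir = cache)
  cbw <- .conv2d_bw(sc$x, P$score_fr$W, ds_fr, 0L)
  g$score_fr <- list(W = cbw$dW, b = cbw$db)
  da <- cbw$dx

  for (nm in c("conv7", "conv6")) {
    ly <- get(nm, envir = cache)
    if (!is.null(ly$mask)) da <- da * ly$mask
    da <- .relu_bw(da, ly$z)
    cbw <- .conv2d_bw(ly$x, P[[nm]]$W, da, spec[[nm]]$pad)
    g[[nm]] <- list(W = cbw$dW, b = cbw$db)
    da <- cbw$dx
  }

  for (b in 5:1) {
    pool <- get(sprintf("pool%d", b), envir = cache)
    if (b == 4L) da <- da + dP4_score
    if (b == 3L) da <- da + dP3_score
    da <- .maxpool2_bw(da, pool$idx, pool$dim[1], pool$dim[2], pool$dim[3])
    for (j in rev(seq_len(net$config$convs_per_block[b]))) {
      nm <- sprintf("conv%d_%d", b, j)
      ly <- get(nm, envir = cache)
      da <- .relu_bw(da, ly$z)
      cbw <- .conv2d_bw(ly$x, P[[nm]]$W, da, spec[[nm]]$pad)
      g[[nm]] <- list(W = cbw$dW, b = cbw$db)
      da <- cbw$dx
    }
  }
  g
}

#' Forward pass of a segmentation network
#'
#' Generic so that lightweight stand-in predictors (e.g. stubs in tests) can
#' implement the same contract: given an `(h, w, 3)` array (or
#' [plot_image]), return an `(h, w, cl)` array of per-pixel class
#' probabilities summing to 1. For `fcn8_net`, evaluation mode (the default)
#' disables dropout, so repeated calls are deterministic.
#'
#' @param object network object.
#' @param x input image array or [plot_image].
#' @param ... method-specific arguments (`train = FALSE` for `fcn8_net`).
#' @return `(h, w, cl)` probability array.
#' @export
forward <- function(object, x, ...) UseMethod("forward")

#' @rdname forward
#' @param train enable dropout (training mode).
#' @export
forward.fcn8_net <- function(object, x, train = FALSE, ...) {
  fcn8_forward(object, x, train = train)$probs
}
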