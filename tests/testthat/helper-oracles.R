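# Independent oracles used by the metric, stitching and architecture tests.
# These deliberately use brute-force double loops / direct enumeration so
# they share no code with the package implementation.

# Pixel-by-pixel double-loop confusion metrics for binary masks.
oracle_metrics <- function(pred, truth) {
  pred <- unclass(pred); truth <- unclass(truth)
  tp <- c(0, 0); fp <- c(0, 0); fn <- c(0, 0); tot <- c(0, 0)
  for (r in seq_len(nrow(truth))) {
    for (c in seq_len(ncol(truth))) {
      t <- truth[r, c]; p <- pred[r, c]
      tot[t + 1] <- tot[t + 1] + 1
      if (p == t) tp[t + 1] <- tp[t + 1] + 1
      else { fp[p + 1] <- fp[p + 1] + 1; fn[t + 1] <- fn[t + 1] + 1 }
    }
  }
  np <- length(truth)
  cls_acc <- ifelse(tot > 0, tp / pmax(tot, 1), NA)
  un <- tp + fp + fn
  cls_iou <- ifelse(un > 0, tp / pmax(un, 1), NA)
  list(GA = sum(tp) / np,
       class_acc = cls_acc, MA = mean(cls_acc, na.rm = TRUE),
       class_iou = cls_iou, MIoU = mean(cls_iou, na.rm = TRUE))
}

# Accumulate-and-divide stitching oracle over an explicit tile list.
oracle_stitch <- function(predictor, x, offsets, window) {
  d <- dim(x)
  acc <- NULL; cov <- matrix(0, d[1], d[2])
  for (i in seq_len(nrow(offsets))) {
    r <- offsets$row[i]; c <- offsets$col[i]
    rows <- (r + 1):(r + window); cols <- (c + 1):(c + window)
    p <- predictor(x[rows, cols, , drop = FALSE], r, c)
    if (is.null(acc)) acc <- array(0, c(d[1], d[2], dim(p)[3]))
    for (k in seq_len(dim(p)[3]))
      acc[rows, cols, k] <- acc[rows, cols, k] + p[, , k]
    cov[rows, cols] <- cov[rows, cols] + 1
  }
  for (k in seq_len(dim(acc)[3])) acc[, , k] <- acc[, , k] / cov
  acc
}

# Closed-form FCN-8 parameter count from the architecture description
# alone (kernel arithmetic, no package code).
oracle_param_count <- function(width = 1, classes = 2, in_channels = 3) {
  f <- pmax(1, round(c(64, 128, 256, 512, 512) * width))
  head <- max(1, round(4096 * width))
  per_block <- c(2, 2, 3, 3, 3)
  total <- 0
  cin <- in_channels
  for (b in 1:5) {
    for (j in seq_len(per_block[b])) {
      total <- total + 3 * 3 * cin * f[b] + f[b]
      cin <- f[b]
    }
  }
  total <- total + 7 * 7 * f[5] * head + head        # conv6
  total <- total + 1 * 1 * head * head + head        # conv7
  total <- total + head * classes + classes          # score_fr
  total <- total + f[4] * classes + classes          # score_p4
  total <- total + f[3] * classes + classes          # score_p3
  total <- total + 2 * (4 * 4 * classes * classes + classes)  # x2 upsamplers
  total <- total + 16 * 16 * classes * classes + classes      # x8 upsampler
  total
}

# Stub predictors implementing the forward() contract.
constant_stub <- function(p_spike) {
  structure(list(p = p_spike), class = "constant_stub")
}
forward.constant_stub <- function(object, x, ...) {
  d <- dim(x)
  array(rep(c(1 - object$p, object$p), each = d[1] * d[2]),
        c(d[1], d[2], 2))
}

# Position-dependent stub: probability derived from the tile's pixel values
# so overlapping tiles genuinely disagree.
content_stub <- function() structure(list(), class = "content_stub")
forward.content_stub <- function(object, x, ...) {
  d <- dim(x)
  v <- 1 / (1 + exp(-(x[, , 1] - x[, , 2])))
  out <- array(0, c(d[1], d[2], 2))
  out[, , 1] <- 1 - v; out[, , 2] <- v
  out
}

registerS3method("forward", "constant_stub", forward.constant_stub,
                 envir = asNamespace("spikeseg"))
registerS3method("forward", "content_stub", forward.content_stub,
                 envir = asNamespace("spikeseg"))
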