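#' Pixel confusion tallies between a predicted and a true mask
#'
#' Exact per-class counts from which every segmentation metric derives:
#' true positives `tp` (equal to the correctly-predicted count `n_ii`),
#' false positives `fp`, false negatives `fn`, the class pixel totals
#' `t = n_ii + fn`, and the total pixel count `n_p`.
#'
#' @param pred,truth [binary_mask]s (or 0/1 matrices) of equal shape.
#' @param classes number of classes (2 for the binary spike task).
#' @return Object of class `confusion_counts` with vectors `tp`, `fp`,
#'   `fn`, `t` (one entry per class, class 0 first) and scalar `n_p`.
#' @export
confusion_counts <- function(pred, truth, classes = 2L) {
  pred <- unclass(pred); truth <- unclass(truth)
  if (!all(dim(pred) == dim(truth))) stop_("mask shape mismatch")
  tp <- fp <- fn <- tt <- numeric(classes)
  for (k in seq_len(classes) - 1L) {
    tp[k + 1] <- sum(pred == k & truth == k)
    fp[k + 1] <- sum(pred == k & truth != k)
    fn[k + 1] <- sum(pred != k & truth == k)
    tt[k + 1] <- sum(truth == k)
  }
  structure(list(tp = tp, fp = fp, fn = fn, t = tt,
                 n_p = length(truth)),
            class = "confusion_counts")
}

#' Pool confusion tallies across images
#' @param ... `confusion_counts` objects (or a single list of them).
#' @return Their elementwise sum.
#' @export
pool_confusion <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "confusion_counts")) xs <- xs[[1]]
  out <- xs[[1]]
  for (x in xs[-1]) {
    out$tp <- out$tp + x$tp; out$fp <- out$fp + x$fp
    out$fn <- out$fn + x$fn; out$t <- out$t + x$t
    out$n_p <- out$n_p + x$n_p
  }
  out
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts over %d px>\n", x$n_p))
  print(data.frame(class = seq_along(x$tp) - 1L, tp = x$tp, fp = x$fp,
                   fn = x$fn, total = x$t))
  invisible(x)
}

#' Global pixel accuracy
#'
#' Fraction of all pixels predicted correctly over all classes:
#' `GA = sum_i n_ii / n_p`. Note that under heavy class imbalance GA can be
#' high while the minority-class IoU is 0 (an all-background prediction on
#' a truth with spike prevalence `q` scores `GA = 1 - q`).
#'
#' @param counts a `confusion_counts`.
#' @return Proportion in `[0, 1]`.
#' @export
global_accuracy <- function(counts) {
  if (counts$n_p <= 0) stop_("empty image")
  sum(counts$tp) / counts$n_p
}

#' Per-class accuracy and its mean
#'
#' Class accuracy is `n_ii / t_i`, the fraction of a class's true pixels
#' predicted as that class; it is undefined when the class has no true
#' pixels (`t_i = 0`). `mean_class_accuracy` averages over the defined
#' classes only and flags exclusions via the `"excluded"` attribute.
#'
#' @param counts a `confusion_counts`.
#' @param class 0-based class index.
#' @return Proportion in `[0, 1]` (`NA` with a warning if undefined).
#' @export
class_accuracy <- function(counts, class) {
  i <- class + 1L
  if (counts$t[i] == 0) {
    warning(sprintf("class %d has no true pixels: accuracy undefined", class))
    return(NA_real_)
  }
  counts$tp[i] / counts$t[i]
}

#' @rdname class_accuracy
#' @export
mean_class_accuracy <- function(counts) {
  defined <- counts$t > 0
  acc <- ifelse(defined, counts$tp / pmax(counts$t, 1), NA_real_)
  out <- mean(acc[defined])
  attr(out, "excluded") <- which(!defined) - 1L
  out
}

#' Intersection over union per class and its mean
#'
#' `IoU = tp / (tp + fp + fn)`, the harshest of the segmentation metrics:
#' it penalises both false positives and false negatives. A class absent
#' from both prediction and truth (`tp + fp + fn = 0`) is excluded from the
#' mean and flagged.
#'
#' @param counts a `confusion_counts`.
#' @param class 0-based class index.
#' @return Proportion in `[0, 1]` (`NA` with a warning if the union is
#'   empty).
#' @export
iou <- function(counts, class) {
  i <- class + 1L
  u <- counts$tp[i] + counts$fp[i] + counts$fn[i]
  if (u == 0) {
    warning(sprintf("class %d absent from prediction and truth: IoU undefined",
                    class))
    return(NA_real_)
  }
  counts$tp[i] / u
}

#' @rdname iou
#' @export
mean_iou <- function(counts) {
  u <- counts$tp + counts$fp + counts$fn
  defined <- u > 0
  vals <- ifelse(defined, counts$tp / pmax(u, 1), NA_real_)
  out <- mean(vals[defined])
  attr(out, "excluded") <- which(!defined) - 1L
  out
}

# One metric-report row from pooled counts. Values are proportions; the
# percentage scale is formatting only.
metric_row <- function(counts, group = "overall") {
  suppressWarnings(data.frame(
    group = group,
    GA = global_accuracy(counts),
    MA = as.numeric(mean_class_accuracy(counts)),
    spike_acc = class_accuracy(counts, 1L),
    bg_acc = class_accuracy(counts, 0L),
    MIoU = as.numeric(mean_iou(counts)),
    spike_iou = iou(counts, 1L),
    bg_iou = iou(counts, 0L)))
}

#' Precision-recall curve over spike probability thresholds
#'
#' For each threshold `t` the spike-probability planes are binarized at
#' `>= t` and the confusion is pooled over all supplied images
#' (micro-averaging), giving one (precision, recall) point. Recall is
#' non-increasing in `t`; at `t = 0` every pixel is predicted spike so
#' recall is 1.
#'
#' @param prob_maps list of `(h, w)` spike-probability matrices (or
#'   `prediction_map`s).
#' @param truths list of matching [binary_mask]s.
#' @param thresholds ascending thresholds in `[0, 1]`.
#' @return `data.frame(threshold, precision, recall)`; precision is `NA`
#'   where nothing is predicted spike. If the truths contain no spike
#'   pixels, recall is undefined and the frame carries attribute
#'   `no_positives = TRUE`.
#' @export
precision_recall_curve <- function(prob_maps, truths,
                                   thresholds = seq(0, 1, length.out = 101)) {
  if (!is.list(prob_maps)) prob_maps <- list(prob_maps)
  if (!is.list(truths)) truths <- list(truths)
  prob_maps <- lapply(prob_maps, spike_probability_plane)
  stopifnot(length(prob_maps) == length(truths))
  pos <- sum(vapply(truths, function(t) sum(unclass(t) == 1L), 0))
  out <- data.frame(threshold = thresholds, precision = NA_real_,
                    recall = NA_real_)
  for (j in seq_along(thresholds)) {
    th <- thresholds[j]
    tp <- 0; fp <- 0
    for (i in seq_along(prob_maps)) {
      pred <- prob_maps[[i]] >= th
      tr <- unclass(truths[[i]]) == 1L
      tp <- tp + sum(pred & tr)
      fp <- fp + sum(pred & !tr)
    }
    out$precision[j] <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    out$recall[j] <- if (pos > 0) tp / pos else NA_real_
  }
  if (pos == 0) {
    warning("no spike pixels in truth: recall undefined")
    attr(out, "no_positives") <- TRUE
  }
  out
}

spike_probability_plane <- function(x) {
  if (inherits(x, "prediction_map")) return(x$probs[, , 2])
  if (length(dim(x)) == 3L) return(x[, , 2])
  x
}

#' Evaluate a model over a dataset manifest
#'
#' Runs sliding-window prediction and the argmax decision for every image,
#' pools the pixel confusion within each group and reports GA, MA,
#' per-class accuracy, MIoU and per-class IoU. The `"overall"` row pools
#' over all pixels of all images - it is not the mean of per-group means,
#' so with imbalanced groups the two differ.
#'
#' @param network anything with a [forward()] method.
#' @param manifest a `spikeseg_manifest`.
#' @param window,stride tiling parameters.
#' @param group_by `"overall"`, `"stage"` or `"image"`.
#' @return `data.frame` of metric rows (one per group plus the pooled
#'   `"overall"` row); attribute `per_image` holds the per-image rows.
#' @export
evaluate_dataset <- function(network, manifest, window = 512L,
                             stride = window,
                             group_by = c("overall", "stage", "image")) {
  group_by <- match.arg(group_by)
  if (nrow(manifest) == 0L) stop_("empty manifest")
  counts <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    pr <- manifest_pair(manifest, i)
    d <- dim(pr$image$pixels)
    map <- sliding_window_predict(network, pr$image,
                                  min(window, d[1], d[2]), stride)
    counts[[i]] <- confusion_counts(prediction_to_mask(map), pr$mask)
  }
  per_image <- do.call(rbind, lapply(seq_along(counts), function(i)
    metric_row(counts[[i]], manifest$id[i])))
  overall <- metric_row(pool_confusion(counts), "overall")
  out <- switch(group_by,
    overall = overall,
    image = rbind(per_image, overall),
    stage = {
      groups <- lapply(split(seq_len(nrow(manifest)), manifest$stage),
                       function(ix) pool_confusion(counts[ix]))
      stage_rows <- do.call(rbind, lapply(names(groups), function(g)
        metric_row(groups[[g]], g)))
      ord <- order(match(stage_rows$group, GROWTH_STAGES))
      rbind(stage_rows[ord, ], overall)
    })
  rownames(out) <- NULL
  attr(out, "per_image") <- per_image
  out
}

#' Max-pool activation maps of the encoder blocks
#'
#' Returns the max-pool output tensor of each requested encoder block -
#' the intermediate features used to inspect what the network responds to
#' (early blocks: edges and spikelet-scale detail; deep blocks: coarse
#' size/texture evidence of spike regions).
#'
#' @param network an `fcn8_net` or `fcn8_fit`.
#' @param image a [plot_image] or `(h, w, 3)` array.
#' @param blocks subset of `1:5`.
#' @return Named list `P<block>` of `(h/2^b, w/2^b, filters)` arrays.
#' @export
activation_maps <- function(network, image, blocks = c(1L, 3L, 5L)) {
  if (!all(blocks %in% 1:5)) stop_("blocks must be a subset of 1..5")
  if (inherits(network, "fcn8_fit")) {
    x <- if (inherits(image, "plot_image")) image$pixels else image
    for (k in 1:3) x[, , k] <- x[, , k] - network$channel_means[k]
    net <- network$network
  } else {
    net <- network
    x <- if (inherits(image, "plot_image")) image$pixels else image
  }
  fw <- fcn8_forward(net, x, want_taps = TRUE)
  fw$taps[sprintf("P%d", sort(unique(as.integer(blocks))))]
}

#' Render an activation-map grid to PNG
#'
#' Normalizes each requested channel to `[0, 1]` and tiles them into a
#' grayscale grid for visual inspection.
#'
#' @param maps one element of [activation_maps()] output.
#' @param path output PNG path.
#' @param channels which feature channels to show (default up to 16).
#' @export
render_activation_grid <- function(maps, path,
                                   channels = seq_len(min(16, dim(maps)[3]))) {
  d <- dim(maps)
  ncol_ <- ceiling(sqrt(length(channels)))
  nrow_ <- ceiling(length(channels) / ncol_)
  canvas <- matrix(0, nrow_ * (d[1] + 2), ncol_ * (d[2] + 2))
  for (i in seq_along(channels)) {
    m <- maps[, , channels[i]]
    rng <- range(m)
    if (diff(rng) > 0) m <- (m - rng[1]) / diff(rng)
    r0 <- ((i - 1) %/% ncol_) * (d[1] + 2)
    c0 <- ((i - 1) %% ncol_) * (d[2] + 2)
    canvas[r0 + seq_len(d[1]), c0 + seq_len(d[2])] <- m
  }
  png::writePNG(canvas, path)
  invisible(path)
}
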