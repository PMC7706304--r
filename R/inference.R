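#' Sliding-window prediction over a full image
#'
#' Forwards every tile of [tile_positions()] through the network and
#' assembles a full-resolution prediction map: per-pixel class probabilities
#' are accumulated over all tiles covering the pixel and divided by the
#' coverage count (probability averaging keeps each pixel on the simplex
#' and is order-independent). With `window` equal to the image extent the
#' result equals the direct forward pass exactly.
#'
#' @param network anything with a [forward()] method (an `fcn8_net`, an
#'   `fcn8_fit`, or a stub).
#' @param image a [plot_image] or `(h, w, 3)` array.
#' @param window square tile side, px.
#' @param stride tile step, px; default `window` (non-overlapping, clamped
#'   at the far edges).
#' @return Object of class `prediction_map`: `probs` (`(h, w, cl)` array),
#'   `coverage` (`(h, w)` integer matrix, >= 1 everywhere).
#' @export
sliding_window_predict <- function(network, image, window, stride = window) {
  x <- if (inherits(image, "plot_image")) image$pixels else image
  d <- dim(x)
  grid <- tile_positions(d[1], d[2], window, stride)
  probs <- NULL
  coverage <- matrix(0L, d[1], d[2])
  for (i in seq_len(nrow(grid$offsets))) {
    r <- grid$offsets$row[i]; c <- grid$offsets$col[i]
    rows <- (r + 1):(r + window); cols <- (c + 1):(c + window)
    p <- forward(network, x[rows, cols, , drop = FALSE])
    if (is.null(probs)) probs <- array(0, c(d[1], d[2], dim(p)[3]))
    probs[rows, cols, ] <- probs[rows, cols, , drop = FALSE] + p
    coverage[rows, cols] <- coverage[rows, cols] + 1L
  }
  for (k in seq_len(dim(probs)[3]))
    probs[, , k] <- probs[, , k] / coverage
  structure(list(probs = probs, coverage = coverage),
            class = "prediction_map")
}

#' @export
print.prediction_map <- function(x, ...) {
  d <- dim(x$probs)
  cat(sprintf("<prediction_map %dx%d px, %d classes, coverage %d-%d>\n",
              d[1], d[2], d[3], min(x$coverage), max(x$coverage)))
  invisible(x)
}

#' Final per-pixel class decision
#'
#' Argmax over the two class probabilities; an exact tie goes to background
#' (class 0), so an uninformative uniform map yields an all-background mask.
#'
#' @param map a `prediction_map` (or bare `(h, w, 2)` probability array)
#'   with two classes.
#' @return A [binary_mask].
#' @export
prediction_to_mask <- function(map) {
  p <- if (inherits(map, "prediction_map")) map$probs else map
  if (dim(p)[3] != 2L)
    stop_("binary mask export needs exactly 2 classes (got %d)", dim(p)[3])
  binary_mask((p[, , 2] > p[, , 1]) * 1L)
}

#' Spike-probability plane of a prediction map
#' @param map a `prediction_map`.
#' @return `(h, w)` matrix of spike (class 1) probabilities.
#' @export
spike_probability <- function(map) {
  p <- if (inherits(map, "prediction_map")) map$probs else map
  p[, , 2]
}
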