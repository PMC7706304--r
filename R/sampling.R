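#' Randomly sample training subimages from a dataset
#'
#' Draws `n` square windows by choosing a source image uniformly, then a
#' fully in-bounds top-left offset uniformly (unstratified: no balancing on
#' spike content, though `min_spike_frac` can impose a floor). The submask
#' is cut from the same offset as the subimage. Deterministic under `seed`.
#'
#' @param manifest a `spikeseg_manifest`.
#' @param window square window side, px; must not exceed the smallest image
#'   dimension in the manifest.
#' @param n number of subimages.
#' @param seed integer seed.
#' @param pixels materialize pixel data (`TRUE`) or return the index only
#'   (`FALSE`), useful for very large draws that are consumed lazily.
#' @param min_spike_frac optional minimum spike-pixel fraction per subimage;
#'   draws below it are rejected and redrawn (default 0 = off).
#' @return A list of class `subimage_set`: `index` (data.frame with
#'   `source_id, row, col`, 0-based offsets), `window`, and - when
#'   materialized - `samples`, a list of `list(x = (window,window,3) array,
#'   y = (window,window) 0/1 matrix)`.
#' @export
sample_subimages <- function(manifest, window, n, seed = 1, pixels = TRUE,
                             min_spike_frac = 0) {
  if (nrow(manifest) == 0L) stop_("empty manifest")
  if (n < 1) stop_("n must be >= 1")
  dims <- matrix(NA_integer_, nrow(manifest), 2)
  cache <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    pr <- manifest_pair(manifest, i)
    dims[i, ] <- dim(pr$image$pixels)[1:2]
    cache[[i]] <- pr
  }
  if (window > min(dims)) stop_("window (%d px) larger than smallest image (%d px)",
                                window, min(dims))
  idx <- data.frame(source_id = character(n), row = integer(n),
                    col = integer(n))
  samples <- if (pixels) vector("list", n) else NULL
  with_seed(seed, {
    for (k in seq_len(n)) {
      repeat {
        i <- sample.int(nrow(manifest), 1)
        r <- sample.int(dims[i, 1] - window + 1L, 1) - 1L
        c <- sample.int(dims[i, 2] - window + 1L, 1) - 1L
        if (min_spike_frac <= 0) break
        y <- cache[[i]]$mask[(r + 1):(r + window), (c + 1):(c + window)]
        if (mean(y) >= min_spike_frac) break
      }
      idx$source_id[k] <- manifest$id[i]
      idx$row[k] <- r; idx$col[k] <- c
      if (pixels)
        samples[[k]] <- list(
          x = cache[[i]]$image$pixels[(r + 1):(r + window),
                                      (c + 1):(c + window), , drop = FALSE],
          y = unclass(cache[[i]]$mask)[(r + 1):(r + window),
                                       (c + 1):(c + window)])
    }
  })
  structure(list(index = idx, window = as.integer(window), samples = samples),
            class = "subimage_set")
}

#' @export
print.subimage_set <- function(x, ...) {
  cat(sprintf("<subimage_set: %d windows of %dx%d px%s>\n",
              nrow(x$index), x$window, x$window,
              if (is.null(x$samples)) " (index only)" else ""))
  invisible(x)
}

#' Deterministic tile grid for sliding-window inference
#'
#' Top-left offsets at multiples of `stride`; when the regular grid would
#' overshoot, a final row/column tile is clamped to `(h - window,
#' w - window)` so that every pixel is covered. Tiles are clamped, never
#' padded - no pixel content is invented at borders.
#'
#' @param h,w image extent, px.
#' @param window square tile side, px.
#' @param stride step between tiles, px, at most `window` (default `window`:
#'   non-overlapping).
#' @return List of class `tile_grid`: `offsets` (data.frame `row, col`,
#'   0-based), `window`, `stride`, `h`, `w`.
#' @export
tile_positions <- function(h, w, window, stride = window) {
  if (window < 1 || stride < 1) stop_("window and stride must be >= 1")
  if (stride > window)
    stop_("stride (%d) larger than window (%d) would leave uncovered gaps",
          stride, window)
  if (window > min(h, w)) stop_("window (%d px) larger than image (%dx%d)",
                                window, h, w)
  axis_offsets <- function(extent) {
    off <- seq.int(0L, max(extent - window, 0L), by = stride)
    if (off[length(off)] < extent - window) off <- c(off, extent - window)
    as.integer(off)
  }
  ro <- axis_offsets(h); co <- axis_offsets(w)
  structure(list(offsets = expand.grid(row = ro, col = co,
                                       KEEP.OUT.ATTRS = FALSE),
                 window = as.integer(window), stride = as.integer(stride),
                 h = as.integer(h), w = as.integer(w)),
            class = "tile_grid")
}
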