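#' Stage-specific defaults for the scene generator
#'
#' Returns the spike count range, ellipse axis ranges (px) and base colour
#' for one growth stage. The defaults encode the phenology the generator
#' emulates: few, small, partly hidden greenish spikes at booting; more and
#' larger spikes through heading into flowering; at grain filling counts
#' comparable to flowering but slightly larger spikes with the hue shifted
#' toward gold. Expected spike-pixel fraction is therefore non-decreasing
#' booting -> heading -> flowering, and flowering vs grain filling are
#' comparable.
#'
#' @param stage one of [GROWTH_STAGES].
#' @return List with `count_range`, `major_range`, `minor_range`, `colour`
#'   (RGB in `[0,1]`).
#' @export
default_stage_params <- function(stage) {
  stage <- match.arg(stage, GROWTH_STAGES)
  switch(stage,
    booting = list(count_range = c(0L, 2L), major_range = c(8, 14),
                   minor_range = c(2.5, 4.5), colour = c(0.55, 0.62, 0.30)),
    heading = list(count_range = c(3L, 8L), major_range = c(10, 18),
                   minor_range = c(3, 6), colour = c(0.65, 0.66, 0.32)),
    flowering = list(count_range = c(8L, 16L), major_range = c(14, 24),
                     minor_range = c(4, 8), colour = c(0.76, 0.68, 0.36)),
    grain_filling = list(count_range = c(8L, 16L), major_range = c(16, 26),
                         minor_range = c(5, 9), colour = c(0.82, 0.66, 0.28)))
}

#' Scene generator parameters
#'
#' Assembles the full parameter set for [generate_scene()]. Defaults emulate
#' the structure of field plot imagery at desk scale: a sky band at the top,
#' a textured green canopy with vertical stem strokes, soil patches near the
#' bottom, spikes rendered as textured ellipses with awn strokes,
#' multiplicative illumination variation (over-exposed "sunny" scenes clip
#' at channel max), additive sensor noise, and grass-like distractor regions
#' that share the canopy hue but carry a spike-like texture frequency (the
#' false-positive regime seen in real fields).
#'
#' @param stage growth stage whose spike defaults to merge (see
#'   [default_stage_params()]); may be `NULL` if count/size ranges are given
#'   explicitly via `...`.
#' @param h,w scene extent in pixels.
#' @param sky_frac fraction of rows occupied by the sky band.
#' @param illum_range range of the global illumination multiplier (> 0).
#' @param noise_sd standard deviation of additive Gaussian channel noise.
#' @param grass_prob probability that the scene contains grass distractors.
#' @param grass_size side of a grass patch, px.
#' @param ... overrides for any stage field (`count_range`, `major_range`,
#'   `minor_range`, `colour`).
#' @return List of class `scene_params`.
#' @export
scene_params <- function(stage = "flowering", h = 192, w = 192,
                         sky_frac = 0.15, illum_range = c(0.7, 1.35),
                         noise_sd = 0.02, grass_prob = 0.5, grass_size = 28,
                         ...) {
  base <- if (is.null(stage)) list() else default_stage_params(stage)
  p <- modifyList(c(list(stage = stage, h = as.integer(h), w = as.integer(w),
                         sky_frac = sky_frac, illum_range = illum_range,
                         noise_sd = noise_sd, grass_prob = grass_prob,
                         grass_size = grass_size), base),
                  list(...))
  if (p$h < 8 || p$w < 8) stop_("degenerate scene size")
  if (any(p$illum_range <= 0)) stop_("illumination multiplier must be > 0")
  if (diff(range(p$count_range)) < 0 || diff(range(p$major_range)) < 0)
    stop_("parameter ranges must be non-empty")
  if (max(p$major_range) * 2 > min(p$h, p$w))
    stop_("spike axes larger than image")
  class(p) <- "scene_params"
  p
}

# Smooth 2-d noise in [0,1]: coarse uniform grid, bilinearly upsampled.
smooth_noise <- function(h, w, cells = 8) {
  g <- matrix(runif((cells + 1)^2), cells + 1, cells + 1)
  ri <- seq(1, cells + 1, length.out = h)
  ci <- seq(1, cells + 1, length.out = w)
  r0 <- pmin(floor(ri), cells); c0 <- pmin(floor(ci), cells)
  fr <- ri - r0; fc <- ci - c0
  a <- g[cbind(rep(r0, w), rep(c0, each = h))]
  b <- g[cbind(rep(r0 + 1, w), rep(c0, each = h))]
  cc <- g[cbind(rep(r0, w), rep(c0 + 1, each = h))]
  d <- g[cbind(rep(r0 + 1, w), rep(c0 + 1, each = h))]
  fr <- rep(fr, w); fc <- rep(fc, each = h)
  matrix((1 - fr) * (1 - fc) * a + fr * (1 - fc) * b +
         (1 - fr) * fc * cc + fr * fc * d, h, w)
}

# Paint an ellipse (plus awn strokes) into colour planes and the footprint
# mask. Returns the updated list(img, mask).
render_spike <- function(img, mask, cr, cc, a, b, theta, colour, h, w) {
  pad <- ceiling(a + 4)
  rs <- max(1, floor(cr - pad)):min(h, ceiling(cr + pad))
  cs <- max(1, floor(cc - pad)):min(w, ceiling(cc + pad))
  R <- outer(rs - cr, rep(1, length(cs)))
  C <- outer(rep(1, length(rs)), cs - cc)
  u <- cos(theta) * R + sin(theta) * C
  v <- -sin(theta) * R + cos(theta) * C
  inside <- (u / a)^2 + (v / b)^2 <= 1
  if (!any(inside)) return(list(img = img, mask = mask))
  # spikelet texture: brightness ripple along the major axis
  ripple <- 0.85 + 0.3 * abs(sin(u * pi / max(2.5, b)))
  shade <- 1 - 0.25 * (abs(v) / b)^2
  jit <- colour * runif(1, 0.9, 1.1)
  for (k in 1:3) {
    plane <- img[, , k]
    vals <- pmin(1, jit[k] * ripple[inside] * shade[inside])
    plane[rs, cs][inside] <- vals
    img[, , k] <- plane
  }
  mask[rs, cs][inside] <- 1L
  # awns: short bright strokes off the spike tip, part of the footprint
  tip_r <- cr - a * cos(theta); tip_c <- cc - a * sin(theta)
  for (s in seq_len(3 + floor(runif(1) * 3))) {
    ang <- theta + runif(1, -0.5, 0.5)
    len <- runif(1, 2, max(3, a * 0.35))
    t <- seq(0, len, by = 0.5)
    ar <- round(tip_r - t * cos(ang)); ac <- round(tip_c - t * sin(ang))
    ok <- ar >= 1 & ar <= h & ac >= 1 & ac <= w
    if (!any(ok)) next
    ix <- cbind(ar[ok], ac[ok])
    for (k in 1:3) {
      plane <- img[, , k]
      plane[ix] <- pmin(1, jit[k] * 1.05)
      img[, , k] <- plane
    }
    mask[ix] <- 1L
  }
  list(img = img, mask = mask)
}

#' Generate one synthetic wheat-plot scene with its exact mask
#'
#' Composites sky, textured canopy with stem strokes, soil patches, spikes
#' (textured ellipses with awn strokes) and optional grass distractors, then
#' applies an illumination field and additive noise. The returned mask is
#' exactly the union of rendered spike footprints (awns included);
#' distractors, illumination and noise never touch the mask. The same
#' `(stage, params, seed)` reproduces bit-identical output.
#'
#' @param stage one of [GROWTH_STAGES].
#' @param params a [scene_params()]; built from the stage defaults if `NULL`.
#' @param seed integer RNG seed.
#' @return List with `image` ([plot_image]) and `mask` ([binary_mask]).
#' @export
generate_scene <- function(stage = "flowering", params = NULL, seed = 1) {
  stage <- match.arg(stage, GROWTH_STAGES)
  p <- params %||% scene_params(stage)
  h <- p$h; w <- p$w
  with_seed(seed, {
    img <- array(0, c(h, w, 3))
    sky_h <- max(1, round(p$sky_frac * h))
    # sky: pale blue-white with a soft gradient and cloud mottling
    grad <- seq(1, 0.75, length.out = sky_h)
    cloud <- smooth_noise(sky_h, w, 5) * 0.15
    img[1:sky_h, , 1] <- 0.70 * grad + cloud
    img[1:sky_h, , 2] <- 0.80 * grad + cloud
    img[1:sky_h, , 3] <- 0.92 * grad + cloud
    # canopy: green base modulated by low-frequency texture
    cr_ <- (sky_h + 1):h
    tex <- smooth_noise(length(cr_), w, 10)
    img[cr_, , 1] <- 0.16 + 0.12 * tex
    img[cr_, , 2] <- 0.34 + 0.20 * tex
    img[cr_, , 3] <- 0.12 + 0.08 * tex
    # stems: thin lighter vertical strokes
    for (s in seq_len(round(w / 6))) {
      x0 <- sample.int(w, 1)
      top <- sample((sky_h + 1):max(sky_h + 1, h - 20), 1)
      rows <- top:h
      cols <- pmin(w, pmax(1, round(x0 + (rows - top) * runif(1, -0.08, 0.08))))
      ix <- cbind(rows, cols)
      img[, , 1][ix] <- 0.25; img[, , 2][ix] <- 0.48; img[, , 3][ix] <- 0.18
    }
    # soil patches near the bottom
    for (s in seq_len(3)) {
      pr <- sample(max(sky_h + 1, h - round(0.25 * h)):h, 1)
      pc <- sample.int(w, 1)
      rr <- max(1, pr - 6):min(h, pr + 6)
      cc <- max(1, pc - 10):min(w, pc + 10)
      img[rr, cc, 1] <- 0.42; img[rr, cc, 2] <- 0.30; img[rr, cc, 3] <- 0.18
    }
    mask <- matrix(0L, h, w)
    n_spikes <- p$count_range[1] +
      sample.int(p$count_range[2] - p$count_range[1] + 1L, 1) - 1L
    for (s in seq_len(n_spikes)) {
      a <- runif(1, p$major_range[1], p$major_range[2])
      b <- runif(1, p$minor_range[1], p$minor_range[2])
      cr0 <- runif(1, sky_h + a + 1, h - a - 1)
      cc0 <- runif(1, a + 1, w - a - 1)
      theta <- runif(1, -pi / 6, pi / 6)
      res <- render_spike(img, mask, cr0, cc0, a, b, theta, p$colour, h, w)
      img <- res$img; mask <- res$mask
    }
    # grass distractors: canopy hue, spike-like stripe frequency; background
    # by construction (mask untouched)
    if (runif(1) < p$grass_prob) {
      for (g in seq_len(2)) {
        gs <- p$grass_size
        gr <- sample(max(sky_h + 1, h - 2 * gs):max(sky_h + 2, h - gs), 1)
        gc <- sample.int(max(1, w - gs), 1)
        rr <- gr:min(h, gr + gs - 1)
        cc <- gc:min(w, gc + gs - 1)
        stripe <- 0.8 + 0.35 * abs(sin(outer(rr, cc, "+") * pi / 4))
        img[rr, cc, 1] <- pmin(1, 0.30 * stripe)
        img[rr, cc, 2] <- pmin(1, 0.46 * stripe)
        img[rr, cc, 3] <- pmin(1, 0.16 * stripe)
      }
    }
    # illumination: global multiplier x smooth gradient; sunny scenes clip
    illum <- runif(1, p$illum_range[1], p$illum_range[2])
    dir_r <- runif(1, -0.15, 0.15); dir_c <- runif(1, -0.15, 0.15)
    field <- illum * (1 + dir_r * (row(mask) / h - 0.5) +
                        dir_c * (col(mask) / w - 0.5))
    for (k in 1:3) img[, , k] <- img[, , k] * field
    img <- img + array(rnorm(h * w * 3, 0, p$noise_sd), c(h, w, 3))
    img <- pmin(pmax(img, 0), 1)
    list(image = plot_image(img, id = sprintf("synth_%s_%d", stage, seed),
                            stage = stage),
         mask = binary_mask(mask))
  })
}

#' Generate a synthetic season and write it to disk
#'
#' Writes `n_images` image/mask PNG pairs plus a manifest CSV. Realized
#' per-stage counts follow `stage_mix` by largest-remainder rounding, so
#' e.g. 90 images with mix `c(12, 22, 37, 19)/90` yield exactly 12 booting,
#' 22 heading, 37 flowering and 19 grain-filling scenes. Deterministic under
#' `seed`.
#'
#' @param n_images number of scenes.
#' @param stage_mix per-stage proportions in [GROWTH_STAGES] order; must sum
#'   to 1 (within 1e-6). The default mirrors a realistic field campaign in
#'   which flowering is the most frequently imaged stage.
#' @param params optional [scene_params()] overriding scene structure; the
#'   stage-specific spike ranges are still taken per stage.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @param year year recorded in the manifest (split role follows it).
#' @return The written manifest (invisibly reloadable via
#'   [load_manifest()]).
#' @export
generate_season <- function(n_images, stage_mix = c(12, 22, 37, 19) / 90,
                            params = NULL, seed = 1, dir = tempfile("season"),
                            year = 2015L) {
  if (n_images < 1) stop_("n_images must be >= 1")
  if (length(stage_mix) != 4L || any(stage_mix < 0) ||
      abs(sum(stage_mix) - 1) > 1e-6)
    stop_("stage_mix must be 4 non-negative proportions summing to 1")
  counts <- largest_remainder(stage_mix * n_images)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stages <- rep(GROWTH_STAGES, counts)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    st <- stages[i]
    p <- if (is.null(params)) scene_params(st) else {
      frag <- default_stage_params(st)
      modifyList(params, c(frag, list(stage = st)))
    }
    class(p) <- "scene_params"
    sc <- generate_scene(st, p, seed = (seed * 1000L + i) %% .Machine$integer.max)
    id <- sprintf("img_%03d", i)
    write_image(sc$image, file.path(dir, paste0(id, ".png")))
    write_mask(sc$mask, file.path(dir, paste0(id, "_mask.png")))
    rows[[i]] <- data.frame(id = id, image = paste0(id, ".png"),
                            mask = paste0(id, "_mask.png"),
                            year = year, stage = st)
  }
  df <- do.call(rbind, rows)
  write_manifest(df, file.path(dir, "manifest.csv"))
  load_manifest(file.path(dir, "manifest.csv"), validate = FALSE)
}

# Largest-remainder rounding of non-negative reals to integers preserving
# the (integer) total.
largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}
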