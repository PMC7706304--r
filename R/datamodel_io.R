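#' Plot image container
#'
#' Bundles an RGB pixel array with its identity and field metadata. Pixels
#' are stored as a numeric array with `dim = c(h, w, 3)` (rows, columns,
#' channels), origin top-left, values in `[0, 1]` (the normalized form,
#' flagged by `normalized = TRUE`).
#'
#' @param pixels numeric array `(h, w, 3)` with values in `[0, 1]`.
#' @param id character identifier.
#' @param year integer acquisition year (drives the train/val/test split).
#' @param stage one of [GROWTH_STAGES], or `NA`.
#' @return An object of class `plot_image`.
#' @export
plot_image <- function(pixels, id = NA_character_, year = NA_integer_,
                       stage = NA_character_) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) stop_("pixels must be an (h, w, 3) array")
  if (d[1] < 1L || d[2] < 1L) stop_("image must have positive extent")
  if (!is.na(stage) && !stage %in% GROWTH_STAGES)
    stop_("unknown growth stage '%s'", stage)
  structure(list(pixels = pixels, id = id, year = as.integer(year),
                 stage = stage, normalized = TRUE),
            class = "plot_image")
}

#' @export
print.plot_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<plot_image '%s' %dx%d px, year %s, stage %s>\n",
              x$id, d[1], d[2], x$year, x$stage))
  invisible(x)
}

#' Binary spike mask
#'
#' A per-pixel class map aligned to a [plot_image]: 0 = background,
#' 1 = spike. Stored as an integer matrix with the same (h, w) as the image
#' it annotates, so `labels[r, c]` labels `pixels[r, c, ]`.
#'
#' @param labels matrix of 0/1 values.
#' @return Integer matrix of class `binary_mask`.
#' @export
binary_mask <- function(labels) {
  labels <- as.matrix(labels)
  if (!all(labels %in% c(0L, 1L))) stop_("mask values must be 0 or 1")
  structure(matrix(as.integer(labels), nrow(labels), ncol(labels)),
            class = c("binary_mask", "matrix"))
}

decode_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop_("file not found: %s", path)
  px <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop_("unsupported image format '.%s' (PNG/JPEG/TIFF)", ext))
  px
}

#' Read an RGB plot image
#'
#' Decodes a PNG/JPEG/TIFF file into a [plot_image]. Grayscale inputs are
#' replicated to three channels; an alpha channel is dropped; more than four
#' channels is an error.
#'
#' @param path file path.
#' @param id,year,stage metadata attached to the result; `id` defaults to
#'   the file name without extension.
#' @return A [plot_image] with values in `[0, 1]`.
#' @export
read_image <- function(path, id = NULL, year = NA_integer_,
                       stage = NA_character_) {
  px <- decode_raster(path)
  if (is.matrix(px)) px <- array(px, c(dim(px), 1L))
  nc <- dim(px)[3]
  if (nc == 1L) px <- array(rep(px, 3L), c(dim(px)[1:2], 3L))
  else if (nc == 4L) px <- px[, , 1:3, drop = FALSE]
  else if (nc != 3L) stop_("unsupported channel count (%d) in %s", nc, path)
  plot_image(px, id = id %||% tools::file_path_sans_ext(basename(path)),
             year = year, stage = stage)
}

#' Read a binary spike mask
#'
#' Reads a single-channel (or channel-identical RGB) mask file and
#' binarizes it: 8-bit intensities at or above `threshold` become spike (1),
#' the rest background (0). The default threshold of 128 is robust to
#' anti-aliased annotation exports.
#'
#' @param path PNG/TIFF mask file.
#' @param threshold intensity cut on the 0-255 scale.
#' @return A [binary_mask].
#' @export
read_mask <- function(path, threshold = 128) {
  px <- decode_raster(path)
  if (!is.matrix(px)) {
    nc <- dim(px)[3]
    if (nc == 4L) px <- px[, , 1:3, drop = FALSE]
    if (dim(px)[3] == 3L) {
      if (max(abs(px[, , 1] - px[, , 2])) > 0 ||
          max(abs(px[, , 1] - px[, , 3])) > 0)
        stop_("mask channels disagree in %s: not a binary annotation", path)
    }
    px <- px[, , 1]
  }
  binary_mask((px >= threshold / 255) * 1L)
}

#' Write a binary mask as a single-channel PNG
#'
#' Spike pixels are written as 255, background as 0, so the file round-trips
#' through [read_mask()] to the identical mask.
#'
#' @param mask a [binary_mask] (or plain 0/1 matrix).
#' @param path output path (PNG).
#' @export
write_mask <- function(mask, path) {
  m <- unclass(mask)
  if (!all(m %in% c(0L, 1L))) stop_("mask values must be 0 or 1")
  png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)), path)
  invisible(path)
}

#' Write a plot image as PNG
#' @param image a [plot_image].
#' @param path output path.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image$pixels, 0), 1), path)
  invisible(path)
}

default_year_roles <- c("2015" = "train", "2016" = "validation",
                        "2017" = "test")

#' Load and validate a dataset manifest
#'
#' Reads a CSV with columns `id,image,mask,year,stage` (and optionally
#' `role`). Paths are resolved relative to the CSV's directory. Each stage
#' token must be one of [GROWTH_STAGES]. When `validate = TRUE` every
#' referenced file must exist and each image/mask pair must agree in
#' spatial dimensions. Split roles default to the year key (2015 train,
#' 2016 validation, 2017 test) but an explicit `role` column overrides this
#' - the year assignment is a study convention, not part of the method.
#'
#' @param path CSV file.
#' @param validate check file existence and image/mask dimension agreement.
#' @return A `data.frame` of class `spikeseg_manifest` with columns
#'   `id, image, mask, year, stage, role`; row order matches the CSV.
#' @export
load_manifest <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop_("manifest not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "image", "mask", "year", "stage")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_("manifest missing column(s): %s",
                          paste(miss, collapse = ", "))
  bad <- which(!df$stage %in% GROWTH_STAGES)
  if (length(bad))
    stop_("row %d: unknown growth stage '%s'", bad[1], df$stage[bad[1]])
  root <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(root, p))
  df$image <- resolve(df$image)
  df$mask <- resolve(df$mask)
  df$year <- as.integer(df$year)
  if (is.null(df$role)) {
    df$role <- unname(default_year_roles[as.character(df$year)])
    if (anyNA(df$role))
      warning("years outside 2015-2017 have no default split role; ",
              "add a 'role' column to assign them")
  }
  if (validate) {
    for (i in seq_len(nrow(df))) {
      if (!file.exists(df$image[i])) stop_("row %d: missing image %s", i, df$image[i])
      if (!file.exists(df$mask[i])) stop_("row %d: missing mask %s", i, df$mask[i])
      im <- read_image(df$image[i])
      mk <- read_mask(df$mask[i])
      if (!all(dim(im$pixels)[1:2] == dim(mk)))
        stop_("row %d: image (%dx%d) and mask (%dx%d) dimensions differ",
              i, dim(im$pixels)[1], dim(im$pixels)[2], dim(mk)[1], dim(mk)[2])
    }
  }
  class(df) <- c("spikeseg_manifest", "data.frame")
  df
}

#' Write a dataset manifest CSV
#' @param manifest a `spikeseg_manifest` (or compatible data.frame).
#' @param path output CSV path; image/mask paths are written relative to it
#'   when possible.
#' @export
write_manifest <- function(manifest, path) {
  df <- as.data.frame(manifest)
  root <- normalizePath(dirname(path))
  rel <- function(p) {
    ap <- normalizePath(p, mustWork = FALSE)
    ifelse(startsWith(ap, paste0(root, "/")),
           substring(ap, nchar(root) + 2L), ap)
  }
  df$image <- rel(df$image); df$mask <- rel(df$mask)
  write.csv(df[, intersect(c("id", "image", "mask", "year", "stage", "role"),
                           names(df))], path, row.names = FALSE)
  invisible(path)
}

# Read an image/mask pair for one manifest row.
manifest_pair <- function(manifest, i) {
  r <- manifest[i, ]
  list(image = read_image(r$image, id = r$id, year = r$year, stage = r$stage),
       mask = read_mask(r$mask))
}
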