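# Programmatic fixtures: tiny images, masks and manifests built in temp
# directories at test time.

write_tiny_dataset <- function(dir, n = 2, h = 48, w = 48,
                               stages = rep("flowering", n),
                               years = rep(2015L, n), seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_len(n), function(i) {
    sc <- generate_scene(stages[i], scene_params(stages[i], h = h, w = w,
                                                 major_range = c(4, 8),
                                                 minor_range = c(2, 3)),
                         seed = seed + i)
    id <- sprintf("t%02d", i)
    write_image(sc$image, file.path(dir, paste0(id, ".png")))
    write_mask(sc$mask, file.path(dir, paste0(id, "_mask.png")))
    data.frame(id = id, image = paste0(id, ".png"),
               mask = paste0(id, "_mask.png"),
               year = years[i], stage = stages[i])
  })
  write_manifest(do.call(rbind, rows), file.path(dir, "manifest.csv"))
  file.path(dir, "manifest.csv")
}

random_mask <- function(h, w, p = 0.3) {
  binary_mask(matrix(rbinom(h * w, 1, p), h, w))
}

# The trained desk-scale model is expensive; compute it once per test run
# and share it across acceptance blocks.
bench_cache <- new.env(parent = emptyenv())
get_benchmark <- function() {
  if (is.null(bench_cache$res))
    bench_cache$res <- synthetic_benchmark(seed = 7)
  bench_cache$res
}
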