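# shared fixtures, built once per test session

clamp <- rcpscope:::clamp

.fixture_env <- new.env(parent = emptyenv())

# memoize expensive rendered scenes across test files
fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# a mid-size two-channel scene with artifacts, used by several files
std_scene <- function() fixture("std_scene", function() {
  cfg <- scene_config(image_height_px = 512, image_width_px = 512,
                      spot_density = 120, artifact_density = 25,
                      peak_snr = 8, mutant_fraction = 0.5, seed = 421)
  scene <- render_scene(cfg)
  set <- suppressWarnings(preprocess_stacks(scene$stacks))
  list(scene = scene, set = set)
})

# minimal measured-objects table for base-calling unit tests;
# per-channel means/backgrounds given as named lists of equal length
make_measured_objects <- function(mean, bg_mean = NULL, bg_sd = 0.005) {
  n <- length(mean[[1]])
  df <- data.frame(object_id = seq_len(n))
  for (ch in names(mean)) {
    df[[paste0("mean_", ch)]] <- mean[[ch]]
    df[[paste0("bg_mean_", ch)]] <-
      if (is.null(bg_mean)) rep(0, n) else bg_mean[[ch]]
    df[[paste0("bg_sd_", ch)]] <- rep_len(bg_sd, n)
  }
  class(df) <- c("detected_objects", "data.frame")
  df
}

# detected_objects table from explicit pixel index sets
make_objects <- function(pixel_sets, dims) {
  h <- dims[1]
  rows <- vapply(pixel_sets, function(p) mean(((p - 1) %% h) + 1), numeric(1))
  cols <- vapply(pixel_sets, function(p) mean(((p - 1) %/% h) + 1), numeric(1))
  df <- data.frame(object_id = seq_along(pixel_sets), row = rows, col = cols,
                   area_px = lengths(pixel_sets),
                   eq_diameter_px = 2 * sqrt(lengths(pixel_sets) / pi),
                   channel = "cy3", threshold_used = 0.1)
  df$pixels <- pixel_sets
  class(df) <- c("detected_objects", "data.frame")
  df
}

# constant raster wrapped as a channel_image
const_image <- function(v, h = 32, w = 32, channel = "cy3")
  channel_image(channel, matrix(v, h, w))
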