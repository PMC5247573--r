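test_that("white top-hat flattens backgrounds and keeps small spots", {
  expect_equal(enhance_spots(const_image(0.25), 4)$data, matrix(0, 32, 32))
  # a ~3 px spot on a flat offset survives almost unchanged
  img <- matrix(0.1, 64, 64)
  for (r in 1:64) for (c in 1:64)
    img[r, c] <- img[r, c] + 0.3 * exp(-((r - 32)^2 + (c - 32)^2) / (2 * 1.3^2))
  enh <- enhance_spots(channel_image("cy3", clamp(img, 0, 1)), 4)$data
  expect_lt(abs(max(enh) - 0.3) / 0.3, 0.05)
  expect_lt(max(enh[1:16, 1:16]), 1e-6)
  # a gradient much broader than the disk is suppressed
  ramp <- matrix(rep(seq(0, 0.5, length.out = 128), each = 128), 128,
                 byrow = FALSE)
  out <- enhance_spots(channel_image("cy3", ramp), 4)$data
  expect_lt(max(out), 0.1 * 0.5)
  expect_error(enhance_spots(const_image(0.1), 0), "radius")
})

test_that("identify_objects finds constructed spots and applies gates", {
  h <- 128
  img <- matrix(0.01, h, h)
  centers <- cbind(seq(15, 105, by = 10), seq(105, 15, by = -10))
  sig <- seq(0.9, 1.6, length.out = 10)  # diameters roughly 3-6 px
  for (i in 1:10)
    for (r in -6:6) for (c in -6:6)
      img[centers[i, 1] + r, centers[i, 2] + c] <-
        img[centers[i, 1] + r, centers[i, 2] + c] +
        0.3 * exp(-(r^2 + c^2) / (2 * sig[i]^2))
  objs <- identify_objects(channel_image("cy3", clamp(img, 0, 1)),
                           detection_config(intensity_threshold = 0.1))
  expect_equal(nrow(objs), 10)
  truth <- data.frame(object_id = 1:10, row = centers[, 1],
                      col = centers[, 2])
  m <- match_to_truth(objs, truth, tol_px = 1)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)

  # a single suprathreshold pixel (diameter 1.13) is below the size gate
  speck <- matrix(0.01, 32, 32); speck[16, 16] <- 0.5
  expect_equal(nrow(identify_objects(channel_image("cy3", speck),
                                     detection_config())), 0)
  # a broad blob above the size gate is excluded too
  blob <- matrix(0.01, 64, 64)
  blob[outer(1:64, 1:64, function(r, c) (r - 32)^2 + (c - 32)^2 <= 36)] <- 0.5
  expect_equal(nrow(identify_objects(channel_image("cy3", blob),
                                     detection_config())), 0)
})

test_that("components are 8-connected", {
  img <- matrix(0.01, 16, 16)
  img[cbind(c(4, 5, 6, 7), c(4, 5, 6, 7))] <- 0.5  # diagonal chain
  objs <- identify_objects(channel_image("cy3", img),
                           detection_config(min_diameter_px = 1.5))
  expect_equal(nrow(objs), 1)
  expect_equal(objs$area_px, 4)
})

test_that("detection is deterministic, ordered, and monotone in threshold", {
  fx <- std_scene()
  enh <- enhance_spots(fx$set$images$cy3, 4)
  a <- identify_objects(enh, detection_config())
  b <- identify_objects(enh, detection_config())
  expect_identical(a, b)
  expect_true(!is.unsorted(a$row))
  counts <- vapply(c(0.08, 0.12, 0.16, 0.2, 0.3), function(t)
    nrow(identify_objects(enh, detection_config(intensity_threshold = t))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("adaptive thresholds stay within the 0.1-0.4 gate", {
  fx <- std_scene()
  enh <- enhance_spots(fx$set$images$cy3, 4)
  objs <- identify_objects(enh, detection_config(adaptive = TRUE))
  expect_gte(objs$threshold_used[1], 0.1)
  expect_lte(objs$threshold_used[1], 0.4)
})

test_that("detection recovers sparse synthetic scenes nearly perfectly", {
  cfg <- scene_config(image_height_px = 512, image_width_px = 512,
                      spot_density = 125, artifact_density = 0,
                      peak_snr = 5, mutant_fraction = 0.5, seed = 77)
  scene <- render_scene(cfg)
  set <- suppressWarnings(preprocess_stacks(scene$stacks))
  objs <- detect_scene(set)
  m <- match_to_truth(objs, scene$truth, tol_px = 2)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
})

test_that("measurement reports exact statistics on constant images", {
  set <- structure(list(reference = "cy3",
                        images = list(cy3 = const_image(0.4, 32, 32)),
                        shifts = list(cy3 = c(0, 0)),
                        failed = c(cy3 = FALSE)),
                   class = "registered_set")
  objs <- make_objects(list(c(100, 101, 102, 132, 133)), c(32, 32))
  m <- measure_across_channels(objs, set)
  expect_equal(m$mean_cy3, 0.4)
  expect_equal(m$max_cy3, 0.4)
  expect_equal(m$min_cy3, 0.4)
  expect_equal(m$int_cy3, 0.4 * 5)
  # empty object list passes through with the stat columns added
  e <- measure_across_channels(objs[0, ], set)
  expect_equal(nrow(e), 0)
  expect_true("mean_cy3" %in% names(e))
  # pixels outside the raster are an error
  bad <- make_objects(list(c(5000)), c(32, 32))
  expect_error(measure_across_channels(bad, set), "outside")
})

test_that("integrated intensity of rendered spots matches a PSF oracle", {
  cfg <- scene_config(image_height_px = 128, image_width_px = 128,
                      spot_density = 6, channels = "cy5", peak_snr = 40,
                      seed = 23)
  scene <- render_scene(cfg)
  set <- preprocess_stacks(scene$stacks)
  objs <- detect_scene(set)
  m <- measure_across_channels(objs, set)
  mt <- match_to_truth(m, scene$truth, tol_px = 2)
  expect_gt(nrow(mt$matches), 0)
  # oracle: rasterize the noise-free expectation image from ground truth
  # (background + Gaussian PSF per spot), blur it with the same discrete
  # kernel the denoiser uses, and sum over each detected pixel set
  sigma <- cfg$psf_sigma_px
  h <- 128
  expect_img <- matrix(0.02, h, h)
  for (j in seq_len(nrow(scene$truth))) {
    tr <- scene$truth[j, ]
    expect_img <- expect_img + tr$amp_cy5 *
      outer(1:h, 1:h, function(r, c)
        exp(-((r - tr$row)^2 + (c - tr$col)^2) / (2 * sigma^2)))
  }
  oracle_img <- EBImage::filter2(expect_img, rcpscope:::gaussian_kernel(1),
                                 boundary = "replicate")
  for (k in seq_len(nrow(mt$matches))) {
    ob <- m[m$object_id == mt$matches$object_id[k], ]
    oracle <- sum(oracle_img[ob$pixels[[1]]])
    expect_lt(abs(ob$int_cy5 - oracle) / oracle, 0.10)
  }
})

test_that("truth matching counts hits, misses and permutations correctly", {
  truth <- data.frame(object_id = 1:5, row = c(10, 20, 30, 40, 50),
                      col = c(10, 20, 30, 40, 50))
  objs <- make_objects(lapply(truth$row, function(r) (r - 1) * 64 + r),
                       c(64, 64))
  perfect <- match_to_truth(objs, truth, 2)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  partial <- match_to_truth(objs[-3, ], truth, 2)
  expect_equal(partial$recall, 4 / 5)
  expect_equal(partial$precision, 1)
  shuffled <- match_to_truth(objs[c(4, 2, 5, 1, 3), ], truth, 2)
  expect_equal(shuffled$recall, 1)
  expect_setequal(shuffled$matches$truth_id, 1:5)
  expect_error(match_to_truth(objs, truth, 0), "tol_px")
})
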