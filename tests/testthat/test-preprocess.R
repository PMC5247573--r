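test_that("frame averaging is the normalized pixel-wise mean", {
  frames <- replicate(5, matrix(2000, 16, 16), simplify = FALSE)
  img <- average_frames(frame_stack("cy3", frames))
  expect_equal(img$data, matrix(2000 / 65535, 16, 16))
  expect_equal(img$provenance$n_frames_averaged, 5)
})

test_that("averaging N frames shrinks noise by sqrt(N)", {
  set.seed(1)
  sd_dn <- 400
  frames <- replicate(5, matrix(pmax(0, rnorm(512^2, 8000, sd_dn)), 512),
                      simplify = FALSE)
  img <- average_frames(frame_stack("cy3", frames))
  resid_sd <- sd(img$data) * 65535
  expect_lt(abs(resid_sd / (sd_dn / sqrt(5)) - 1), 0.10)
})

test_that("averaging warns on few frames and rejects bad stacks", {
  expect_warning(average_frames(frame_stack("cy3", list(matrix(1, 4, 4)))),
                 "5 or more")
  one <- suppressWarnings(
    average_frames(frame_stack("cy3", list(matrix(655.35, 4, 4)))))
  expect_equal(one$data, matrix(0.01, 4, 4))
  expect_error(frame_stack("cy3", list()), "empty")
  expect_error(frame_stack("cy3", list(matrix(1, 4, 4), matrix(1, 5, 4))),
               "same shape")
  expect_error(frame_stack("cy3", list(matrix(-5, 4, 4))), "65535")
})

test_that("averaging is permutation-invariant and linear", {
  set.seed(2)
  frames <- replicate(4, matrix(runif(64, 0, 1000), 8), simplify = FALSE)
  a <- suppressWarnings(average_frames(frame_stack("cy3", frames)))
  b <- suppressWarnings(average_frames(frame_stack("cy3", frames[c(3, 1, 4, 2)])))
  expect_equal(a$data, b$data)
  half <- suppressWarnings(
    average_frames(frame_stack("cy3", lapply(frames, `*`, 0.5))))
  expect_equal(half$data, a$data * 0.5, tolerance = 1e-12)
})

test_that("gaussian denoising leaves constants alone and conserves mass", {
  expect_equal(gaussian_denoise(const_image(0.3), 1)$data,
               matrix(0.3, 32, 32))
  imp <- matrix(0, 33, 33); imp[17, 17] <- 0.5
  out <- gaussian_denoise(channel_image("cy3", imp), 1)$data
  k <- rcpscope:::gaussian_kernel(1)
  expect_equal(out[17, 17], 0.5 * max(k), tolerance = 1e-8)
  expect_lt(abs(sum(out) - 0.5), 1e-6)
  expect_error(gaussian_denoise(const_image(0.3), 0), "sigma")
})

test_that("gaussian filtering reduces white-noise variance as expected", {
  set.seed(3)
  img <- channel_image("cy3", matrix(runif(256^2, 0.3, 0.7), 256))
  out <- gaussian_denoise(img, 1)
  # variance multiplier for white noise is the sum of squared kernel weights,
  # approximately 1/(4*pi*sigma^2)
  centre <- out$data[17:240, 17:240]
  ratio <- var(as.vector(centre)) / var(as.vector(img$data))
  expect_lt(abs(ratio / (1 / (4 * pi)) - 1), 0.15)
})

test_that("registration recovers known translations", {
  fx <- std_scene()
  ref <- fx$set$images$cy3
  mov <- channel_image("cy5", clamp(rcpscope:::fourier_shift(ref$data, 3, -2),
                                    0, 1))
  reg <- register_channels(ref, mov)
  expect_equal(reg$shifts$cy5[1], 3, tolerance = 0.25)
  expect_equal(reg$shifts$cy5[2], -2, tolerance = 0.25)
  # the aligned image is back on the reference grid
  expect_lt(mean(abs(reg$images$cy5$data - ref$data)), 0.005)
  # identity
  reg0 <- register_channels(ref, channel_image("cy5", ref$data))
  expect_equal(reg0$shifts$cy5, c(0, 0), tolerance = 0.1)
})

test_that("registration tolerates noise at modest SNR", {
  fx <- std_scene()
  ref <- fx$set$images$cy3
  set.seed(4)
  noisy <- clamp(rcpscope:::fourier_shift(ref$data, 2, 2) +
                 matrix(rnorm(length(ref$data), 0, 0.02), nrow(ref$data)),
                 0, 1)
  reg <- register_channels(ref, channel_image("cy5", noisy))
  expect_lt(max(abs(reg$shifts$cy5 - c(2, 2))), 0.5)
})

test_that("mean registration error stays below 0.3 px over random shifts", {
  cfg <- scene_config(image_height_px = 256, image_width_px = 256,
                      spot_density = 40, channels = "cy3", peak_snr = 8,
                      seed = 314)
  ref <- gaussian_denoise(average_frames(render_scene(cfg)$stacks$cy3), 1)
  set.seed(314)
  errs <- replicate(50, {
    dy <- runif(1, -5, 5); dx <- runif(1, -5, 5)
    mov <- clamp(rcpscope:::fourier_shift(ref$data, dy, dx), 0, 1)
    s <- register_channels(ref, channel_image("cy5", mov))$shifts$cy5
    mean(abs(s - c(dy, dx)))
  })
  expect_lt(mean(errs), 0.3)
})

test_that("registration flags failures instead of mangling images", {
  fx <- std_scene()
  ref <- fx$set$images$cy3
  big <- channel_image("cy5", clamp(rcpscope:::fourier_shift(ref$data, 8, 0),
                                    0, 1))
  expect_warning(reg <- register_channels(ref, big, max_shift_px = 5),
                 "unshifted")
  expect_true(reg$failed["cy5"])
  expect_equal(reg$images$cy5$data, big$data)
  expect_error(register_channels(ref, channel_image("cy5", matrix(0.1, 8, 8))),
               "shape")
  blank <- channel_image("cy3", matrix(0.5, 64, 64))
  expect_warning(register_channels(blank, channel_image("cy5",
                                                        matrix(0.5, 64, 64))),
                 "structure|common features")
})

test_that("superimpose builds an additive clipped colour composite", {
  h <- 16
  a <- matrix(0, h, h); a[4, 4] <- 0.8
  b <- matrix(0, h, h); b[12, 12] <- 0.6
  set <- structure(list(reference = "cy3",
                        images = list(cy3 = channel_image("cy3", a),
                                      cy5 = channel_image("cy5", b)),
                        shifts = list(cy3 = c(0, 0), cy5 = c(0, 0)),
                        failed = c(cy3 = FALSE, cy5 = FALSE)),
                   class = "registered_set")
  one <- superimpose(set, c(cy3 = "green"))
  expect_equal(one[, , 2], a)
  expect_equal(max(one[, , 1]), 0)
  both <- superimpose(set, c(cy3 = "green", cy5 = "red"))
  expect_equal(both[4, 4, 2], 0.8)   # green only at the cy3 spot
  expect_equal(both[4, 4, 1], 0)
  expect_equal(both[12, 12, 1], 0.6) # red only at the cy5 spot
  expect_equal(both[12, 12, 2], 0)
  # overlapping equal spots blend additively and clip at 1
  set$images$cy5 <- channel_image("cy5", a)
  blend <- superimpose(set, c(cy3 = "yellow", cy5 = "yellow"))
  expect_equal(blend[4, 4, 1], 1)
  expect_error(superimpose(set, c(dapi = "blue")), "unknown")
})
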