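#' Frame stack constructor
#'
#' The unit of acquisition: N repeated raw frames of one fluorescence
#' channel over the same region of interest, stored as 16-bit intensities
#' (data numbers in \[0, 65535\]).
#'
#' @param channel one of `cy3, cy5, fitc, txred, anchor, brightfield`.
#' @param frames list of equally sized numeric matrices.
#' @param pixel_size_um object-plane pixel pitch in um/px.
#' @return object of class `frame_stack`.
#' @export
frame_stack <- function(channel, frames, pixel_size_um = 0.42) {
  ok <- c("cy3", "cy5", "fitc", "txred", "anchor", "brightfield")
  if (!channel %in% ok) stop("unknown channel label: ", channel)
  if (length(frames) < 1) stop("empty frame stack")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have the same shape")
  rng <- range(vapply(frames, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > 65535)
    stop("frame intensities must lie in [0, 65535]")
  structure(list(channel = channel, frames = frames,
                 pixel_size_um = pixel_size_um),
            class = "frame_stack")
}

#' Channel image constructor
#'
#' A single processed image of one channel with intensities normalized to
#' \[0, 1\] (by the full 16-bit range, so absolute intensity gates are
#' comparable across images) and a provenance record.
#'
#' @param channel channel label.
#' @param data numeric matrix in \[0, 1\].
#' @param pixel_size_um pixel pitch.
#' @param provenance named list (e.g. `n_frames_averaged`,
#'   `gaussian_sigma_px`, `enhanced`).
#' @return object of class `channel_image`.
#' @export
channel_image <- function(channel, data, pixel_size_um = 0.42,
                          provenance = list()) {
  if (min(data) < 0 || max(data) > 1)
    stop("channel_image values must lie in [0, 1]")
  structure(list(channel = channel, data = data,
                 pixel_size_um = pixel_size_um, provenance = provenance),
            class = "channel_image")
}

#' Average the frames of a stack
#'
#' Pixel-wise arithmetic mean over the N frames, then normalization by the
#' full 16-bit range into \[0, 1\]. Averaging N frames with independent
#' noise improves the signal-to-noise ratio by sqrt(N).
#'
#' @param stack a [frame_stack()].
#' @return a [channel_image()] with `n_frames_averaged` recorded.
#' @export
average_frames <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- length(stack$frames)
  if (n < 5)
    warning("averaging only ", n, " frame(s); 5 or more are recommended")
  acc <- Reduce(`+`, stack$frames) / n
  channel_image(stack$channel, clamp(acc / 65535, 0, 1),
                stack$pixel_size_um,
                provenance = list(n_frames_averaged = n))
}

# normalized 2-D Gaussian kernel of odd size covering +-3 sigma
gaussian_kernel <- function(sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  x <- (-r):r
  k1 <- exp(-x^2 / (2 * sigma_px^2))
  k <- outer(k1, k1)
  k / sum(k)
}

#' Gaussian denoising
#'
#' Convolution with a normalized 2-D Gaussian kernel (edge-replicating
#' boundary). Reduces pixel noise at the cost of widening spots; with the
#' default sigma of 1 px a diffraction-limited spot keeps well over half of
#' its peak amplitude.
#'
#' @param img a [channel_image()].
#' @param sigma_px Gaussian sigma in pixels (> 0).
#' @return filtered [channel_image()] with `gaussian_sigma_px` recorded.
#' @export
gaussian_denoise <- function(img, sigma_px = 1.0) {
  stopifnot(inherits(img, "channel_image"))
  if (sigma_px <= 0) stop("sigma_px must be > 0")
  k <- gaussian_kernel(sigma_px)
  out <- EBImage::filter2(img$data, k, boundary = "replicate")
  prov <- img$provenance
  prov$gaussian_sigma_px <- sigma_px
  channel_image(img$channel, clamp(out, 0, 1), img$pixel_size_um, prov)
}

# signed FFT frequency indices 0, 1, ..., floor(n/2), -(n - floor(n/2) - 1), ..., -1
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  ifelse(k > n / 2, k - n, k)
}

# phase correlation between two equally sized matrices.
# Returns (dy, dx) such that mov ~ ref translated by (dy, dx).
# The whitened correlation surface is first maximized on the pixel grid,
# then refined by evaluating the inverse DFT on a fine local grid
# (upsampled-DFT refinement); a single-bin parabolic fit is unreliable here
# because the whitened peak splits with alternating signs at half-integer
# offsets.
phase_correlate <- function(ref, mov, refine_halfwidth = 2, refine_step = 0.05) {
  stopifnot(all(dim(ref) == dim(mov)))
  h <- nrow(ref); w <- ncol(ref)
  # Hann window: the images are not periodic, and the shared frame edges
  # otherwise correlate spuriously at zero offset along each axis
  wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(h) - 1) / (h - 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(w) - 1) / (w - 1))
  win <- outer(wy, wx)
  fa <- stats::fft((ref - mean(ref)) * win)
  fb <- stats::fft((mov - mean(mov)) * win)
  cross <- fa * Conj(fb)
  cn <- cross / (Mod(cross) + 1e-12)
  r <- Re(stats::fft(cn, inverse = TRUE)) / (h * w)
  p <- which.max(r)
  sy0 <- (p - 1) %% h
  sx0 <- (p - 1) %/% h
  if (sy0 > h / 2) sy0 <- sy0 - h
  if (sx0 > w / 2) sx0 <- sx0 - w
  gy <- sy0 + seq(-refine_halfwidth, refine_halfwidth, by = refine_step)
  gx <- sx0 + seq(-refine_halfwidth, refine_halfwidth, by = refine_step)
  ky <- fft_freqs(h); kx <- fft_freqs(w)
  ey <- exp(outer(ky, gy) * (2i * pi / h))
  ex <- exp(outer(kx, gx) * (2i * pi / w))
  r_up <- Re(t(ey) %*% cn %*% ex) / (h * w)
  q <- which.max(r_up)
  sy <- gy[((q - 1) %% length(gy)) + 1]
  sx <- gx[((q - 1) %/% length(gy)) + 1]
  # sign convention: peak of ifft(Fa * conj(Fb)) sits at minus the
  # displacement of mov relative to ref
  list(shift = c(-sy, -sx), peak = max(r_up))
}

# sub-pixel translation by Fourier shift theorem (periodic boundary).
fourier_shift <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  ky <- c(0:floor(h / 2), -(ceiling(h / 2) - 1):-1)[1:h] / h
  kx <- c(0:floor(w / 2), -(ceiling(w / 2) - 1):-1)[1:w] / w
  ph <- outer(exp(-2i * pi * ky * dy), exp(-2i * pi * kx * dx))
  Re(stats::fft(stats::fft(m) * ph, inverse = TRUE)) / (h * w)
}

#' Co-register channels by translation
#'
#' Estimates a rigid translation of each moving channel relative to the
#' reference by phase correlation on the image structure, refines the peak
#' to sub-pixel precision, and realigns each moving image onto the
#' reference grid by a Fourier-domain shift. A shift estimate exceeding
#' `max_shift_px` is treated as a failed registration: the image is passed
#' through unshifted and flagged. The same applies when the correlation
#' peak is too weak to be trustworthy — translation can only be estimated
#' from spatial features the two channels share (double-stained structures,
#' an anchor stain or a bright-field frame), and two channels staining
#' disjoint object sets provide none.
#'
#' @param reference reference [channel_image()].
#' @param moving list of [channel_image()]s to align onto the reference.
#' @param max_shift_px largest plausible shift in px.
#' @param min_peak_corr minimum normalized phase-correlation peak height
#'   accepted as evidence of a common-feature match.
#' @return object of class `registered_set`: `reference` (label), `images`
#'   (named list, reference first, all on the reference grid), `shifts`
#'   (named list of estimated `(dy, dx)` of each channel's content relative
#'   to the reference) and `failed` (named logical).
#' @export
register_channels <- function(reference, moving, max_shift_px = 10,
                              min_peak_corr = 0.01) {
  stopifnot(inherits(reference, "channel_image"))
  if (inherits(moving, "channel_image")) moving <- list(moving)
  if (max(reference$data) - min(reference$data) < 1e-6)
    warning("reference image has no structure; registration is unreliable")
  images <- stats::setNames(list(reference), reference$channel)
  shifts <- stats::setNames(list(c(0, 0)), reference$channel)
  failed <- stats::setNames(FALSE, reference$channel)
  for (m in moving) {
    stopifnot(inherits(m, "channel_image"))
    if (!all(dim(m$data) == dim(reference$data)))
      stop("channel images must share the same shape")
    pc <- phase_correlate(reference$data, m$data)
    s <- pc$shift
    if (max(abs(s)) > max_shift_px || pc$peak < min_peak_corr) {
      warning("registration of channel ", m$channel,
              if (pc$peak < min_peak_corr)
                " found no reliable common features"
              else " exceeds max_shift_px",
              "; passing through unshifted")
      images[[m$channel]] <- m
      shifts[[m$channel]] <- c(0, 0)
      failed[m$channel] <- TRUE
      next
    }
    aligned <- clamp(fourier_shift(m$data, -s[1], -s[2]), 0, 1)
    prov <- m$provenance
    prov$registered_shift <- s
    images[[m$channel]] <- channel_image(m$channel, aligned,
                                         m$pixel_size_um, prov)
    shifts[[m$channel]] <- s
    failed[m$channel] <- FALSE
  }
  structure(list(reference = reference$channel, images = images,
                 shifts = shifts, failed = failed),
            class = "registered_set")
}

#' Colour composite of registered channels
#'
#' Maps each channel to a display colour, sums the resulting RGB planes and
#' clips at 1. Purely a reporting aid; no analysis reads the composite.
#'
#' @param set a `registered_set`.
#' @param mapping named character vector channel -> colour name
#'   (e.g. `c(cy3 = "green", cy5 = "red")`).
#' @return `height x width x 3` array in \[0, 1\].
#' @export
superimpose <- function(set, mapping = c(cy3 = "green", cy5 = "red")) {
  stopifnot(inherits(set, "registered_set"))
  unknown <- setdiff(names(mapping), names(set$images))
  if (length(unknown))
    stop("mapping names unknown channel(s): ", paste(unknown, collapse = ", "))
  d <- dim(set$images[[1]]$data)
  comp <- array(0, c(d, 3))
  for (ch in names(mapping)) {
    rgb <- grDevices::col2rgb(mapping[[ch]])[, 1] / 255
    img <- set$images[[ch]]$data
    for (k in 1:3) comp[, , k] <- comp[, , k] + img * rgb[k]
  }
  clamp(comp, 0, 1)
}
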