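#' Synthetic micrograph scene configuration
#'
#' Describes a simulated field of view for a multi-channel fluorescence
#' microscope imaging rolling-circle amplification products (RCPs):
#' diffraction-limited spots of ~1 um physical diameter rendered as isotropic
#' Gaussians, plus larger, elliptical auto-fluorescent artifacts that stain
#' in several channels at once. Each channel is acquired as `n_frames`
#' independent noisy frames, mimicking repeated exposures of the same region
#' of interest.
#'
#' The photometric model is: expected signal (16-bit data numbers, DN) =
#' background + sum of object point-spread functions; each frame draws
#' `gain * Poisson(expectation / gain)` shot noise plus additive Gaussian
#' read noise, then clips into \[0, 65535\]. The read-noise standard
#' deviation is set so that the single-frame background noise s.d. equals
#' `mean spot amplitude / peak_snr`; `peak_snr` is therefore the peak
#' signal-to-noise ratio of an average spot on one raw frame, before the
#' sqrt(N) gain of frame averaging.
#'
#' @param image_height_px,image_width_px tile size in pixels.
#' @param pixel_size_um object-plane pixel pitch in um/px.
#' @param spot_density expected number of true RCPs per tile (Poisson mean).
#' @param artifact_density expected number of auto-fluorescent artifacts.
#' @param spot_diameter_um physical spot diameter (um); sets the PSF sigma
#'   as `spot_diameter_um / (2.355 * pixel_size_um)` (FWHM convention)
#'   unless `psf_sigma_px` is given.
#' @param psf_sigma_px optional explicit PSF sigma in pixels.
#' @param peak_snr single-frame peak SNR of an average-amplitude spot.
#' @param n_frames frames acquired per channel.
#' @param channel_shift_px length-2 numeric `(dy, dx)`: rigid shift applied
#'   to every non-reference channel (the first of `channels` is reference).
#' @param mutant_fraction fraction of true RCPs assigned to the mutant
#'   channel; the rest go to the wild-type channel.
#' @param seed integer RNG seed; identical configs render bit-identically.
#' @param channels signal channels to render, subset of
#'   `c("cy3","cy5","fitc","txred")`; first is the reference channel.
#' @param include_anchor render an anchor channel ("anchor") in which every
#'   true RCP, but no artifact, emits.
#' @param mutant_channel which signal channel codes the mutant allele.
#' @param background_norm background level as a fraction of full scale.
#' @param spot_amp_range normalized peak-amplitude range from which each
#'   RCP's brightness is drawn uniformly.
#' @param artifact_sigma_range major-axis Gaussian sigma range (px) for
#'   artifacts.
#' @param artifact_ecc_range artifact eccentricity range (>= 0.6 keeps them
#'   visibly elongated compared to round RCPs).
#' @param artifact_ratio_range minor/major channel amplitude ratio range for
#'   artifacts; kept above 0.3 so artifacts are true double-stainers.
#' @param gain sensor gain in DN per photoelectron.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(image_height_px = 1024, image_width_px = 1024,
                         pixel_size_um = 0.42,
                         spot_density = 200, artifact_density = 0,
                         spot_diameter_um = 1.0, psf_sigma_px = NULL,
                         peak_snr = 12, n_frames = 5,
                         channel_shift_px = c(0, 0),
                         mutant_fraction = 0, seed = 1,
                         channels = c("cy3", "cy5"),
                         include_anchor = FALSE,
                         mutant_channel = "cy3",
                         background_norm = 0.02,
                         spot_amp_range = c(0.30, 0.55),
                         artifact_sigma_range = c(1.8, 4.0),
                         artifact_ecc_range = c(0.6, 0.92),
                         artifact_ratio_range = c(0.35, 0.95),
                         gain = 2) {
  if (image_height_px < 1 || image_width_px < 1)
    stop("image dimensions must be positive")
  if (spot_density < 0 || artifact_density < 0)
    stop("densities must be >= 0")
  if (mutant_fraction < 0 || mutant_fraction > 1)
    stop("mutant_fraction must be in [0, 1]")
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (is.null(psf_sigma_px))
    psf_sigma_px <- spot_diameter_um / (2.355 * pixel_size_um)
  if (psf_sigma_px <= 0) stop("psf_sigma_px must be > 0")
  known <- c("cy3", "cy5", "fitc", "txred")
  if (!all(channels %in% known))
    stop("unknown channel(s): ", paste(setdiff(channels, known), collapse = ", "))
  if (length(channels) > 1 && !(mutant_channel %in% channels))
    stop("mutant_channel must be one of the rendered channels")
  stopifnot(length(channel_shift_px) == 2, peak_snr > 0, gain > 0)
  structure(list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    pixel_size_um = pixel_size_um,
    spot_density = spot_density, artifact_density = artifact_density,
    spot_diameter_um = spot_diameter_um, psf_sigma_px = psf_sigma_px,
    peak_snr = peak_snr, n_frames = as.integer(n_frames),
    channel_shift_px = as.numeric(channel_shift_px),
    mutant_fraction = mutant_fraction, seed = as.integer(seed),
    channels = channels, include_anchor = include_anchor,
    mutant_channel = mutant_channel,
    background_norm = background_norm,
    spot_amp_range = spot_amp_range,
    artifact_sigma_range = artifact_sigma_range,
    artifact_ecc_range = artifact_ecc_range,
    artifact_ratio_range = artifact_ratio_range,
    gain = gain
  ), class = "scene_config")
}

# single base coded by each channel (sequencing-by-ligation convention:
# A on cy5, T on fitc, G on cy3, C on texas red or blank)
channel_base <- c(cy5 = "A", fitc = "T", cy3 = "G", txred = "C")

# add an (optionally elliptical) Gaussian blob to an expectation image.
# theta is the major-axis angle; sa/sb the axis sigmas in px.
add_blob <- function(img, r0, c0, amp, sa, sb = sa, theta = 0) {
  h <- nrow(img); w <- ncol(img)
  ext <- ceiling(4 * max(sa, sb))
  rows <- max(1, floor(r0 - ext)):min(h, ceiling(r0 + ext))
  cols <- max(1, floor(c0 - ext)):min(w, ceiling(c0 + ext))
  if (!length(rows) || !length(cols) || rows[1] > rows[length(rows)] ||
      cols[1] > cols[length(cols)]) return(img)
  dr <- outer(rows - r0, rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - c0)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  img[rows, cols] <- img[rows, cols] +
    amp * exp(-(u^2 / (2 * sa^2) + v^2 / (2 * sb^2)))
  img
}

#' Render a synthetic multi-channel scene with ground truth
#'
#' Draws Poisson numbers of RCPs and artifacts, renders their point-spread
#' functions into per-channel expectation images, applies the configured
#' rigid shift to non-reference channels, and acquires `n_frames`
#' independent noisy frames per channel. True RCPs emit in exactly one
#' signal channel (their coding channel) plus, if enabled, the anchor
#' channel; artifacts emit in two signal channels with a minor/major
#' amplitude ratio above 0.3 and never in the anchor channel.
#'
#' @param config a [scene_config()].
#' @return list with `stacks` (named list of `frame_stack`), `truth`
#'   (ground-truth `data.frame`: `object_id`, `row`, `col` (1-based, may be
#'   fractional), `class`, `base`, and normalized per-channel peak
#'   amplitudes `amp_cy3 ... amp_anchor`) and `config`.
#' @export
render_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, render_scene_impl(config))
}

empty_truth <- function() {
  data.frame(object_id = integer(0), row = numeric(0), col = numeric(0),
             class = character(0), base = character(0),
             amp_cy3 = numeric(0), amp_cy5 = numeric(0),
             amp_fitc = numeric(0), amp_txred = numeric(0),
             amp_anchor = numeric(0))
}

render_scene_impl <- function(cfg) {
  h <- cfg$image_height_px; w <- cfg$image_width_px
  sig_ch <- cfg$channels
  all_ch <- c(sig_ch, if (cfg$include_anchor) "anchor")
  bg_dn <- cfg$background_norm * 65535
  amp_ref_dn <- mean(cfg$spot_amp_range) * 65535
  sigma_target <- amp_ref_dn / cfg$peak_snr
  read_sd <- sqrt(max(0, sigma_target^2 - cfg$gain * bg_dn))

  n_rcp <- stats::rpois(1, cfg$spot_density)
  n_art <- stats::rpois(1, cfg$artifact_density)

  expect <- lapply(all_ch, function(ch) matrix(bg_dn, h, w))
  names(expect) <- all_ch
  shift <- cfg$channel_shift_px
  ref_ch <- sig_ch[1]
  ch_shift <- function(ch) if (ch == ref_ch) c(0, 0) else shift

  truth_parts <- list(empty_truth())

  if (n_rcp > 0) {
    r0 <- stats::runif(n_rcp, 1, h); c0 <- stats::runif(n_rcp, 1, w)
    amp <- stats::runif(n_rcp, cfg$spot_amp_range[1], cfg$spot_amp_range[2])
    if (length(sig_ch) > 1) {
      is_mut <- stats::runif(n_rcp) < cfg$mutant_fraction
      wt_ch <- setdiff(sig_ch, cfg$mutant_channel)[1]
      ch_of <- ifelse(is_mut, cfg$mutant_channel, wt_ch)
    } else {
      ch_of <- rep(sig_ch, n_rcp)
    }
    anchor_amp <- if (cfg$include_anchor)
      amp * stats::runif(n_rcp, 0.7, 1.0) else rep(0, n_rcp)
    for (i in seq_len(n_rcp)) {
      ch <- ch_of[i]; ds <- ch_shift(ch)
      expect[[ch]] <- add_blob(expect[[ch]], r0[i] + ds[1], c0[i] + ds[2],
                               amp[i] * 65535, cfg$psf_sigma_px)
      if (cfg$include_anchor)
        expect[["anchor"]] <- add_blob(expect[["anchor"]],
                                       r0[i] + shift[1], c0[i] + shift[2],
                                       anchor_amp[i] * 65535, cfg$psf_sigma_px)
    }
    tr <- data.frame(object_id = seq_len(n_rcp), row = r0, col = c0,
                     class = "rcp", base = unname(channel_base[ch_of]),
                     amp_cy3 = ifelse(ch_of == "cy3", amp, 0),
                     amp_cy5 = ifelse(ch_of == "cy5", amp, 0),
                     amp_fitc = ifelse(ch_of == "fitc", amp, 0),
                     amp_txred = ifelse(ch_of == "txred", amp, 0),
                     amp_anchor = anchor_amp)
    truth_parts <- c(truth_parts, list(tr))
  }

  if (n_art > 0) {
    r0 <- stats::runif(n_art, 1, h); c0 <- stats::runif(n_art, 1, w)
    sa <- stats::runif(n_art, cfg$artifact_sigma_range[1],
                       cfg$artifact_sigma_range[2])
    ecc <- stats::runif(n_art, cfg$artifact_ecc_range[1],
                        cfg$artifact_ecc_range[2])
    sb <- sa * sqrt(1 - ecc^2)
    th <- stats::runif(n_art, 0, pi)
    amp_major <- stats::runif(n_art, cfg$spot_amp_range[1],
                              cfg$spot_amp_range[2])
    ratio <- stats::runif(n_art, cfg$artifact_ratio_range[1],
                          cfg$artifact_ratio_range[2])
    amp_by_ch <- matrix(0, n_art, length(sig_ch),
                        dimnames = list(NULL, sig_ch))
    for (i in seq_len(n_art)) {
      if (length(sig_ch) > 1) {
        major <- sample(sig_ch, 1)
        minor <- sample(setdiff(sig_ch, major), 1)
        amp_by_ch[i, major] <- amp_major[i]
        amp_by_ch[i, minor] <- amp_major[i] * ratio[i]
      } else {
        amp_by_ch[i, sig_ch] <- amp_major[i]
      }
      for (ch in sig_ch) {
        if (amp_by_ch[i, ch] == 0) next
        ds <- ch_shift(ch)
        expect[[ch]] <- add_blob(expect[[ch]], r0[i] + ds[1], c0[i] + ds[2],
                                 amp_by_ch[i, ch] * 65535, sa[i], sb[i], th[i])
      }
    }
    get_amp <- function(ch) if (ch %in% sig_ch) amp_by_ch[, ch] else rep(0, n_art)
    tr <- data.frame(object_id = n_rcp + seq_len(n_art), row = r0, col = c0,
                     class = "artifact", base = "none",
                     amp_cy3 = get_amp("cy3"), amp_cy5 = get_amp("cy5"),
                     amp_fitc = get_amp("fitc"), amp_txred = get_amp("txred"),
                     amp_anchor = 0)
    truth_parts <- c(truth_parts, list(tr))
  }

  stacks <- lapply(all_ch, function(ch) {
    lam <- expect[[ch]] / cfg$gain
    frames <- lapply(seq_len(cfg$n_frames), function(f) {
      x <- cfg$gain * matrix(stats::rpois(h * w, lam), h, w)
      if (read_sd > 0) x <- x + matrix(stats::rnorm(h * w, 0, read_sd), h, w)
      matrix(clamp(round(x), 0, 65535), h, w)
    })
    frame_stack(ch, frames, cfg$pixel_size_um)
  })
  names(stacks) <- all_ch
  truth <- do.call(rbind, truth_parts)
  rownames(truth) <- NULL
  list(stacks = stacks, truth = truth, config = cfg)
}

#' Render a dilution series of scenes
#'
#' One scene per concentration, with expected spot density proportional to
#' concentration, emulating digital quantification of a log10 dilution
#' series of circularized templates.
#'
#' @param base_config template [scene_config()]; its `spot_density` is
#'   overridden per concentration and its `seed` offset per scene.
#' @param concentrations strictly positive molar concentrations.
#' @param densities expected spots per tile for each concentration; must be
#'   non-decreasing in concentration.
#' @return list with one element per concentration:
#'   `list(concentration, scene)`.
#' @export
render_dilution_series <- function(base_config, concentrations, densities) {
  stopifnot(inherits(base_config, "scene_config"))
  if (length(concentrations) == 0) stop("empty concentration list")
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  if (length(densities) != length(concentrations))
    stop("one density per concentration required")
  o <- order(concentrations)
  if (is.unsorted(densities[o]))
    stop("densities must be monotone non-decreasing in concentration")
  lapply(seq_along(concentrations), function(i) {
    cfg <- base_config
    cfg$spot_density <- densities[i]
    cfg$seed <- derive_seed(base_config$seed, i)
    list(concentration = concentrations[i], scene = render_scene(cfg))
  })
}

#' Write a rendered scene to disk
#'
#' Each channel stack becomes a multi-page 16-bit grayscale TIFF
#' `<name>_<channel>.tif` (one page per frame); ground truth is written as
#' `<name>_truth.csv` with 0-based pixel coordinates, and the configuration
#' as `<name>_config.yaml`.
#'
#' @param scene result of [render_scene()].
#' @param dir output directory (created if needed).
#' @param name scene name used as the file prefix.
#' @return invisibly, the vector of files written.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (ch in names(scene$stacks)) {
    f <- file.path(dir, sprintf("%s_%s.tif", name, ch))
    pages <- lapply(scene$stacks[[ch]]$frames, function(m) m / 65535)
    tiff::writeTIFF(pages, f, bits.per.sample = 16)
    files <- c(files, f)
  }
  truth <- scene$truth
  out <- truth
  out$row <- out$row - 1
  out$col <- out$col - 1
  ft <- file.path(dir, sprintf("%s_truth.csv", name))
  utils::write.csv(out, ft, row.names = FALSE)
  fc <- file.path(dir, sprintf("%s_config.yaml", name))
  yaml::write_yaml(unclass(scene$config), fc)
  invisible(c(files, ft, fc))
}

#' Read a channel frame stack from a multi-page TIFF
#'
#' @param path TIFF file with one page per frame.
#' @param channel channel label to attach.
#' @param pixel_size_um pixel pitch to record.
#' @return a `frame_stack`.
#' @export
read_frame_stack <- function(path, channel, pixel_size_um = 0.42) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    round(p * 65535)
  })
  frame_stack(channel, frames, pixel_size_um)
}
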