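#' The fixed 14-feature recognition panel
#'
#' Per-object features fed to the spot classifier, in their fixed,
#' versioned order: six intensity statistics (mean, max, min, integrated,
#' s.d., median), four size/shape descriptors (area, equivalent diameter,
#' perimeter, eccentricity), two regularity descriptors (solidity,
#' compactness) and two local-context descriptors (contrast of the object
#' mean over a surrounding annulus, and peak SNR as max intensity over the
#' annulus s.d.). Intensity, size and shape jointly separate
#' diffraction-limited, near-circular RCPs from the larger, elongated
#' auto-fluorescent artifacts.
#'
#' @format character vector of 14 feature names.
#' @export
rcp_feature_names <- c(
  "mean_intensity", "max_intensity", "min_intensity",
  "integrated_intensity", "intensity_sd", "intensity_median",
  "area_px", "equivalent_diameter_px", "perimeter_px", "eccentricity",
  "solidity", "compactness", "local_background_contrast", "peak_snr"
)

# perimeter as the number of exposed 4-neighbour edges of the pixel set
region_perimeter <- function(rows, cols) {
  key <- paste(rows, cols)
  inset <- function(r, c) paste(r, c) %in% key
  4 * length(rows) - sum(inset(rows - 1, cols)) - sum(inset(rows + 1, cols)) -
    sum(inset(rows, cols - 1)) - sum(inset(rows, cols + 1))
}

# eccentricity of the equivalent ellipse from central second moments
region_eccentricity <- function(rows, cols) {
  if (length(rows) < 2) return(0)
  r <- rows - mean(rows); c <- cols - mean(cols)
  mu20 <- mean(r^2); mu02 <- mean(c^2); mu11 <- mean(r * c)
  disc <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + disc) / 2
  l2 <- (mu20 + mu02 - disc) / 2
  if (l1 <= 0) return(0)
  sqrt(max(0, 1 - l2 / l1))
}

# solidity: area over the pixel-counted area of the convex hull of the set
region_solidity <- function(rows, cols) {
  n <- length(rows)
  pts <- unique(cbind(rows, cols))
  if (nrow(pts) < 3) return(1)
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(hull) < 3) return(1)
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  # candidate pixels: bounding box; point inside convex polygon iff on a
  # consistent side of every (clockwise-ordered) edge
  gr <- seq(min(rows), max(rows)); gc <- seq(min(cols), max(cols))
  cand <- cbind(rep(gr, times = length(gc)), rep(gc, each = length(gr)))
  nh <- length(hull)
  inside <- rep(TRUE, nrow(cand))
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1 else i + 1
    cr <- (hx[j] - hx[i]) * (cand[, 2] - hy[i]) -
          (hy[j] - hy[i]) * (cand[, 1] - hx[i])
    inside <- inside & (cr <= 1e-9)
  }
  hull_area <- sum(inside)
  if (hull_area < n) return(1)
  n / hull_area
}

#' Extract the 14 recognition features for detected objects
#'
#' Deterministic per-object feature vectors measured on a single channel
#' image. Annulus-based context features use a 2-px-wide ring starting 2 px
#' outside the object; when the ring is empty (object against the image
#' border) the global image median/MAD stand in and the object is flagged.
#'
#' @param objects a `detected_objects` table.
#' @param img the [channel_image()] the objects were detected on.
#' @return `data.frame` with the 14 columns of [rcp_feature_names] plus
#'   `annulus_fallback`; row order follows `objects`.
#' @export
extract_features <- function(objects, img) {
  stopifnot(inherits(objects, "detected_objects"),
            inherits(img, "channel_image"))
  dat <- img$data
  dims <- dim(dat)
  h <- dims[1]
  g_bg <- stats::median(dat)
  g_sd <- max(stats::mad(dat), 1e-6)
  n <- nrow(objects)
  out <- matrix(NA_real_, n, length(rcp_feature_names),
                dimnames = list(NULL, rcp_feature_names))
  fallback <- logical(n)
  for (i in seq_len(n)) {
    px <- objects$pixels[[i]]
    v <- dat[px]
    rows <- ((px - 1) %% h) + 1
    cols <- ((px - 1) %/% h) + 1
    ann <- object_annulus(px, dims)
    if (length(ann) > 1) {
      bm <- mean(dat[ann])
      bs <- max(stats::sd(dat[ann]), 1e-6)
    } else {
      bm <- g_bg; bs <- g_sd; fallback[i] <- TRUE
    }
    area <- length(px)
    per <- region_perimeter(rows, cols)
    out[i, ] <- c(mean(v), max(v), min(v), sum(v),
                  if (area > 1) stats::sd(v) else 0, stats::median(v),
                  area, 2 * sqrt(area / pi), per,
                  region_eccentricity(rows, cols),
                  region_solidity(rows, cols),
                  per^2 / (4 * pi * area),
                  mean(v) - bm, max(v) / bs)
  }
  res <- as.data.frame(out)
  res$annulus_fallback <- fallback
  res
}
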