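#' Detection configuration
#'
#' Gates for spot identification: connected components of pixels at or
#' above `intensity_threshold` (normalized units) are kept when their
#' equivalent circular diameter lies within
#' `[min_diameter_px, max_diameter_px]`. The defaults — size window 2-8 px
#' and intensity threshold inside 0.1-0.4 — suit ~1 um spots imaged at
#' ~0.42 um/px. The adaptive mode derives the threshold from the image as
#' `median + k * MAD`, clipped into \[0.1, 0.4\], which makes the
#' per-sample threshold choice reproducible when auto-fluorescence levels
#' vary.
#'
#' @param enhance_radius_px disk radius for white top-hat enhancement.
#' @param intensity_threshold absolute threshold in (0, 1).
#' @param min_diameter_px,max_diameter_px equivalent-diameter gate.
#' @param adaptive if `TRUE`, derive the threshold per image.
#' @param adaptive_k multiplier on the MAD in adaptive mode.
#' @return object of class `detection_config`.
#' @export
detection_config <- function(enhance_radius_px = 4,
                             intensity_threshold = 0.1,
                             min_diameter_px = 2, max_diameter_px = 8,
                             adaptive = FALSE, adaptive_k = 6) {
  if (min_diameter_px >= max_diameter_px)
    stop("min_diameter_px must be < max_diameter_px")
  if (intensity_threshold <= 0 || intensity_threshold >= 1)
    stop("intensity_threshold must be in (0, 1)")
  if (enhance_radius_px < 1) stop("enhance_radius_px must be >= 1")
  structure(list(enhance_radius_px = as.integer(enhance_radius_px),
                 intensity_threshold = intensity_threshold,
                 min_diameter_px = min_diameter_px,
                 max_diameter_px = max_diameter_px,
                 adaptive = adaptive, adaptive_k = adaptive_k),
            class = "detection_config")
}

#' White top-hat spot enhancement
#'
#' Subtracts the morphological opening with a disk structuring element from
#' the image: flat background and structures broader than the disk are
#' suppressed towards zero while compact bright spots smaller than the disk
#' are preserved.
#'
#' @param img a [channel_image()].
#' @param radius_px disk radius in pixels (>= 1); should exceed the spot
#'   radius.
#' @return enhanced [channel_image()] with `enhanced = TRUE` in provenance.
#' @export
enhance_spots <- function(img, radius_px = 4) {
  stopifnot(inherits(img, "channel_image"))
  if (radius_px < 1) stop("radius_px must be >= 1")
  brush <- EBImage::makeBrush(2 * as.integer(radius_px) + 1, shape = "disc")
  opened <- EBImage::opening(img$data, brush)
  prov <- img$provenance
  prov$enhanced <- TRUE
  prov$enhance_radius_px <- radius_px
  channel_image(img$channel, clamp(img$data - opened, 0, 1),
                img$pixel_size_um, prov)
}

# exact 8-connected labelling: 4-connected labelling (EBImage::bwlabel)
# followed by union-find merging of diagonally adjacent label pairs
label_components_8 <- function(mask) {
  l4 <- EBImage::bwlabel(mask)
  n <- max(l4)
  if (n == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  h <- nrow(l4); w <- ncol(l4)
  a <- cbind(as.vector(l4[-h, -w]), as.vector(l4[-1, -1]))   # down-right
  b <- cbind(as.vector(l4[-h, -1]), as.vector(l4[-1, -w]))   # down-left
  pairs <- rbind(a, b)
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  # compact ids in order of first appearance (column-major scan)
  dense <- match(root, sort(unique(root)))
  out <- matrix(0L, h, w)
  nz <- l4 > 0
  out[nz] <- dense[l4[nz]]
  out
}

#' Identify candidate spot objects
#'
#' Thresholds the image, labels 8-connected components, and keeps
#' components whose equivalent circular diameter `2*sqrt(area/pi)` lies in
#' the configured window. Output is sorted by centroid (row, then column)
#' and fully deterministic.
#'
#' @param img a [channel_image()] (enhanced or raw; recorded in the result).
#' @param cfg a [detection_config()].
#' @return `data.frame` of class `detected_objects` with columns
#'   `object_id`, `row`, `col` (1-based centroids), `area_px`,
#'   `eq_diameter_px`, `channel`, `threshold_used`, and a list column
#'   `pixels` of linear pixel indices into the image matrix.
#' @export
identify_objects <- function(img, cfg = detection_config()) {
  stopifnot(inherits(img, "channel_image"), inherits(cfg, "detection_config"))
  thr <- cfg$intensity_threshold
  if (isTRUE(cfg$adaptive)) {
    thr <- stats::median(img$data) + cfg$adaptive_k * stats::mad(img$data)
    thr <- clamp(thr, 0.1, 0.4)
  }
  lab <- label_components_8(img$data >= thr)
  n <- max(lab)
  empty <- data.frame(object_id = integer(0), row = numeric(0),
                      col = numeric(0), area_px = integer(0),
                      eq_diameter_px = numeric(0), channel = character(0),
                      threshold_used = numeric(0))
  if (n == 0) {
    empty$pixels <- list()
    class(empty) <- c("detected_objects", "data.frame")
    return(empty)
  }
  h <- nrow(lab)
  idx <- which(lab > 0)
  lv <- lab[idx]
  area <- tabulate(lv, nbins = n)
  rows <- ((idx - 1) %% h) + 1
  cols <- ((idx - 1) %/% h) + 1
  cr <- rowsum(rows, lv)[, 1] / area
  cc <- rowsum(cols, lv)[, 1] / area
  eqd <- 2 * sqrt(area / pi)
  keep <- which(eqd >= cfg$min_diameter_px & eqd <= cfg$max_diameter_px)
  if (!length(keep)) {
    empty$pixels <- list()
    class(empty) <- c("detected_objects", "data.frame")
    return(empty)
  }
  ord <- keep[order(cr[keep], cc[keep])]
  px <- split(idx, lv)
  objs <- data.frame(object_id = seq_along(ord),
                     row = cr[ord], col = cc[ord],
                     area_px = area[ord], eq_diameter_px = eqd[ord],
                     channel = img$channel, threshold_used = thr)
  objs$pixels <- unname(px[as.character(ord)])
  class(objs) <- c("detected_objects", "data.frame")
  objs
}

# annulus pixel indices for one object: ring at dilation distance
# (inner_px, outer_px] around the pixel set, clipped at image borders
object_annulus <- function(pixels, dims, inner_px = 2, outer_px = 4) {
  h <- dims[1]; w <- dims[2]
  rows <- ((pixels - 1) %% h) + 1
  cols <- ((pixels - 1) %/% h) + 1
  r0 <- max(1, min(rows) - outer_px); r1 <- min(h, max(rows) + outer_px)
  c0 <- max(1, min(cols) - outer_px); c1 <- min(w, max(cols) + outer_px)
  wh <- r1 - r0 + 1; ww <- c1 - c0 + 1
  m <- matrix(0L, wh, ww)
  m[cbind(rows - r0 + 1, cols - c0 + 1)] <- 1L
  b_in <- EBImage::makeBrush(2 * inner_px + 1, shape = "disc")
  b_out <- EBImage::makeBrush(2 * outer_px + 1, shape = "disc")
  ring <- EBImage::dilate(m, b_out) & !EBImage::dilate(m, b_in)
  wi <- which(ring)
  if (!length(wi)) return(integer(0))
  rr <- ((wi - 1) %% wh) + r0
  cc <- ((wi - 1) %/% wh) + c0
  (cc - 1) * h + rr
}

#' Measure objects across registered channels
#'
#' For every detected object and every channel in the registered set,
#' computes mean, max, min and integrated intensity over the object's pixel
#' set, plus the mean and standard deviation of a local background annulus
#' (a ring 2 px wide starting 2 px outside the object) used downstream for
#' background-subtracted base calling.
#'
#' @param objects a `detected_objects` table.
#' @param set a `registered_set`.
#' @return `objects` with columns `mean_<ch>`, `max_<ch>`, `min_<ch>`,
#'   `int_<ch>`, `bg_mean_<ch>`, `bg_sd_<ch>` per channel, and
#'   `annulus_clipped` flagging objects whose annulus was empty (global
#'   background used instead).
#' @export
measure_across_channels <- function(objects, set) {
  stopifnot(inherits(objects, "detected_objects"),
            inherits(set, "registered_set"))
  dims <- dim(set$images[[1]]$data)
  n <- nrow(objects)
  channels <- names(set$images)
  if (n == 0) {
    for (ch in channels)
      for (s in c("mean_", "max_", "min_", "int_", "bg_mean_", "bg_sd_"))
        objects[[paste0(s, ch)]] <- numeric(0)
    objects$annulus_clipped <- logical(0)
    return(objects)
  }
  npix <- prod(dims)
  bad <- vapply(objects$pixels,
                function(p) any(p < 1 | p > npix), logical(1))
  if (any(bad)) stop("object pixels outside the image raster")
  annuli <- lapply(objects$pixels, object_annulus, dims = dims)
  objects$annulus_clipped <- lengths(annuli) == 0
  for (ch in channels) {
    img <- set$images[[ch]]$data
    g_bg <- stats::median(img)
    g_sd <- stats::mad(img)
    st <- vapply(seq_len(n), function(i) {
      v <- img[objects$pixels[[i]]]
      a <- annuli[[i]]
      if (length(a)) {
        bm <- mean(img[a])
        bs <- stats::sd(img[a])
        if (is.na(bs)) bs <- g_sd
      } else {
        bm <- g_bg; bs <- g_sd
      }
      c(mean(v), max(v), min(v), sum(v), bm, bs)
    }, numeric(6))
    objects[[paste0("mean_", ch)]] <- st[1, ]
    objects[[paste0("max_", ch)]] <- st[2, ]
    objects[[paste0("min_", ch)]] <- st[3, ]
    objects[[paste0("int_", ch)]] <- st[4, ]
    objects[[paste0("bg_mean_", ch)]] <- st[5, ]
    objects[[paste0("bg_sd_", ch)]] <- st[6, ]
  }
  objects
}

#' Match detections against ground truth
#'
#' Greedy one-to-one nearest-neighbour matching within a tolerance radius,
#' yielding detection precision and recall against a generator ground-truth
#' table.
#'
#' @param objects a `detected_objects` table.
#' @param truth ground-truth `data.frame` with `row`, `col` (1-based) and
#'   optionally `class`/`base` columns (carried into the matches).
#' @param tol_px matching radius in pixels (> 0).
#' @return list with `precision`, `recall` and `matches` (`data.frame` of
#'   `object_id`, `truth_id`, `dist_px` plus any `class`/`base` columns of
#'   the truth table).
#' @export
match_to_truth <- function(objects, truth, tol_px = 2) {
  if (tol_px <= 0) stop("tol_px must be > 0")
  nd <- nrow(objects); nt <- nrow(truth)
  matches <- data.frame(object_id = integer(0), truth_id = integer(0),
                        dist_px = numeric(0))
  if (nd == 0 || nt == 0) {
    return(list(precision = if (nd == 0) 1 else 0,
                recall = if (nt == 0) 1 else 0, matches = matches))
  }
  d2 <- outer(objects$row, truth$row, "-")^2 +
        outer(objects$col, truth$col, "-")^2
  cand <- which(d2 <= tol_px^2, arr.ind = TRUE)
  if (nrow(cand)) {
    ord <- order(d2[cand])
    cand <- cand[ord, , drop = FALSE]
    used_d <- logical(nd); used_t <- logical(nt)
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      di <- cand[i, 1]; ti <- cand[i, 2]
      if (!used_d[di] && !used_t[ti]) {
        used_d[di] <- TRUE; used_t[ti] <- TRUE; keep[i] <- TRUE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    matches <- data.frame(object_id = objects$object_id[cand[, 1]],
                          truth_id = truth$object_id[cand[, 2]],
                          dist_px = sqrt(d2[cand]))
    for (col in intersect(c("class", "base"), names(truth)))
      matches[[col]] <- truth[[col]][cand[, 2]]
  }
  list(precision = nrow(matches) / nd, recall = nrow(matches) / nt,
       matches = matches)
}

#' Export detected objects as a plain table
#'
#' Drops the pixel list column and converts centroids to 0-based
#' coordinates for CSV interchange.
#'
#' @param objects a `detected_objects` table.
#' @return plain `data.frame`.
#' @export
objects_to_table <- function(objects) {
  out <- as.data.frame(objects[, setdiff(names(objects), "pixels")])
  out$row <- out$row - 1
  out$col <- out$col - 1
  out
}
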