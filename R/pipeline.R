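#' Preprocess raw channel stacks into a registered image set
#'
#' Frame-averages each channel stack, Gaussian-denoises the averaged
#' images, and co-registers all channels onto the first signal channel by
#' phase correlation.
#'
#' @param stacks named list of [frame_stack()]s (e.g. from
#'   [render_scene()]).
#' @param gaussian_sigma_px denoising sigma (px).
#' @param register estimate and correct inter-channel shifts.
#' @param max_shift_px registration shift bound.
#' @return a `registered_set` of denoised images.
#' @export
preprocess_stacks <- function(stacks, gaussian_sigma_px = 1.0,
                              register = TRUE, max_shift_px = 10) {
  stopifnot(length(stacks) >= 1)
  imgs <- lapply(stacks, function(s)
    gaussian_denoise(average_frames(s), gaussian_sigma_px))
  if (length(imgs) == 1 || !register) {
    images <- imgs
    set <- structure(list(reference = imgs[[1]]$channel, images = images,
                          shifts = stats::setNames(
                            rep(list(c(0, 0)), length(imgs)), names(imgs)),
                          failed = stats::setNames(
                            rep(FALSE, length(imgs)), names(imgs))),
                     class = "registered_set")
    return(set)
  }
  register_channels(imgs[[1]], imgs[-1], max_shift_px = max_shift_px)
}

# merge per-channel detections: objects from later channels whose centroid
# falls within tol_px of an already kept object are considered the same
# physical object (e.g. a double-stained artifact) and dropped
merge_detections <- function(object_lists, tol_px = 2) {
  object_lists <- Filter(function(o) nrow(o) > 0, object_lists)
  if (!length(object_lists)) {
    e <- data.frame(object_id = integer(0), row = numeric(0),
                    col = numeric(0), area_px = integer(0),
                    eq_diameter_px = numeric(0), channel = character(0),
                    threshold_used = numeric(0))
    e$pixels <- list()
    class(e) <- c("detected_objects", "data.frame")
    return(e)
  }
  merged <- object_lists[[1]]
  for (o in object_lists[-1]) {
    if (nrow(merged) == 0) { merged <- o; next }
    d2 <- outer(o$row, merged$row, "-")^2 + outer(o$col, merged$col, "-")^2
    new <- apply(d2 > tol_px^2, 1, all)
    merged <- rbind(merged, o[new, , drop = FALSE])
  }
  merged <- merged[order(merged$row, merged$col), , drop = FALSE]
  merged$object_id <- seq_len(nrow(merged))
  rownames(merged) <- NULL
  class(merged) <- c("detected_objects", "data.frame")
  merged
}

#' Detect and measure spots across the signal channels of a set
#'
#' White top-hat enhancement and size/intensity gating on every signal
#' channel, merging of per-channel detections (a double-stained object is
#' counted once), then per-channel intensity measurement on the denoised
#' registered images.
#'
#' @param set a `registered_set` from [preprocess_stacks()].
#' @param cfg a [detection_config()].
#' @param signal_channels channels to detect on; defaults to all channels
#'   except anchor/brightfield.
#' @return measured `detected_objects` table.
#' @export
detect_scene <- function(set, cfg = detection_config(),
                         signal_channels = NULL) {
  stopifnot(inherits(set, "registered_set"))
  if (is.null(signal_channels))
    signal_channels <- setdiff(names(set$images), c("anchor", "brightfield"))
  per_ch <- lapply(signal_channels, function(ch) {
    enh <- enhance_spots(set$images[[ch]], cfg$enhance_radius_px)
    identify_objects(enh, cfg)
  })
  objs <- merge_detections(per_ch)
  measure_across_channels(objs, set)
}

#' Run the full digital counting pipeline on one scene
#'
#' Chains preprocessing, detection, optional random-forest filtering,
#' anchor gating (when an anchor channel is present) and base calling, and
#' tallies the result.
#'
#' @param stacks named list of [frame_stack()]s.
#' @param cfg a [detection_config()].
#' @param coding a [base_coding_map()].
#' @param model optional `rcp_forest`; when supplied, detections the forest
#'   labels `not_rcp` are removed before base calling (rule-based gates
#'   only, otherwise).
#' @param gaussian_sigma_px denoising sigma.
#' @param anchor_min_intensity see [anchor_gate()].
#' @param ratio_threshold double-stain rejection threshold.
#' @return list: `set`, `objects` (all measured detections), `calls`
#'   (base calls incl. anchor-rejected rows), `tally`,
#'   `n_classifier_rejected`.
#' @export
count_scene <- function(stacks, cfg = detection_config(),
                        coding = base_coding_map(), model = NULL,
                        gaussian_sigma_px = 1.0,
                        anchor_min_intensity = NULL,
                        ratio_threshold = 0.3) {
  set <- preprocess_stacks(stacks, gaussian_sigma_px)
  objects <- detect_scene(set, cfg)
  kept <- objects
  n_cls_rej <- 0L
  if (!is.null(model) && nrow(kept) > 0) {
    feats <- do.call(rbind, lapply(split(kept, kept$channel), function(d) {
      cbind(idx = d$object_id,
            extract_features(`class<-`(d, c("detected_objects", "data.frame")),
                             set$images[[d$channel[1]]]))
    }))
    feats <- feats[order(feats$idx), , drop = FALSE]
    pred <- predict_rcp(model, feats)
    drop_ids <- feats$idx[pred$label == "not_rcp"]
    n_cls_rej <- length(drop_ids)
    kept <- kept[!kept$object_id %in% drop_ids, , drop = FALSE]
  }
  anchor_rows <- NULL
  if (paste0("mean_", coding$anchor) %in% names(kept)) {
    g <- anchor_gate(kept, coding$anchor, anchor_min_intensity)
    kept <- g$kept
    if (nrow(g$rejected))
      anchor_rows <- data.frame(object_id = g$rejected$object_id,
                                called_base = "no_call",
                                status = "rejected_no_anchor",
                                dominant_channel = "none",
                                double_stain_ratio = NA_real_)
  }
  calls <- if (nrow(kept)) call_bases(kept, coding,
                                      ratio_threshold = ratio_threshold)
           else data.frame(object_id = integer(0), called_base = character(0),
                           status = character(0),
                           dominant_channel = character(0),
                           double_stain_ratio = numeric(0))
  if (!is.null(anchor_rows)) calls <- rbind(calls, anchor_rows)
  class(calls) <- c("base_calls", "data.frame")
  list(set = set, objects = objects, calls = calls,
       tally = tally_calls(calls), n_classifier_rejected = n_cls_rej)
}

#' Simulate a labelled object set for classifier work
#'
#' Renders synthetic scenes containing both true RCPs and auto-fluorescent
#' artifacts, runs the detection stage, labels each detection by matching
#' against the generator ground truth (`rcp` vs `not_rcp`), and extracts
#' the 14-feature panel. Scenes are rendered until the requested number of
#' labelled examples of each class is reached.
#'
#' @param n_rcp,n_artifact requested examples per class.
#' @param peak_snr scene peak SNR.
#' @param seed master seed.
#' @param cfg detection configuration.
#' @param tile_px scene tile size.
#' @return `data.frame`: 14 feature columns plus `label`.
#' @export
simulate_labelled_objects <- function(n_rcp = 500, n_artifact = 500,
                                      peak_snr = 5, seed = 1,
                                      cfg = detection_config(),
                                      tile_px = 1024) {
  feats <- list()
  got_rcp <- 0L; got_art <- 0L; k <- 0L
  while ((got_rcp < n_rcp || got_art < n_artifact) && k < 50L) {
    k <- k + 1L
    sc <- scene_config(image_height_px = tile_px, image_width_px = tile_px,
                       spot_density = 160, artifact_density = 160,
                       peak_snr = peak_snr, mutant_fraction = 0.5,
                       seed = derive_seed(seed, k))
    scene <- render_scene(sc)
    set <- preprocess_stacks(scene$stacks)
    for (ch in names(set$images)) {
      enh <- enhance_spots(set$images[[ch]], cfg$enhance_radius_px)
      objs <- identify_objects(enh, cfg)
      if (nrow(objs) == 0) next
      m <- match_to_truth(objs, scene$truth, tol_px = 2)
      if (nrow(m$matches) == 0) next
      lab <- ifelse(m$matches$class == "rcp", "rcp", "not_rcp")
      fv <- extract_features(objs[match(m$matches$object_id,
                                        objs$object_id), , drop = FALSE],
                             set$images[[ch]])
      fv$label <- lab
      feats[[length(feats) + 1L]] <- fv
      got_rcp <- got_rcp + sum(lab == "rcp")
      got_art <- got_art + sum(lab == "not_rcp")
    }
  }
  all <- do.call(rbind, feats)
  rcp_rows <- which(all$label == "rcp")[seq_len(min(n_rcp, got_rcp))]
  art_rows <- which(all$label == "not_rcp")[seq_len(min(n_artifact, got_art))]
  out <- all[c(rcp_rows, art_rows), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate digital counts for a dilution series
#'
#' Renders a log10 dilution series with spot densities proportional to
#' concentration, runs preprocessing + detection on each tile, and returns
#' per-replicate mean counts per tile. The lowest concentrations are
#' rendered over several tiles so that Poisson noise on a handful of spots
#' does not dominate the regression.
#'
#' @param seed master seed.
#' @param concentrations molar concentrations (default 1 fM - 10 pM in
#'   log10 steps).
#' @param densities expected spots per tile per concentration.
#' @param replicates replicate measurements per concentration.
#' @param tiles_per_conc tiles averaged within one replicate at each
#'   concentration.
#' @param peak_snr scene peak SNR.
#' @param tile_px tile size.
#' @param cfg detection configuration.
#' @return `data.frame` with `conc_molar`, `replicate`, `count` (mean
#'   detected objects per tile).
#' @export
simulate_dilution_counts <- function(seed = 1,
                                     concentrations = 10^seq(-15, -11),
                                     densities = c(2, 20, 200, 2000, 20000),
                                     replicates = 3,
                                     tiles_per_conc = c(4, 2, 1, 1, 1),
                                     peak_snr = 8, tile_px = 1024,
                                     cfg = detection_config()) {
  stopifnot(length(concentrations) == length(densities),
            length(tiles_per_conc) == length(densities))
  rows <- list()
  for (i in seq_along(concentrations)) {
    for (r in seq_len(replicates)) {
      counts <- vapply(seq_len(tiles_per_conc[i]), function(t) {
        sc <- scene_config(image_height_px = tile_px,
                           image_width_px = tile_px,
                           spot_density = densities[i],
                           artifact_density = 0, peak_snr = peak_snr,
                           channels = "cy5",
                           seed = derive_seed(seed, 1000 * i + 10 * r + t))
        scene <- render_scene(sc)
        set <- preprocess_stacks(scene$stacks)
        objs <- detect_scene(set, cfg)
        nrow(objs)
      }, numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(conc_molar = concentrations[i], replicate = r,
                   count = mean(counts))
    }
  }
  do.call(rbind, rows)
}
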