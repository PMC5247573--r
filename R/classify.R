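#' Train the RCP random-forest classifier
#'
#' Fits a bootstrap-aggregated ("bagged") forest of decision trees with
#' random feature subsets per split on the 14-feature panel, separating
#' true RCP detections from background and artifact detections. Training
#' rows are first sorted by a stable key so that the fitted model is
#' invariant to the row order of the training set; all remaining
#' randomness (bootstrap and feature sampling) is governed by `seed`.
#'
#' @param features `data.frame` containing the 14 columns of
#'   [rcp_feature_names] (extra columns are ignored).
#' @param labels factor or character vector with levels `rcp` / `not_rcp`.
#' @param n_trees number of trees (default 100).
#' @param mtry features considered per split (default `ceiling(sqrt(14))`).
#' @param seed integer seed for bootstrap/feature randomness.
#' @return object of class `rcp_forest` with elements `forest`,
#'   `feature_names`, `feature_signature`, `n_trees`, `mtry`, `seed`,
#'   `oob_accuracy`, `version`.
#' @export
train_rcp_classifier <- function(features, labels, n_trees = 100,
                                 mtry = ceiling(sqrt(14)), seed = 1) {
  miss <- setdiff(rcp_feature_names, names(features))
  if (length(miss)) stop("missing feature column(s): ",
                         paste(miss, collapse = ", "))
  x <- features[, rcp_feature_names, drop = FALSE]
  if (any(!vapply(x, function(c) all(is.finite(c)), logical(1))))
    stop("features must be finite")
  y <- factor(as.character(labels), levels = c("not_rcp", "rcp"))
  if (any(is.na(y))) stop("labels must be 'rcp' or 'not_rcp'")
  if (nlevels(droplevels(y)) < 2)
    stop("training set must contain both classes")
  if (min(table(y)) < 10)
    stop("need at least 10 examples per class")
  # canonical row order: model independent of how rows were assembled
  ord <- do.call(order, c(as.list(x), list(as.integer(y))))
  x <- x[ord, , drop = FALSE]
  y <- y[ord]
  rf <- with_seed(seed,
    randomForest::randomForest(x, y, ntree = n_trees, mtry = mtry))
  oob <- 1 - rf$err.rate[n_trees, "OOB"]
  structure(list(forest = rf, feature_names = rcp_feature_names,
                 feature_signature = paste(rcp_feature_names, collapse = ","),
                 n_trees = n_trees, mtry = mtry, seed = seed,
                 oob_accuracy = unname(oob), version = 1L),
            class = "rcp_forest")
}

#' Classify feature vectors with a trained forest
#'
#' Majority vote over the trees; exact ties are resolved conservatively to
#' `not_rcp`, since spurious counts from auto-fluorescent structures are
#' the failure mode digital counting must guard against.
#'
#' @param model an `rcp_forest`.
#' @param features `data.frame` containing the 14 feature columns in the
#'   panel (order is checked against the model's feature signature).
#' @return `data.frame` with `label` (`rcp`/`not_rcp`) and `vote_fraction`
#'   (fraction of trees voting for the assigned label).
#' @export
predict_rcp <- function(model, features) {
  stopifnot(inherits(model, "rcp_forest"))
  miss <- setdiff(model$feature_names, names(features))
  if (length(miss)) stop("feature mismatch; missing: ",
                         paste(miss, collapse = ", "))
  sig <- paste(model$feature_names, collapse = ",")
  if (!identical(sig, model$feature_signature))
    stop("feature order signature does not match the model")
  x <- features[, model$feature_names, drop = FALSE]
  votes <- stats::predict(model$forest, x, type = "vote", norm.votes = TRUE)
  p_rcp <- votes[, "rcp"]
  label <- ifelse(p_rcp > 0.5, "rcp", "not_rcp")  # tie (0.5) -> not_rcp
  data.frame(label = label,
             vote_fraction = ifelse(label == "rcp", p_rcp, 1 - p_rcp),
             row.names = NULL)
}

#' Cross-validated accuracy of the classifier
#'
#' Stratified k-fold cross-validation: folds are assigned per class under
#' the given seed, a forest is trained on each training split (seed derived
#' per fold) and evaluated on the held-out split.
#'
#' @param features feature table (14 panel columns).
#' @param labels class labels (`rcp`/`not_rcp`).
#' @param k_folds number of folds (>= 2).
#' @param n_trees trees per fold model.
#' @param seed seed controlling fold assignment and per-fold training.
#' @return list with `mean_accuracy`, `sd_accuracy`, `fold_accuracy`.
#' @export
evaluate_rcp_classifier <- function(features, labels, k_folds = 5,
                                    n_trees = 100, seed = 1) {
  if (k_folds < 2) stop("k_folds must be >= 2")
  y <- factor(as.character(labels), levels = c("not_rcp", "rcp"))
  n <- length(y)
  fold <- with_seed(derive_seed(seed, 0), {
    f <- integer(n)
    for (cl in levels(y)) {
      ix <- which(y == cl)
      f[ix] <- rep_len(sample(k_folds), length(ix))
    }
    f
  })
  if (any(vapply(seq_len(k_folds), function(k)
    nlevels(droplevels(y[fold != k])) < 2, logical(1))))
    stop("a fold lost one class entirely; use fewer folds or more data")
  acc <- vapply(seq_len(k_folds), function(k) {
    tr <- fold != k
    m <- train_rcp_classifier(features[tr, , drop = FALSE], y[tr],
                              n_trees = n_trees, seed = derive_seed(seed, k))
    pred <- predict_rcp(m, features[!tr, , drop = FALSE])
    mean(pred$label == as.character(y[!tr]))
  }, numeric(1))
  list(mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
       fold_accuracy = acc)
}

#' Save / load a trained classifier
#'
#' The model is persisted as a single versioned file embedding the feature
#' order signature; loading verifies both so that a stale model cannot be
#' silently applied to a different feature layout.
#'
#' @param model an `rcp_forest`.
#' @param path file path.
#' @return `save_rcp_model`: invisibly, `path`; `load_rcp_model`: the
#'   restored `rcp_forest`.
#' @export
save_rcp_model <- function(model, path) {
  stopifnot(inherits(model, "rcp_forest"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_rcp_model
#' @export
load_rcp_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "rcp_forest")) stop("not an rcp_forest model file")
  if (!identical(model$feature_signature,
                 paste(rcp_feature_names, collapse = ",")))
    stop("model feature signature does not match this package version")
  model
}
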