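#' Pool RCP counts over regions of interest
#'
#' Element-wise sums of mutant / wild-type / rejected counts over the ROIs
#' of one sample. In tissue practice at least six randomly chosen imaged
#' areas are needed to accumulate enough mutant RCPs for a stable ratio;
#' fewer ROIs set a warning flag.
#'
#' @param rois `data.frame` with columns `n_mutant`, `n_wildtype` and
#'   optionally `n_rejected`.
#' @param min_rois minimum number of ROIs considered sufficient.
#' @return list with `n_rois`, `n_mutant`, `n_wildtype`, `n_rejected` and
#'   `insufficient_rois` flag.
#' @export
pool_rois <- function(rois, min_rois = 6) {
  if (is.null(nrow(rois)) || nrow(rois) == 0) stop("empty ROI list")
  if (any(rois$n_mutant < 0) || any(rois$n_wildtype < 0))
    stop("counts must be >= 0")
  nrej <- if ("n_rejected" %in% names(rois)) sum(rois$n_rejected) else 0L
  list(n_rois = nrow(rois),
       n_mutant = sum(rois$n_mutant),
       n_wildtype = sum(rois$n_wildtype),
       n_rejected = nrej,
       insufficient_rois = nrow(rois) < min_rois)
}

#' Score a sample as Mutant or Wild type
#'
#' Computes the pooled mutant/wild-type ratio `100 * MT / WT` and scores
#' the sample `Mutant` when the (unrounded) ratio exceeds
#' `threshold_percent`, `Wild type` otherwise (a ratio exactly at the
#' threshold scores wild type). The reported `ratio_percent` is rounded to
#' one decimal, half up, matching how such tables are printed; the
#' score itself never depends on display rounding.
#'
#' @param n_mutant,n_wildtype pooled counts (vectorized).
#' @param threshold_percent scoring threshold in percent (default 8, the
#'   highest mutant ratio observed on clinically wild-type tissue).
#' @param sample_id optional sample label(s) used in error messages.
#' @return `data.frame` with `sample_id` (if given), `n_mutant`,
#'   `n_wildtype`, `ratio_percent` (1 decimal), `score` and
#'   `threshold_percent`.
#' @export
score_genotype <- function(n_mutant, n_wildtype, threshold_percent = 8,
                           sample_id = NULL) {
  if (any(n_wildtype <= 0)) {
    bad <- which(n_wildtype <= 0)
    lab <- if (!is.null(sample_id)) paste(sample_id[bad], collapse = ", ")
           else paste(bad, collapse = ", ")
    stop("undefined mutant/wild-type ratio (no wild-type RCPs) for: ", lab)
  }
  ratio <- 100 * n_mutant / n_wildtype
  out <- data.frame(n_mutant = n_mutant, n_wildtype = n_wildtype,
                    ratio_percent = round_half_up(ratio, 1),
                    score = ifelse(ratio > threshold_percent,
                                   "Mutant", "Wild type"),
                    threshold_percent = threshold_percent)
  if (!is.null(sample_id)) out <- cbind(sample_id = sample_id, out)
  out
}

#' Concordance between genotype calls and reference genotypes
#'
#' @param calls character vector of `Mutant`/`Wild type` calls, named by
#'   sample or accompanied by `sample_id`.
#' @param reference reference genotypes (`Mutant`/`Wild type`), same
#'   samples.
#' @param sample_id,reference_id optional explicit sample identifiers.
#' @return percent agreement in \[0, 100\].
#' @export
concordance <- function(calls, reference, sample_id = names(calls),
                        reference_id = names(reference)) {
  if (length(calls) == 0) stop("no genotype calls supplied")
  if (!is.null(sample_id) && !is.null(reference_id)) {
    if (!setequal(sample_id, reference_id))
      stop("sample ids of calls and reference do not match")
    reference <- reference[match(sample_id, reference_id)]
  } else if (length(calls) != length(reference)) {
    stop("calls and reference differ in length and carry no ids")
  }
  100 * mean(calls == reference)
}

#' Log-log regression of a dilution series
#'
#' Ordinary least squares of `log10(mean count)` on `log10(concentration)`.
#' The linear dynamic range is the widest contiguous span of
#' concentrations over which the fit restricted to that span has
#' R-squared >= `r2_min`; a saturating top point therefore drops out of the
#' reported span. The returned slope/intercept/R-squared describe the fit
#' on that linear span.
#'
#' @param points `data.frame` with columns `conc_molar` and `count`
#'   (replicates as repeated rows; a `replicate` column is allowed and
#'   ignored).
#' @param r2_min R-squared required of the linear span (default 0.98).
#' @return object of class `dilution_fit`: `points` (per-concentration
#'   mean, s.d., n), `slope`, `intercept`, `r_squared`,
#'   `dynamic_range_decades`, `span_concentrations`.
#' @export
dilution_regression <- function(points, r2_min = 0.98) {
  stopifnot(all(c("conc_molar", "count") %in% names(points)))
  agg <- do.call(rbind, lapply(split(points, points$conc_molar), function(d) {
    data.frame(conc_molar = d$conc_molar[1], mean_count = mean(d$count),
               sd_count = if (nrow(d) > 1) stats::sd(d$count) else 0,
               n = nrow(d))
  }))
  agg <- agg[order(agg$conc_molar), ]
  rownames(agg) <- NULL
  pos <- agg[agg$mean_count > 0, ]
  if (nrow(pos) < 2)
    stop("need at least 2 concentrations with positive mean counts")
  x <- log10(pos$conc_molar); y <- log10(pos$mean_count)
  fit_span <- function(i, j) {
    xi <- x[i:j]; yi <- y[i:j]
    f <- stats::lm(yi ~ xi)
    sst <- sum((yi - mean(yi))^2)
    r2 <- if (j - i + 1 <= 2 || sst == 0) 1
          else 1 - sum(stats::residuals(f)^2) / sst
    list(i = i, j = j, slope = unname(stats::coef(f)[2]),
         intercept = unname(stats::coef(f)[1]), r2 = r2,
         decades = x[j] - x[i])
  }
  best <- NULL
  m <- length(x)
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    fs <- fit_span(i, j)
    if (fs$r2 >= r2_min &&
        (is.null(best) || fs$decades > best$decades ||
         (fs$decades == best$decades && (fs$j - fs$i) > (best$j - best$i))))
      best <- fs
  }
  if (is.null(best)) best <- fit_span(1, m)  # no span met r2_min; report full
  structure(list(points = agg, slope = best$slope,
                 intercept = best$intercept, r_squared = best$r2,
                 dynamic_range_decades = best$decades,
                 span_concentrations = pos$conc_molar[best$i:best$j]),
            class = "dilution_fit")
}

#' Bundled tumour-section RCP counts
#'
#' Example dataset: pooled mutant / wild-type RCP counts from mobile-phone
#' in situ KRAS genotyping of six colon tumour sections, together with the
#' clinical NGS genotype of each sample. Used in examples and to exercise
#' the scoring and concordance operations on published real-world counts.
#'
#' @return `data.frame` with columns `sample_id`, `n_rois`, `n_mutant`,
#'   `n_wildtype`, `clinical` (`Mutant`/`Wild type`), `clinical_detail`.
#' @export
tumour_counts <- function() {
  f <- system.file("extdata", "tumour_counts.csv", package = "rcpscope",
                   mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
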