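#' Base-to-channel coding map
#'
#' Sequencing-by-ligation colour code for the interrogated position:
#' by default A is read out on Cy5, T on FITC, G on Cy3 and C on Texas red
#' or, in two-channel operation, by the absence of signal ("blank").
#' Calling the blank base from absent signal is disabled by default; with
#' it disabled, signal-free objects yield `no_call`.
#'
#' @param channels named character vector channel -> base.
#' @param anchor label of the anchor channel (common stain on every RCP).
#' @param blank_base base coded by absence of signal.
#' @param call_blank whether absence of signal calls `blank_base`.
#' @return object of class `base_coding_map`.
#' @export
base_coding_map <- function(channels = c(cy5 = "A", fitc = "T",
                                         cy3 = "G", txred = "C"),
                            anchor = "anchor", blank_base = "C",
                            call_blank = FALSE) {
  if (anyDuplicated(channels))
    stop("each base may map to at most one channel")
  if (anchor %in% names(channels))
    stop("anchor channel cannot also code a base")
  structure(list(channels = channels, anchor = anchor,
                 blank_base = blank_base, call_blank = call_blank),
            class = "base_coding_map")
}

# background-subtracted per-channel mean signals for measured objects,
# floored at zero; channels restricted to those in the coding map AND
# measured on the objects
object_signals <- function(objects, coding) {
  chs <- intersect(names(coding$channels),
                   sub("^mean_", "", grep("^mean_", names(objects),
                                          value = TRUE)))
  if (!length(chs)) stop("no coded channels measured on these objects")
  sig <- sapply(chs, function(ch) {
    pmax(0, objects[[paste0("mean_", ch)]] - objects[[paste0("bg_mean_", ch)]])
  })
  if (is.null(dim(sig))) sig <- matrix(sig, nrow = nrow(objects),
                                       dimnames = list(NULL, chs))
  sig
}

#' Anchor-channel gating
#'
#' The anchor stain marks every true RCP; detected objects whose
#' background-subtracted anchor signal falls below the gate are discarded
#' as non-RCPs. If the anchor channel was not measured (two-channel
#' operation), gating is skipped with a warning and all objects are kept.
#'
#' @param objects measured `detected_objects`
#'   (see [measure_across_channels()]).
#' @param anchor_channel anchor channel label.
#' @param anchor_min_intensity gate on the background-subtracted anchor
#'   mean; `NULL` uses 3x the median anchor annulus s.d.
#' @return list with `kept` and `rejected` object tables; `rejected`
#'   carries `status = "rejected_no_anchor"`.
#' @export
anchor_gate <- function(objects, anchor_channel = "anchor",
                        anchor_min_intensity = NULL) {
  mcol <- paste0("mean_", anchor_channel)
  if (!mcol %in% names(objects)) {
    warning("anchor channel '", anchor_channel,
            "' not measured; anchor gating skipped")
    return(list(kept = objects, rejected = objects[0, , drop = FALSE]))
  }
  sig <- pmax(0, objects[[mcol]] - objects[[paste0("bg_mean_", anchor_channel)]])
  if (is.null(anchor_min_intensity))
    anchor_min_intensity <-
      3 * stats::median(objects[[paste0("bg_sd_", anchor_channel)]])
  keep <- sig >= anchor_min_intensity
  rejected <- objects[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$status <- "rejected_no_anchor"
  list(kept = objects[keep, , drop = FALSE], rejected = rejected)
}

#' Double-stain ratio of measured objects
#'
#' Ratio of the second-highest to the highest background-subtracted
#' channel mean over the coded signal channels; 0 when the highest signal
#' is 0. Objects with a ratio above 0.3 are conventionally discarded as
#' auto-fluorescent, since a genuine single-base stain lights only one
#' channel.
#'
#' @param objects measured `detected_objects`.
#' @param coding a [base_coding_map()].
#' @return numeric vector of ratios in \[0, 1\].
#' @export
double_stain_ratio <- function(objects, coding = base_coding_map()) {
  sig <- object_signals(objects, coding)
  apply(sig, 1, function(s) {
    s <- sort(s, decreasing = TRUE)
    if (s[1] <= 0) 0
    else if (length(s) < 2) 0
    else s[2] / s[1]
  })
}

#' Call a base for each measured object
#'
#' Decision rule per object, on background-subtracted channel means:
#' if every coded channel is below `min_signal`, call the blank base if
#' the coding declares one (else `no_call`); otherwise, if the double-stain
#' ratio exceeds `ratio_threshold`, reject the object as auto-fluorescent;
#' otherwise call the base coded by the dominant channel. A ratio exactly
#' at the threshold is kept.
#'
#' @param objects measured `detected_objects`.
#' @param coding a [base_coding_map()].
#' @param min_signal minimum background-subtracted signal regarded as a
#'   stain; `NULL` uses 3x the median annulus s.d. per channel.
#' @param ratio_threshold double-stain rejection threshold in (0, 1).
#' @return `data.frame` of class `base_calls`: `object_id`, `called_base`
#'   (`A`/`T`/`G`/`C`/`no_call`), `status` (`accepted`,
#'   `rejected_double_stain`, `no_call`), `dominant_channel`,
#'   `double_stain_ratio`.
#' @export
call_bases <- function(objects, coding = base_coding_map(),
                       min_signal = NULL, ratio_threshold = 0.3) {
  if (ratio_threshold <= 0 || ratio_threshold >= 1)
    stop("ratio_threshold must be in (0, 1)")
  sig <- object_signals(objects, coding)
  chs <- colnames(sig)
  if (is.null(min_signal)) {
    ms <- vapply(chs, function(ch)
      3 * stats::median(objects[[paste0("bg_sd_", ch)]]), numeric(1))
  } else {
    ms <- rep_len(min_signal, length(chs))
    names(ms) <- chs
  }
  n <- nrow(objects)
  base <- character(n); status <- character(n)
  dom <- character(n); ratio <- numeric(n)
  for (i in seq_len(n)) {
    s <- sig[i, ]
    o <- order(s, decreasing = TRUE)
    top <- chs[o[1]]
    ratio[i] <- if (s[o[1]] <= 0) 0
                else if (length(s) < 2) 0
                else s[o[2]] / s[o[1]]
    if (all(s < ms)) {
      dom[i] <- "none"
      if (isTRUE(coding$call_blank)) {
        base[i] <- coding$blank_base; status[i] <- "accepted"
      } else {
        base[i] <- "no_call"; status[i] <- "no_call"
      }
    } else if (ratio[i] > ratio_threshold) {
      base[i] <- "no_call"; status[i] <- "rejected_double_stain"
      dom[i] <- top
    } else {
      base[i] <- unname(coding$channels[top]); status[i] <- "accepted"
      dom[i] <- top
    }
  }
  out <- data.frame(object_id = objects$object_id, called_base = base,
                    status = status, dominant_channel = dom,
                    double_stain_ratio = ratio)
  class(out) <- c("base_calls", "data.frame")
  out
}

#' Tally base calls
#'
#' Counts calls per base and per status; the grand total is preserved.
#'
#' @param calls a `base_calls` table (possibly with extra
#'   `rejected_no_anchor` rows appended).
#' @return list with `base_counts` (named integer vector over A/T/G/C),
#'   `status_counts` (named integer vector) and `total`.
#' @export
tally_calls <- function(calls) {
  bases <- c("A", "T", "G", "C")
  statuses <- c("accepted", "rejected_double_stain", "rejected_no_anchor",
                "no_call")
  acc <- calls$called_base[calls$status == "accepted"]
  base_counts <- vapply(bases, function(b) sum(acc == b), integer(1))
  status_counts <- vapply(statuses, function(s) sum(calls$status == s),
                          integer(1))
  list(base_counts = base_counts, status_counts = status_counts,
       total = nrow(calls))
}
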