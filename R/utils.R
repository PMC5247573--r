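#' Round half away from zero
#'
#' Decimal rounding with ties going up (`0.65 -> 0.7` at one decimal),
#' matching how ratio percentages are conventionally printed in genotyping
#' reports. Base R's `round()` rounds half to even and is not suitable for
#' reproducing printed tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Effective magnification of a camera plus external lens
#'
#' For a fixed-focus camera module imaging through an external objective
#' lens placed in front of it, the effective transverse magnification is the
#' ratio of the camera focal length to the external lens focal length.
#'
#' @param camera_focal_mm focal length of the camera module in mm.
#' @param lens_focal_mm focal length of the external lens in mm.
#' @return magnification factor (dimensionless).
#' @examples
#' effective_magnification(6.86, 2.6) # ~2.6x
#' @export
effective_magnification <- function(camera_focal_mm, lens_focal_mm) {
  stopifnot(camera_focal_mm > 0, lens_focal_mm > 0)
  camera_focal_mm / lens_focal_mm
}

# clamp values into [lo, hi]
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# run expr with a temporarily seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stable small-integer sub-seed derived from a master seed
derive_seed <- function(seed, k) {
  (as.integer(seed) * 7919L + as.integer(k) * 104729L) %% 2147483629L
}
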