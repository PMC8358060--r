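#' Peaked Arrhenius temperature-correction factor for Vcmax
#'
#' Ratio of Vcmax at leaf temperature to Vcmax at 25 degrees C under the
#' peaked Arrhenius response
#' \deqn{f(T_l) = \exp\!\left[\frac{H_a (T_l - T_{ref})}{T_{ref} R T_l}\right]
#'   \frac{1 + \exp\!\left(\frac{T_{ref}\Delta S - H_d}{T_{ref} R}\right)}
#'        {1 + \exp\!\left(\frac{T_l \Delta S - H_d}{T_l R}\right)}}
#' with \eqn{T_l} in Kelvin. The function equals 1 exactly at 25 degrees C
#' and has a single interior optimum (activation term rising, deactivation
#' term collapsing at high temperature). Temperature acclimation of the
#' parameters is deliberately not modelled.
#'
#' @param tleaf Leaf temperature in degrees C (vectorized).
#' @param constants A [physio_constants()] object.
#' @param apply_floor If `TRUE`, the factor is floored at
#'   `constants$temp_floor` (guard used when projecting model output at
#'   extreme cold temperatures). Default `FALSE`.
#' @return Dimensionless scale factor(s), same length as `tleaf`.
#' @examples
#' arrhenius_factor(25) # exactly 1
#' arrhenius_factor(30) # ~1.351
#' @export
arrhenius_factor <- function(tleaf, constants = physio_constants(),
                             apply_floor = FALSE) {
  if (any(is.nan(tleaf) | is.infinite(tleaf))) {
    stop("tleaf contains non-finite values")
  }
  tl <- tleaf + 273.15
  if (any(tl <= 0, na.rm = TRUE)) stop("leaf temperature below 0 K")
  with(constants, {
    act <- exp(Ha * (tl - Tref) / (Tref * R * tl))
    peak <- (1 + exp((Tref * deltaS - Hd) / (Tref * R))) /
      (1 + exp((tl * deltaS - Hd) / (tl * R)))
    f <- act * peak
    if (apply_floor) f <- pmax(f, temp_floor)
    f
  })
}

#' Standardize Vcmax measured at leaf temperature to 25 degrees C
#'
#' @param vcmax_at_tleaf Vcmax at `tleaf` (umol m-2 s-1); non-negative.
#' @param tleaf Leaf temperature (degrees C).
#' @inheritParams arrhenius_factor
#' @return Vcmax25 (umol m-2 s-1).
#' @seealso [project_from_25()] for the exact inverse.
#' @export
standardize_to_25 <- function(vcmax_at_tleaf, tleaf,
                              constants = physio_constants()) {
  if (any(vcmax_at_tleaf < 0, na.rm = TRUE)) {
    stop("vcmax_at_tleaf must be non-negative")
  }
  f <- arrhenius_factor(tleaf, constants)
  if (any(f <= 0, na.rm = TRUE)) stop("non-positive temperature factor")
  vcmax_at_tleaf / f
}

#' Project Vcmax25 to a leaf temperature
#'
#' Exact inverse of [standardize_to_25()].
#'
#' @param vcmax25 Vcmax at 25 degrees C (umol m-2 s-1); non-negative.
#' @inheritParams standardize_to_25
#' @inheritParams arrhenius_factor
#' @return Vcmax at `tleaf` (umol m-2 s-1).
#' @export
project_from_25 <- function(vcmax25, tleaf, constants = physio_constants(),
                            apply_floor = FALSE) {
  if (any(vcmax25 < 0, na.rm = TRUE)) stop("vcmax25 must be non-negative")
  vcmax25 * arrhenius_factor(tleaf, constants, apply_floor = apply_floor)
}
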