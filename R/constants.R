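#' Physiological constants linking Vcmax25, leaf nitrogen and fLNR
#'
#' Bundles the constants of the RuBisCO nitrogen-allocation identity
#' \deqn{V_{cmax}^{25} = \alpha^{25} \times LNC \times fNR \times fLNR}
#' and of the peaked Arrhenius temperature response used to standardize
#' Vcmax to 25 degrees C.
#'
#' @param alpha25 Specific activity of RuBisCO, the maximum carboxylation
#'   rate per gram of RuBisCO at 25 degrees C
#'   (umol CO2 g-1 RuBisCO s-1). Default 47.34.
#' @param fNR Mass of RuBisCO per unit nitrogen in RuBisCO
#'   (g RuBisCO g-1 N). Default 6.25.
#' @param Ha Activation energy for carboxylation (J mol-1).
#' @param Hd Deactivation energy (J mol-1). Must exceed `Ha`.
#' @param deltaS Entropy term (J mol-1 K-1).
#' @param R Universal gas constant (J mol-1 K-1).
#' @param Tref Reference temperature (K); 298.15 K = 25 degrees C.
#' @param alpha25_range,fNR_range Literature uncertainty ranges used by the
#'   bootstrap; `alpha25` and `fNR` must fall inside them.
#' @param temp_floor Minimum admissible value of the temperature-correction
#'   factor. Only applied when explicitly requested (see
#'   [arrhenius_factor()]); 0.08 is the conventional guard against extreme
#'   cold-temperature projections.
#'
#' @return An object of class `physio_constants` (a named list).
#' @examples
#' cs <- physio_constants()
#' cs$alpha25 * cs$fNR # nitrogen-to-Vcmax25 conversion at fLNR = 1, LNC = 1
#' @export
physio_constants <- function(alpha25 = 47.34,
                             fNR = 6.25,
                             Ha = 71513,
                             Hd = 200000,
                             deltaS = 649.12,
                             R = 8.314,
                             Tref = 298.15,
                             alpha25_range = c(47.34, 60.0),
                             fNR_range = c(6.11, 7.16),
                             temp_floor = 0.08) {
  stopifnot(
    is.numeric(alpha25), length(alpha25) == 1L, is.finite(alpha25),
    is.numeric(fNR), length(fNR) == 1L, is.finite(fNR),
    length(alpha25_range) == 2L, length(fNR_range) == 2L
  )
  if (!(Hd > Ha && Ha > 0)) {
    stop("deactivation energy Hd must exceed activation energy Ha > 0")
  }
  if (Tref <= 0) stop("Tref must be a positive Kelvin temperature")
  if (alpha25 < alpha25_range[1] || alpha25 > alpha25_range[2]) {
    stop(sprintf(
      "alpha25 = %g outside its admissible range [%g, %g]",
      alpha25, alpha25_range[1], alpha25_range[2]
    ))
  }
  if (fNR < fNR_range[1] || fNR > fNR_range[2]) {
    stop(sprintf(
      "fNR = %g outside its admissible range [%g, %g]",
      fNR, fNR_range[1], fNR_range[2]
    ))
  }
  structure(
    list(
      alpha25 = alpha25, fNR = fNR,
      Ha = Ha, Hd = Hd, deltaS = deltaS, R = R, Tref = Tref,
      alpha25_range = alpha25_range, fNR_range = fNR_range,
      temp_floor = temp_floor
    ),
    class = "physio_constants"
  )
}

#' @export
print.physio_constants <- function(x, ...) {
  cat("Physiological constants:\n")
  cat(sprintf(
    "  alpha25 = %g umol CO2 g-1 RuBisCO s-1 (range %g-%g)\n",
    x$alpha25, x$alpha25_range[1], x$alpha25_range[2]
  ))
  cat(sprintf(
    "  fNR     = %g g RuBisCO g-1 N (range %g-%g)\n",
    x$fNR, x$fNR_range[1], x$fNR_range[2]
  ))
  cat(sprintf(
    "  Ha = %g, Hd = %g J mol-1; deltaS = %g J mol-1 K-1; Tref = %g K\n",
    x$Ha, x$Hd, x$deltaS, x$Tref
  ))
  invisible(x)
}
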