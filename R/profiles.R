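#' Describe one absorption peak
#'
#' A Gaussian absorption band with a per-class amplitude, the building
#' block of the synthetic class profiles.
#'
#' @param center Band center in cm^-1.
#' @param width Gaussian standard deviation in cm^-1 (> 0).
#' @param amplitude_by_class Named nonnegative numeric vector mapping each
#'   origin class to its peak amplitude (absorbance units).
#'
#' @return An object of class `peak_spec`.
#' @export
peak_spec <- function(center, width, amplitude_by_class) {
  if (!is.finite(center)) stop("`center` must be finite", call. = FALSE)
  if (!is.finite(width) || width <= 0) {
    stop("`width` must be > 0", call. = FALSE)
  }
  if (is.null(names(amplitude_by_class)) ||
      any(!nzchar(names(amplitude_by_class)))) {
    stop("`amplitude_by_class` must be a fully named vector", call. = FALSE)
  }
  if (any(!is.finite(amplitude_by_class)) || any(amplitude_by_class < 0)) {
    stop("amplitudes must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(center = center, width = width,
         amplitude_by_class = amplitude_by_class),
    class = "peak_spec"
  )
}

#' Default per-class absorption profiles of the four Maojian origins
#'
#' Encodes the spectral structure that separates the origins:
#' all four classes share bands at 4258, 4404, 4666, 5191, 5781 and
#' 6884 cm^-1; a band at 8778 cm^-1 is present, with equal amplitude,
#' only for Changsha and Zunyi. The polyphenol/sugar-associated bands
#' (4258, 4404, 4666, 5781, 6884 cm^-1) carry class-ordered amplitudes,
#' Changsha > Chengdu > Xinyang > Zunyi (multiplicative factors 1.0, 0.9,
#' 0.8, 0.7), while the caffeine band at 5191 cm^-1 is nearly equal across
#' classes (within 5 percent relative spread). Absolute amplitudes are in
#' raw absorbance units; their overall scale is arbitrary because the
#' pipeline normalizes each spectrum.
#'
#' @param width Gaussian band width (sd, cm^-1) shared by all peaks.
#'
#' @return List of [peak_spec] objects.
#' @export
#' @examples
#' profs <- default_class_profiles()
#' sapply(profs, function(p) p$center)
default_class_profiles <- function(width = 60) {
  cls <- maojian_classes()  # Changsha, Chengdu, Xinyang, Zunyi
  ordered_factors <- c(Changsha = 1.0, Chengdu = 0.9,
                       Xinyang = 0.8, Zunyi = 0.7)
  flat_factors <- c(Changsha = 1.00, Chengdu = 0.99,
                    Xinyang = 1.01, Zunyi = 1.00)
  base <- c(`4258` = 0.90, `4404` = 0.70, `4666` = 0.80, `5191` = 0.85,
            `5781` = 0.55, `6884` = 0.45)
  peaks <- lapply(names(base), function(wn) {
    fac <- if (wn == "5191") flat_factors else ordered_factors
    peak_spec(as.numeric(wn), width, base[[wn]] * fac[cls])
  })
  marker <- peak_spec(8778, width,
                      c(Changsha = 0.25, Chengdu = 0, Xinyang = 0,
                        Zunyi = 0.25))
  c(peaks, list(marker))
}
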