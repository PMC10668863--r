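## CIE 1924 photopic luminous efficiency V(lambda), 380-780 nm at 5 nm
## (the CIE 1931 y-bar values; maximum exactly 1 at 555 nm).
CIE_VLAMBDA_NM <- seq(380, 780, by = 5)
CIE_VLAMBDA <- c(
  0.000039, 0.000064, 0.000120, 0.000217, 0.000396, 0.000640, 0.001210,
  0.002180, 0.004000, 0.007300, 0.011600, 0.016840, 0.023000, 0.029800,
  0.038000, 0.048000, 0.060000, 0.073900, 0.090980, 0.112600, 0.139020,
  0.169300, 0.208020, 0.258600, 0.323000, 0.407300, 0.503000, 0.608200,
  0.710000, 0.793200, 0.862000, 0.914850, 0.954000, 0.980300, 0.994950,
  1.000000, 0.995000, 0.978600, 0.952000, 0.915400, 0.870000, 0.816300,
  0.757000, 0.694900, 0.631000, 0.566800, 0.503000, 0.441200, 0.381000,
  0.321000, 0.265000, 0.217000, 0.175000, 0.138200, 0.107000, 0.081600,
  0.061000, 0.044580, 0.032000, 0.023200, 0.017000, 0.011920, 0.008210,
  0.005723, 0.004102, 0.002929, 0.002091, 0.001484, 0.001047, 0.000740,
  0.000520, 0.000361, 0.000249, 0.000172, 0.000120, 0.000085, 0.000060,
  0.000042, 0.000030, 0.000021, 0.000015)

#' Photopic luminosity function V(lambda)
#'
#' The standard human photopic weighting used to bridge radiometric and
#' photometric units (the candela is defined through it). Values are linearly
#' interpolated from the tabulated 5 nm curve and are zero outside 380-780 nm;
#' the maximum is exactly 1 at 555 nm.
#'
#' @param grid Wavelengths (nm) at which to evaluate; defaults to the
#'   tabulated grid.
#' @return A [spectrum()] with unit `"sensitivity"`.
#' @export
luminosity_function <- function(grid = CIE_VLAMBDA_NM) {
  v <- stats::approx(CIE_VLAMBDA_NM, CIE_VLAMBDA, xout = grid, rule = 1)$y
  v[is.na(v)] <- 0
  spectrum(grid, v, "sensitivity")
}

#' Luminous intensity of a radiant-intensity spectrum
#'
#' Computes 683 * integral of s(lambda) * V(lambda) d lambda (trapezoidal),
#' the photometric luminous intensity in candela of a source whose spectral
#' radiant intensity (W/sr/nm) is `s`. A one-point spectrum is treated as a
#' monochromatic line carrying its value in W/sr. Used only to label stimulus
#' intensity settings in human units; perceived brightness for a bird is a
#' different quantity and is not modelled here.
#'
#' @param s A [spectrum()] of spectral radiant intensity per nm.
#' @param vl A luminosity function spectrum, defaulting to
#'   [luminosity_function()] on the grid of `s`.
#' @return Luminous intensity in candela.
#' @export
luminous_intensity <- function(s, vl = NULL) {
  stopifnot(inherits(s, "spectrum"))
  if (length(s) == 1L) {
    v <- luminosity_function(s$wavelengths)$values
    return(683 * s$values * v)
  }
  if (is.null(vl)) vl <- luminosity_function(s$wavelengths)
  stopifnot(inherits(vl, "spectrum"))
  if (length(vl$wavelengths) != length(s$wavelengths) ||
      any(vl$wavelengths != s$wavelengths)) {
    vl <- resample(vl, s$wavelengths)
  }
  w <- s$values * vl$values
  if (all(w == 0)) {
    warning("spectrum has no support under V(lambda); luminous intensity 0",
            call. = FALSE)
    return(0)
  }
  683 * trapz(s$wavelengths, w)
}
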