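#' Quantum catch of a receptor
#'
#' Integral of the stimulus photon-flux spectrum weighted by a receptor's
#' spectral sensitivity, \eqn{Q_i = \int R(\lambda) S_i(\lambda) d\lambda},
#' by the trapezoid rule on the common grid.
#'
#' @param stimulus A photon-flux [spectrum()].
#' @param sensitivity A sensitivity [spectrum()] on the same grid.
#' @return The quantum catch (non-negative scalar).
#' @export
quantum_catch <- function(stimulus, sensitivity) {
  stopifnot(inherits(stimulus, "spectrum"), inherits(sensitivity, "spectrum"))
  if (length(stimulus$wavelengths) != length(sensitivity$wavelengths) ||
      any(stimulus$wavelengths != sensitivity$wavelengths)) {
    sensitivity <- resample(sensitivity, stimulus$wavelengths)
  }
  trapz(stimulus$wavelengths, stimulus$values * sensitivity$values)
}

#' Receptor noise per cone channel
#'
#' Per-channel noise standard deviations on the log-signal scale, scaled from
#' the Weber fraction of the most abundant cone class by the inverse square
#' root of relative density:
#' \eqn{e_i = \omega \sqrt{\eta_{max} / \eta_i}}.
#'
#' @param vs A [visual_system()].
#' @return Named numeric vector of noise values, one per cone.
#' @export
receptor_noise <- function(vs) {
  stopifnot(inherits(vs, "visual_system"))
  eta <- vapply(vs$cones, `[[`, numeric(1), "density")
  if (any(eta <= 0)) stop("cone densities must be positive", call. = FALSE)
  e <- vs$weber_fraction * sqrt(max(eta) / eta)
  stats::setNames(e, vapply(vs$cones, `[[`, "", "name"))
}

#' Receptor-noise-limited chromatic contrast
#'
#' Chromatic distance in just-noticeable-difference (JND) units between a
#' stimulus and the background it is viewed against, for an n-cone visual
#' system. Receptor signals are the log catch ratios after von Kries
#' adaptation to the background,
#' \eqn{\Delta f_i = \ln(Q_i^{stim} / Q_i^{bg})}, and the contrast is the
#' general n-receptor noise-limited distance
#' \deqn{\Delta S^2 = \frac{\sum_{i<j} \left(\prod_{k \ne i,j} e_k\right)^2
#'   (\Delta f_i - \Delta f_j)^2}{\sum_i \left(\prod_{k \ne i} e_k\right)^2}.}
#' For two receptors this reduces to
#' \eqn{|\Delta f_1 - \Delta f_2| / \sqrt{e_1^2 + e_2^2}}. The distance
#' depends only on differences of the \eqn{\Delta f_i}, so scaling the
#' stimulus intensity leaves it unchanged: it is a colour, not a brightness,
#' measure.
#'
#' @param stimulus,background Photon-flux [spectrum()] objects on the working
#'   grid.
#' @param vs A [visual_system()].
#' @return An object of class `contrast_result`: list with `delta_s` (JND),
#'   `delta_f` (per-cone log signals), `noise` (per-cone e_i) and `catches`
#'   (stimulus and background quantum catches).
#' @export
chromatic_contrast <- function(stimulus, background, vs) {
  stopifnot(inherits(stimulus, "spectrum"), inherits(background, "spectrum"),
            inherits(vs, "visual_system"))
  if (stimulus$unit != "photon_flux" || background$unit != "photon_flux") {
    stop("chromatic_contrast expects photon_flux spectra", call. = FALSE)
  }
  q_stim <- vapply(vs$sensitivities, quantum_catch, numeric(1),
                   stimulus = stimulus)
  q_bg <- vapply(vs$sensitivities, quantum_catch, numeric(1),
                 stimulus = background)
  zero <- q_stim <= 0 | q_bg <= 0
  if (any(zero)) {
    stop("zero quantum catch in cone(s): ",
         paste(names(vs$sensitivities)[zero], collapse = ", "),
         call. = FALSE)
  }
  delta_f <- log(q_stim / q_bg)
  e <- receptor_noise(vs)
  structure(list(delta_s = rnl_distance(delta_f, e),
                 delta_f = delta_f, noise = e,
                 catches = list(stimulus = q_stim, background = q_bg)),
            class = "contrast_result")
}

#' @exportS3Method base::print
print.contrast_result <- function(x, ...) {
  cat(sprintf("<chromatic contrast: %.3f JND (%d cones)>\n",
              x$delta_s, length(x$delta_f)))
  invisible(x)
}

#' General n-receptor noise-limited distance
#'
#' The distance formula underlying [chromatic_contrast()], exposed for direct
#' use on precomputed log signals.
#'
#' @param delta_f Numeric vector of per-receptor log signals.
#' @param e Positive numeric vector of per-receptor noise values.
#' @return The chromatic distance in JND.
#' @export
rnl_distance <- function(delta_f, e) {
  n <- length(delta_f)
  stopifnot(length(e) == n, n >= 2L, all(e > 0))
  prod_e2 <- prod(e^2)
  num <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      # (prod of e_k for k not in {i,j})^2
      num <- num + prod_e2 / (e[i]^2 * e[j]^2) * (delta_f[i] - delta_f[j])^2
    }
  }
  den <- sum(prod_e2 / e^2)
  as.numeric(sqrt(num / den))
}

#' Robustness of a stimulus contrast to a background change
#'
#' Absolute difference in JND between the contrast of one stimulus seen
#' against two different backgrounds (e.g. clear vs cloudy sky).
#'
#' @param stimulus Photon-flux [spectrum()].
#' @param background_a,background_b Photon-flux [spectrum()] backgrounds.
#' @param vs A [visual_system()].
#' @return Non-negative JND difference.
#' @export
contrast_difference <- function(stimulus, background_a, background_b, vs) {
  a <- chromatic_contrast(stimulus, background_a, vs)$delta_s
  b <- chromatic_contrast(stimulus, background_b, vs)$delta_s
  abs(a - b)
}
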