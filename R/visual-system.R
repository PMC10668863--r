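#' Visual pigment absorbance template (A1 nomogram)
#'
#' Standard A1 visual-pigment nomogram of Govardovskii et al. (2000, Visual
#' Neuroscience 17:509-528): the alpha band
#' \deqn{S_\alpha(x) = 1 / (e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D)}
#' with \eqn{x = \lambda_{max}/\lambda}, A = 69.7, B = 28, C = -14.9,
#' D = 0.674, b = 0.922, c = 1.104 and
#' \eqn{a = 0.8795 + 0.0459\,e^{-(\lambda_{max}-300)^2/11940}}, plus the
#' Gaussian beta band with amplitude 0.26. The sum is renormalized to a
#' global maximum of exactly 1 on the requested grid.
#'
#' @param lambda_max Pigment peak wavelength in nm, within \[330, 700\].
#' @param grid Wavelength grid (nm); default [working_grid()].
#' @return A [spectrum()] with unit `"sensitivity"`, maximum 1 at the grid
#'   point nearest `lambda_max`.
#' @export
pigment_template <- function(lambda_max, grid = working_grid()) {
  if (!is.numeric(lambda_max) || length(lambda_max) != 1L ||
      lambda_max < 330 || lambda_max > 700) {
    stop("lambda_max must be a single wavelength in [330, 700] nm",
         call. = FALSE)
  }
  x <- lambda_max / grid
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  lam_beta <- 189 + 0.315 * lambda_max
  b_beta <- -40.5 + 0.195 * lambda_max
  beta <- 0.26 * exp(-((grid - lam_beta) / b_beta)^2)
  v <- alpha + beta
  spectrum(grid, v / max(v), "sensitivity")
}

#' Parametric oil-droplet transmittance
#'
#' Long-pass cut-off filter used for avian cone oil droplets when a measured
#' transmittance table is not available: a Gompertz sigmoid
#' \eqn{T(\lambda) = \exp(-e^{-B(\lambda - \lambda_{cut})})} rising from 0
#' below the cut-off to 1 at long wavelengths, with T = 1/e at
#' `lambda_cut`. A transparent droplet is `oil_droplet(NULL)`.
#'
#' @param lambda_cut Cut-off wavelength in nm, or `NULL` for a transparent
#'   droplet.
#' @param slope Steepness B in 1/nm (default 0.2).
#' @param grid Wavelength grid (nm).
#' @return A [spectrum()] with unit `"transmittance"`.
#' @export
oil_droplet_transmittance <- function(lambda_cut, slope = 0.2,
                                      grid = working_grid()) {
  if (is.null(lambda_cut)) {
    return(spectrum(grid, rep(1, length(grid)), "transmittance"))
  }
  stopifnot(is.numeric(lambda_cut), length(lambda_cut) == 1L, slope > 0)
  v <- exp(-exp(-slope * (grid - lambda_cut)))
  spectrum(grid, v, "transmittance")
}

#' Cone photoreceptor class
#'
#' @param name Label, e.g. `"VS"`, `"SWS"`, `"MWS"`, `"LWS"`.
#' @param lambda_max Pigment peak wavelength (nm).
#' @param oil_droplet A transmittance [spectrum()], a cut-off wavelength in nm
#'   (parametric droplet), or `NULL` for a transparent droplet.
#' @param density Relative photoreceptor density (positive; only ratios
#'   matter).
#' @return An object of class `cone_class`.
#' @export
cone_class <- function(name, lambda_max, oil_droplet = NULL, density = 1) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(density), length(density) == 1L)
  if (!is.finite(density) || density <= 0) {
    stop("cone density must be a positive finite number", call. = FALSE)
  }
  structure(list(name = name, lambda_max = lambda_max,
                 oil_droplet = oil_droplet, density = density),
            class = "cone_class")
}

#' Ocular media transmittance from repeated scans
#'
#' Averages the scans, normalizes the mean curve to a maximum of 1, and
#' locates the 50%-transmittance wavelength (lambda_T0.5) by linear
#' interpolation of the lowest-wavelength upward crossing of 0.5. A
#' four-parameter logistic is then fitted by least squares and replaces the
#' measured curve below lambda_T0.5, so instrument noise in the steep
#' short-wavelength tail cannot leak into downstream quantum catches.
#'
#' @param scans List of transmittance [spectrum()] objects on a common grid
#'   (or a single spectrum).
#' @return An object of class `ocular_media` with elements `transmittance`
#'   (a [spectrum()] with maximum 1), `lambda_t50` (nm) and `fit` (the
#'   logistic parameters).
#' @export
ocular_media_from_scans <- function(scans) {
  if (inherits(scans, "spectrum")) scans <- list(scans)
  if (!length(scans)) stop("no ocular media scans supplied", call. = FALSE)
  avg <- average_spectra(scans)
  avg <- normalize_peak(avg, 1)
  wl <- avg$wavelengths
  v <- avg$values
  t50 <- upward_crossing(wl, v, 0.5)
  if (is.na(t50)) {
    stop("ocular media transmittance never crosses 0.5: no cutoff found",
         call. = FALSE)
  }
  fit <- fit_logistic4(wl, v, mid_start = t50)
  below <- wl < t50
  smoothed <- v
  smoothed[below] <- pmin(pmax(logistic4(wl[below], fit), 0), 1)
  out <- spectrum(wl, pmin(smoothed, 1), "transmittance")
  structure(list(transmittance = out, lambda_t50 = t50, fit = fit),
            class = "ocular_media")
}

#' @exportS3Method base::print
print.ocular_media <- function(x, ...) {
  cat(sprintf("<ocular media: lambda_T0.5 = %.1f nm, %d points>\n",
              x$lambda_t50, length(x$transmittance)))
  invisible(x)
}

## first upward crossing of `level` scanning from short wavelengths,
## linearly interpolated between grid points
upward_crossing <- function(wl, v, level) {
  below <- v < level
  for (i in seq_len(length(wl) - 1L)) {
    if (below[i] && v[i + 1L] >= level) {
      return(wl[i] + (level - v[i]) * (wl[i + 1L] - wl[i]) / (v[i + 1L] - v[i]))
    }
  }
  NA_real_
}

logistic4 <- function(x, p) {
  p[["lo"]] + (p[["hi"]] - p[["lo"]]) / (1 + exp(-(x - p[["mid"]]) / p[["scal"]]))
}

fit_logistic4 <- function(x, y, mid_start) {
  start <- c(lo = max(min(y), 1e-6), hi = max(y), mid = mid_start, scal = 5)
  obj <- function(p) {
    p <- stats::setNames(p, names(start))
    if (p[["scal"]] <= 0) return(1e10)
    sum((y - logistic4(x, p))^2)
  }
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  stats::setNames(opt$par, names(start))
}

#' Receptor spectral sensitivity
#'
#' Combines pigment absorbance, oil-droplet transmittance and ocular-media
#' transmittance multiplicatively and renormalizes to a peak of 1:
#' \eqn{S_i(\lambda) = A_i(\lambda) D_i(\lambda) O(\lambda) / \max}.
#'
#' @param cone A [cone_class()].
#' @param ocular An `ocular_media` object, a transmittance [spectrum()], or
#'   `NULL` for perfectly transparent media.
#' @param grid Wavelength grid (nm).
#' @return A [spectrum()] with unit `"sensitivity"`, maximum exactly 1.
#' @export
receptor_sensitivity <- function(cone, ocular = NULL, grid = working_grid()) {
  stopifnot(inherits(cone, "cone_class"))
  a <- pigment_template(cone$lambda_max, grid)$values
  d <- droplet_values(cone$oil_droplet, grid)
  o <- ocular_values(ocular, grid)
  v <- a * d * o
  if (max(v) <= 0) {
    stop("receptor sensitivity is identically zero for cone ", cone$name,
         call. = FALSE)
  }
  spectrum(grid, v / max(v), "sensitivity")
}

droplet_values <- function(od, grid) {
  if (is.null(od)) return(rep(1, length(grid)))
  if (inherits(od, "spectrum")) return(resample(od, grid)$values)
  if (is.numeric(od) && length(od) == 1L) {
    return(oil_droplet_transmittance(od, grid = grid)$values)
  }
  stop("oil_droplet must be NULL, a spectrum, or a cutoff wavelength",
       call. = FALSE)
}

ocular_values <- function(ocular, grid) {
  if (is.null(ocular)) return(rep(1, length(grid)))
  if (inherits(ocular, "ocular_media")) ocular <- ocular$transmittance
  if (inherits(ocular, "spectrum")) return(resample(ocular, grid)$values)
  stop("ocular must be NULL, a spectrum, or an ocular_media object",
       call. = FALSE)
}

#' Assemble a visual system
#'
#' Bundles an ordered set of cone classes, the ocular media, and the Weber
#' fraction of the most abundant cone class. Receptor sensitivities are
#' precomputed on the grid.
#'
#' @param cones List of [cone_class()] objects (at least two).
#' @param ocular An `ocular_media`, transmittance [spectrum()], or `NULL`.
#' @param weber_fraction Weber fraction of the most abundant cone class
#'   (default 0.1, the common photopic convention).
#' @param grid Wavelength grid (nm).
#' @return An object of class `visual_system` with elements `cones`,
#'   `ocular`, `weber_fraction`, `grid` and `sensitivities` (list of
#'   [spectrum()] per cone).
#' @export
visual_system <- function(cones, ocular = NULL, weber_fraction = 0.1,
                          grid = working_grid()) {
  if (length(cones) < 2L) stop("need at least two cone classes", call. = FALSE)
  stopifnot(all(vapply(cones, inherits, logical(1), "cone_class")))
  if (!is.numeric(weber_fraction) || weber_fraction <= 0 ||
      weber_fraction >= 1) {
    stop("weber_fraction must lie in (0, 1)", call. = FALSE)
  }
  sens <- lapply(cones, receptor_sensitivity, ocular = ocular, grid = grid)
  names(sens) <- vapply(cones, `[[`, "", "name")
  structure(list(cones = cones, ocular = ocular,
                 weber_fraction = weber_fraction, grid = grid,
                 sensitivities = sens),
            class = "visual_system")
}

#' @exportS3Method base::print
print.visual_system <- function(x, ...) {
  peaks <- vapply(x$cones, `[[`, numeric(1), "lambda_max")
  cat(sprintf("<visual system: %d cones (lambda_max %s nm), omega = %g>\n",
              length(x$cones), paste(peaks, collapse = "/"),
              x$weber_fraction))
  invisible(x)
}

#' Read a visual-system configuration file
#'
#' YAML file with a `cones:` list (fields `name`, `lambda_max`,
#' `oil_droplet_cut` (optional), `density`), a `weber_fraction`, and an
#' optional `ocular_media_csv` path (resolved relative to the config file)
#' pointing at a transmittance spectrum.
#'
#' @param path Path to a YAML configuration file.
#' @param grid Wavelength grid (nm).
#' @return A [visual_system()].
#' @export
read_visual_system <- function(path, grid = working_grid()) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read visual-system configs",
         call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$cones)) stop("config has no 'cones' list", call. = FALSE)
  cones <- lapply(cfg$cones, function(cc) {
    cone_class(cc$name, cc$lambda_max,
               oil_droplet = cc$oil_droplet_cut %||% NULL,
               density = cc$density %||% 1)
  })
  ocular <- NULL
  if (!is.null(cfg$ocular_media_csv)) {
    om_path <- cfg$ocular_media_csv
    if (!file.exists(om_path)) {
      om_path <- file.path(dirname(path), cfg$ocular_media_csv)
    }
    ocular <- ocular_media_from_scans(read_spectrum(om_path, "transmittance"))
  }
  visual_system(cones, ocular = ocular,
                weber_fraction = cfg$weber_fraction %||% 0.1, grid = grid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
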