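#' @keywords internal
"_PACKAGE"

## Physical constants (SI)
PLANCK_H <- 6.62607015e-34   # J s
LIGHT_C  <- 2.99792458e8     # m / s

SPECTRUM_UNITS <- c("photon_flux", "energy", "transmittance", "sensitivity",
                    "radiance", "irradiance")

#' Wavelength-indexed spectrum
#'
#' A `spectrum` is the basic container of the spectral module: a strictly
#' increasing wavelength grid (nanometres) with one non-negative value per
#' wavelength and a unit tag. Transmittance and sensitivity spectra are
#' dimensionless and expected to lie in \[0, 1\] once normalized; the other
#' tags are radiometric quantities on whatever absolute scale the instrument
#' exported.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing after construction (unsorted input is sorted; duplicated
#'   wavelengths are averaged).
#' @param values Numeric vector of non-negative spectral values, same length
#'   as `wavelengths`.
#' @param unit One of `"photon_flux"`, `"energy"`, `"transmittance"`,
#'   `"sensitivity"`, `"radiance"`, `"irradiance"`.
#' @return An object of class `spectrum`.
#' @examples
#' s <- spectrum(400:700, rep(1, 301), "radiance")
#' range(wavelengths(s))
#' @export
spectrum <- function(wavelengths, values, unit = "photon_flux") {
  unit <- match.arg(unit, SPECTRUM_UNITS)
  if (length(wavelengths) != length(values)) {
    stop("wavelengths and values must have the same length", call. = FALSE)
  }
  if (length(wavelengths) == 0L) {
    stop("a spectrum needs at least one point", call. = FALSE)
  }
  if (anyNA(wavelengths) || anyNA(values)) {
    stop("NA values are not allowed in a spectrum", call. = FALSE)
  }
  if (!is.numeric(wavelengths) || !is.numeric(values)) {
    stop("wavelengths and values must be numeric", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("spectral values must be non-negative", call. = FALSE)
  }
  ord <- order(wavelengths)
  wavelengths <- as.numeric(wavelengths[ord])
  values <- as.numeric(values[ord])
  if (anyDuplicated(wavelengths)) {
    # instrument re-scans: average values recorded at the same wavelength
    values <- as.numeric(tapply(values, wavelengths, mean))
    wavelengths <- sort(unique(wavelengths))
  }
  structure(list(wavelengths = wavelengths, values = values, unit = unit),
            class = "spectrum")
}

#' @rdname spectrum
#' @param x A `spectrum`.
#' @export
wavelengths <- function(x) x$wavelengths

#' @rdname spectrum
#' @export
spec_values <- function(x) x$values

#' @rdname spectrum
#' @export
spec_unit <- function(x) x$unit

#' @exportS3Method base::print
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %d points, %.1f-%.1f nm, unit = %s>\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$unit))
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$wavelengths)

#' Default working wavelength grid
#'
#' 300 to 700 nm in 1 nm steps: the range scanned when designing stimuli and
#' the binning of typical spectroradiometer exports.
#'
#' @return Integer-valued numeric vector of wavelengths in nm.
#' @export
working_grid <- function() seq(300, 700, by = 1)

#' Read a spectrum from a two-column CSV file
#'
#' Expects the dialect `wavelength_nm,value` with an optional `# unit:` comment
#' line; spectroradiometer exports in that shape round-trip through
#' [write_spectrum()]. Rows are sorted by wavelength and duplicated
#' wavelengths averaged.
#'
#' @param path Path to a CSV file.
#' @param unit Unit tag to assign; overridden by a `# unit:` header line when
#'   `unit` is `NULL`.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, unit = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty spectrum file: ", path, call. = FALSE)
  header_unit <- NULL
  comment <- grepl("^\\s*#", lines)
  unit_line <- grep("^\\s*#\\s*unit:", lines, value = TRUE)
  if (length(unit_line)) {
    header_unit <- trimws(sub("^\\s*#\\s*unit:", "", unit_line[1]))
  }
  body <- lines[!comment]
  if (length(body) && grepl("wavelength", body[1], ignore.case = TRUE)) {
    body <- body[-1]
  }
  if (length(body) == 0L) stop("no data rows in spectrum file: ", path, call. = FALSE)
  parts <- strsplit(body, ",", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    stop("malformed row in spectrum file ", path, call. = FALSE)
  }
  wl <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  val <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(wl) || anyNA(val)) {
    stop("non-numeric rows in spectrum file ", path, call. = FALSE)
  }
  if (is.null(unit)) unit <- if (is.null(header_unit)) "photon_flux" else header_unit
  spectrum(wl, val, unit)
}

#' @rdname read_spectrum
#' @param s A `spectrum` to write.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit: %s", s$unit), con)
  writeLines("wavelength_nm,value", con)
  writeLines(sprintf("%.10g,%.10g", s$wavelengths, s$values), con)
  invisible(path)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; wavelengths outside the support of `s` get value 0
#' with a warning (measured sky and LED files cover different ranges).
#'
#' @param s A [spectrum()].
#' @param grid Numeric vector of target wavelengths (nm), increasing.
#' @return A `spectrum` on `grid` with the unit of `s`.
#' @export
resample <- function(s, grid) {
  stopifnot(inherits(s, "spectrum"))
  if (length(grid) == 0L) stop("empty resampling grid", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE)) grid <- sort(unique(grid))
  outside <- grid < min(s$wavelengths) | grid > max(s$wavelengths)
  if (any(outside)) {
    warning(sprintf("%d grid wavelengths outside spectrum support set to 0",
                    sum(outside)), call. = FALSE)
  }
  v <- if (length(s$wavelengths) == 1L) {
    ifelse(grid == s$wavelengths, s$values, 0)
  } else {
    stats::approx(s$wavelengths, s$values, xout = grid, rule = 1)$y
  }
  v[is.na(v)] <- 0
  spectrum(grid, v, s$unit)
}

#' Convert between energy and photon-count spectra
#'
#' A photon at wavelength lambda carries energy h*c/lambda, so an energy
#' spectrum E(lambda) corresponds to a photon spectrum
#' N(lambda) = E(lambda) * lambda / (h*c) with lambda in metres.
#'
#' @param s A [spectrum()] with unit `"energy"` (or `"photon_flux"` for the
#'   inverse).
#' @return A `spectrum` in the converted unit.
#' @export
energy_to_photons <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  if (s$unit != "energy") {
    stop("energy_to_photons expects unit 'energy', got '", s$unit, "'",
         call. = FALSE)
  }
  lambda_m <- s$wavelengths * 1e-9
  spectrum(s$wavelengths, s$values * lambda_m / (PLANCK_H * LIGHT_C),
           "photon_flux")
}

#' @rdname energy_to_photons
#' @export
photons_to_energy <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  if (s$unit != "photon_flux") {
    stop("photons_to_energy expects unit 'photon_flux', got '", s$unit, "'",
         call. = FALSE)
  }
  lambda_m <- s$wavelengths * 1e-9
  spectrum(s$wavelengths, s$values * (PLANCK_H * LIGHT_C) / lambda_m, "energy")
}

#' Trapezoidal integral of a spectrum
#'
#' @param s A [spectrum()].
#' @return The trapezoidal integral of value over wavelength (per-nm basis).
#' @export
integrate_spectrum <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  trapz(s$wavelengths, s$values)
}

## trapezoid rule on an arbitrary (sorted) grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Normalize a spectrum to a target peak value
#'
#' Rescales so that the maximum value equals `target`; ratios between
#' wavelengths (the spectral shape) are preserved. Used to put every
#' simulated LED on a common footing, e.g. a peak of 4000 photon counts.
#'
#' @param s A [spectrum()] with a positive maximum.
#' @param target Positive peak value after scaling.
#' @return Rescaled `spectrum`.
#' @export
normalize_peak <- function(s, target = 1) {
  stopifnot(inherits(s, "spectrum"))
  m <- max(s$values)
  if (m <= 0) stop("cannot peak-normalize an all-zero spectrum", call. = FALSE)
  if (!is.numeric(target) || length(target) != 1L || target <= 0) {
    stop("target must be a single positive number", call. = FALSE)
  }
  spectrum(s$wavelengths, s$values * (target / m), s$unit)
}

#' Total photon output of a stimulus
#'
#' Sum of the per-bin photon counts across the spectrum's wavelength range,
#' the convention used to report the total radiant output of an LED stimulus
#' binned at 1 nm.
#'
#' @param s A [spectrum()] in photon-flux units.
#' @return Total photon count (sum over bins).
#' @export
total_photon_output <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  if (s$unit != "photon_flux") {
    stop("total_photon_output expects unit 'photon_flux'", call. = FALSE)
  }
  sum(s$values)
}

#' Pointwise mean of several spectra
#'
#' All spectra must share one wavelength grid and one unit; resample first if
#' they do not (averaging repeated sky measurements, ocular-media scans, ...).
#'
#' @param spectra List of [spectrum()] objects.
#' @return A `spectrum` holding the pointwise arithmetic mean.
#' @export
average_spectra <- function(spectra) {
  if (!length(spectra)) stop("no spectra to average", call. = FALSE)
  stopifnot(all(vapply(spectra, inherits, logical(1), "spectrum")))
  units <- vapply(spectra, spec_unit, "")
  if (length(unique(units)) != 1L) {
    stop("cannot average spectra with different units: ",
         paste(unique(units), collapse = ", "), call. = FALSE)
  }
  grid <- spectra[[1]]$wavelengths
  for (s in spectra[-1]) {
    if (length(s$wavelengths) != length(grid) ||
        any(s$wavelengths != grid)) {
      stop("spectra must share a wavelength grid; resample first",
           call. = FALSE)
    }
  }
  vals <- rowMeans(vapply(spectra, spec_values, numeric(length(grid))))
  spectrum(grid, vals, units[1])
}
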