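#' Generate a series of peak-shifted LED spectra
#'
#' Rigidly translates a measured (or synthetic) LED emission template so its
#' argmax sits at each target peak from `start` to `stop` in steps of `step`
#' nm, truncates to the working grid, and peak-normalizes each spectrum to
#' `peak_target`. A 300-700 nm scan at 2 nm steps yields 201 spectra.
#'
#' @param template A unimodal [spectrum()] with a positive peak (any unit;
#'   output is tagged photon_flux).
#' @param start,stop,step Peak positions in nm (default 300 to 700 by 2).
#' @param peak_target Peak photon count after normalization (default 4000).
#' @param grid Working wavelength grid.
#' @return Named list of photon-flux [spectrum()] objects, one per peak,
#'   names `"peak_<nm>"`.
#' @export
simulate_led_series <- function(template, start = 300, stop = 700, step = 2,
                                peak_target = 4000, grid = working_grid()) {
  stopifnot(inherits(template, "spectrum"))
  if (start >= stop || step <= 0) {
    stop("need start < stop and step > 0", call. = FALSE)
  }
  if (max(template$values) <= 0) {
    stop("template has no positive peak", call. = FALSE)
  }
  peak0 <- template$wavelengths[which.max(template$values)]
  peaks <- seq(start, stop, by = step)
  base_level <- min(template$values)
  out <- lapply(peaks, function(p) {
    shifted_wl <- template$wavelengths + (p - peak0)
    sh <- spectrum(shifted_wl, template$values, "photon_flux")
    on_grid <- suppressWarnings(resample(sh, grid))
    # grid regions beyond the translated support keep the template's
    # baseline emission level rather than dropping to zero
    v <- pmax(on_grid$values, base_level)
    if (max(v) <= 0) {
      stop("template shifted to ", p, " nm has no support on the grid",
           call. = FALSE)
    }
    normalize_peak(spectrum(grid, v, "photon_flux"), peak_target)
  })
  names(out) <- paste0("peak_", peaks)
  out
}

#' Chromatic-contrast scan of an LED series against a background
#'
#' Scores every LED in the series with [chromatic_contrast()] against one
#' background for one visual system. LEDs that produce a zero quantum catch
#' in any cone get a missing contrast and a warning rather than aborting the
#' scan.
#'
#' @param leds List of photon-flux [spectrum()] objects (as produced by
#'   [simulate_led_series()]).
#' @param background Photon-flux [spectrum()] on the same grid.
#' @param vs A [visual_system()].
#' @return A `scan_result`: data.frame with columns `peak_nm` and
#'   `delta_s_jnd`, one row per LED, ordered by peak wavelength.
#' @export
contrast_scan <- function(leds, background, vs) {
  if (!length(leds)) stop("empty LED list", call. = FALSE)
  peaks <- vapply(leds, function(s) s$wavelengths[which.max(s$values)],
                  numeric(1))
  ds <- vapply(leds, function(s) {
    tryCatch(chromatic_contrast(s, background, vs)$delta_s,
             error = function(e) {
               warning("LED at ", s$wavelengths[which.max(s$values)],
                       " nm skipped: ", conditionMessage(e), call. = FALSE)
               NA_real_
             })
  }, numeric(1))
  ord <- order(peaks)
  out <- data.frame(peak_nm = peaks[ord], delta_s_jnd = ds[ord],
                    row.names = NULL)
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Candidate stimulus peaks from a contrast scan
#'
#' Finds local maxima of the JND-vs-peak-wavelength curve and keeps them
#' greedily in decreasing contrast order subject to a minimum pairwise
#' separation, so that one candidate emerges per relative peak of chromatic
#' contrast. Ties are broken toward the shorter wavelength.
#'
#' @param scan A `scan_result` from [contrast_scan()].
#' @param min_separation Minimum distance between selected peaks in nm
#'   (default 60).
#' @param n_max Maximum number of candidates to return (default all).
#' @return Numeric vector of candidate peak wavelengths (nm), in decreasing
#'   contrast order.
#' @export
select_candidate_peaks <- function(scan, min_separation = 60, n_max = Inf) {
  stopifnot(inherits(scan, "data.frame"), nrow(scan) > 0)
  wl <- scan$peak_nm
  ds <- scan$delta_s_jnd
  keep <- !is.na(ds)
  if (!any(keep)) stop("all contrasts in the scan are missing", call. = FALSE)
  wl <- wl[keep]; ds <- ds[keep]
  n <- length(wl)
  if (n == 1L) return(wl)
  is_max <- logical(n)
  for (i in seq_len(n)) {
    left <- if (i == 1L) -Inf else ds[i - 1L]
    right <- if (i == n) -Inf else ds[i + 1L]
    is_max[i] <- ds[i] >= left && ds[i] >= right
  }
  if (all(ds == ds[1])) {
    warning("flat contrast scan: returning shortest wavelength",
            call. = FALSE)
    return(wl[1])
  }
  cand_wl <- wl[is_max]
  cand_ds <- ds[is_max]
  # decreasing contrast, ties toward shorter wavelength
  ord <- order(-cand_ds, cand_wl)
  chosen <- numeric(0)
  for (k in ord) {
    if (!length(chosen) || all(abs(chosen - cand_wl[k]) >= min_separation)) {
      chosen <- c(chosen, cand_wl[k])
      if (length(chosen) >= n_max) break
    }
  }
  chosen
}

#' Radiometrically match two stimulus colours
#'
#' Given candidate intensity settings for each of two colours (e.g. LED
#' driver levels labelled in candela), picks the pair whose peak photon
#' outputs are most similar, so that the colours differ in wavelength but
#' not in the number of photons delivered.
#'
#' @param settings_a,settings_b Named lists of photon-flux [spectrum()]
#'   objects, one per intensity setting of each colour.
#' @return A `stimulus_choice`: list with per-colour elements `label`,
#'   `peak_nm`, `peak_photons`, `total_photons`, plus the relative peak
#'   difference `rel_diff`.
#' @export
radiometric_match <- function(settings_a, settings_b) {
  if (!length(settings_a) || !length(settings_b)) {
    stop("need at least one setting per colour", call. = FALSE)
  }
  summarize <- function(lst) {
    data.frame(label = names(lst),
               peak_nm = vapply(lst, function(s)
                 s$wavelengths[which.max(s$values)], numeric(1)),
               peak_photons = vapply(lst, function(s) max(s$values),
                                     numeric(1)),
               total_photons = vapply(lst, total_photon_output, numeric(1)),
               row.names = NULL)
  }
  a <- summarize(settings_a)
  b <- summarize(settings_b)
  best <- NULL
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      rel <- abs(a$peak_photons[i] - b$peak_photons[j]) /
        max(a$peak_photons[i], b$peak_photons[j])
      if (is.null(best) || rel < best$rel_diff) {
        best <- list(a = a[i, ], b = b[j, ], rel_diff = rel)
      }
    }
  }
  structure(best, class = "stimulus_choice")
}

#' @exportS3Method base::print
print.stimulus_choice <- function(x, ...) {
  cat(sprintf(
    "<stimulus choice: %s (%.0f photons at %.0f nm) vs %s (%.0f photons at %.0f nm); rel. diff %.1f%%>\n",
    x$a$label, x$a$peak_photons, x$a$peak_nm,
    x$b$label, x$b$peak_photons, x$b$peak_nm, 100 * x$rel_diff))
  invisible(x)
}
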