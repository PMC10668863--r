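test_that("spectrum construction sorts, averages duplicates, and validates", {
  s <- spectrum(c(500, 400), c(1, 2), "radiance")
  expect_equal(wavelengths(s), c(400, 500))
  expect_equal(spec_values(s), c(2, 1))

  # duplicated wavelengths are instrument re-scans: averaged, not rejected
  s <- spectrum(c(400, 400), c(1, 3), "radiance")
  expect_equal(length(s), 1L)
  expect_equal(spec_values(s), 2)

  expect_error(spectrum(400, -1), "non-negative")
  expect_error(spectrum(c(400, 500), 1), "same length")
})

test_that("CSV round trip preserves spectra and bad files error", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  s <- spectrum(seq(400, 500, 10), runif(11, 0, 3), "energy")
  write_spectrum(s, tmp)
  s2 <- read_spectrum(tmp)
  expect_equal(s2$wavelengths, s$wavelengths)
  expect_equal(s2$values, s$values, tolerance = 1e-9)
  expect_identical(s2$unit, "energy")

  writeLines(c("wavelength_nm,value", "400,1", "401,2"), tmp)
  expect_equal(length(read_spectrum(tmp, "radiance")), 2L)
  writeLines(c("500,1", "400,2"), tmp)
  expect_equal(wavelengths(read_spectrum(tmp)), c(400, 500))
  writeLines(c("400,abc"), tmp)
  expect_error(read_spectrum(tmp), "non-numeric")
  writeLines(character(0), tmp)
  expect_error(read_spectrum(tmp), "empty")
})

test_that("resample interpolates linearly and zeroes outside support", {
  grid <- seq(400, 500, 10)
  s <- spectrum(grid, grid, "radiance")  # v(lambda) = lambda
  mid <- seq(405, 495, 10)
  expect_equal(spec_values(resample(s, mid)), mid)

  # resampling onto own grid is the identity, and is idempotent
  r1 <- resample(s, grid)
  expect_equal(spec_values(r1), spec_values(s))
  expect_equal(spec_values(resample(r1, grid)), spec_values(r1))

  # independent pointwise interpolation oracle
  set.seed(42)
  s <- random_spectrum(seq(300, 700, 7))
  target <- sort(runif(50, 310, 690))
  got <- spec_values(resample(s, target))
  expected <- vapply(target, function(w) {
    i <- max(which(s$wavelengths <= w))
    if (s$wavelengths[i] == w) return(s$values[i])
    frac <- (w - s$wavelengths[i]) / (s$wavelengths[i + 1] - s$wavelengths[i])
    (1 - frac) * s$values[i] + frac * s$values[i + 1]
  }, numeric(1))
  expect_equal(got, expected, tolerance = 1e-12)

  expect_warning(resample(s, c(200, 400)), "outside")
  expect_error(resample(s, numeric(0)), "empty")
})

test_that("energy/photon conversion follows N = E * lambda / (h c)", {
  hc <- 6.62607015e-34 * 2.99792458e8
  s <- spectrum(c(400, 555, 800), c(1, 1, 1), "energy")
  n <- energy_to_photons(s)
  expect_identical(spec_unit(n), "photon_flux")
  # hand-computed photon count for 1 W at 555 nm
  expect_equal(spec_values(n)[2], 555e-9 / hc, tolerance = 1e-12)
  # equal energy at 400 and 800 nm -> photon ratio exactly 1:2
  expect_equal(spec_values(n)[3] / spec_values(n)[1], 2, tolerance = 1e-12)
  # zero spectrum maps to zero
  z <- spectrum(c(400, 500), c(0, 0), "energy")
  expect_equal(spec_values(energy_to_photons(z)), c(0, 0))
  # algebraic inverse recovers the input
  set.seed(7)
  s <- random_spectrum(seq(300, 700, 5), unit = "energy")
  back <- photons_to_energy(energy_to_photons(s))
  expect_equal(spec_values(back), spec_values(s), tolerance = 1e-12)
  expect_error(energy_to_photons(n), "unit")
})

test_that("luminous intensity matches the candela definition and is linear", {
  # monochromatic 1 W/sr at 555 nm is 683 cd by definition
  expect_equal(luminous_intensity(spectrum(555, 1, "radiance")), 683)
  z <- spectrum(seq(400, 700, 10), rep(0, 31), "radiance")
  expect_equal(suppressWarnings(luminous_intensity(z)), 0)

  set.seed(1)
  grid <- seq(380, 780, 5)
  s <- random_spectrum(grid, "radiance")
  vl <- luminosity_function(grid)
  expect_equal(luminous_intensity(s),
               683 * trapz_oracle(grid, spec_values(s) * spec_values(vl)),
               tolerance = 1e-10)
  # linearity
  s3 <- spectrum(grid, 3 * spec_values(s), "radiance")
  expect_equal(luminous_intensity(s3), 3 * luminous_intensity(s),
               tolerance = 1e-10)
  # disjoint support warns and returns 0
  uv <- spectrum(c(300, 320), c(1, 1), "radiance")
  expect_warning(out <- luminous_intensity(uv), "support")
  expect_equal(out, 0)
})

test_that("V(lambda) peaks at exactly 1 at 555 nm and vanishes outside", {
  vl <- luminosity_function(seq(300, 830, 1))
  expect_equal(max(spec_values(vl)), 1)
  expect_equal(vl$wavelengths[which.max(spec_values(vl))], 555)
  expect_true(all(spec_values(vl)[vl$wavelengths < 380] == 0))
})

test_that("peak normalization hits the target exactly and preserves shape", {
  set.seed(3)
  s <- random_spectrum(seq(300, 700, 2))
  n <- normalize_peak(s, 4000)
  expect_equal(max(spec_values(n)), 4000)
  expect_equal(spec_values(n) / max(spec_values(n)),
               spec_values(s) / max(spec_values(s)), tolerance = 1e-12)
  # scale invariance of the result
  s10 <- spectrum(s$wavelengths, 10 * s$values, s$unit)
  expect_equal(spec_values(normalize_peak(s10, 4000)), spec_values(n),
               tolerance = 1e-12)
  # idempotence at the target
  expect_equal(spec_values(normalize_peak(n, 4000)), spec_values(n))
  two <- spectrum(c(400, 500), c(1, 0.5))
  expect_equal(spec_values(normalize_peak(two, 10)), c(10, 5))
  expect_error(normalize_peak(spectrum(c(1, 2), c(0, 0)), 10), "all-zero")
})

test_that("total photon output sums per-bin counts", {
  s <- spectrum(c(400, 401, 402), c(10, 20, 30), "photon_flux")
  expect_equal(total_photon_output(s), 60)
  expect_equal(total_photon_output(spectrum(400:410, rep(0, 11))), 0)
  expect_error(total_photon_output(spectrum(400, 1, "energy")), "photon_flux")
})

test_that("averaging spectra is a pointwise mean with unit checks", {
  g <- 400:410
  a <- spectrum(g, rep(1, 11))
  b <- spectrum(g, rep(3, 11))
  expect_equal(spec_values(average_spectra(list(a, b))), rep(2, 11))
  expect_equal(spec_values(average_spectra(list(a))), spec_values(a))
  set.seed(9)
  many <- replicate(10, random_spectrum(g), simplify = FALSE)
  mat <- sapply(many, spec_values)
  expect_equal(spec_values(average_spectra(many)), rowMeans(mat),
               tolerance = 1e-12)
  expect_error(average_spectra(list(a, spectrum(g, rep(1, 11), "energy"))),
               "units")
})
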