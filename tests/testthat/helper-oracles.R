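# Independent oracles used across tests. These deliberately re-derive
# quantities with different code paths than the package implementation.

# trapezoid integral, written as an explicit loop
trapz_oracle <- function(x, y) {
  total <- 0
  for (i in seq_len(length(x) - 1)) {
    total <- total + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  total
}

# closed-form receptor-noise-limited distances for 2, 3 and 4 receptors
rnl_dichromat <- function(f, e) {
  abs(f[1] - f[2]) / sqrt(e[1]^2 + e[2]^2)
}

rnl_trichromat <- function(f, e) {
  num <- e[1]^2 * (f[3] - f[2])^2 + e[2]^2 * (f[3] - f[1])^2 +
    e[3]^2 * (f[1] - f[2])^2
  den <- (e[1] * e[2])^2 + (e[1] * e[3])^2 + (e[2] * e[3])^2
  sqrt(num / den)
}

rnl_tetrachromat <- function(f, e) {
  num <- (e[3] * e[4])^2 * (f[1] - f[2])^2 +
    (e[2] * e[4])^2 * (f[1] - f[3])^2 +
    (e[2] * e[3])^2 * (f[1] - f[4])^2 +
    (e[1] * e[4])^2 * (f[2] - f[3])^2 +
    (e[1] * e[3])^2 * (f[2] - f[4])^2 +
    (e[1] * e[2])^2 * (f[3] - f[4])^2
  den <- (e[2] * e[3] * e[4])^2 + (e[1] * e[3] * e[4])^2 +
    (e[1] * e[2] * e[4])^2 + (e[1] * e[2] * e[3])^2
  sqrt(num / den)
}

# random positive spectrum on a given grid
random_spectrum <- function(grid, unit = "photon_flux") {
  spectrum(grid, stats::runif(length(grid), 0.1, 5), unit)
}

# small dichromatic system with transparent droplets and media, for cheap
# contrast tests
dichromat_system <- function(peaks = c(450, 560), omega = 0.1,
                             densities = c(1, 2), grid = working_grid()) {
  cones <- mapply(function(p, d, i) cone_class(paste0("c", i), p, NULL, d),
                  peaks, densities, seq_along(peaks), SIMPLIFY = FALSE)
  visual_system(cones, ocular = NULL, weber_fraction = omega, grid = grid)
}

# choice dataset with ambient PC1 attached, for model-layer tests
prepared_choice_data <- function(params) {
  ds <- synth_choice_dataset(params)
  ds$ambient_pc1 <- ambient_pca(ds)$scores
  add_movement_rates(ds)
}
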