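## Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
## RNG stream is untouched. All generators route randomness through this.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Synthetic LED emission template
#'
#' Asymmetric-Gaussian emission spectrum standing in for a measured
#' narrow-band LED: Gaussian on each side of the peak with a slightly wider
#' long-wavelength shoulder (asymmetry ratio 1.1), total full width at half
#' maximum equal to `fwhm`, unit peak.
#'
#' @param peak Peak wavelength (nm) inside the grid.
#' @param fwhm Full width at half maximum (nm, default 30).
#' @param floor Relative emission floor (default 1e-4 of the peak),
#'   emulating the noise floor of a measured spectrum; a pure Gaussian tail
#'   underflows to zero and would make long-range quantum-catch ratios
#'   meaningless.
#' @param grid Wavelength grid.
#' @return A photon-flux [spectrum()] with maximum 1 at `peak`.
#' @export
synth_led_template <- function(peak, fwhm = 30, floor = 1e-4,
                               grid = working_grid()) {
  if (fwhm <= 0) stop("fwhm must be positive", call. = FALSE)
  if (peak < min(grid) || peak > max(grid)) {
    stop("peak must lie inside the grid", call. = FALSE)
  }
  asym <- 1.1
  hwhm_l <- fwhm / (1 + asym)
  hwhm_r <- fwhm * asym / (1 + asym)
  sig_l <- hwhm_l / sqrt(2 * log(2))
  sig_r <- hwhm_r / sqrt(2 * log(2))
  v <- ifelse(grid <= peak,
              exp(-(grid - peak)^2 / (2 * sig_l^2)),
              exp(-(grid - peak)^2 / (2 * sig_r^2)))
  spectrum(grid, pmax(v, floor), "photon_flux")
}

#' Synthetic sky radiance background
#'
#' Smooth, strictly positive photon-flux spectrum emulating open-sky
#' radiance: a short-wavelength scattering bump over a broad daylight
#' continuum, with small seeded perturbations so repeated "measurements"
#' differ slightly. The cloudy condition is a flattened (spectrally mixed
#' toward neutral) and dimmer variant of the clear sky.
#'
#' @param condition `"clear"` or `"cloudy"`.
#' @param seed Integer seed; the spectrum is deterministic given the seed.
#' @param grid Wavelength grid.
#' @return A photon-flux [spectrum()], positive everywhere on the grid.
#' @export
synth_sky <- function(condition = c("clear", "cloudy"), seed = 1,
                      grid = working_grid()) {
  condition <- match.arg(condition)
  with_seed(seed, {
    base <- 0.35 + (grid - 300) / 400 * 0.8            # rising continuum
    bump <- 1.6 * exp(-((grid - 460) / 90)^2)          # Rayleigh-ish blue bump
    wig <- 0.04 * sin(grid / (18 + stats::runif(1, 0, 6)) +
                        stats::runif(1, 0, 2 * pi))
    v <- base + bump + wig
    if (condition == "cloudy") {
      v <- 0.35 * (0.45 * v + 0.55 * mean(v))          # flatter and dimmer
    }
    spectrum(grid, 1e4 * pmax(v, 0.01), "photon_flux")
  })
}

#' Synthetic ocular-media transmittance scans
#'
#' Repeated noisy measurements of a sigmoidal lens/cornea transmittance
#' curve with a known 50% cutoff, for testing cutoff recovery.
#'
#' @param n_scans Number of scans (default 20).
#' @param midpoint True lambda_T0.5 (nm, default 369).
#' @param scale Logistic scale (nm, default 8).
#' @param noise_sd Gaussian noise SD per point (default 0.01).
#' @param seed Integer seed.
#' @param grid Wavelength grid.
#' @return List of transmittance [spectrum()] objects.
#' @export
synth_ocular_scans <- function(n_scans = 20, midpoint = 369, scale = 8,
                               noise_sd = 0.01, seed = 1,
                               grid = working_grid()) {
  truth <- 1 / (1 + exp(-(grid - midpoint) / scale))
  with_seed(seed, {
    lapply(seq_len(n_scans), function(i) {
      v <- truth + stats::rnorm(length(grid), 0, noise_sd)
      spectrum(grid, pmin(pmax(v, 0), 1), "transmittance")
    })
  })
}

#' Synthetic avian visual system
#'
#' Placeholder tetrachromatic (by default) visual system with pigment peaks
#' spread over 400-610 nm, long-pass oil droplets on all but the
#' shortest-wavelength cone, densities increasing toward long wavelengths,
#' a Weber fraction of 0.1 on the most abundant cone, and logistic ocular
#' media. Parameters receive small seeded jitter so different seeds give
#' distinct but plausible systems.
#'
#' @param n_cones Number of single-cone classes (default 4, minimum 2).
#' @param seed Integer seed.
#' @param weber_fraction Weber fraction (default 0.1).
#' @param grid Wavelength grid.
#' @return A [visual_system()].
#' @export
synth_visual_system <- function(n_cones = 4, seed = 1, weber_fraction = 0.1,
                                grid = working_grid()) {
  if (n_cones < 2) stop("need at least two cones", call. = FALSE)
  with_seed(seed, {
    peaks <- seq(415, 605, length.out = n_cones) +
      stats::runif(n_cones, -6, 6)
    peaks <- sort(peaks)
    dens <- seq(1, 2.5, length.out = n_cones) *
      exp(stats::rnorm(n_cones, 0, 0.08))
    cones <- lapply(seq_len(n_cones), function(i) {
      cut <- if (i == 1) NULL else peaks[i] - 40 + stats::runif(1, -5, 5)
      cone_class(paste0("cone", i), peaks[i], oil_droplet = cut,
                 density = dens[i])
    })
    ocular <- ocular_media_from_scans(
      synth_ocular_scans(5, midpoint = 369, noise_sd = 0.005,
                         seed = sample.int(1e6, 1), grid = grid))
    visual_system(cones, ocular = ocular, weber_fraction = weber_fraction,
                  grid = grid)
  })
}

#' Default avoidance log-odds table
#'
#' Per-cell avoidance log-odds for colour x trial-order emulating the
#' observed pattern: avoidance of the red light starts high and declines
#' steadily toward attraction with repeated exposure (mere-exposure
#' trajectory), while the blue light follows a shallower
#' avoid-attract-avoid oscillation.
#'
#' @return 2 x 8 numeric matrix, rows `blue`/`red`, columns trials 1-8, in
#'   log-odds of avoidance.
#' @export
default_avoidance_logodds <- function() {
  # red: ~0.9 avoidance on first exposure declining to near-certain
  # attraction by trial 8; blue: initial approach, then a shallow
  # avoid-approach-avoid oscillation settling around 0.65 avoidance
  red <- seq(2.2, -3.4, length.out = 8)
  blue <- c(-0.6, 0.85, 0.85, -0.6, -0.6, 0.6, 0.6, 0.6)
  rbind(blue = blue, red = red)
}

#' Simulation parameters for a synthetic choice experiment
#'
#' @param n_birds Number of birds (default 19, the completing cohort size).
#' @param beta_logodds 2 x 8 matrix of avoidance log-odds per colour and
#'   trial (rows `blue`, `red`); default [default_avoidance_logodds()].
#' @param gamma_freq_ambient Coefficient of the pulsing-frequency x ambient
#'   interaction on the avoidance log-odds: pulsing trials get
#'   `+gamma * ambient`, steady trials `-gamma * ambient` (default 0.5).
#' @param sigma_b SD of the Gaussian per-bird random intercept on the
#'   avoidance log-odds (default 0.2, echoing near-zero between-individual
#'   variation in avoidance).
#' @param rho_lux Target Pearson correlation between the raw lux readings on
#'   the lit and unlit sides (default 0.83).
#' @param lux_meanlog,lux_sdlog Log-normal parameters of the lux readings
#'   (defaults log(800) and 0.5).
#' @param latency_mean_s,latency_shape Gamma latency distribution (defaults
#'   35 s, shape 1.2).
#' @param sigma_b_latency SD of the per-bird multiplicative (log-scale)
#'   latency intercept (default 0.4).
#' @param head_rate,body_rate Mean Poisson movement rates in events/s
#'   (defaults 1.1 and 0.45).
#' @param mistrial_prob Probability a trial ends without a choice and is
#'   dropped (default 0.03); latencies reaching the 600 s cap also become
#'   mistrials.
#' @param seed Integer seed.
#' @return A `choice_sim_params` list.
#' @export
choice_sim_params <- function(n_birds = 19,
                              beta_logodds = default_avoidance_logodds(),
                              gamma_freq_ambient = 0.5,
                              sigma_b = 0.2,
                              rho_lux = 0.83,
                              lux_meanlog = log(800), lux_sdlog = 0.5,
                              latency_mean_s = 35, latency_shape = 1.2,
                              sigma_b_latency = 0.4,
                              head_rate = 1.1, body_rate = 0.45,
                              mistrial_prob = 0.03,
                              seed = 1) {
  stopifnot(n_birds >= 1, sigma_b >= 0, abs(rho_lux) < 1,
            nrow(beta_logodds) == 2, ncol(beta_logodds) == 8,
            mistrial_prob >= 0, mistrial_prob < 1)
  structure(list(n_birds = n_birds, beta_logodds = beta_logodds,
                 gamma_freq_ambient = gamma_freq_ambient, sigma_b = sigma_b,
                 rho_lux = rho_lux, lux_meanlog = lux_meanlog,
                 lux_sdlog = lux_sdlog, latency_mean_s = latency_mean_s,
                 latency_shape = latency_shape,
                 sigma_b_latency = sigma_b_latency,
                 head_rate = head_rate, body_rate = body_rate,
                 mistrial_prob = mistrial_prob, seed = seed),
            class = "choice_sim_params")
}

## normal-scale correlation that yields Pearson correlation `rho` between
## two log-normals sharing sdlog; inverse of the standard log-normal
## correlation formula
lognormal_rho_normal_scale <- function(rho, sdlog) {
  log(1 + rho * (exp(sdlog^2) - 1)) / sdlog^2
}

#' Simulate a repeated-measures single-choice dataset
#'
#' Generates the trial table the analysis pipeline consumes. Each bird gets
#' the counterbalanced schedule of the experiment: all four colour x
#' frequency cells in randomized order in trials 1-4 with randomized lit
#' sides, the same cells in a new random order in trials 5-8 with the
#' opposite side per cell. Paired ambient lux readings are bivariate
#' log-normal with the requested raw-scale correlation; the avoidance
#' outcome is Bernoulli with log-odds
#' `beta[colour, trial] + gamma * (+/-1 for pulsing/steady) * ambient + b_bird`,
#' where `ambient` is the generator's standardized common light factor (the
#' quantity the ambient PCA recovers); latency is gamma with a log-normal
#' per-bird intercept, capped at 600 s (capped trials become mistrials and
#' are dropped); head and body movement counts are Poisson over a visible
#' duration tied to latency.
#'
#' @param p A [choice_sim_params()].
#' @return A validated choice dataset (see [validate_choice_data()]) with a
#'   `side_right` convenience column.
#' @export
synth_choice_dataset <- function(p = choice_sim_params()) {
  stopifnot(inherits(p, "choice_sim_params"))
  cells <- expand.grid(color = c("blue", "red"),
                       frequency = c("steady", "pulsing"),
                       stringsAsFactors = FALSE)
  rho_n <- lognormal_rho_normal_scale(p$rho_lux, p$lux_sdlog)
  with_seed(p$seed, {
    rows <- list()
    for (b in seq_len(p$n_birds)) {
      b_avoid <- stats::rnorm(1, 0, p$sigma_b)
      b_lat <- stats::rnorm(1, 0, p$sigma_b_latency)
      perm1 <- sample.int(4)
      sides1 <- sample(c("left", "right"), 4, replace = TRUE)
      perm2 <- sample.int(4)
      side_of_cell <- stats::setNames(sides1, perm1)
      for (t in 1:8) {
        cell <- if (t <= 4) perm1[t] else perm2[t - 4]
        side <- if (t <= 4) side_of_cell[[as.character(cell)]] else {
          setdiff(c("left", "right"), side_of_cell[[as.character(cell)]])
        }
        col <- cells$color[cell]
        frq <- cells$frequency[cell]
        # paired ambient readings with a common latent light level
        z1 <- stats::rnorm(1)
        z2 <- rho_n * z1 + sqrt(1 - rho_n^2) * stats::rnorm(1)
        lux_on <- exp(p$lux_meanlog + p$lux_sdlog * z1)
        lux_off <- exp(p$lux_meanlog + p$lux_sdlog * z2)
        ambient <- (z1 + z2) / sqrt(2 * (1 + rho_n))
        freq_sign <- if (frq == "pulsing") 1 else -1
        eta <- p$beta_logodds[col, t] +
          p$gamma_freq_ambient * freq_sign * ambient + b_avoid
        avoid <- stats::rbinom(1, 1, stats::plogis(eta))
        lat <- stats::rgamma(1, shape = p$latency_shape,
                             rate = p$latency_shape /
                               (p$latency_mean_s * exp(b_lat)))
        mistrial <- lat >= 600 || stats::runif(1) < p$mistrial_prob
        if (mistrial) next
        visible <- lat * stats::runif(1, 0.6, 0.95) + 1
        rows[[length(rows) + 1L]] <- data.frame(
          bird_id = sprintf("bird%02d", b), trial_order = t,
          color = col, frequency = frq, light_side = side,
          choice_avoid = avoid, latency_s = lat,
          head_events = stats::rpois(1, p$head_rate * visible),
          body_events = stats::rpois(1, p$body_rate * visible),
          visible_s = visible, lux_on = lux_on, lux_off = lux_off,
          side_right = NA_integer_)
      }
    }
    df <- do.call(rbind, rows)
    # chosen side: the lit side if the bird approached, the other if it avoided
    chose_lit <- df$choice_avoid == 0
    df$side_right <- as.integer(ifelse(chose_lit,
                                       df$light_side == "right",
                                       df$light_side == "left"))
    validate_choice_data(df)
  })
}

#' Simulate a side-bias pre-test dataset
#'
#' Trials with both lights off: each bird makes `n_trials` left/right
#' choices with probability of going right `plogis(intercept + b_bird)`.
#'
#' @param n_birds Number of birds (default 23).
#' @param n_trials Trials per bird (default 3).
#' @param intercept Log-odds of choosing the right side (default 0).
#' @param sigma_b SD of the per-bird random intercept (default 0.5).
#' @param seed Integer seed.
#' @return Data frame with `bird_id` and `side_right`.
#' @export
synth_side_bias_dataset <- function(n_birds = 23, n_trials = 3,
                                    intercept = 0, sigma_b = 0.5, seed = 1) {
  with_seed(seed, {
    b <- stats::rnorm(n_birds, 0, sigma_b)
    df <- expand.grid(bird = seq_len(n_birds), trial = seq_len(n_trials))
    df$side_right <- stats::rbinom(nrow(df), 1,
                                   stats::plogis(intercept + b[df$bird]))
    data.frame(bird_id = sprintf("bird%02d", df$bird),
               side_right = df$side_right)
  })
}

#' Reconstruct a side-bias dataset from summary counts
#'
#' Builds the smallest-structure trial table consistent with reported
#' side-choice counts: `n_right` right choices and `n_left` left choices
#' spread as evenly as possible across `n_birds` birds (so between-bird
#' variance is minimal). Useful for re-running the side-bias model when only
#' the counts, not the raw table, are available.
#'
#' @param n_right,n_left Total right and left choices.
#' @param n_birds Number of birds.
#' @return Data frame with `bird_id` and `side_right`.
#' @export
side_bias_from_counts <- function(n_right, n_left, n_birds) {
  n <- n_right + n_left
  stopifnot(n >= n_birds)
  # cycle birds so right choices land on distinct birds before repeating
  bird <- rep_len(seq_len(n_birds), n)
  side <- rep(0L, n)
  side[seq_len(n_right)] <- 1L
  data.frame(bird_id = sprintf("bird%02d", bird), side_right = side)
}

#' Overlay a gaussian response with a known variance partition
#'
#' Adds a response column to an existing choice dataset with a prescribed
#' variance decomposition: treatment (colour x trial-order cell) effects
#' scaled to contribute `share_fixed` of the total variance, a per-bird
#' intercept contributing `share_individual`, and residual noise making up
#' the remainder. The expected marginal R-squared is `100 * share_fixed`
#' and the expected repeatability is
#' `100 * share_individual / (share_individual + share_residual)`.
#'
#' @param data A validated choice dataset.
#' @param share_fixed,share_individual Variance shares in (0, 1) with sum
#'   below 1.
#' @param total_var Total variance of the response (default 1).
#' @param response_name Name of the new column (default `"response"`).
#' @param seed Integer seed.
#' @return `data` with the new response column.
#' @export
synth_partitioned_response <- function(data, share_fixed, share_individual,
                                       total_var = 1,
                                       response_name = "response",
                                       seed = 1) {
  stopifnot(share_fixed > 0, share_individual > 0,
            share_fixed + share_individual < 1)
  with_seed(seed, {
    cell <- interaction(data$color, data$trial_order)
    raw_eff <- stats::rnorm(nlevels(cell))
    eff <- raw_eff[as.integer(cell)]
    eff <- eff - mean(eff)
    eff <- eff * sqrt(share_fixed * total_var) / stats::sd(eff)
    birds <- levels(data$bird_id)
    b <- stats::rnorm(length(birds), 0,
                      sqrt(share_individual * total_var))
    resid_sd <- sqrt((1 - share_fixed - share_individual) * total_var)
    data[[response_name]] <- eff + b[as.integer(data$bird_id)] +
      stats::rnorm(nrow(data), 0, resid_sd)
    data
  })
}
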