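params_small <- choice_sim_params(n_birds = 12, seed = 31)

test_that("movement rates divide events by visible time", {
  expect_equal(movement_rate(0, 10), 0)
  expect_equal(movement_rate(12, 10), 1.2)
  set.seed(2)
  n <- rpois(20, 10); d <- runif(20, 1, 60)
  expect_equal(movement_rate(n, d), n / d)
  expect_error(movement_rate(3, 0), "positive")
})

test_that("choice data validation enforces the trial schema", {
  ds <- synth_choice_dataset(params_small)
  expect_s3_class(ds$color, "factor")
  expect_true(all(table(ds$bird_id) <= 8))

  bad <- ds; bad$latency_s[1] <- 700
  expect_error(validate_choice_data(bad), "600")
  bad <- ds; bad$choice_avoid[1] <- 2
  expect_error(validate_choice_data(bad), "choice_avoid")
  bad <- ds; bad$lux_on <- NULL
  expect_error(validate_choice_data(bad), "lux_on")

  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(ds, tmp, row.names = FALSE)
  rt <- read_choice_data(tmp)
  expect_equal(nrow(rt), nrow(ds))
})

test_that("collinearity screen reports pairwise r with flags", {
  set.seed(4)
  n <- 200
  x <- rnorm(n)
  df <- data.frame(lux_on = exp(x), lux_off = exp(0.9 * x + 0.3 * rnorm(n)),
                   temp_C = rnorm(n))
  out <- collinearity_screen(df)
  expect_equal(nrow(out), 3)
  r_oracle <- cor(df$lux_on, df$lux_off)
  expect_equal(out$r[out$var1 == "lux_on" & out$var2 == "lux_off"], r_oracle)
  expect_true(out$flagged[1])

  # perfectly correlated pair has r exactly 1
  df2 <- data.frame(lux_on = 1:10, lux_off = 2 * (1:10) + 3)
  expect_equal(collinearity_screen(df2, c("lux_on", "lux_off"))$r, 1)
  # constant column warns with NA
  df3 <- data.frame(lux_on = 1:10, lux_off = rep(1, 10))
  expect_warning(out3 <- collinearity_screen(df3, c("lux_on", "lux_off")),
                 "constant")
  expect_true(is.na(out3$r))

  # independent pairs rarely flag at n = 1000
  set.seed(5)
  hits <- replicate(40, {
    d <- data.frame(lux_on = rnorm(1000), lux_off = rnorm(1000))
    abs(collinearity_screen(d, c("lux_on", "lux_off"))$r) > 0.1
  })
  expect_lt(mean(hits), 0.05)
})

test_that("ambient PCA follows the 2x2 correlation closed form", {
  set.seed(6)
  n <- 400
  z <- rnorm(n)
  df <- data.frame(lux_on = exp(z + 0.4 * rnorm(n)),
                   lux_off = exp(z + 0.4 * rnorm(n)))
  r <- cor(df$lux_on, df$lux_off)
  p <- ambient_pca(df)
  expect_equal(p$eigenvalues[1], 1 + r, tolerance = 1e-12)
  expect_equal(sum(p$eigenvalues), 2, tolerance = 1e-12)
  expect_equal(p$proportion_variance[1], (1 + r) / 2, tolerance = 1e-12)
  # loadings are variable-score correlations, oriented positive
  expect_equal(unname(p$loadings[, 1]), rep(sqrt((1 + r) / 2), 2),
               tolerance = 1e-9)
  expect_equal(mean(p$scores), 0, tolerance = 1e-12)
  expect_equal(cor(p$scores, df$lux_on), cor(p$scores, df$lux_off),
               tolerance = 0.2)
  # scores rise with ambient light on both sides
  expect_gt(cor(p$scores, log(df$lux_on)), 0)

  # uncorrelated pair: eigenvalues (1,1), nothing retained
  df0 <- data.frame(lux_on = c(1, 2, 3), lux_off = c(1, 3, 1))
  expect_warning(p0 <- ambient_pca(df0), "retained")
  expect_equal(p0$eigenvalues, c(1, 1), tolerance = 1e-12)
  expect_equal(p0$n_retained, 0L)
  expect_null(p0$scores)
  expect_error(ambient_pca(data.frame(lux_on = c(1, 1), lux_off = c(1, 2))),
               "constant")
})

test_that("side-bias model is symmetric and flags separation", {
  # perfectly balanced outcomes, no bird signal: intercept ~ 0
  df <- data.frame(bird_id = rep(sprintf("b%02d", 1:20), each = 4),
                   side_right = rep(c(0, 1), 40))
  out <- suppressMessages(side_bias_test(df))
  expect_equal(out$intercept, 0, tolerance = 1e-4)
  expect_gt(out$p, 0.9)

  df$side_right <- 1
  expect_error(side_bias_test(df), "separation")
})

test_that("gaussian mixed model recovers known effects and components", {
  ds <- prepared_choice_data(choice_sim_params(n_birds = 60, seed = 41,
                                               mistrial_prob = 0))
  # redraw the response repeatedly with known structure (effect of red = 2,
  # bird sd = 1, residual sd = 0.5): the 2-SE interval should cover the
  # truth at close to its nominal rate
  set.seed(42)
  birds <- levels(ds$bird_id)
  covered <- 0
  n_rep <- 50
  for (r in seq_len(n_rep)) {
    b <- rnorm(length(birds), 0, 1)
    ds$y <- 10 + 2 * (ds$color == "red") + b[as.integer(ds$bird_id)] +
      rnorm(nrow(ds), 0, 0.5)
    fit <- fit_mixed(ds, "y", c("color"), "gaussian")
    est <- fit$coefficients["colorred", ]
    covered <- covered +
      (abs(est[["Estimate"]] - 2) < 2 * est[["Std. Error"]])
  }
  expect_gte(covered / n_rep, 0.84)
  expect_equal(fit$v_individual, 1, tolerance = 0.6)
  expect_equal(fit$v_residual, 0.25, tolerance = 0.2)

  # a near-pure bird-offset response drives slopes and residual variance
  # toward zero
  b <- rnorm(length(birds), 0, 1)
  ds$y0 <- b[as.integer(ds$bird_id)] + rnorm(nrow(ds), 0, 1e-4)
  fit0 <- suppressWarnings(
    suppressMessages(fit_mixed(ds, "y0", c("color"), "gaussian")))
  expect_equal(unname(fit0$coefficients["colorred", "Estimate"]), 0,
               tolerance = 1e-3)
  expect_lt(fit0$v_residual, 1e-6)

  # duplicated predictor is reported as aliasing
  ds$color2 <- ds$color
  expect_error(fit_mixed(ds, "y", c("color", "color2"), "gaussian"),
               "aliased|rank")
})

test_that("term tests give F tables for gaussian and LRT for binomial fits", {
  ds <- prepared_choice_data(choice_sim_params(n_birds = 15, seed = 51))
  fit <- fit_mixed(ds, "latency_s", family = "gaussian")
  tt <- term_tests(fit)
  expect_setequal(tt$term,
                  c("color", "frequency", "trial_order", "ambient_pc1"))
  expect_true(all(is.finite(tt$statistic)))
  expect_true(all(tt$df2 > 0))   # Satterthwaite denominator df
  expect_equal(tt$df1[tt$term == "trial_order"], 7)

  fitb <- suppressMessages(
    fit_mixed(ds, "choice_avoid", family = "binomial", nAGQ = 0))
  ttb <- term_tests(fitb)
  expect_true(all(is.na(ttb$df2)))
  expect_true(all(ttb$p >= 0 & ttb$p <= 1))
  expect_equal(ttb$df1[ttb$term == "trial_order"], 7)
})

test_that("satterthwaite F tests hold their size on null gaussian data", {
  # repeated small experiments with no true fixed effects: the colour term
  # should reject at close to the nominal 5% rate
  hits <- 0
  n_sim <- 200
  for (r in seq_len(n_sim)) {
    ds <- prepared_choice_data(choice_sim_params(n_birds = 10,
                                                 seed = 6000 + r))
    set.seed(r)
    b <- rnorm(nlevels(ds$bird_id), 0, 0.5)
    ds$y <- b[as.integer(ds$bird_id)] + rnorm(nrow(ds))
    fit <- suppressMessages(fit_mixed(ds, "y", c("color", "frequency"),
                                      "gaussian"))
    hits <- hits + (term_tests(fit)$p[1] < 0.05)
  }
  expect_gt(hits / n_sim, 0.01)
  expect_lt(hits / n_sim, 0.09)
})

test_that("estimated marginal means reduce to group means when balanced", {
  ds <- prepared_choice_data(choice_sim_params(n_birds = 30, seed = 61,
                                               mistrial_prob = 0))
  set.seed(62)
  ds$y <- 5 + 3 * (ds$color == "red") + rnorm(nrow(ds), 0, 0.1)
  fit <- suppressMessages(fit_mixed(ds, "y", c("color"), "gaussian"))
  emm <- estimated_marginal_means(fit, "color")
  raw <- tapply(ds$y, ds$color, mean)
  expect_equal(emm$mean, as.numeric(raw[emm$level]), tolerance = 1e-6)
  expect_error(estimated_marginal_means(fit, "frequency"), "not in the model")

  # binomial means come back on the probability scale
  fitb <- suppressMessages(fit_mixed(ds, "choice_avoid", c("color"),
                                     "binomial"))
  emmb <- estimated_marginal_means(fitb, "color")
  expect_true(all(emmb$mean > 0 & emmb$mean < 1))
})

test_that("R2 decomposition behaves at its boundaries and recovers truth", {
  ds <- prepared_choice_data(choice_sim_params(n_birds = 40, seed = 71,
                                               mistrial_prob = 0))
  # known partition: 20% fixed, 20% individual, 60% residual
  ds <- synth_partitioned_response(ds, 0.20, 0.20, total_var = 4, seed = 72)
  fit <- fit_mixed(ds, "response",
                   c("color", "trial_order", "color:trial_order"), "gaussian")
  r2 <- r2_mixed(fit)
  expect_equal(r2$marginal, 20, tolerance = 6)
  expect_equal(r2$conditional, 40, tolerance = 8)

  # with a zero random-effect estimate, marginal and conditional coincide
  set.seed(73)
  ds$flat <- 2 * (ds$color == "red") + rnorm(nrow(ds))
  fitf <- suppressMessages(fit_mixed(ds, "flat", c("color"), "gaussian"))
  if (fitf$v_individual == 0) {
    expect_true(fitf$singular)
    expect_equal(r2_mixed(fitf)$marginal, r2_mixed(fitf)$conditional)
  }
})

test_that("repeatability ratio, CI and categories are correct", {
  expect_equal(repeatability_category(20), "low")
  expect_equal(repeatability_category(40), "moderate")
  expect_equal(repeatability_category(41), "high")

  ds <- prepared_choice_data(choice_sim_params(n_birds = 40, seed = 81,
                                               mistrial_prob = 0))
  ds <- synth_partitioned_response(ds, 0.05, 0.25, seed = 82)
  fit <- fit_mixed(ds, "response", c("color"), "gaussian")
  # truth: 25 / (25 + 70) = 26.3%
  rep_est <- repeatability(fit, n_boot = 60, seed = 83)
  expect_equal(rep_est$value, 100 * 25 / 95, tolerance = 8)
  expect_true(rep_est$ci_low <= rep_est$value &&
                rep_est$value <= rep_est$ci_high)
  expect_equal(rep_est$category, "moderate")

  # no individual variance: repeatability 0, category low
  set.seed(84)
  ds$pure <- rnorm(nrow(ds))
  fit0 <- suppressMessages(fit_mixed(ds, "pure", c("color"), "gaussian"))
  if (fit0$v_individual == 0) {
    r0 <- repeatability(fit0, n_boot = 0)
    expect_equal(r0$value, 0)
    expect_equal(r0$category, "low")
  }
})

test_that("the stepwise ladder reports every test and keeps planted effects", {
  ds <- prepared_choice_data(choice_sim_params(n_birds = 40, seed = 91))
  lad <- suppressMessages(suppressWarnings(
    stepwise_interaction_ladder(ds, "choice_avoid", "binomial", nAGQ = 0)))
  expect_equal(nrow(lad$report), 5)   # 1 + 2 + 2 candidate tests
  expect_equal(lad$report$step, c(1, 2, 2, 3, 3))
  expect_true(all(lad$kept %in% lad$report$term[lad$report$kept]))
  # final model terms are base + survivors
  expect_setequal(lad$final$fixed_terms,
                  c("color", "frequency", "trial_order", "ambient_pc1",
                    lad$kept))
  # default generator plants the colour x order trajectory; it is retained
  expect_true("color:trial_order" %in% lad$kept)

  # gaussian ladder runs the same protocol with F tests
  ds <- synth_partitioned_response(ds, 0.1, 0.1, seed = 92)
  ladg <- suppressMessages(
    stepwise_interaction_ladder(ds, "response", "gaussian"))
  expect_equal(nrow(ladg$report), 5)
  expect_true(all(is.finite(ladg$report$p)))
})

test_that("lit-side association diagnostic returns per-term chi-squares", {
  ds <- prepared_choice_data(choice_sim_params(n_birds = 20, seed = 95))
  out <- side_design_association(ds)
  expect_true(all(c("color", "trial_order") %in% out$term))
  expect_true(all(out$p >= 0 & out$p <= 1, na.rm = TRUE))
})
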