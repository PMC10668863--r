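## Residual variance on the latent (logit) scale of a binomial mixed model:
## the standard-logistic variance, used for R-squared and repeatability
## ratios.
LOGIT_RESIDUAL_VAR <- pi^2 / 3

#' Pairwise collinearity screen of confounding covariates
#'
#' Pearson product-moment correlations with two-sided p-values for every
#' pair of candidate covariates, flagging pairs whose |r| exceeds the
#' threshold so that redundant confounds can be summarized (e.g. by a
#' principal component) or dropped before modelling.
#'
#' @param df Data frame of trials.
#' @param variables Character vector of numeric column names (default the
#'   paired ambient-light readings plus any of `temp_C` / `time_of_day`
#'   present).
#' @param threshold |r| above which a pair is flagged (default 0.7).
#' @return Data frame with columns `var1`, `var2`, `r`, `p`, `flagged`.
#'   Constant variables give `NA` correlations with a warning.
#' @export
collinearity_screen <- function(df, variables = NULL, threshold = 0.7) {
  if (is.null(variables)) {
    variables <- intersect(c("lux_on", "lux_off", "temp_C", "time_of_day"),
                           names(df))
  }
  if (length(variables) < 2L) {
    stop("need at least two variables to screen", call. = FALSE)
  }
  if (nrow(df) < 3L) stop("need at least 3 complete trials", call. = FALSE)
  pairs <- utils::combn(variables, 2L)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    v1 <- df[[pairs[1, k]]]
    v2 <- df[[pairs[2, k]]]
    if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
      warning("constant variable in pair ", pairs[1, k], "/", pairs[2, k],
              call. = FALSE)
      return(data.frame(var1 = pairs[1, k], var2 = pairs[2, k],
                        r = NA_real_, p = NA_real_, flagged = NA))
    }
    ct <- stats::cor.test(v1, v2)
    data.frame(var1 = pairs[1, k], var2 = pairs[2, k],
               r = unname(ct$estimate), p = ct$p.value,
               flagged = abs(ct$estimate) > threshold)
  }))
  rownames(out) <- NULL
  out
}

#' Principal component of the paired ambient-light readings
#'
#' Standardizes the lux readings on the lit and unlit sides, eigendecomposes
#' their correlation matrix, and retains components with eigenvalue above 1
#' (Kaiser rule). For two standardized variables with correlation r the
#' first eigenvalue is exactly 1 + |r| and explains (1 + |r|)/2 of the
#' variance. PCA1 is oriented so both loadings are positive: higher scores
#' mean brighter ambient light on both sides of the arena. Loadings are
#' reported as correlations between the original variables and the scores.
#'
#' @param df Data frame with numeric `lux_on` and `lux_off` columns.
#' @return An `ambient_pca` object: list with `eigenvalues`,
#'   `proportion_variance`, `loadings`, `scores` (zero-mean PCA1 per trial,
#'   `NULL` if nothing is retained) and `n_retained`.
#' @export
ambient_pca <- function(df) {
  x <- cbind(lux_on = df$lux_on, lux_off = df$lux_off)
  if (any(apply(x, 2, stats::sd) == 0)) {
    stop("constant lux column: cannot standardize for PCA", call. = FALSE)
  }
  z <- scale(x)
  cm <- stats::cor(x)
  eg <- eigen(cm, symmetric = TRUE)
  retained <- which(eg$values > 1)
  scores_all <- z %*% eg$vectors
  # loadings as variable-score correlations = eigenvector * sqrt(eigenvalue)
  loadings <- sweep(eg$vectors, 2, sqrt(pmax(eg$values, 0)), `*`)
  # orient each component so its loading sum is positive
  for (j in seq_along(eg$values)) {
    if (sum(loadings[, j]) < 0) {
      loadings[, j] <- -loadings[, j]
      scores_all[, j] <- -scores_all[, j]
    }
  }
  dimnames(loadings) <- list(colnames(x), paste0("PCA", seq_along(eg$values)))
  if (!length(retained)) {
    warning("no eigenvalue exceeds 1: no component retained", call. = FALSE)
  }
  structure(list(
    eigenvalues = eg$values,
    proportion_variance = eg$values / sum(eg$values),
    loadings = loadings,
    scores = if (length(retained)) scores_all[, 1] else NULL,
    n_retained = length(retained)), class = "ambient_pca")
}

#' @exportS3Method base::print
print.ambient_pca <- function(x, ...) {
  cat(sprintf("<ambient PCA: eigenvalues %s; %d retained (>1)>\n",
              paste(sprintf("%.3f", x$eigenvalues), collapse = ", "),
              x$n_retained))
  invisible(x)
}

#' Side-bias diagnostic for a choice arena
#'
#' Intercept-only logistic mixed model of the probability of choosing the
#' right side, with bird identity as a random intercept (Laplace maximum
#' likelihood). A non-significant intercept supports the absence of a side
#' bias.
#'
#' @param df Data frame with a binary `side_right` column (1 = right) and a
#'   `bird_id` column; alternatively a validated choice dataset whose
#'   `light_side`/choice columns encode the chosen side.
#' @return List with `intercept`, `se`, `z`, `p`, `v_individual` and the
#'   fitted `model`.
#' @export
side_bias_test <- function(df) {
  if (!"side_right" %in% names(df)) {
    stop("side_bias_test needs a binary 'side_right' column", call. = FALSE)
  }
  y <- df$side_right
  if (!all(y %in% c(0, 1))) stop("side_right must be 0/1", call. = FALSE)
  if (all(y == 0) || all(y == 1)) {
    stop("complete separation: every trial chose the same side",
         call. = FALSE)
  }
  m <- lme4::glmer(side_right ~ 1 + (1 | bird_id), data = df,
                   family = stats::binomial())
  co <- summary(m)$coefficients
  list(intercept = co[1, 1], se = co[1, 2], z = co[1, 3], p = co[1, 4],
       v_individual = as.numeric(lme4::VarCorr(m)$bird_id[1]),
       model = m)
}

#' Fit a mixed model for one behavioural response
#'
#' Gaussian responses are fitted by REML with Satterthwaite-ready machinery;
#' binomial responses by Laplace maximum likelihood. The random structure is
#' a single random intercept per bird. Singular fits are flagged, not
#' discarded: with a repeated-measures design the random intercept is kept
#' to account for non-independence even when its variance estimate hits
#' zero.
#'
#' @param data Validated choice dataset (with movement rates added if those
#'   are the response).
#' @param response Response column name.
#' @param fixed_terms Character vector of fixed-effect terms (may include
#'   interactions like `"color:trial_order"`).
#' @param family `"gaussian"` or `"binomial"`.
#' @return A `mixed_fit`: list with the fitted `model`, `family`,
#'   `formula`, `data`, fixed-effect table `coefficients`, variance
#'   components `v_individual` and `v_residual` (latent-scale pi^2/3 for
#'   binomial), and `singular` / `converged` flags.
#' @export
fit_mixed <- function(data, response,
                      fixed_terms = c("color", "frequency", "trial_order",
                                      "ambient_pc1"),
                      family = c("gaussian", "binomial"), nAGQ = 1) {
  family <- match.arg(family)
  rhs <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(response, "~", rhs, "+ (1 | bird_id)"))
  if (family == "gaussian") {
    model <- lmerTest::lmer(fml, data = data, REML = TRUE)
  } else {
    # bobyqa + no derivative recalculation: identical logLik surface, much
    # faster on factorial fixed-effect structures
    model <- lme4::glmer(fml, data = data, family = stats::binomial(),
                         nAGQ = nAGQ,
                         control = lme4::glmerControl(
                           optimizer = "bobyqa", calc.derivs = FALSE))
  }
  X_full <- stats::model.matrix(lme4::nobars(fml), data)
  if (anyNA(lme4::fixef(model)) ||
      length(lme4::fixef(model)) < ncol(X_full)) {
    stop("aliased fixed-effect term: model matrix is rank deficient",
         call. = FALSE)
  }
  msgs <- model@optinfo$conv$lme4$messages
  converged <- is.null(msgs) ||
    !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  v_ind <- as.numeric(lme4::VarCorr(model)$bird_id[1])
  v_res <- if (family == "gaussian") stats::sigma(model)^2 else LOGIT_RESIDUAL_VAR
  co <- stats::coef(summary(model))
  structure(list(model = model, family = family, formula = fml,
                 response = response, fixed_terms = fixed_terms,
                 nAGQ = nAGQ, data = data, coefficients = co,
                 v_individual = v_ind, v_residual = v_res,
                 singular = lme4::isSingular(model),
                 converged = converged),
            class = "mixed_fit")
}

#' @exportS3Method base::print
print.mixed_fit <- function(x, ...) {
  cat(sprintf("<mixed_fit [%s]: %s>\n", x$family, deparse(x$formula)))
  cat(sprintf("  V_individual = %.4g, V_residual = %.4g%s%s\n",
              x$v_individual, x$v_residual,
              if (x$singular) " [singular]" else "",
              if (!x$converged) " [convergence warning]" else ""))
  invisible(x)
}

#' Per-term significance tests for a mixed model
#'
#' Gaussian fits get type-III F tests with Satterthwaite denominator degrees
#' of freedom (a small-sample approximation in the Kenward-Roger family);
#' binomial fits get likelihood-ratio chi-square tests, each term removed in
#' turn from the otherwise-full model and the fit repeated.
#'
#' @param fit A [fit_mixed()] result.
#' @return Data frame with columns `term`, `statistic` (`F` or `Chisq`),
#'   `df1`, `df2` (`NA` for chi-square), `p`.
#' @export
term_tests <- function(fit) {
  stopifnot(inherits(fit, "mixed_fit"))
  if (fit$family == "gaussian") {
    an <- stats::anova(fit$model, type = 3, ddf = "Satterthwaite")
    data.frame(term = rownames(an), statistic = an[["F value"]],
               df1 = an[["NumDF"]], df2 = an[["DenDF"]],
               p = an[["Pr(>F)"]], row.names = NULL)
  } else {
    do.call(rbind, lapply(fit$fixed_terms, binomial_lrt_term, fit = fit))
  }
}

## type-III-style model matrix: sum-to-zero contrasts for every factor, so
## that removing one term's columns tests that term with the others (and
## their interactions) still in the model
type3_model_matrix <- function(fit) {
  fml_fixed <- stats::reformulate(fit$fixed_terms)
  vars <- all.vars(fml_fixed)
  fac <- vars[vapply(vars, function(v) is.factor(fit$data[[v]]), logical(1))]
  contr <- stats::setNames(rep(list("contr.sum"), length(fac)), fac)
  stats::model.matrix(fml_fixed, fit$data,
                      contrasts.arg = if (length(fac)) contr else NULL)
}

## likelihood-ratio chi-square for one term of a binomial mixed fit: drop
## the term's sum-contrast columns and refit. The full-model likelihood is
## invariant to the recoding, so the original fit serves as the reference.
binomial_lrt_term <- function(fit, term) {
  canon <- function(x) vapply(strsplit(x, ":", fixed = TRUE),
                              function(p) paste(sort(p), collapse = ":"), "")
  X <- type3_model_matrix(fit)
  labels <- attr(stats::terms(stats::reformulate(fit$fixed_terms)),
                 "term.labels")
  j <- match(canon(term), canon(labels))
  if (is.na(j)) stop("term '", term, "' not found in model", call. = FALSE)
  keep <- attr(X, "assign") != j
  df <- sum(!keep)
  dd <- fit$data
  dd$.X <- X[, keep, drop = FALSE]
  fml <- stats::as.formula(paste(fit$response, "~ 0 + .X + (1 | bird_id)"))
  red <- lme4::glmer(fml, data = dd, family = stats::binomial(),
                     nAGQ = fit$nAGQ,
                     control = lme4::glmerControl(optimizer = "bobyqa",
                                                  calc.derivs = FALSE))
  stat <- max(2 * (as.numeric(stats::logLik(fit$model)) -
                     as.numeric(stats::logLik(red))), 0)
  data.frame(term = term, statistic = stat, df1 = df, df2 = NA_real_,
             p = stats::pchisq(stat, df, lower.tail = FALSE))
}

## p-value for a single named term in a fitted mixed model (used by the
## stepwise ladder): Satterthwaite F for gaussian, a single LRT refit for
## binomial
term_p_value <- function(fit, term) {
  key <- function(x) vapply(strsplit(x, ":", fixed = TRUE),
                            function(p) paste(sort(p), collapse = ":"), "")
  if (fit$family == "gaussian") {
    tt <- term_tests(fit)
    # anova() canonicalizes interaction order; match on sorted components
    idx <- match(key(term), key(tt$term))
    if (is.na(idx)) stop("term '", term, "' not found in model", call. = FALSE)
    return(tt[idx, , drop = FALSE])
  }
  binomial_lrt_term(fit, term)
}

#' Stepwise two-way-interaction ladder
#'
#' Builds the final model for one response by evaluating candidate two-way
#' interactions in four ordered steps on top of the base terms (colour,
#' pulsing frequency, trial order, ambient-light PC1), keeping only
#' significant interactions:
#' \enumerate{
#'   \item base + colour x frequency; drop if non-significant;
#'   \item + colour x trial-order and frequency x trial-order; drop
#'     non-significant ones;
#'   \item + colour x ambient and frequency x ambient; drop
#'     non-significant ones;
#'   \item refit base + all surviving interactions.
#' }
#' Interactions are tested within the step's model (Satterthwaite F for
#' gaussian responses, likelihood-ratio chi-square for binomial).
#'
#' @param data Validated choice dataset with an `ambient_pc1` column (see
#'   [ambient_pca()]) and movement rates if needed.
#' @param response Response column name.
#' @param family `"gaussian"` or `"binomial"`.
#' @param alpha Retention threshold (default 0.05).
#' @param base_terms Main-effect terms of the base model.
#' @return A `ladder_result`: list with `final` (a [fit_mixed()]), `kept`
#'   (character vector of retained interactions) and `report` (data frame of
#'   every interaction test: step, term, statistic, df, p, kept).
#' @export
stepwise_interaction_ladder <- function(data, response,
                                        family = c("gaussian", "binomial"),
                                        alpha = 0.05,
                                        base_terms = c("color", "frequency",
                                                       "trial_order",
                                                       "ambient_pc1"),
                                        nAGQ = 1) {
  family <- match.arg(family)
  steps <- list(
    "color:frequency",
    c("color:trial_order", "frequency:trial_order"),
    c("color:ambient_pc1", "frequency:ambient_pc1"))
  kept <- character(0)
  report <- NULL
  for (k in seq_along(steps)) {
    cand <- steps[[k]]
    fit_k <- tryCatch(
      fit_mixed(data, response, c(base_terms, kept, cand), family,
                nAGQ = nAGQ),
      error = function(e) stop("ladder step ", k, " failed: ",
                               conditionMessage(e), call. = FALSE))
    for (tm in cand) {
      row <- term_p_value(fit_k, tm)
      keep_tm <- is.finite(row$p) && row$p < alpha
      report <- rbind(report,
                      data.frame(step = k, term = tm,
                                 statistic = row$statistic, df1 = row$df1,
                                 df2 = row$df2, p = row$p, kept = keep_tm))
      if (keep_tm) kept <- c(kept, tm)
    }
  }
  final <- fit_mixed(data, response, c(base_terms, kept), family,
                     nAGQ = nAGQ)
  structure(list(final = final, kept = kept, report = report),
            class = "ladder_result")
}

#' @exportS3Method base::print
print.ladder_result <- function(x, ...) {
  cat("<stepwise interaction ladder>\n")
  cat("  retained:", if (length(x$kept)) paste(x$kept, collapse = ", ")
      else "(none)", "\n")
  print(x$report, digits = 3)
  invisible(x)
}

#' Estimated marginal means for a factor
#'
#' Least-square means: model predictions averaged over a balanced grid of
#' the other factors with covariates held at their means, back-transformed
#' to the response scale for binomial fits (delta-method standard errors).
#'
#' @param fit A [fit_mixed()] result.
#' @param factor_name Name of a factor in the model.
#' @return Data frame with columns `level`, `mean`, `se`.
#' @export
estimated_marginal_means <- function(fit, factor_name) {
  stopifnot(inherits(fit, "mixed_fit"))
  if (!factor_name %in% all.vars(fit$formula)) {
    stop("factor '", factor_name, "' is not in the model", call. = FALSE)
  }
  em <- emmeans::emmeans(fit$model, specs = factor_name,
                         type = "response",
                         data = fit$data,
                         lmer.df = "satterthwaite")
  s <- as.data.frame(summary(em))
  mean_col <- intersect(c("emmean", "prob", "response", "rate"), names(s))[1]
  data.frame(level = as.character(s[[factor_name]]),
             mean = s[[mean_col]], se = s[["SE"]], row.names = NULL)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-explained decomposition for mixed models: the marginal
#' R-squared is the variance of the fixed-effect predictions over the total
#' (fixed + individual + residual) variance; the conditional R-squared adds
#' the random-intercept variance to the numerator. For binomial fits the
#' residual variance is the latent-logit pi^2/3.
#'
#' @param fit A [fit_mixed()] result.
#' @return List with `marginal` and `conditional`, both in percent.
#' @export
r2_mixed <- function(fit) {
  stopifnot(inherits(fit, "mixed_fit"))
  X <- stats::model.matrix(fit$model)
  var_fixed <- stats::var(as.numeric(X %*% lme4::fixef(fit$model)))
  total <- var_fixed + fit$v_individual + fit$v_residual
  list(marginal = 100 * var_fixed / total,
       conditional = 100 * (var_fixed + fit$v_individual) / total)
}

#' Repeatability (between-individual variance share)
#'
#' \eqn{R = V_{individual} / (V_{individual} + V_{residual})}, expressed in
#' percent, with a parametric-bootstrap percentile confidence interval:
#' responses are simulated from the fitted model (new random effects and
#' residuals each time), the model refitted, and the ratio recomputed.
#' Values at or below 20% are categorized `low`, above 20 up to 40%
#' `moderate`, above 40% `high`.
#'
#' @param fit A [fit_mixed()] result.
#' @param n_boot Number of bootstrap refits (default 1000; 0 skips the CI).
#' @param seed Integer seed for the bootstrap.
#' @param level Confidence level (default 0.95).
#' @return A `repeatability_estimate`: list with `value`, `ci_low`,
#'   `ci_high` (percent; `NA` when `n_boot = 0`) and `category`.
#' @export
repeatability <- function(fit, n_boot = 1000, seed = 1, level = 0.95) {
  stopifnot(inherits(fit, "mixed_fit"))
  denom <- fit$v_individual + fit$v_residual
  if (denom <= 0) {
    stop("both variance components are zero: repeatability undefined",
         call. = FALSE)
  }
  value <- 100 * fit$v_individual / denom
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    sims <- with_seed(seed, stats::simulate(fit$model, nsim = n_boot,
                                            use.u = FALSE))
    ratios <- vapply(seq_len(n_boot), function(b) {
      m <- suppressWarnings(suppressMessages(
        tryCatch(lme4::refit(fit$model, sims[[b]]),
                 error = function(e) NULL)))
      if (is.null(m)) return(NA_real_)
      vi <- as.numeric(lme4::VarCorr(m)$bird_id[1])
      vr <- if (fit$family == "gaussian") stats::sigma(m)^2 else LOGIT_RESIDUAL_VAR
      100 * vi / (vi + vr)
    }, numeric(1))
    ratios <- ratios[is.finite(ratios)]
    if (length(ratios) >= 20) {
      ci <- unname(stats::quantile(ratios, c((1 - level) / 2,
                                             1 - (1 - level) / 2)))
    }
  }
  structure(list(value = value, ci_low = ci[1], ci_high = ci[2],
                 category = repeatability_category(value)),
            class = "repeatability_estimate")
}

#' @rdname repeatability
#' @param value Repeatability in percent.
#' @export
repeatability_category <- function(value) {
  stopifnot(value >= 0, value <= 100)
  if (value <= 20) "low" else if (value <= 40) "moderate" else "high"
}

#' @exportS3Method base::print
print.repeatability_estimate <- function(x, ...) {
  cat(sprintf("<repeatability: %.1f%% (CI %.1f-%.1f%%), %s>\n",
              x$value, x$ci_low, x$ci_high, x$category))
  invisible(x)
}

#' Association of the lit side with the design factors
#'
#' Diagnostic for counterbalanced designs: a logistic GLM of the lit side
#' (right = 1) on the categorical design factors and their interactions,
#' with likelihood-ratio tests per term. A significant association justifies
#' excluding the lit side from the behavioural models.
#'
#' @param data Validated choice dataset.
#' @return Data frame of per-term LR chi-square tests (`term`, `statistic`,
#'   `df`, `p`).
#' @export
side_design_association <- function(data) {
  d <- data
  d$side_right <- as.integer(d$light_side == "right")
  m <- stats::glm(side_right ~ color * frequency * trial_order, data = d,
                  family = stats::binomial())
  an <- stats::anova(m, test = "Chisq")
  an <- an[-1, , drop = FALSE]
  data.frame(term = rownames(an), statistic = an$Deviance, df = an$Df,
             p = an[["Pr(>Chi)"]], row.names = NULL)
}
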