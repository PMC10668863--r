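---
title: "Designing salient light stimuli for birds and analysing single-choice experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing salient light stimuli for birds and analysing single-choice experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avistim)
```

## Overview

`avistim` covers the two computational halves of a light-deterrent study on
birds:

1. **Stimulus design.** Given a parameterized avian visual system and a sky
   background, score a family of peak-shifted LED spectra by their chromatic
   contrast in just-noticeable-difference (JND) units under the
   receptor-noise-limited (RNL) model, pick candidate peak wavelengths from
   the relative maxima of that scan, and radiometrically match intensity
   settings across the chosen colours.
2. **Behavioural analysis.** For a repeated-measures single-choice
   experiment (one bird, one lit side, a binary approach/avoid outcome),
   run the confound screen, summarize the paired ambient-light readings with
   a principal component, test for arena side bias, build per-response mixed
   models through a fixed four-step interaction ladder, and report estimated
   marginal means, marginal/conditional R², and repeatability.

A synthetic-data module generates spectra and trial tables with the
statistical structure these analyses assume, so the entire pipeline is
testable without any instrument files.

## The receptor-noise-limited model

A photoreceptor of class $i$ with spectral sensitivity $S_i(\lambda)$ viewing
a stimulus with photon-flux spectrum $R(\lambda)$ collects the quantum catch

$$Q_i = \int R(\lambda)\, S_i(\lambda)\, d\lambda ,$$

computed here by the trapezoid rule on a 1 nm grid from 300 to 700 nm (the
range scanned during stimulus design and the binning of typical
spectroradiometer exports). Receptor signals are log catch ratios after von
Kries adaptation to the background, $\Delta f_i = \ln(Q_i^{stim}/Q_i^{bg})$:
the background itself is the adapting field, which is the natural reading for
emissive stimuli viewed against the sky — there is no separate illuminant to
divide out. The log-linear code is the bright-light (photopic) limit of the
RNL framework, which is the regime a daytime choice experiment operates in.

Channel noise is set by the Weber fraction $\omega$ of the most abundant cone
class and scales with the inverse square root of relative cone density
$\eta_i$:

$$e_i = \omega \sqrt{\eta_{max}/\eta_i}.$$

$\omega$ defaults to 0.1, the common photopic convention; it is a free
parameter of `visual_system()` because species-specific behavioural estimates
are rare. The chromatic distance for $n$ receptor classes is

$$\Delta S^2 = \frac{\sum_{i<j} \big(\prod_{k \ne i,j} e_k\big)^2 (\Delta f_i - \Delta f_j)^2}
                    {\sum_i \big(\prod_{k \ne i} e_k\big)^2},$$

implemented once for arbitrary $n$ (`rnl_distance()`); the test suite proves
it equal to the published dichromat, trichromat and tetrachromat closed forms
to $10^{-10}$ on random inputs. Because $\Delta S$ depends only on
differences of the $\Delta f_i$, multiplying the stimulus by any positive
constant leaves it unchanged: it is a colour distance, not a brightness
distance. Achromatic (double-cone) contrast is deliberately out of scope.

Zero quantum catches raise an error naming the cone rather than being
clamped; a clamped catch would silently turn a numerical underflow into an
arbitrarily large JND.

## Building receptor sensitivities

`pigment_template()` evaluates the standard A1 visual-pigment nomogram of
Govardovskii et al. (2000) — the alpha band plus the 0.26-amplitude beta
band — and renormalizes to a maximum of exactly 1 on the grid. Oil droplets
can be supplied as measured transmittance tables or as a parametric long-pass
Gompertz cut-off (`oil_droplet_transmittance()`), the form the synthetic
module uses; the shortest-wavelength cone of the synthetic system carries no
droplet, matching the usual droplet-free violet/UV cone.

Ocular media transmittance is estimated from repeated scans by
`ocular_media_from_scans()`: scans are averaged, max-normalized, and the 50%
cutoff $\lambda_{T0.5}$ located by linear interpolation of the first upward
crossing of 0.5 from short wavelengths. A four-parameter logistic is then
fitted by least squares and replaces the measured curve *below* the cutoff,
so that instrument noise in the steep short-wavelength tail — where true
transmittance is near zero and relative noise is worst — cannot leak into
quantum catches. The logistic is our choice of monotone de-noising curve; on
synthetic sigmoids the cutoff is recovered to better than 1 nm for point
noise up to sd 0.02, and the whole procedure is invariant to uniform
rescaling of the input scans.

## The LED scan

`simulate_led_series()` translates a measured (or synthetic) LED template
rigidly along the wavelength axis — spectral shape is not warped — so its
peak visits 300 to 700 nm in 2 nm steps (201 spectra), then peak-normalizes
each spectrum to 4000 photon counts. Normalization is to *peak*, not total,
output. Where a shifted template leaves the grid, the baseline emission
level of the template is retained rather than zero: a measured emission
spectrum has an instrument noise floor, and a literal zero tail would make
long-range catch ratios meaningless. For the same reason the synthetic
template `synth_led_template()` carries a relative floor of $10^{-4}$ under
its asymmetric-Gaussian profile (30 nm FWHM by default; the asymmetry ratio
of 1.1 gives the slightly heavier long-wavelength shoulder typical of real
LEDs).

`contrast_scan()` scores every LED against a background and returns a tidy
(peak, JND) table; `select_candidate_peaks()` takes the local maxima of that
curve greedily in decreasing contrast order subject to a minimum pairwise
separation (default 60 nm, so one short- and one long-wavelength candidate
emerge rather than two neighbours of the same bump), breaking ties toward
the shorter wavelength. Commercial availability of LEDs at a candidate peak
is a procurement question, not an algorithmic one, so the function only
ranks candidates. `radiometric_match()` then picks, from candidate intensity
settings of the two colours, the pair with the most similar peak photon
output, so treatments differ in wavelength and pulse but not in photons
delivered.

## The choice-experiment pipeline

The trial table schema is validated by `validate_choice_data()`: bird id,
trial order 1–8 (treated as categorical throughout — the design asks how
responses change across specific exposures, not for a linear trend), colour,
pulsing frequency, lit side, the binary avoidance outcome, latency (capped
at 600 s by the 10-minute trial rule; mistrials are absent rows, never
imputed), head/body movement counts with the visible duration they are rated
over (`movement_rate()` divides them), and paired lux readings.

The analysis steps mirror the study design:

* **Collinearity screen** (`collinearity_screen()`): pairwise Pearson
  correlations among candidate confounds with a default flag at |r| > 0.7.
* **Ambient PCA** (`ambient_pca()`): correlation-matrix PCA of the
  standardized lux pair, retaining components with eigenvalue above 1. The
  correlation (not covariance) matrix is used because lux readings are
  strongly right-skewed and scale-heterogeneous; for two standardized
  variables the first eigenvalue is exactly $1 + |r|$, which the tests
  assert to $10^{-12}$. PCA1 is oriented so both loadings are positive,
  making higher scores mean brighter conditions on both sides.
* **Side bias** (`side_bias_test()`): intercept-only logistic mixed model
  of choosing the right side, bird as random intercept, Laplace ML.
  `side_design_association()` provides the companion diagnostic — a
  logistic GLM of the lit side on the design factors — which justifies
  excluding the lit side from the behavioural models in counterbalanced
  designs.
* **Mixed models** (`fit_mixed()`): gaussian responses by REML, binomial by
  Laplace ML, always with a single random intercept per bird. Singular
  fits are flagged and kept: the random intercept encodes the repeated
  measures and removing it would fake independence. Per-term tests
  (`term_tests()`) use type-III F statistics with Satterthwaite denominator
  degrees of freedom for gaussian responses — a small-sample approximation
  in the same family as Kenward–Roger, which is the package's default
  because the Satterthwaite machinery is available directly in the fitting
  stack — and type-III-style likelihood-ratio chi-squares for binomial
  responses, computed by refitting with the term's sum-to-zero contrast
  columns removed so that main effects remain testable underneath their
  interactions.
* **The interaction ladder** (`stepwise_interaction_ladder()`): with eight
  trials per bird, fitting all ten two-way interactions at once would
  overparameterize, so candidates are evaluated in a fixed order — (1)
  colour × frequency, (2) colour × order and frequency × order, (3)
  colour × ambient and frequency × ambient, (4) refit base plus survivors —
  dropping non-significant candidates at each step (default
  $\alpha = 0.05$). Every intermediate test is reported.
* **Effect summaries**: `estimated_marginal_means()` (least-square means on
  the response scale over a balanced factor grid, delta-method SEs for
  binomial), `r2_mixed()` (marginal = fixed-effect prediction variance over
  total; conditional adds the random-intercept variance; for binomial fits
  the residual variance is the latent-logit $\pi^2/3$), and
  `repeatability()` ($V_{ind}/(V_{ind}+V_{res})$ in percent, categorized
  low ≤ 20 < moderate ≤ 40 < high, with a parametric-bootstrap percentile
  CI — the bootstrap simulates new random effects and residuals from the
  fit and refits, 1000 times by default; the analysis scripts use 200,
  which is enough for a stable 95% interval here).

For replicated simulation studies `fit_mixed()` and the ladder accept
`nAGQ = 0`, which profiles the fixed effects inside the penalized
least-squares step instead of the outer optimization. On this design it
changes likelihood-ratio p-values only in the fourth decimal while being
roughly thirty times faster; the calibration suite runs both ways give the
same type-I error (about 0.04–0.05 at the nominal 0.05).

## What the synthetic generator does and does not emulate

`synth_choice_dataset()` reproduces the design exactly: every bird sees all
four colour × frequency cells in randomized order in trials 1–4 with
randomized lit sides, then again in trials 5–8 with the opposite side per
cell. Ambient lux pairs are bivariate log-normal with the raw-scale Pearson
correlation set by inverting the log-normal correlation formula (default
0.83); the avoidance outcome is Bernoulli with log-odds
$\beta_{colour,trial} + \gamma\,(\pm 1)\,A + b_{bird}$, where $A$ is the
generator's standardized common light factor (what the ambient PCA
recovers), the sign follows pulsing/steady, and $b \sim N(0, \sigma_b^2)$.
Default choices and why:

* `default_avoidance_logodds()` encodes the observed trajectories: red
  avoidance declining from about 0.9 to near 0 across the eight exposures
  (a mere-exposure trajectory) and blue following a shallower
  avoid–approach–avoid oscillation around 0.6. Order is categorical in the
  fitted models, so no learning mechanism is imposed — the table *is* the
  trajectory.
* $\sigma_b = 0.2$ for avoidance, echoing the near-zero between-individual
  variation such experiments report for the choice outcome.
* $\gamma = 0.5$ for the pulsing × ambient interaction; latencies are gamma
  (mean 35 s, shape 1.2) with a log-normal per-bird intercept and are
  capped at 600 s (capped trials become mistrials, default extra mistrial
  probability 0.03); movement counts are Poisson over a visible duration
  tied to latency.

`synth_partitioned_response()` overlays a gaussian response with an exact
variance partition (treatment-cell, individual, residual shares), which is
how the variance-decomposition pipeline is validated against known truth.
One caveat it makes visible: the marginal R² estimator uses the variance of
*fitted* fixed-effect predictions, which carries an upward overfitting bias
of order $k\,V_{res}/n$ for $k$ fixed-effect parameters on $n$ trials. At
the scale the acceptance script uses (2400 trials, 16 cell parameters) the
bias is a fraction of a percentage point; at 19-bird scale it is visibly
larger, which is worth remembering when reading small-sample marginal R²
values anywhere.

What the generator does **not** emulate: temporal autocorrelation across a
bird's trials beyond the shared intercept, weather-driven drift in ambient
light, any dependence of latency on the treatment cell by default, or
mechanistic habituation dynamics. Passing tests therefore demonstrate that
the pipeline recovers the structure it models, not that real birds behave
like the generator.

The synthetic visual system (`synth_visual_system()`) is likewise a
plausible tetrachromat placeholder — pigment peaks spread over roughly
415–605 nm, droplet cuts 40 nm below each peak, densities rising toward long
wavelengths, logistic ocular media with a 369 nm cutoff — not a transcribed
parameter set for any species; species parameters enter through
`read_visual_system()` config files when available. JND values computed with
the placeholder are internally consistent but not comparable to values
computed with real retinal data.

## Numerical choices and degenerate inputs

* Trapezoidal integration everywhere; 1 nm grid, 300–700 nm.
* Duplicate wavelengths in spectral files are averaged (instrument
  re-scans), out-of-support resampling yields 0 with a warning, empty or
  non-numeric files error.
* Peak normalization errors on all-zero spectra; `normalize_peak` is exact
  at the target and idempotent.
* The candidate selector warns and returns the shortest wavelength on a
  perfectly flat scan; ties in contrast break toward shorter wavelengths.
* glmer fits use `bobyqa` without derivative re-estimation (the likelihood
  surface is unchanged; only post-fit Hessian checks are skipped), Laplace
  `nAGQ = 1` by default.
* Complete separation in the side-bias model (all trials one side) is an
  error, as is an aliased fixed-effect term (detected by comparing the
  model-matrix rank before and after fitting).
* Repeatability is undefined (error) when both variance components are
  zero; a zero individual component gives 0% with category "low".

## Problem sizes

The test suite and acceptance script size their simulations to be
informative while staying lightweight: 100 replicates of 40 birds for ladder
power and size (power ≥ 0.9 against the planted colour × order interaction
of log-odds amplitude 1.5; per-candidate retention under the null compatible
with the 5% test level), 200 replicates of 50 birds × 20 trials for
side-bias interval coverage, 30 replicates for repeatability recovery, 10
000 trials for the lux-correlation and PCA summary, and 2400 trials for the
variance-partition reproduction. The analysis scripts run the full pipeline
at the study scale of 19 birds.
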