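---
title: "Duration-adjusted occurrence models for camera-trap ethograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duration-adjusted occurrence models for camera-trap ethograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occdur)
```

## The modelling problem

Camera traps at chimpanzee drumming trees record short clips in which an
individual performs a tree-directed signalling activity — hand/foot
drumming, stone throwing ("stone-assisted drumming"), or both — and the
analyst scores whether each of several accompanying behaviours (pant
hooting, climax screaming, piloerection, swaying, sound surround, alert
focus on the environment) occurred at least once in the window before,
and in the window after, the signal. The scientific question is whether
the probability of each accompanying behaviour differs between the three
activity types.

Two features of such data shape the model:

* **Repeated observation of individuals.** The same adult males appear in
  many clips, so records are not independent. `occdur` fits a logistic
  mixed model with a random intercept $u_i \sim N(0, \sigma^2)$ per
  individual.
* **Unequal visibility windows.** An individual may be visible from 1 s
  up to 61 s. A behaviour has more opportunity to occur in a long window,
  so raw occurrence probabilities are not comparable across windows.

## The duration offset and the per-second rate B

`occdur` handles exposure through a window-level occurrence probability
built from a per-second baseline rate $B$. If each second of a window of
$T$ seconds independently carries probability $B$ of the behaviour
occurring, the probability that it occurs at least once is

$$O(B, T) = 1 - (1 - B)^T,$$

which is 0 at $T = 0$, equals $B$ at $T = 1$, rises monotonically in both
arguments, and satisfies the recursion
$O(B,T) = O(B,T-1) + B\,(1 - O(B,T-1))$. The model enters this on the
logit scale as an offset:

$$\mathrm{logit}\, p_{ij} = x_{ij}'\beta + u_i +
  \mathrm{logit}\, O(B, T_{ij}),$$

with $x_{ij}$ the dummy-coded activity type (drumming as reference level,
contrasts for stone-and-drum and stone-only) and $y_{ij} \sim
\mathrm{Bernoulli}(p_{ij})$. Unlike a conventional `log(T)` exposure
offset, $\mathrm{logit}\,O$ saturates: doubling an already long window
barely raises the occurrence probability, which matches the behaviour of
short, discrete display events.

An alternative power form $O = B^T$ can be selected with
`offset_form = "literal"`. It *decreases* with duration and cannot serve
as an exposure adjustment; it is retained only so that analyses using
that expression can be audited. The at-least-one-event form is the
default throughout.

$B$ is not fixed in advance. It is estimated by an outer
maximum-likelihood loop: for a candidate $B$ the offset is computed, the
mixed model is fitted, and the achieved marginal log-likelihood defines
the profile $L^*(B) = \max_{\beta,\sigma} \ell(\beta, \sigma; B)$, which
is maximized over $B$.

## Estimation machinery

**Marginal likelihood.** The random intercept is integrated out per
individual with adaptive Gauss–Hermite quadrature: the integrand is
re-centred at each individual's conditional mode (found by Newton steps
on a strictly concave function) and scaled by the curvature there,
with 20 nodes by default. A dense-grid trapezoidal integrator
(`brute_force_marg_loglik()`, 20 001 points over $\pm 10\sigma$) serves
as an independent ground truth; the test suite requires agreement to
$10^{-6}$ on random small models, and doubling the node count changes
toy-model likelihoods by less than $10^{-8}$. At $\sigma = 0$ the
quadrature is bypassed and the degenerate conditional likelihood is
returned exactly, so the likelihood is continuous at the boundary.

**Inner optimization.** For fixed $B$, $(\beta, \log\sigma)$ are
maximized with a quasi-Newton optimizer (`nlminb`) using the analytic
posterior-expected-score gradient computed alongside the likelihood.
Starts: $\beta$ from an ordinary logistic fit without random effect,
$\sigma \in \{0.1, 1\}$; an explicit boundary fit at $\sigma = 0$ is
always compared, and ties are broken towards the smaller $\sigma$.
Convergence uses a relative log-likelihood tolerance of $10^{-10}$;
near-stationary points that the optimizer labels conservatively are
accepted only if the gradient norm is small. Degenerate inputs are
flagged rather than repaired: constant responses (`converged = FALSE`
unless forced), coefficients beyond 15 on the logit scale
(`separation`), a single individual (`boundary_sigma`).

**Profile of B.** $L^*(B)$ is evaluated on a 9-point grid equally
spaced in $\mathrm{logit}(B)$ over the search interval (default
$[10^{-4}, 0.99]$), then refined by Brent search between the grid
neighbours of the maximum, to a tolerance of $10^{-5}$ on the logit
scale (far below the statistical uncertainty of $\hat B$). Successive evaluations are warm-started, but the refinement and
the final fit are re-anchored at the best parameters seen and the final
fit repeats the full multi-start battery, so the reported optimum never
inherits a stale warm start. When all durations are equal the offset is
a constant absorbed by the intercept and the profile is exactly flat;
this is detected up front, `B_identifiable` is set to `FALSE`, and a
warning is issued. A profile maximum on the search boundary also warns,
since there $B$ and the intercept become confounded.

**Standard errors.** With $B$ estimated, reported standard errors come
from the observed information of the joint likelihood in
$(\beta, \log\sigma, \mathrm{logit}\,B)$, so the sampling uncertainty of
$\hat B$ — which trades off against the intercept — is propagated. In
recovery simulations this brings the ratio of empirical sampling SD to
mean reported SE for all three fixed effects to within a few percent of
1, whereas conditioning on $\hat B$ understates the intercept's
uncertainty by roughly a factor of two. With $B$ supplied by the user
the conventional conditional information is used.

## Inference workflow

* **Activity-type test.** `occm_lrt()` drops the activity factor and
  compares full and reduced fits by a likelihood-ratio test with 2
  degrees of freedom (three activity levels). Both models re-profile $B$
  by default, so the statistic compares true profile maxima; a fixed-$B$
  variant (`reprofile_B = FALSE`) exists for sensitivity analysis. The
  choice to re-profile is a design decision: it keeps the null
  distribution of the statistic asymptotically $\chi^2_2$ because $B$ is
  treated symmetrically in both hypotheses.
* **Confidence limits.** `occm_boot()` implements a parametric
  bootstrap: responses re-simulated from the fitted model (fresh random
  intercepts), $(\beta, \sigma)$ refitted with $B$ held at the point
  estimate, and 2.5/97.5 percentiles of the replicate estimates taken as
  95% limits. Percentile intervals are used because only "95% confidence
  limits" is specified by convention in this workflow; holding $B$ fixed
  mirrors the stability procedure and the mechanics of offset-based
  refitting. Failed refits are dropped and counted — never imputed — and
  more than 10% failures flags the result unreliable.
* **Stability.** `occm_loo()` refits once per individual left out, $B$
  constant, and reports componentwise min/max of the estimates, the
  conventional influence summary for grouped data.
* **Reporting.** `occm_table()` assembles estimate, SE, bootstrap limits,
  the $\chi^2$/df/P of the activity test and the stability range into
  one block per model; `run_pipeline()` does this for the standard
  ten-model battery (four behaviours in both periods, swaying before
  only, climax scream after only) and writes per-model CSVs, a combined
  report, and a log of seeds, tolerances and the profile trace of $B$.

## The synthetic ethogram generator

Real video-coded data are not distributable with the package, so every
statistical claim is exercised on synthetic data with known truth.
`simulate_occurrence()` draws, per individual, one random intercept, and
per event an activity type, an integer duration on 1–61 s (uniform by
default: the design only fixes the range, so the flattest choice is
used), and a response from exactly the Bernoulli probability the model
assumes. This makes recovery tests well-posed: the generator and the
fitter share one probability model. An optional per-second hazard
mechanism (`mechanism = "per_second"`) draws each second independently
with probability $B$; it coincides with the model only at zero linear
predictor and is used as a cross-check that the offset construction
matches an explicit event process.

`simulate_study()` produces a full study-shaped table: 28 individuals in
3 sites, per-individual event counts from a shifted Poisson (mean 5.5,
so most individuals contribute few events, as in unbalanced field data),
before/after windows present with probabilities 0.87/0.97 (so roughly
135 before- and 155 after-windows in expectation), and all six
behaviours scored per window with behaviour-specific base rates and, by
default, no activity effect. These defaults were chosen once to mirror
the targeted study design and are not tuned.

What the generator does **not** emulate: temporal sequencing of
behaviours within a window, site-level random variation, activity
preferences that differ by individual, and misclassification in video
coding. Passing tests therefore demonstrate correctness of the
estimator and its inference under the model's own assumptions — not
robustness to coding error or model misspecification.

## Validation summary

The test suite (and `scripts/acceptance.R`, which recomputes the same
quantities from scratch) checks, among others:

* offset identities and the at-least-one-event recursion to $10^{-12}$;
* adaptive quadrature versus dense-grid integration to $10^{-6}$;
* parameter recovery over replicated datasets of 200 individuals × 10
  events (mean bias of every fixed effect below 0.1; median $\hat B$
  near the generating 0.05; sampling SD within 25% of reported SE);
* likelihood-ratio-test size close to the nominal 5% over 500 null
  replicates of 100 individuals × 5 events, and power above 80% for a
  strong contrast;
* bootstrap 95% intervals covering the generating contrast in 90–99% of
  200 replicated datasets (100 bootstrap draws each);
* an end-to-end pipeline run emitting exactly the ten-model battery,
  each with a 2-df activity test, byte-identical under a repeated seed.

The replicate counts are the package's chosen simulation sizes; they
keep Monte-Carlo error comfortably below the acceptance margins above.

## Known limitations

* $B$ is assumed common to all individuals and activity types within a
  model; only the linear predictor moves occurrence probabilities.
* The bootstrap holds $B$ at its point estimate, so intercept intervals
  omit the (propagated-in-SE) uncertainty of $\hat B$; contrast
  intervals are essentially unaffected, and a `refit_B = TRUE` variant
  is available at cost.
* No random slopes, crossed random effects or site effects — single
  observations per individual-activity combination make them
  unidentifiable in the targeted design.
* No multiple-testing correction across the ten-model battery, by
  design, mirroring the reporting convention of the workflow.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_individuals = 50, events_per_individual = 10,
                  true_B = 0.05, true_beta = c(0.5, -0.5, 1),
                  true_sigma = 1, seed = 3)
d <- simulate_occurrence(cfg)
fit <- occm(occurred ~ activity, d)
summary(fit)
lrt <- occm_lrt(fit, d)
boot <- occm_boot(fit, n_boot = 1000, seed = 1)
loo <- occm_loo(fit)
occm_table(fit, lrt, boot, loo,
           behaviour = "pant_hoot", period = "before")
```
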