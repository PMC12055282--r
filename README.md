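# occdur

Duration-adjusted binomial mixed models for behaviour occurrence in
variable-length observation windows.

## The problem

Camera-trap studies of chimpanzee signalling score, per video clip,
whether an accompanying behaviour (pant hooting, climax screaming,
piloerection, swaying, sound surround, alert focus on the environment)
occurred at least once while the focal individual was visible — before
and after a tree-directed signal that was drumming, stone throwing, or
both. Two nuisances stand between those binary scores and the question
"does behaviour probability differ between activity types?": the same
individuals recur across clips, and visibility windows range from 1 s to
just over a minute, giving behaviours unequal opportunity to be seen.

`occdur` is for analysts of such ethogram event tables. It fits the
logistic mixed model

    logit p_ij = x_ij' beta + u_i + logit O(B, T_ij),
    O(B, T) = 1 - (1 - B)^T,      u_i ~ N(0, sigma^2)

where `x_ij` dummy-codes activity type with drumming as the reference
level, `u_i` is an individual random intercept, `T_ij` is the window
duration in seconds, and `O(B, T)` is the probability that a behaviour
with per-second baseline rate `B` occurs at least once in `T` seconds.
The offset `logit O` enters the linear predictor as a known term once
`B` is given; `B` itself is estimated in an outer loop that maximizes
the profile likelihood `L*(B) = max_{beta, sigma} l(beta, sigma; B)`.
Random intercepts are integrated out by adaptive Gauss–Hermite
quadrature (compiled, with analytic gradients), validated against a
dense-grid integrator.

Around the fitter sits the complete inference workflow: a 2-df
likelihood-ratio test for the activity effect, parametric-bootstrap 95%
confidence limits (B held at its estimate during refits),
leave-one-individual-out stability ranges, report tables, a synthetic
ethogram generator with known ground truth, and a batch pipeline over
the standard ten-model battery (four behaviours in both periods, swaying
before only, climax scream after only).

## Worked example

```r
library(occdur)

cfg <- sim_config(n_individuals = 50, events_per_individual = 10,
                  true_B = 0.05, true_beta = c(0.5, -0.5, 1),
                  true_sigma = 1, seed = 3)
d   <- simulate_occurrence(cfg)
fit <- occm(occurred ~ activity, d)
fit
#> Duration-adjusted binomial mixed model (logit link)
#>   formula: occurred ~ activity
#>   500 events, 50 individuals
#>   per-second baseline B = 0.045 (profiled)
#>   random-intercept SD sigma = 0.641
#>   log-likelihood: -195.56091
#> Coefficients:
#>            (Intercept) activitystone_and_drum          activitystone
#>                  0.974                 -0.915                  0.759
```

The profiled per-second rate (0.045) and the fixed effects sit close to
the generating values (`B = 0.05`, contrasts −0.5 and 1 against the
drumming reference; the intercept absorbs part of the offset scale).
Completing the inference workflow:

```r
lrt  <- occm_lrt(fit, d)                      # 2-df test of activity type
boot <- occm_boot(fit, n_boot = 1000, seed = 1)
loo  <- occm_loo(fit)
occm_table(fit, lrt, boot, loo, behaviour = "pant_hoot", period = "before")
#>  behaviour period         term   Est.    SE CI_lower CI_upper   chi2 df  P    min    max
#>  pant_hoot before    intercept  0.974 0.537    0.537    1.527     NA NA NA  0.930  1.078
#>  pant_hoot before Beh. St & Dr -0.915 0.310   -1.543   -0.335 25.703  2  0 -1.028 -0.792
#>  pant_hoot before      Beh. St  0.759 0.366    0.054    1.492     NA NA NA  0.645  0.891
```

Each row is one fixed-effect term: estimate, standard error (from the
joint observed information, so the uncertainty of the estimated `B` is
propagated), percentile-bootstrap 95% limits, the activity
likelihood-ratio test (chi-square, df, P on the first contrast row), and
the min–max range of estimates across leave-one-individual-out refits.
Here both contrasts exclude zero and the activity test is strongly
significant, as expected for data generated with real contrasts; the
narrow stability ranges say no single individual drives the result.

`run_pipeline()` applies the same steps to every behaviour/period model
in a configured battery and writes per-model summaries, bootstrap
replicates, a combined report and a run log. A thin command-line wrapper
is included at `inst/cli/occdur-cli.R`
(`simulate` / `pipeline` / `show-config`).

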