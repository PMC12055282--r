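test_that("fixed-B fit recovers null parameters on a large simulation", {
  cfg <- sim_config(n_individuals = 100, events_per_individual = 50,
                    true_B = 0.1, true_beta = c(0, 0, 0), true_sigma = 0,
                    seed = 51)
  d <- simulate_occurrence(cfg)
  fit <- occm(occurred ~ activity, d, B = 0.1)
  expect_true(fit$converged)
  expect_true(fit$B_fixed)
  expect_lt(max(abs(coef(fit))), 3.5 * max(fit$se))
  expect_lt(fit$sigma, 0.1)
})

test_that("single-individual data raise the sigma boundary flag", {
  d <- simulate_occurrence(sim_config(n_individuals = 1,
                                      events_per_individual = 60, seed = 52))
  expect_warning(fit <- occm(occurred ~ activity, d, B = 0.05),
                 "one individual")
  expect_true(fit$boundary_sigma)
  expect_identical(fit$sigma, 0)
})

test_that("the optimum dominates a parameter grid around it", {
  d <- simulate_occurrence(sim_config(n_individuals = 30,
                                      events_per_individual = 8, seed = 53))
  fit <- occm(occurred ~ activity, d, B = 0.05)
  lay <- list(y = fit$y, X = fit$X, id = fit$id, T = fit$T)
  ll_hat <- fit$loglik
  for (i in seq_len(20)) {
    set.seed(i)
    beta <- coef(fit) + stats::rnorm(3, 0, 0.15)
    sigma <- max(0, fit$sigma + stats::rnorm(1, 0, 0.15))
    ll <- marg_loglik(beta, sigma, fit$B, lay$y, lay$X, lay$id, lay$T)
    expect_lte(ll, ll_hat + 1e-8)
  }
})

test_that("profiling recovers the generating per-second rate", {
  d <- recovery_data(seed = 54)
  fit <- occm(occurred ~ activity, d)
  expect_false(fit$B_fixed)
  expect_gt(fit$B, 0.02)
  expect_lt(fit$B, 0.10)
  # profile maximum dominates a grid over the search interval
  for (B in plogis(seq(qlogis(0.001), qlogis(0.6), length.out = 15))) {
    # fits at extreme fixed B may legitimately warn about separation
    ll_B <- suppressWarnings(occm(occurred ~ activity, d, B = B)$loglik)
    expect_lte(ll_B, fit$loglik + 1e-5)
  }
  # refitting at the profiled optimum reproduces the estimates
  refit <- occm(occurred ~ activity, d, B = fit$B)
  expect_equal(coef(refit), coef(fit), tolerance = 1e-5)
  expect_equal(refit$sigma, fit$sigma, tolerance = 1e-5)
  expect_equal(refit$loglik, fit$loglik, tolerance = 1e-6)
})

test_that("equal durations leave B unidentified and flagged", {
  d <- simulate_occurrence(sim_config(n_individuals = 25,
                                      events_per_individual = 8, seed = 55))
  d$duration_s <- 30L
  expect_warning(fit <- occm(occurred ~ activity, d), "flat")
  expect_false(fit$B_identifiable)
})

test_that("estimates are invariant to row order and individual relabelling", {
  d <- simulate_occurrence(sim_config(n_individuals = 30,
                                      events_per_individual = 6, seed = 56))
  fit1 <- occm(occurred ~ activity, d, B = 0.05)
  set.seed(1)
  d2 <- d[sample(nrow(d)), ]
  d2$individual_id <- paste0("zz_", d2$individual_id) # bijective relabelling
  fit2 <- occm(occurred ~ activity, d2, B = 0.05)
  expect_equal(coef(fit2), coef(fit1), tolerance = 1e-6)
  expect_equal(fit2$sigma, fit1$sigma, tolerance = 1e-6)
  expect_equal(fit2$loglik, fit1$loglik, tolerance = 1e-8)
})

test_that("likelihood-ratio test for activity behaves as a nested test", {
  d <- recovery_data(seed = 57, n_individuals = 60, events_per_individual = 8)
  fit <- occm(occurred ~ activity, d)
  lrt <- occm_lrt(fit, d)
  expect_identical(lrt$df, 3L - 1L) # two contrasts dropped
  expect_gte(lrt$chi2, 0)
  expect_lt(lrt$p, 0.05) # strong simulated activity effect
  # nesting: full profile maximum dominates the reduced one
  red <- attr(lrt, "reduced")
  expect_gte(fit$loglik, red$loglik - 1e-6)
})

test_that("a single activity level collapses the test to the null", {
  d <- simulate_occurrence(sim_config(
    n_individuals = 20, events_per_individual = 8,
    activity_probs = c(1, 0, 0), seed = 58))
  expect_true(all(d$activity == "drum"))
  fit <- occm(occurred ~ activity, d)
  expect_identical(unname(ncol(fit$X)), 1L)
  lrt <- occm_lrt(fit, d)
  expect_identical(lrt$chi2, 0)
  expect_identical(lrt$p, 1)
})

test_that("fits agree with an independent mixed-model implementation", {
  # same model, same fixed offset, fitted by lme4's adaptive quadrature
  library(lme4)
  d <- simulate_occurrence(sim_config(n_individuals = 40,
                                      events_per_individual = 10, seed = 59))
  B <- 0.05
  fit <- occm(occurred ~ activity, d, B = B)
  d$off <- occ_offset(B, d$duration_s)
  ref <- glmer(occurred ~ activity + (1 | individual_id) + offset(off),
               data = d, family = binomial, nAGQ = 25)
  expect_equal(unname(coef(fit)), unname(fixef(ref)), tolerance = 2e-3)
  expect_equal(unname(fit$sigma), sqrt(unname(unlist(VarCorr(ref)))),
               tolerance = 5e-3)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-4)
  expect_equal(unname(fit$se),
               unname(coef(summary(ref))[, "Std. Error"]), tolerance = 0.02)
})
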