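test_that("invalid simulation configs are rejected with diagnostics", {
  expect_error(sim_config(activity_probs = c(0.5, 0.5, 0.1)), "simplex")
  expect_error(sim_config(true_sigma = -1), "non-negative")
  expect_error(sim_config(true_B = 0), "inside \\(0, 1\\)")
  expect_error(sim_config(true_B = 1), "inside \\(0, 1\\)")
  expect_error(sim_config(duration_probs = rep(1 / 60, 60)), "61")
  expect_error(sim_config(events_per_individual = 0), ">= 1")
})

test_that("simulation is bit-reproducible given the seed and well-formed", {
  cfg <- sim_config(n_individuals = 12, events_per_individual = 7, seed = 42)
  d1 <- simulate_occurrence(cfg)
  d2 <- simulate_occurrence(cfg)
  expect_identical(d1, d2)
  expect_true(all(d1$occurred %in% 0:1))
  expect_true(all(d1$duration_s %in% 1:61))
  expect_true(all(d1$individual_id %in% sprintf("ind_%02d", 1:12)))
  expect_identical(levels(d1$activity), c("drum", "stone_and_drum", "stone"))
  d3 <- simulate_occurrence(sim_config(n_individuals = 12,
                                       events_per_individual = 7, seed = 43))
  expect_false(identical(d1$occurred, d3$occurred))
})

test_that("empirical occurrence matches the generating probability", {
  # sigma = 0, beta = 0, T = 1: p = B exactly
  one_sec <- c(1, rep(0, 60))
  cfg <- sim_config(n_individuals = 100, events_per_individual = 500,
                    true_B = 0.1, true_beta = c(0, 0, 0), true_sigma = 0,
                    duration_probs = one_sec, seed = 5)
  d <- simulate_occurrence(cfg)
  se <- sqrt(0.1 * 0.9 / nrow(d))
  expect_lt(abs(mean(d$occurred) - 0.1), 3 * se)

  # saturation: B ~ 1 gives near-certain occurrence
  cfg2 <- sim_config(n_individuals = 20, events_per_individual = 100,
                     true_B = 0.999, true_beta = c(0, 0, 0), true_sigma = 0,
                     seed = 6)
  expect_gt(mean(simulate_occurrence(cfg2)$occurred), 0.99)

  # law of large numbers at fixed T = 7: rate converges to 1-(1-B)^7
  seven <- rep(0, 61); seven[7] <- 1
  cfg3 <- sim_config(n_individuals = 100, events_per_individual = 500,
                     true_B = 0.05, true_beta = c(0, 0, 0), true_sigma = 0,
                     duration_probs = seven, seed = 7)
  d3 <- simulate_occurrence(cfg3)
  p7 <- occ_prob(0.05, 7)
  expect_lt(abs(mean(d3$occurred) - p7), 3 * sqrt(p7 * (1 - p7) / nrow(d3)))
})

test_that("occurrence rate is non-decreasing in duration", {
  cfg <- sim_config(n_individuals = 100, events_per_individual = 500,
                    true_B = 0.05, true_beta = c(0, 0, 0), true_sigma = 0,
                    seed = 8)
  d <- simulate_occurrence(cfg)
  bins <- cut(d$duration_s, breaks = c(seq(0, 60, by = 10), 62))
  rates <- tapply(d$occurred, bins, mean)
  expect_true(all(diff(rates) > -0.01)) # monotone up to Monte-Carlo noise
  expect_gt(stats::cor(as.integer(bins), d$occurred, method = "spearman"), 0)
})

test_that("per-second hazard generator matches the model at zero predictor", {
  mk <- function(mech, seed) simulate_occurrence(sim_config(
    n_individuals = 50, events_per_individual = 200,
    true_B = 0.05, true_beta = c(0, 0, 0), true_sigma = 0,
    mechanism = mech, seed = seed))
  r_model <- mean(mk("bernoulli", 21)$occurred)
  r_hazard <- mean(mk("per_second", 22)$occurred)
  expect_lt(abs(r_model - r_hazard), 4 * sqrt(0.25 / 10000))
})

test_that("simulating from a fitted model is deterministic and faithful", {
  d <- simulate_occurrence(sim_config(n_individuals = 40,
                                      events_per_individual = 10,
                                      true_beta = c(0.3, 0, 0), seed = 31))
  fit <- occm(occurred ~ activity, d)
  s1 <- simulate(fit, nsim = 3, seed = 9)
  s2 <- simulate(fit, nsim = 3, seed = 9)
  expect_identical(s1, s2)
  expect_true(all(unlist(s1) %in% 0:1))
  # mean simulated rate close to the source data rate
  s <- simulate(fit, nsim = 300, seed = 10)
  rate <- mean(colMeans(as.matrix(s)))
  expect_lt(abs(rate - mean(d$occurred)), 0.05)
})

test_that("simulation from a non-converged fit is refused", {
  d <- simulate_occurrence(sim_config(n_individuals = 10,
                                      events_per_individual = 5, seed = 12))
  d$occurred <- 0L # degenerate: behaviour never occurs
  fit <- suppressWarnings(occm(occurred ~ activity, d, force = TRUE))
  expect_false(fit$converged)
  expect_error(simulate(fit), "non-converged")
})
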