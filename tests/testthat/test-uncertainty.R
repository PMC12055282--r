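test_that("parametric bootstrap is deterministic and accounts for replicates", {
  d <- simulate_occurrence(sim_config(n_individuals = 30,
                                      events_per_individual = 8, seed = 71))
  fit <- occm(occurred ~ activity, d)
  b1 <- occm_boot(fit, n_boot = 40, seed = 3)
  b2 <- occm_boot(fit, n_boot = 40, seed = 3)
  expect_identical(b1$estimates, b2$estimates)
  expect_identical(b1$ci, b2$ci)
  expect_identical(b1$n_failed + nrow(b1$estimates), b1$n_boot)
  b3 <- occm_boot(fit, n_boot = 40, seed = 4)
  expect_false(identical(b1$estimates, b3$estimates))
})

test_that("bootstrap spread matches the analytic standard errors at large n", {
  # no random-effect variance, ample data: percentile spread ~ Wald SE
  cfg <- sim_config(n_individuals = 100, events_per_individual = 100,
                    true_B = 0.05, true_beta = c(0.5, -0.5, 1),
                    true_sigma = 0, seed = 72)
  d <- simulate_occurrence(cfg)
  fit <- occm(occurred ~ activity, d)
  # bootstrap refits hold B at the point estimate, so its spread measures
  # the conditional sampling variance: compare against the fixed-B fit's
  # Wald standard errors
  fit_c <- occm(occurred ~ activity, d, B = fit$B)
  bb <- occm_boot(fit_c, n_boot = 200, seed = 5)
  sd_boot <- apply(bb$estimates, 2, stats::sd)
  expect_true(all(abs(sd_boot / fit_c$se - 1) < 0.2))
})

test_that("bootstrap interval width shrinks like one over root n", {
  widths <- vapply(c(500, 2000, 8000), function(n) {
    d <- simulate_occurrence(sim_config(
      n_individuals = 50, events_per_individual = n / 50,
      true_B = 0.05, true_beta = c(0.5, -0.5, 1), true_sigma = 0.5,
      seed = 73))
    fit <- occm(occurred ~ activity, d)
    bb <- occm_boot(fit, n_boot = 150, seed = 6)
    unname(diff(bb$ci["activitystone", ]))
  }, numeric(1))
  expect_true(all(diff(widths) < 0)) # monotone decreasing
  # successive quadrupling of n should roughly halve the width
  expect_lt(abs(widths[1] / widths[2] - 2), 0.6)
  expect_lt(abs(widths[2] / widths[3] - 2), 0.6)
})

test_that("leave-one-out produces one subset per individual and brackets them", {
  d <- simulate_occurrence(sim_config(n_individuals = 25,
                                      events_per_individual = 8, seed = 74))
  fit <- occm(occurred ~ activity, d)
  loo <- occm_loo(fit)
  expect_identical(nrow(loo$estimates), 25L)
  expect_identical(rownames(loo$estimates), levels(fit$id))
  # the ranges bracket independently recomputed subset estimates
  for (drop_id in levels(fit$id)[c(1, 13, 25)]) {
    sub <- d[d$individual_id != drop_id, ]
    ref <- occm(occurred ~ activity, sub, B = fit$B)
    expect_true(all(coef(ref) >= loo$range[, "min"] - 1e-4))
    expect_true(all(coef(ref) <= loo$range[, "max"] + 1e-4))
  }
})

test_that("stability ranges are narrow for balanced data, wide for an influential individual", {
  d <- simulate_occurrence(sim_config(n_individuals = 40,
                                      events_per_individual = 25,
                                      true_beta = c(0, 0, 0),
                                      true_sigma = 0.3, seed = 75))
  fit <- occm(occurred ~ activity, d)
  loo <- occm_loo(fit)
  expect_lt(max(loo$range[, "max"] - loo$range[, "min"]), 0.5)

  # one individual carries all stone-activity occurrences
  d2 <- simulate_occurrence(sim_config(n_individuals = 12,
                                       events_per_individual = 10,
                                       true_beta = c(-1, 0, 0),
                                       true_sigma = 0.2, seed = 76))
  stone <- d2$activity == "stone"
  d2$occurred[stone] <- 0L
  inf_id <- d2$individual_id == "ind_01"
  d2$occurred[stone & inf_id] <- 1L
  fit2 <- suppressWarnings(occm(occurred ~ activity, d2, B = 0.05))
  loo2 <- suppressWarnings(occm_loo(fit2))
  spread <- loo2$range[, "max"] - loo2$range[, "min"]
  expect_gt(spread["activitystone"], 2)
})

test_that("leave-one-out needs at least three individuals", {
  d <- simulate_occurrence(sim_config(n_individuals = 2,
                                      events_per_individual = 30, seed = 77))
  fit <- occm(occurred ~ activity, d, B = 0.05)
  expect_error(occm_loo(fit), "at least 3")
})

test_that("report tables assemble all components at full precision", {
  d <- simulate_occurrence(sim_config(n_individuals = 20,
                                      events_per_individual = 8, seed = 78))
  fit <- occm(occurred ~ activity, d)
  lrt <- occm_lrt(fit, d)
  boot <- occm_boot(fit, n_boot = 30, seed = 8)
  loo <- occm_loo(fit)
  tab <- occm_table(fit, lrt, boot, loo, behaviour = "pant_hoot",
                    period = "before")
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$term, c("intercept", "Beh. St & Dr", "Beh. St"))
  expect_identical(names(tab), c("behaviour", "period", "term", "Est.", "SE",
                                 "CI_lower", "CI_upper", "chi2", "df", "P",
                                 "min", "max"))
  expect_identical(tab$df[2], 2)
  expect_true(all(is.na(tab$chi2[c(1, 3)])))
  expect_identical(tab$Est., unname(coef(fit))) # full precision retained
  # display rounding equals round(full precision, 3)
  printed <- capture.output(print(tab))
  expect_true(any(grepl(format(round(tab$Est.[1], 3)), printed, fixed = TRUE)))
  # mismatched components are refused
  fit2 <- occm(occurred ~ 1, d)
  boot2 <- occm_boot(fit2, n_boot = 10, seed = 9)
  expect_error(occm_table(fit, boot = boot2), "different model")
})
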