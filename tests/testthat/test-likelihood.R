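test_that("conditional log-likelihood matches hand-computed arithmetic", {
  d <- toy_design()
  # single record, p = 0.5 exactly
  expect_equal(
    cond_loglik(c(0, 0, 0), c(a = 0), B = 0.5,
                y = 1, X = matrix(1, 1, 3), id = "a", T = 1),
    log(0.5), tolerance = 1e-12)

  # 4-record toy set: independent spreadsheet-style sum via dbinom
  beta <- c(0.2, -0.4, 0.9)
  u <- c(a = 0.3, b = -0.6)
  B <- 0.04
  eta <- drop(d$X %*% beta) + u[d$id] + qlogis(1 - (1 - B)^d$T)
  expected <- sum(dbinom(d$y, 1, plogis(eta), log = TRUE))
  got <- cond_loglik(beta, u, B, d$y, d$X, d$id, d$T)
  expect_equal(got, expected, tolerance = 1e-12)
  expect_lt(got, 0) # log-probability of non-empty data

  expect_error(
    cond_loglik(beta, c(a = 0.3), B, d$y, d$X, d$id, d$T),
    "no intercept supplied .*b")
})

test_that("marginal likelihood degenerates exactly at sigma = 0", {
  d <- toy_design()
  beta <- c(0.1, 0.5, -0.3)
  ml <- marg_loglik(beta, 0, 0.06, d$y, d$X, d$id, d$T)
  cl <- cond_loglik(beta, c(a = 0, b = 0), 0.06, d$y, d$X, d$id, d$T)
  expect_identical(ml, cl)
})

test_that("symmetric single-record integral equals log(1/2)", {
  # y = 1, eta = u ~ N(0,1): E[plogis(u)] = 1/2 by symmetry
  ml <- marg_loglik(c(0, 0, 0), 1, 0.5, y = 1, X = matrix(1, 1, 3),
                    id = "a", T = 1)
  expect_equal(ml, log(0.5), tolerance = 1e-9)
})

test_that("quadrature agrees with the dense-grid integration oracle", {
  for (seed in 1:6) {
    inst <- random_small_instance(seed)
    q <- marg_loglik(inst$beta, inst$sigma, inst$B, inst$y, inst$X,
                     inst$id, inst$T)
    b <- brute_force_marg_loglik(inst$beta, inst$sigma, inst$B, inst$y,
                                 inst$X, inst$id, inst$T)
    expect_lt(abs(q - b), 1e-6)
  }
})

test_that("quadrature is converged at the default node count", {
  inst <- random_small_instance(101)
  l20 <- marg_loglik(inst$beta, inst$sigma, inst$B, inst$y, inst$X,
                     inst$id, inst$T, nodes = 20)
  l40 <- marg_loglik(inst$beta, inst$sigma, inst$B, inst$y, inst$X,
                     inst$id, inst$T, nodes = 40)
  expect_lt(abs(l20 - l40), 1e-8)
})

test_that("marginal likelihood is continuous at the sigma boundary", {
  d <- toy_design()
  beta <- c(0.1, 0.5, -0.3)
  l0 <- marg_loglik(beta, 0, 0.06, d$y, d$X, d$id, d$T)
  leps <- marg_loglik(beta, 1e-8, 0.06, d$y, d$X, d$id, d$T)
  expect_lt(abs(l0 - leps), 1e-6)
})

test_that("marginal likelihood is additive over individuals", {
  inst <- random_small_instance(7)
  base <- marg_loglik(inst$beta, inst$sigma, inst$B, inst$y, inst$X,
                      inst$id, inst$T)
  # duplicate the first individual under a new label
  sel <- inst$id == inst$id[1]
  y2 <- c(inst$y, inst$y[sel])
  X2 <- rbind(inst$X, inst$X[sel, , drop = FALSE])
  id2 <- c(inst$id, rep("zz_dup", sum(sel)))
  T2 <- c(inst$T, inst$T[sel])
  aug <- marg_loglik(inst$beta, inst$sigma, inst$B, y2, X2, id2, T2)
  solo <- marg_loglik(inst$beta, inst$sigma, inst$B, inst$y[sel],
                      inst$X[sel, , drop = FALSE], inst$id[sel], inst$T[sel])
  expect_equal(aug - base, solo, tolerance = 1e-10)
})

test_that("Gauss-Hermite rule integrates known moments", {
  gh <- gauss_hermite(20)
  expect_equal(sum(gh$weights), sqrt(pi), tolerance = 1e-12)
  # E[z^2] under N(0, 1/2): integral z^2 e^{-z^2} dz = sqrt(pi)/2
  expect_equal(sum(gh$weights * gh$nodes^2), sqrt(pi) / 2, tolerance = 1e-10)
})
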