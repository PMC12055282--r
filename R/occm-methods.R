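#' @export
print.occm <- function(x, digits = 3, ...) {
  cat("Duration-adjusted binomial mixed model (logit link)\n")
  cat("  formula: ", deparse(x$formula), "\n", sep = "")
  cat("  ", x$n_obs, " events, ", x$n_individuals, " individuals\n", sep = "")
  cat("  per-second baseline B = ", format(x$B, digits = digits),
      if (x$B_fixed) " (fixed)" else " (profiled)",
      if (!x$B_identifiable) " [not identifiable]", "\n", sep = "")
  cat("  random-intercept SD sigma = ", format(x$sigma, digits = digits),
      if (x$boundary_sigma) " (boundary)", "\n", sep = "")
  cat("  log-likelihood: ", format(x$loglik, digits = 8), "\n", sep = "")
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  if (!x$converged) cat("Warning: fit did not converge\n")
  if (x$separation) cat("Warning: possible separation\n")
  invisible(x)
}

#' @export
coef.occm <- function(object, ...) object$coefficients

#' @export
vcov.occm <- function(object, ...) object$vcov

#' @export
logLik.occm <- function(object, ...) {
  df <- length(object$coefficients) +
    (!object$boundary_sigma) + (!object$B_fixed && object$B_identifiable)
  structure(object$loglik, df = df, nobs = object$n_obs, class = "logLik")
}

#' @export
summary.occm <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(fit = object, coefficients = tab), class = "summary.occm")
}

#' @export
print.summary.occm <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("\nWald tests (for orientation; inference uses the LRT and bootstrap):\n")
  stats::printCoefmat(x$coefficients, digits = digits, ...)
  invisible(x)
}

#' Predicted occurrence probabilities
#'
#' @param object a fitted [occm()] model
#' @param newdata optional data frame with the model covariates plus the
#'   duration column used at fit time; defaults to the fitting data
#' @param type `"response"` for probabilities at `u = 0` (population
#'   level), `"link"` for the linear predictor, `"marginal"` for
#'   probabilities averaged over the random-intercept distribution
#' @param duration durations for `newdata` (seconds); defaults to the
#'   stored fitting durations when `newdata` is missing
#' @param ... unused
#' @return numeric vector
#' @export
predict.occm <- function(object, newdata = NULL,
                         type = c("response", "link", "marginal"),
                         duration = NULL, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    X <- object$X
    T <- if (is.null(duration)) object$T else duration
  } else {
    mf <- model.frame(stats::delete.response(terms(object$formula)),
                      newdata, xlev = object$xlevels)
    X <- model.matrix(stats::delete.response(terms(object$formula)), mf)
    T <- if (is.null(duration)) newdata$duration_s else duration
  }
  if (is.null(T)) stop("durations required for prediction", call. = FALSE)
  eta <- drop(X %*% object$coefficients) + occ_offset(object$B, T, object$offset_form)
  switch(type,
         link = eta,
         response = plogis(eta),
         marginal = {
           gh <- gauss_hermite(object$nodes)
           # E[plogis(eta + u)], u ~ N(0, sigma^2), by Gauss-Hermite
           s <- object$sigma
           vapply(eta, function(e)
             sum(gh$weights * plogis(e + sqrt(2) * s * gh$nodes)) / sqrt(pi),
             numeric(1))
         })
}

#' @export
residuals.occm <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  p <- predict(object, type = "marginal")
  r <- object$y - p
  if (type == "pearson") r <- r / sqrt(p * (1 - p))
  r
}

#' @export
fitted.occm <- function(object, ...) predict(object, type = "marginal")

#' Simulate responses from a fitted occurrence model
#'
#' Parametric simulation at the original design points: fresh random
#' intercepts are drawn per individual and responses re-drawn from the
#' fitted Bernoulli probabilities; covariates, durations and individual
#' identities are unchanged. Refused for non-converged fits.
#'
#' @param object a converged [occm()] fit
#' @param nsim number of response vectors
#' @param seed optional integer seed (restores the RNG state afterwards as
#'   [stats::simulate()] does)
#' @param ... unused
#' @return a data frame with `nsim` columns `sim_1 ... sim_<nsim>` of
#'   binary responses, rows aligned with the fitting data
#' @export
simulate.occm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$converged)
    stop("refusing to simulate from a non-converged fit", call. = FALSE)
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      set.seed(NULL)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  eta_fix <- drop(object$X %*% object$coefficients) +
    occ_offset(object$B, object$T, object$offset_form)
  gi <- as.integer(object$id)
  G <- nlevels(object$id)
  out <- vapply(seq_len(nsim), function(b) {
    u <- rnorm(G, 0, object$sigma)
    rbinom(length(eta_fix), 1, plogis(eta_fix + u[gi]))
  }, integer(length(eta_fix)))
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Likelihood-ratio test between nested occurrence models
#'
#' `anova()` on two `occm` fits computes `chi^2 = 2 (logLik_full -
#' logLik_reduced)` with degrees of freedom equal to the difference in the
#' number of fixed-effect columns; tiny negative statistics (within 1e-6)
#' are clipped to zero, larger violations of nesting raise a warning.
#'
#' @param object,... two fitted `occm` models on the same data (the model
#'   with more fixed-effect columns is treated as the full model)
#' @return a data frame with `chi2`, `df` and `p`
#' @export
anova.occm <- function(object, ...) {
  others <- Filter(function(o) inherits(o, "occm"), list(...))
  if (length(others) != 1)
    stop("supply exactly two occm fits", call. = FALSE)
  m2 <- others[[1]]
  if (object$n_obs != m2$n_obs)
    stop("models were fitted to different numbers of observations", call. = FALSE)
  if (!object$converged || !m2$converged)
    stop("likelihood-ratio test refused: at least one fit did not converge",
         call. = FALSE)
  full <- if (ncol(object$X) >= ncol(m2$X)) object else m2
  red <- if (ncol(object$X) >= ncol(m2$X)) m2 else object
  df <- ncol(full$X) - ncol(red$X)
  chi2 <- 2 * (full$loglik - red$loglik)
  if (chi2 < 0) {
    if (chi2 > -1e-6) chi2 <- 0
    else warning("full model has lower log-likelihood than the reduced model (",
                 format(chi2), "); models may not be nested or a fit failed",
                 call. = FALSE)
  }
  p <- if (df == 0) 1 else pchisq(max(chi2, 0), df, lower.tail = FALSE)
  structure(data.frame(chi2 = max(chi2, 0), df = df, p = p),
            class = c("occm_lrt", "data.frame"))
}

#' Likelihood-ratio test for the activity-type effect
#'
#' Refits the model with the activity term (all non-intercept fixed
#' effects) dropped and compares full and reduced fits by a likelihood
#' ratio test. By default `B` is re-profiled in the reduced model so both
#' log-likelihoods are true profile maxima; `reprofile_B = FALSE` keeps
#' `B` at the full-model estimate in the reduced fit.
#'
#' When the data contain a single activity level the full design collapses
#' to the reduced one; the test then returns `chi2 = 0`, `df = 0`, `p = 1`.
#'
#' @param object a converged [occm()] fit
#' @param data the data frame the model was fitted to
#' @param reprofile_B re-estimate `B` in the reduced model (default `TRUE`)
#' @param ... passed on to [occm()] for the reduced fit
#' @return a one-row data frame with `chi2`, `df`, `p`
#' @export
occm_lrt <- function(object, data, reprofile_B = TRUE, ...) {
  stopifnot(inherits(object, "occm"))
  if (!object$converged)
    stop("likelihood-ratio test refused: fit did not converge", call. = FALSE)
  if (ncol(object$X) == 1L) # intercept-only full model (e.g. one activity level)
    return(structure(data.frame(chi2 = 0, df = 0L, p = 1),
                     class = c("occm_lrt", "data.frame")))
  red_formula <- update(object$formula, . ~ 1)
  id_v <- as.character(object$id)
  red <- occm(red_formula, data, id = id_v, duration = object$T,
              B = if (reprofile_B) NULL else object$B,
              offset_form = object$offset_form, nodes = object$nodes,
              control = object$control, ...)
  out <- anova(object, red)
  attr(out, "reduced") <- red
  out
}

#' Plot per-individual occurrence rates against the fitted model
#'
#' Dot plot of empirical per-individual occurrence proportions by activity
#' type (dot area proportional to the number of events) with the fitted
#' population-level probability at the median duration overlaid as a
#' horizontal segment.
#'
#' @param x a fitted [occm()] model
#' @param ... passed to [graphics::plot()]
#' @return `x`, invisibly
#' @export
plot.occm <- function(x, ...) {
  act <- x$X[, 2, drop = TRUE] # recover activity from the contrasts
  grp <- factor(ifelse(rowSums(x$X[, -1, drop = FALSE]) == 0, "drum",
                       ifelse(ncol(x$X) > 2 & x$X[, ncol(x$X)] == 1, "stone",
                              "stone_and_drum")),
                levels = .ACTIVITIES)
  emp <- aggregate(list(p = x$y), list(id = x$id, activity = grp), mean)
  nev <- aggregate(list(n = x$y), list(id = x$id, activity = grp), length)
  emp$n <- nev$n
  xs <- as.integer(emp$activity) + runif(nrow(emp), -0.12, 0.12)
  graphics::plot(xs, emp$p, cex = 0.6 * sqrt(emp$n), pch = 16,
                 col = grDevices::adjustcolor("grey30", 0.5),
                 xlim = c(0.5, 3.5), ylim = c(0, 1), xaxt = "n",
                 xlab = "activity type", ylab = "occurrence probability", ...)
  graphics::axis(1, at = 1:3, labels = .ACTIVITIES)
  Tmed <- stats::median(x$T)
  newX <- rbind(c(1, 0, 0), c(1, 1, 0), c(1, 0, 1))[, seq_len(ncol(x$X)), drop = FALSE]
  eta <- drop(newX %*% x$coefficients) + occ_offset(x$B, Tmed, x$offset_form)
  graphics::segments(1:3 - 0.2, plogis(eta), 1:3 + 0.2, plogis(eta),
                     lwd = 2, col = "firebrick")
  invisible(x)
}
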