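#' Parametric bootstrap for an occurrence model
#'
#' For each replicate, responses are re-drawn from the fitted model at the
#' original design points (fresh random intercepts per individual) and
#' `(beta, sigma)` re-estimated with the per-second rate `B` held at the
#' point estimate; 95% limits are the 2.5 and 97.5 percentiles of the
#' replicate estimates. Replicates whose refit fails are dropped and
#' counted, never imputed; more than 10% failures flags the result as
#' unreliable. `refit_B = TRUE` re-profiles `B` in every replicate
#' instead (markedly slower).
#'
#' @param object a converged [occm()] fit
#' @param n_boot number of bootstrap replicates
#' @param seed integer seed for the replicate stream
#' @param refit_B re-profile `B` per replicate (default `FALSE`)
#' @param level confidence level for the percentile interval
#' @return an object of class `occm_boot`: replicate coefficient matrix
#'   `estimates` (and `sigma`), `ci` matrix, counts `n_boot` / `n_failed`,
#'   `seed`, and flag `reliable`
#' @export
occm_boot <- function(object, n_boot = 1000, seed = 1, refit_B = FALSE,
                      level = 0.95) {
  stopifnot(inherits(object, "occm"), n_boot >= 1)
  if (!object$converged)
    stop("bootstrap refused: fit did not converge", call. = FALSE)
  sims <- simulate(object, nsim = n_boot, seed = seed)
  p <- length(object$coefficients)
  est <- matrix(NA_real_, n_boot, p,
                dimnames = list(NULL, names(object$coefficients)))
  sig <- numeric(n_boot)
  ok <- logical(n_boot)
  for (b in seq_len(n_boot)) {
    f <- tryCatch({
      if (refit_B) .occm_boot_profile(object, sims[[b]])
      else .occm_refit(object, y = sims[[b]])
    }, error = function(e) NULL)
    if (!is.null(f) && f$converged && all(is.finite(f$beta))) {
      est[b, ] <- f$beta
      sig[b] <- f$sigma
      ok[b] <- TRUE
    }
  }
  n_failed <- sum(!ok)
  if (n_failed > 0.1 * n_boot)
    warning("more than 10% of bootstrap refits failed; intervals flagged unreliable",
            call. = FALSE)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- t(apply(est[ok, , drop = FALSE], 2, quantile, probs = probs,
                names = FALSE))
  colnames(ci) <- c("CI_lower", "CI_upper")
  structure(list(estimates = est[ok, , drop = FALSE], sigma = sig[ok],
                 ci = ci, n_boot = as.integer(n_boot), n_failed = n_failed,
                 seed = as.integer(seed), level = level,
                 reliable = n_failed <= 0.1 * n_boot),
            class = "occm_boot")
}

# internal: full refit with B re-profiled, for occm_boot(refit_B = TRUE)
.occm_boot_profile <- function(object, ynew) {
  gh <- gauss_hermite(object$nodes)
  fit_at <- local({
    warm <- NULL
    function(Bval) {
      off <- occ_offset(Bval, object$T, object$offset_form)
      f <- .occm_inner(as.integer(ynew), object$X, object$lay,
                       off, gh, object$control, start = warm)
      warm <<- f$par
      f
    }
  })
  lb <- qlogis(c(max(object$B / 5, 1e-5), min(object$B * 5, 0.99)))
  opt <- optimize(function(l) fit_at(plogis(l))$loglik,
                  interval = lb, maximum = TRUE,
                  tol = object$control$profile_tol)
  f <- fit_at(plogis(opt$maximum))
  f$B <- plogis(opt$maximum)
  f
}

#' @export
print.occm_boot <- function(x, digits = 3, ...) {
  cat("Parametric bootstrap: ", x$n_boot, " replicates (",
      x$n_failed, " failed)\n", sep = "")
  if (!x$reliable) cat("WARNING: flagged unreliable (> 10% failed refits)\n")
  print(round(x$ci, digits))
  invisible(x)
}

#' Leave-one-individual-out stability ranges
#'
#' Refits the model once per individual on the data without that
#' individual, holding `B` constant at the full-data estimate, and reports
#' the componentwise minimum and maximum of the fixed-effect estimates
#' across subsets — the conventional min/max stability range. Failed
#' subset refits are excluded and counted.
#'
#' @param object a converged [occm()] fit on data from at least 3
#'   individuals
#' @return an object of class `occm_loo`: `range` matrix (rows = terms,
#'   columns `min`/`max`), the per-subset `estimates` matrix (one row per
#'   individual dropped), and `n_failed`
#' @export
occm_loo <- function(object) {
  stopifnot(inherits(object, "occm"))
  if (!object$converged)
    stop("stability assessment refused: fit did not converge", call. = FALSE)
  G <- object$n_individuals
  if (G < 3) stop("need at least 3 individuals", call. = FALSE)
  p <- length(object$coefficients)
  est <- matrix(NA_real_, G, p,
                dimnames = list(levels(object$id), names(object$coefficients)))
  for (g in seq_len(G)) {
    keep <- as.integer(object$id) != g
    f <- tryCatch(.occm_refit(object, keep = keep), error = function(e) NULL)
    if (!is.null(f) && all(is.finite(f$beta))) est[g, ] <- f$beta
  }
  ok <- complete.cases(est)
  if (!any(ok)) stop("all leave-one-out refits failed", call. = FALSE)
  rng <- cbind(min = apply(est[ok, , drop = FALSE], 2, min),
               max = apply(est[ok, , drop = FALSE], 2, max))
  structure(list(range = rng, estimates = est, n_failed = sum(!ok)),
            class = "occm_loo")
}

#' @export
print.occm_loo <- function(x, digits = 3, ...) {
  cat("Leave-one-individual-out stability (", nrow(x$estimates),
      " subsets, ", x$n_failed, " failed)\n", sep = "")
  print(round(x$range, digits))
  invisible(x)
}

# display names matching the conventional report layout
.TERM_LABELS <- c("(Intercept)" = "intercept",
                  "activitystone_and_drum" = "Beh. St & Dr",
                  "activitystone" = "Beh. St")

#' Assemble a report table for one fitted model
#'
#' Combines point estimates, standard errors, bootstrap confidence limits,
#' the activity likelihood-ratio test, and leave-one-out stability ranges
#' into one table per model: one row per fixed-effect term with columns
#' `Est.`, `SE`, `CI_lower`, `CI_upper`, `chi2`, `df`, `P`, `min`, `max`
#' (the test statistics are printed on the first contrast row, as in the
#' conventional layout). Full precision is retained; the print method
#' rounds to 3 decimals.
#'
#' @param object a fitted [occm()] model
#' @param lrt result of [occm_lrt()] / [anova.occm()] (optional)
#' @param boot result of [occm_boot()] on the same fit (optional)
#' @param loo result of [occm_loo()] on the same fit (optional)
#' @param behaviour,period labels recorded with the block
#' @return a data frame of class `occm_table`
#' @export
occm_table <- function(object, lrt = NULL, boot = NULL, loo = NULL,
                       behaviour = NA_character_, period = NA_character_) {
  stopifnot(inherits(object, "occm"))
  terms_ <- names(object$coefficients)
  p <- length(terms_)
  if (!is.null(boot) && !identical(colnames(boot$estimates), terms_))
    stop("bootstrap was computed for a different model specification",
         call. = FALSE)
  if (!is.null(loo) && !identical(colnames(loo$estimates), terms_))
    stop("stability ranges were computed for a different model specification",
         call. = FALSE)
  lab <- ifelse(terms_ %in% names(.TERM_LABELS), .TERM_LABELS[terms_], terms_)
  out <- data.frame(behaviour = behaviour, period = period, term = unname(lab),
                    Est. = unname(object$coefficients),
                    SE = unname(object$se),
                    CI_lower = if (is.null(boot)) NA_real_ else boot$ci[, 1],
                    CI_upper = if (is.null(boot)) NA_real_ else boot$ci[, 2],
                    chi2 = NA_real_, df = NA_real_, P = NA_real_,
                    min = if (is.null(loo)) NA_real_ else loo$range[, 1],
                    max = if (is.null(loo)) NA_real_ else loo$range[, 2],
                    stringsAsFactors = FALSE)
  if (!is.null(lrt)) {
    i <- min(2, p) # statistics shown on the first contrast row
    out$chi2[i] <- lrt$chi2
    out$df[i] <- lrt$df
    out$P[i] <- lrt$p
  }
  rownames(out) <- NULL
  class(out) <- c("occm_table", "data.frame")
  out
}

#' @export
print.occm_table <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}
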