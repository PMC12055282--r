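#' Control parameters for occurrence-model fitting
#'
#' @param rel_tol relative log-likelihood convergence tolerance of the inner
#'   quasi-Newton optimizer
#' @param grad_tol gradient-norm tolerance used when judging whether a
#'   near-stationary point reported conservatively by the optimizer counts
#'   as converged
#' @param sigma_min,sigma_max bounds for the random-intercept SD on the
#'   internal log scale (an explicit boundary fit at `sigma = 0` is always
#'   performed in addition)
#' @param sigma_starts starting values for the random-intercept SD
#' @param n_grid number of coarse profile-grid points for the baseline rate
#'   `B` (logit-spaced; at least 9)
#' @param profile_tol convergence tolerance of the 1-D profile optimizer on
#'   the logit(B) scale
#' @param max_iter maximum inner optimizer iterations
#' @param separation_threshold absolute coefficient size beyond which a fit
#'   is flagged as (quasi-)separated
#' @return a named list of class `occm_control`
#' @export
occm_control <- function(rel_tol = 1e-10, grad_tol = 1e-5,
                         sigma_min = 1e-6, sigma_max = 30,
                         sigma_starts = c(0.1, 1),
                         n_grid = 9, profile_tol = 1e-5,
                         max_iter = 500, separation_threshold = 15) {
  stopifnot(n_grid >= 9, sigma_min > 0, all(sigma_starts > 0))
  structure(list(rel_tol = rel_tol, grad_tol = grad_tol,
                 sigma_min = sigma_min, sigma_max = sigma_max,
                 sigma_starts = sigma_starts,
                 n_grid = n_grid, profile_tol = profile_tol,
                 max_iter = max_iter,
                 separation_threshold = separation_threshold),
            class = "occm_control")
}

# internal: model preparation shared by occm() and refitting helpers.
# Returns response, design, grouping layout, durations, and bookkeeping.
.occm_prepare <- function(formula, data, id, duration) {
  if (!length(id)) stop("'id' column not found or empty", call. = FALSE)
  if (!length(duration)) stop("'duration' column not found or empty", call. = FALSE)
  mf <- model.frame(formula, data = data, na.action = stats::na.fail)
  y <- model.response(mf)
  if (is.logical(y)) y <- as.integer(y)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (!all(y %in% c(0, 1)))
    stop("response must be binary (0/1)", call. = FALSE)
  # drop single-level factor terms: they carry no contrast
  dropped <- character(0)
  vars <- attr(terms(mf), "term.labels")
  for (v in vars) {
    if (v %in% names(mf) && is.factor(mf[[v]])) {
      mf[[v]] <- droplevels(mf[[v]])
      if (nlevels(mf[[v]]) < 2) dropped <- c(dropped, v)
    }
  }
  form2 <- formula
  if (length(dropped)) {
    form2 <- update(formula,
                    as.formula(paste(". ~ . -", paste(dropped, collapse = " - "))))
    mf <- model.frame(form2, data = data, na.action = stats::na.fail)
  }
  X <- model.matrix(form2, mf)
  id <- droplevels(as.factor(id))
  Tdur <- as.numeric(duration)
  if (any(!is.finite(Tdur)) || any(Tdur < 1))
    stop("durations must be finite and >= 1 second", call. = FALSE)
  if (length(id) != length(y) || length(Tdur) != length(y))
    stop("'id' and 'duration' must match the model rows in length", call. = FALSE)
  lay <- .group_layout(id)
  list(y = as.integer(y), X = X, id = id, T = Tdur, lay = lay,
       formula = form2, dropped_terms = dropped,
       xlevels = stats::.getXlevels(terms(mf), mf))
}

# internal: maximize the marginal log-likelihood over (beta, log sigma) at a
# fixed offset vector. Quasi-Newton (nlminb with the analytic
# posterior-score gradient) from multiple starts plus an explicit sigma = 0
# boundary fit; ties broken towards the smaller sigma. With a warm `start`
# the multi-start battery is skipped and the boundary fit only run when the
# interior optimum lands near sigma = 0.
.occm_inner <- function(y, X, lay, off, gh, control, start = NULL,
                        full = is.null(start), hessian = FALSE) {
  p <- ncol(X)
  ord <- lay$order
  Xo <- X[ord, , drop = FALSE]
  yo <- y[ord]
  offo <- off[ord]

  # value and gradient share one kernel evaluation per parameter point
  cache_par <- NULL
  cache <- NULL
  eval_at <- function(par) {
    if (is.null(cache_par) || !identical(par, cache_par)) {
      cache <<- .agq_loglik_grad_cpp(Xo, offo, par[seq_len(p)], par[p + 1L],
                                     yo, lay$gstart, gh$nodes, gh$weights,
                                     FALSE)
      cache_par <<- par
    }
    cache
  }
  negll <- function(par) {
    v <- eval_at(par)$value
    if (!is.finite(v)) return(1e10)
    -v
  }
  negll_gr <- function(par) -eval_at(par)$gradient
  negll0 <- function(beta)
    -.agq_loglik_grad_cpp(Xo, offo, beta, 0, yo, lay$gstart,
                          gh$nodes, gh$weights, TRUE)$value
  negll0_gr <- function(beta)
    -.agq_loglik_grad_cpp(Xo, offo, beta, 0, yo, lay$gstart,
                          gh$nodes, gh$weights, TRUE)$gradient[seq_len(p)]

  ctl <- list(rel.tol = control$rel_tol, iter.max = control$max_iter,
              eval.max = 4L * control$max_iter)
  lower <- c(rep(-Inf, p), log(control$sigma_min))
  upper <- c(rep(Inf, p), log(control$sigma_max))
  warm <- !is.null(start)

  starts <- list()
  if (warm) starts <- list(pmin(pmax(start, lower), upper))
  if (full || !warm) {
    beta0 <- tryCatch({
      b <- suppressWarnings(
        glm.fit(X, y, family = binomial(), offset = off)$coefficients)
      b[!is.finite(b)] <- 0
      pmin(pmax(b, -10), 10)
    }, error = function(e) numeric(p))
    starts <- c(starts,
                lapply(control$sigma_starts, function(s) c(beta0, log(s))))
  } else {
    beta0 <- start[seq_len(p)]
  }

  run_starts <- function(ss) {
    f <- lapply(ss, function(s0) {
      tryCatch(nlminb(s0, negll, gradient = negll_gr,
                      lower = lower, upper = upper, control = ctl),
               error = function(e) NULL)
    })
    Filter(function(x) !is.null(x) && is.finite(x$objective), f)
  }
  fits <- run_starts(starts)
  # a lean warm fit that drifts to the sigma ceiling is suspect: redo with
  # the full multi-start battery
  if (warm && !full && length(fits) &&
      any(vapply(fits, function(f) f$par[p + 1L] >= upper[p + 1L] - 1e-8,
                 logical(1)))) {
    beta0 <- tryCatch({
      b <- suppressWarnings(
        glm.fit(X, y, family = binomial(), offset = off)$coefficients)
      b[!is.finite(b)] <- 0
      pmin(pmax(b, -10), 10)
    }, error = function(e) numeric(p))
    fits <- c(fits, run_starts(lapply(control$sigma_starts,
                                      function(s) c(beta0, log(s)))))
  }

  lls <- vapply(fits, function(f) -f$objective, numeric(1))
  sds <- vapply(fits, function(f) exp(f$par[p + 1L]), numeric(1))
  # best interior fit; ties (within 1e-8) resolved towards the smaller sigma
  best <- NULL
  if (length(fits)) {
    cand <- which(lls >= max(lls) - 1e-8)
    best <- fits[[cand[which.min(sds[cand])]]]
  }
  ll_int <- if (is.null(best)) -Inf else -best$objective

  # sigma = 0 boundary fit: always for cold starts, for warm starts only
  # when the interior optimum approaches the boundary
  bfit <- NULL
  if (full || is.null(best) || exp(best$par[p + 1L]) < 0.05) {
    b0 <- if (!is.null(best)) best$par[seq_len(p)] else beta0
    bfit <- tryCatch(nlminb(b0, negll0, gradient = negll0_gr, control = ctl),
                     error = function(e) NULL)
  }
  ll_bnd <- if (is.null(bfit)) -Inf else -bfit$objective
  if (is.null(best) && is.null(bfit))
    stop("all optimizer starts failed", call. = FALSE)

  boundary <- FALSE
  if (ll_bnd >= ll_int - 1e-6) {
    boundary <- TRUE
    beta <- bfit$par
    sigma <- 0
    loglik <- ll_bnd
    conv <- bfit$convergence == 0
    par <- c(beta, log(control$sigma_min))
  } else {
    beta <- best$par[seq_len(p)]
    sigma <- unname(exp(best$par[p + 1L]))
    if (sigma <= 2 * control$sigma_min) { sigma <- 0; boundary <- TRUE }
    loglik <- ll_int
    conv <- best$convergence == 0
    par <- best$par
  }
  names(beta) <- colnames(X)

  # accept near-stationary points that nlminb labels false/singular
  # convergence: the analytic gradient gives an honest residual norm,
  # judged relative to the log-likelihood scale
  if (!conv) {
    g <- if (boundary) negll0_gr(beta) else negll_gr(par)
    conv <- sqrt(sum(g^2)) < 100 * control$grad_tol * max(1, abs(loglik))
  }

  out <- list(beta = beta, sigma = sigma, loglik = loglik,
              converged = conv, boundary_sigma = boundary, par = par)
  if (hessian) {
    V <- se <- NULL
    H <- tryCatch({
      if (boundary) optimHess(beta, negll0) else optimHess(par, negll)
    }, error = function(e) NULL)
    if (!is.null(H)) {
      Vfull <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(Vfull) && all(diag(Vfull)[seq_len(p)] > 0)) {
        V <- Vfull[seq_len(p), seq_len(p), drop = FALSE]
        dimnames(V) <- list(colnames(X), colnames(X))
        se <- sqrt(diag(V))
      }
    }
    out$vcov <- V
    out$se <- if (is.null(se)) setNames(rep(NA_real_, p), colnames(X)) else se
  }
  out
}

#' Fit a duration-adjusted binomial mixed model
#'
#' Fits a logistic mixed model for whether a behaviour occurred at least
#' once in an observation window, with individual random intercepts and a
#' duration offset `log(O/(1-O))`, `O = 1 - (1-B)^T`. The fixed effects
#' `beta` and random-intercept SD `sigma` are estimated by maximizing the
#' marginal likelihood (adaptive Gauss-Hermite quadrature); the per-second
#' baseline rate `B` is either held fixed (when supplied) or estimated by
#' maximizing the profile likelihood `L*(B)` with a coarse logit-spaced
#' grid refined by golden-section/parabolic search.
#'
#' Degenerate situations are flagged rather than silently repaired:
#' all-zero or all-one responses give `converged = FALSE` (unless
#' `force = TRUE`), coefficients beyond the separation threshold set the
#' `separation` flag, a single individual (or an estimated `sigma` on the
#' boundary) sets `boundary_sigma`, and a profile of `B` that is flat
#' because all durations are equal sets `B_identifiable = FALSE`.
#'
#' @param formula model formula, e.g. `occurred ~ activity`; the response
#'   must be binary
#' @param data data frame containing the model variables
#' @param id individual identifier column, unquoted (default
#'   `individual_id`) or a vector
#' @param duration observation duration column in seconds, unquoted
#'   (default `duration_s`) or a vector
#' @param B per-second baseline probability; `NULL` (default) profiles it,
#'   a number in (0, 1) holds it fixed
#' @param B_bounds search interval for the profile of `B`
#' @param offset_form `"prob_any"` for the at-least-one-event offset
#'   (default) or `"literal"` for the power form `B^T`
#' @param nodes number of adaptive Gauss-Hermite quadrature nodes
#' @param control an [occm_control()] list
#' @param force fit even with degenerate (constant) responses
#' @return an object of class `occm` with components `coefficients`, `se`,
#'   `sigma`, `B`, `logLik`, convergence/boundary flags, the profile trace
#'   (`profile`), and the model data needed for refitting
#' @seealso [occm_lrt()], [occm_boot()], [occm_loo()], [occm_table()]
#' @examples
#' cfg <- sim_config(n_individuals = 20, events_per_individual = 8, seed = 1)
#' d <- simulate_occurrence(cfg)
#' fit <- occm(occurred ~ activity, d)
#' summary(fit)
#' @export
occm <- function(formula, data, id = individual_id, duration = duration_s,
                 B = NULL, B_bounds = c(1e-4, 0.99),
                 offset_form = c("prob_any", "literal"),
                 nodes = 20, control = occm_control(), force = FALSE) {
  offset_form <- match.arg(offset_form)
  cl <- match.call()
  id_v <- eval(substitute(id), data, parent.frame())
  dur_v <- eval(substitute(duration), data, parent.frame())
  if (is.character(id_v) && length(id_v) == 1 && !is.null(data) &&
      id_v %in% names(data)) id_v <- data[[id_v]]
  if (is.character(dur_v) && length(dur_v) == 1 && !is.null(data) &&
      dur_v %in% names(data)) dur_v <- data[[dur_v]]
  prep <- .occm_prepare(formula, data, id_v, dur_v)

  degenerate <- length(unique(prep$y)) < 2
  if (degenerate && !force)
    warning("all responses identical: estimates lie on the boundary; fit flagged non-converged",
            call. = FALSE)
  single_group <- nlevels(prep$id) < 2
  if (single_group)
    warning("only one individual: random-intercept SD not identifiable (boundary fit)",
            call. = FALSE)

  gh <- gauss_hermite(nodes)
  flat_T <- length(unique(prep$T)) < 2

  # profile evaluations chain warm starts along B; the best parameter
  # vector seen is remembered so refinement and the final (multi-start)
  # fit never inherit a stale optimum from a distant B
  prof_env <- new.env(parent = emptyenv())
  prof_env$warm <- NULL
  prof_env$best_ll <- -Inf
  prof_env$best_par <- NULL
  fit_at <- function(Bval, hessian = FALSE, full = FALSE) {
    off <- occ_offset(Bval, prep$T, offset_form)
    f <- .occm_inner(prep$y, prep$X, prep$lay, off, gh, control,
                     start = prof_env$warm, full = full || is.null(prof_env$warm),
                     hessian = hessian)
    prof_env$warm <- f$par
    if (f$loglik > prof_env$best_ll) {
      prof_env$best_ll <- f$loglik
      prof_env$best_par <- f$par
    }
    f
  }

  profile_df <- NULL
  B_identifiable <- TRUE
  if (!is.null(B)) {
    stopifnot(is.numeric(B), length(B) == 1, B > 0, B < 1)
    B_hat <- B
    B_fixed <- TRUE
  } else {
    B_fixed <- FALSE
    stopifnot(length(B_bounds) == 2, B_bounds[1] > 0, B_bounds[2] < 1,
              B_bounds[1] < B_bounds[2])
    lb <- seq(qlogis(B_bounds[1]), qlogis(B_bounds[2]),
              length.out = control$n_grid)
    if (flat_T) {
      # constant durations make the offset a constant absorbed by the
      # intercept: the profile of B is exactly flat
      B_identifiable <- FALSE
      B_hat <- plogis(mean(range(lb)))
      warning("profile likelihood of B is flat (all durations equal: offset constant, absorbed by the intercept); B is not identifiable and was fixed at the interval midpoint",
              call. = FALSE)
    } else {
    grid_ll <- vapply(lb, function(l) fit_at(plogis(l))$loglik, numeric(1))
    profile_df <- data.frame(B = plogis(lb), loglik = grid_ll)
    if (max(grid_ll) - min(grid_ll) < 1e-4) {
      B_identifiable <- FALSE
      B_hat <- plogis(mean(range(lb)))
      warning("profile likelihood of B is flat; B is not identifiable and was fixed at the interval midpoint",
              call. = FALSE)
    } else {
      k <- which.max(grid_ll)
      lo <- lb[max(1, k - 1)]
      hi <- lb[min(length(lb), k + 1)]
      prof_env$warm <- prof_env$best_par # re-anchor at the grid optimum
      opt <- optimize(function(l) fit_at(plogis(l))$loglik,
                      interval = c(lo, hi), maximum = TRUE,
                      tol = control$profile_tol)
      B_hat <- if (opt$objective >= grid_ll[k]) plogis(opt$maximum) else plogis(lb[k])
      edge <- min(B_hat - B_bounds[1], B_bounds[2] - B_hat)
      if (edge < 1e-4 * diff(B_bounds))
        warning("profile maximum of B lies on the search boundary; B may be confounded with the intercept",
                call. = FALSE)
    }
    }
  }

  prof_env$warm <- prof_env$best_par
  final <- fit_at(B_hat, hessian = TRUE, full = TRUE)

  # when B was estimated, standard errors come from the observed
  # information of the joint likelihood in (beta, log sigma, logit B), so
  # the uncertainty in B (which trades off against the intercept) is
  # propagated; with B fixed the conditional information is kept
  if (!B_fixed && B_identifiable) {
    p <- ncol(prep$X)
    gh_loc <- gh
    ordX <- prep$X[prep$lay$order, , drop = FALSE]
    ordy <- prep$y[prep$lay$order]
    ordT <- prep$T[prep$lay$order]
    joint_neg <- function(par) {
      off <- occ_offset(plogis(par[length(par)]), ordT, offset_form)
      sz <- final$boundary_sigma
      ls <- if (sz) 0 else par[p + 1L]
      -.agq_loglik_grad_cpp(ordX, off, par[seq_len(p)], ls, ordy,
                            prep$lay$gstart, gh_loc$nodes, gh_loc$weights,
                            sz)$value
    }
    par_j <- if (final$boundary_sigma) c(final$beta, qlogis(B_hat))
    else c(final$beta, log(final$sigma), qlogis(B_hat))
    Hj <- tryCatch(optimHess(par_j, joint_neg), error = function(e) NULL)
    if (!is.null(Hj)) {
      Vj <- tryCatch(solve(Hj), error = function(e) NULL)
      if (!is.null(Vj) && all(diag(Vj)[seq_len(p)] > 0)) {
        final$vcov <- Vj[seq_len(p), seq_len(p), drop = FALSE]
        dimnames(final$vcov) <- list(colnames(prep$X), colnames(prep$X))
        final$se <- sqrt(diag(final$vcov))
        final$se_B <- {
          vB <- diag(Vj)[length(par_j)]
          if (vB > 0) sqrt(vB) * B_hat * (1 - B_hat) else NA_real_
        }
      }
    }
  }
  separation <- any(abs(final$beta) > control$separation_threshold)
  if (separation)
    warning("extreme coefficient(s): possible complete separation", call. = FALSE)

  structure(list(
    coefficients = final$beta,
    se = final$se,
    vcov = final$vcov,
    sigma = final$sigma,
    B = B_hat,
    B_fixed = B_fixed,
    B_identifiable = B_identifiable,
    loglik = final$loglik,
    converged = final$converged && !degenerate,
    boundary_sigma = final$boundary_sigma || single_group,
    separation = separation,
    degenerate_response = degenerate,
    profile = profile_df,
    n_obs = length(prep$y),
    n_individuals = nlevels(prep$id),
    nodes = nodes,
    offset_form = offset_form,
    control = control,
    formula = prep$formula,
    dropped_terms = prep$dropped_terms,
    xlevels = prep$xlevels,
    y = prep$y, X = prep$X, id = prep$id, T = prep$T, lay = prep$lay,
    call = cl), class = "occm")
}

# internal: refit (beta, sigma) of an existing model on possibly new
# responses / subset of rows, holding B fixed. Used by bootstrap, stability
# and the LRT plumbing.
.occm_refit <- function(object, y = object$y, keep = NULL, X = object$X,
                        B = object$B, warm = TRUE, hessian = FALSE) {
  id <- object$id
  T <- object$T
  if (!is.null(keep)) {
    y <- y[keep]; X <- X[keep, , drop = FALSE]
    id <- droplevels(id[keep]); T <- T[keep]
  }
  lay <- .group_layout(id)
  off <- occ_offset(B, T, object$offset_form)
  gh <- gauss_hermite(object$nodes)
  start <- if (warm && ncol(X) == ncol(object$X))
    c(object$coefficients, log(max(object$sigma, object$control$sigma_min)))
  else NULL
  .occm_inner(as.integer(y), X, lay, off, gh, object$control,
              start = start, hessian = hessian)
}
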