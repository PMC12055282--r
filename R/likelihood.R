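#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for the weight function `exp(-z^2)` computed by the
#' Golub-Welsch eigenvalue method on the Jacobi matrix of the Hermite
#' recurrence.
#'
#' @param n number of nodes (`>= 1`)
#' @return list with numeric vectors `nodes` and `weights`
#' @keywords internal
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# internal: sort a model's records by individual and build the 0-based group
# start index vector the C++ kernel expects
.group_layout <- function(id) {
  id <- as.factor(id)
  ord <- order(as.integer(id))
  counts <- tabulate(as.integer(id)[ord], nbins = nlevels(id))
  if (any(counts == 0)) { # drop unused levels
    id <- droplevels(id)
    counts <- tabulate(as.integer(id)[ord], nbins = nlevels(id))
  }
  list(order = ord, id = id,
       gstart = as.integer(c(0, cumsum(counts))),
       gidx = as.integer(id) - 1L)
}

#' Conditional log-likelihood given individual intercepts
#'
#' Sum over records of the Bernoulli log-density with
#' `p = plogis(x'beta + u[individual] + occ_offset(B, T))`.
#'
#' @param beta fixed-effect coefficients (matching columns of `X`)
#' @param u named numeric vector of per-individual intercepts; names must
#'   cover every individual in `id`
#' @param B per-second baseline probability in (0, 1)
#' @param y binary response vector
#' @param X fixed-effect design matrix
#' @param id individual identifiers (factor or character)
#' @param T durations in seconds (`>= 1`)
#' @param form offset form passed to [occ_offset()]
#' @return the conditional log-likelihood (scalar)
#' @export
cond_loglik <- function(beta, u, B, y, X, id, T, form = "prob_any") {
  id <- as.factor(id)
  if (is.null(names(u)) && length(u) == nlevels(id)) names(u) <- levels(id)
  missing_u <- setdiff(levels(id), names(u))
  if (length(missing_u))
    stop("no intercept supplied for individual(s): ",
         paste(missing_u, collapse = ", "), call. = FALSE)
  eta0 <- drop(X %*% beta) + occ_offset(B, T, form)
  .cond_loglik_cpp(eta0, as.integer(y), as.integer(id) - 1L,
                   as.numeric(u[levels(id)]))
}

#' Marginal log-likelihood by adaptive Gauss-Hermite quadrature
#'
#' Integrates the random intercept out of the conditional likelihood,
#' individual by individual, with an adaptive Gauss-Hermite rule centred at
#' each individual's conditional mode. At `sigma = 0` the degenerate
#' conditional log-likelihood with all intercepts zero is returned exactly.
#'
#' @inheritParams cond_loglik
#' @param sigma random-intercept standard deviation (`>= 0`)
#' @param nodes number of quadrature nodes (default 20)
#' @return the marginal log-likelihood (scalar)
#' @seealso [brute_force_marg_loglik()] for the dense-grid reference
#'   integrator used to validate the quadrature
#' @export
marg_loglik <- function(beta, sigma, B, y, X, id, T, form = "prob_any",
                        nodes = 20) {
  stopifnot(sigma >= 0, nodes >= 1)
  lay <- .group_layout(id)
  eta0 <- drop(X %*% beta) + occ_offset(B, T, form)
  gh <- gauss_hermite(nodes)
  ll <- .agq_loglik_cpp(eta0[lay$order], as.integer(y)[lay$order],
                        lay$gstart, sigma, gh$nodes, gh$weights)
  if (!is.finite(ll))
    stop("non-finite marginal log-likelihood at the supplied parameters",
         call. = FALSE)
  ll
}

#' Dense-grid reference marginal log-likelihood
#'
#' The same integral as [marg_loglik()], evaluated per individual by
#' trapezoidal integration over `u` on `[-10 sigma, 10 sigma]` with a dense
#' grid. Intended as a slow, quadrature-free ground truth for small
#' problems; not for fitting.
#'
#' @inheritParams marg_loglik
#' @param grid_points number of grid points per individual (default 20001)
#' @return the marginal log-likelihood (scalar)
#' @export
brute_force_marg_loglik <- function(beta, sigma, B, y, X, id, T,
                                    form = "prob_any", grid_points = 20001) {
  stopifnot(sigma >= 0)
  id <- droplevels(as.factor(id))
  eta0 <- drop(X %*% beta) + occ_offset(B, T, form)
  yy <- as.integer(y)
  if (sigma == 0) {
    eta <- eta0
    return(sum(ifelse(yy == 1, -log1p(exp(-eta)), -log1p(exp(eta)))))
  }
  u <- seq(-10 * sigma, 10 * sigma, length.out = grid_points)
  du <- u[2] - u[1]
  total <- 0
  for (g in levels(id)) {
    sel <- id == g
    # log integrand h(u) on the grid
    h <- dnorm(u, 0, sigma, log = TRUE)
    for (j in which(sel)) {
      eta <- eta0[j] + u
      h <- h + if (yy[j] == 1) -log1p(exp(-eta)) else -log1p(exp(eta))
    }
    m <- max(h)
    f <- exp(h - m)
    integral <- du * (sum(f) - (f[1] + f[grid_points]) / 2)
    total <- total + m + log(integral)
  }
  total
}
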