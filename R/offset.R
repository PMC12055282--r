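#' Window occurrence probability implied by a per-second rate
#'
#' Probability that a behaviour occurs at least once during an observation
#' window of `T` seconds when each second carries an independent baseline
#' probability `B`: `O = 1 - (1 - B)^T`. This is the exposure quantity the
#' duration offset is built from. `O` is 0 at `T = 0`, equals `B` at
#' `T = 1`, and increases towards 1 with both `T` and `B`.
#'
#' `form = "literal"` evaluates the alternative power form `O = B^T`
#' instead; it decreases with duration and is provided only for auditing
#' against analyses that used that expression.
#'
#' Non-integer durations are accepted; the power is evaluated continuously.
#'
#' @param B per-second baseline probability, strictly inside (0, 1)
#' @param T window duration in seconds, `>= 0` (vectorised; recycled
#'   against `B`)
#' @param form `"prob_any"` (default) for `1 - (1-B)^T`, `"literal"` for
#'   `B^T`
#' @return numeric vector of probabilities
#' @seealso [occ_offset()] for the logit-scale offset term
#' @examples
#' occ_prob(0.3, 1)      # 0.3: one-second window
#' occ_prob(0.05, 10)    # 1 - 0.95^10
#' @export
occ_prob <- function(B, T, form = c("prob_any", "literal")) {
  form <- match.arg(form)
  if (!is.numeric(B) || any(!is.finite(B)) || any(B <= 0) || any(B >= 1))
    stop("'B' must be strictly inside (0, 1)", call. = FALSE)
  if (!is.numeric(T) || any(!is.finite(T)) || any(T < 0))
    stop("'T' must be a non-negative duration in seconds", call. = FALSE)
  if (form == "literal") return(B^T)
  # 1 - (1-B)^T via expm1/log1p for accuracy at small B
  -expm1(T * log1p(-B))
}

#' Logit-scale duration offset
#'
#' The offset term entering the linear predictor of the occurrence model:
#' `log(O / (1 - O))` with `O = occ_prob(B, T)`. Requires `T >= 1` so that
#' `O` is strictly inside (0, 1); an empty window has `O = 0` and an
#' infinite offset, which is refused.
#'
#' @inheritParams occ_prob
#' @return numeric vector, the offset on the logit scale
#' @examples
#' occ_offset(0.5, 1)    # 0: O = 0.5
#' occ_offset(0.05, 10)  # qlogis(1 - 0.95^10)
#' @export
occ_offset <- function(B, T, form = c("prob_any", "literal")) {
  form <- match.arg(form)
  if (any(T < 1))
    stop("offset requires durations of at least 1 s (T = 0 gives O = 0 and an infinite offset)",
         call. = FALSE)
  if (any(B <= 0) || any(B >= 1))
    stop("'B' must be strictly inside (0, 1)", call. = FALSE)
  # evaluated on the log scale: O itself may round to 1 in double precision
  # for large B*T while logit(O) = log(O) - log(1-O) stays finite
  if (form == "prob_any") {
    l1mO <- T * log1p(-B)          # log(1 - O)
    lO <- log(-expm1(l1mO))        # log(O)
  } else {
    lO <- T * log(B)               # log(O), O = B^T
    l1mO <- log(-expm1(lO))
  }
  off <- lO - l1mO
  if (any(!is.finite(off)))
    stop("offset undefined: occurrence probability on the boundary of (0, 1)",
         call. = FALSE)
  off
}
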