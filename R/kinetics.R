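#' Generalised Hill activation function
#'
#' Saturating activation `X^n / (K^n + X^n)`, used throughout the network for
#' receptor-limited stimulation of cells by biomolecules. With `n = 1` this is
#' Michaelis-Menten kinetics. The value is a fraction in `[0, 1]`.
#'
#' Evaluated as `r / (1 + r)` with `r = (X/K)^n` so that concentrations far
#' below the saturation constant do not underflow `K^n` for large exponents.
#'
#' @param X stimulus concentration(s), g/mL, `X >= 0` (vectorised).
#' @param K saturation (half-maximal) constant, g/mL, `K > 0`.
#' @param n Hill exponent, `n >= 1`.
#' @return activation fraction(s) in `[0, 1]`.
#' @examples
#' hill_activation(2.5e-9, K = 2.5e-9, n = 4.14)  # 0.5 at X == K
#' @export
hill_activation <- function(X, K, n) {
  if (!is.numeric(K) || length(K) != 1 || K <= 0)
    stop("saturation constant K must be a positive scalar", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("Hill exponent n must be >= 1", call. = FALSE)
  if (any(X < 0)) stop("stimulus concentration X must be non-negative", call. = FALSE)
  r <- (X / K)^n
  ifelse(is.infinite(r), 1, r / (1 + r))
}

#' Piecewise blood glucose input
#'
#' Blood glucose over the course of disease in db/db mice, approximated as a
#' ramp between two plateaus: the healthy baseline `G1` before `t1`, a linear
#' increase on `[t1, t2]`, and the diabetic level `G2` after `t2`. The ramp
#' times are stored in weeks and converted at 7 days/week; `t` is in days.
#' Glucose is a prescribed input, not a model state.
#'
#' @param t time(s) in days, `t >= 0` (vectorised).
#' @param params a [gf_params()] object (uses `G1`, `G2`, `t1`, `t2`).
#' @return glucose concentration(s), g/mL.
#' @examples
#' p <- gf_params()
#' glucose_input(0, p)               # healthy baseline
#' glucose_input(24 * 7, p)          # diabetic plateau
#' @export
glucose_input <- function(t, params) {
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  t1d <- params$t1 * GF_DAYS_PER_WEEK
  t2d <- params$t2 * GF_DAYS_PER_WEEK
  ramp <- params$G1 + (params$G2 - params$G1) * (t - t1d) / (t2d - t1d)
  ifelse(t < t1d, params$G1, ifelse(t > t2d, params$G2, ramp))
}
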