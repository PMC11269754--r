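#' Liouville-Caputo fractional derivative of a power function
#'
#' Applies the Caputo power rule to `p(r) = r^w` for derivative order
#' `q > 0`:
#' \itemize{
#'   \item integer `w < ceiling(q)`: the derivative is identically 0
#'     (constants and low-degree integer powers are annihilated);
#'   \item integer `w >= ceiling(q)` or non-integer `w > floor(q)`:
#'     the derivative is `Gamma(w+1)/Gamma(w+1-q) * r^(w-q)`;
#'   \item integer `q`: the same ratio, which reduces to the classical
#'     `q`-fold derivative for every admissible `w`;
#'   \item non-integer `w <= floor(q)` with non-integer `q`: the rule is
#'     classically ill-defined; the result is flagged divergent rather than
#'     raised as an error so that row assembly can proceed (and warn).
#' }
#' The gamma ratio is evaluated as `Gamma(w+1) * (1/Gamma(w+1-q))` in
#' log-space with sign tracking, so poles of the denominator gamma yield a
#' coefficient of exactly 0 instead of overflow (reciprocal-gamma
#' convention).
#'
#' @param w Nonnegative real exponent of the power function.
#' @param q Positive real derivative order.
#' @return A list with fields `coefficient`, `exponent` (`w - q`) and
#'   `divergent_flag`.
#' @examples
#' caputo_power(1.7, 1.7)  # Gamma(2.7), exponent 0
#' caputo_power(1, 1.7)    # annihilated: integer 1 < ceiling(1.7)
#' @export
caputo_power <- function(w, q) {
  if (length(w) != 1L || !is.finite(w) || w < 0)
    stop("'w' must be a single nonnegative number")
  if (length(q) != 1L || !is.finite(q) || q <= 0)
    stop("'q' must be a single positive number")
  is_int <- function(x) abs(x - round(x)) < 1e-12
  w_int <- is_int(w)
  q_int <- is_int(q)
  if (w_int && round(w) < ceiling(q - 1e-12)) {
    return(list(coefficient = 0, exponent = w - q, divergent_flag = FALSE))
  }
  admissible <- (w_int && round(w) >= ceiling(q - 1e-12)) ||
    (!w_int && w > floor(q + 1e-12)) || q_int
  # reciprocal gamma: zero at non-positive integer arguments of Gamma(w+1-q)
  a <- w + 1 - q
  if (is_int(a) && round(a) <= 0) {
    coef <- 0
  } else {
    # sign(Gamma(a)) alternates on the unit intervals left of 0
    sgn <- if (a > 0 || floor(a) %% 2 == 0) 1 else -1
    coef <- sgn * exp(lgamma(w + 1) - lgamma(a))
  }
  list(coefficient = coef, exponent = w - q,
       divergent_flag = !admissible && coef != 0)
}

#' Derivative row of the fractional monomial vector
#'
#' Returns the length-`K + 1` row whose entry `l` is the Liouville-Caputo
#' derivative of order `q` of the fractional monomial `r^(l*alpha)`,
#' evaluated at `r` -- i.e. `coefficient * r^exponent` from
#' [caputo_power()].  With `q = 1` this is the classical first-derivative
#' row needed for the boundary conditions.  The collocation solver builds
#' its operator matrices by stacking these rows at the collocation nodes.
#'
#' @param r Evaluation point in `[0, 1]`.  Entries with strictly negative
#'   resulting exponent and nonzero coefficient are singular at `r = 0` and
#'   raise an error there.
#' @param params An [basis_params()] object supplying `K` and `alpha`.
#' @param q Positive derivative order.
#' @param warn_divergent Warn when a classically ill-defined power-rule
#'   entry (see [caputo_power()]) contributes to the row.
#' @return Numeric vector of length `K + 1`.
#' @examples
#' derivative_row(0.5, basis_params(2, 1), 1)  # c(0, 1, 1)
#' @export
derivative_row <- function(r, params, q, warn_divergent = TRUE) {
  stopifnot(inherits(params, "fsvlf_basis"))
  if (length(r) != 1L || !is.finite(r) || r < 0 || r > 1)
    stop("'r' must be a single value in [0, 1]")
  K <- params$K
  alpha <- params$alpha
  out <- numeric(K + 1)
  any_div <- FALSE
  for (l in 0:K) {
    pd <- caputo_power(l * alpha, q)
    if (pd$divergent_flag) any_div <- TRUE
    if (pd$coefficient == 0) next
    if (r == 0) {
      if (pd$exponent < 0)
        stop(sprintf(
          "derivative of r^%g (order %g) is singular at r = 0", l * alpha, q))
      out[l + 1] <- if (abs(pd$exponent) < 1e-14) pd$coefficient else 0
    } else {
      out[l + 1] <- pd$coefficient * r^pd$exponent
    }
  }
  if (any_div && warn_divergent)
    warning(sprintf(
      "derivative row of order %g contains classically ill-defined power-rule entries (reciprocal-gamma convention applied)", q))
  out
}
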