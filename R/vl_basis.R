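#' Basis parameters for fractional shifted Vieta-Lucas functions
#'
#' Bundles the truncation degree `K` and the fractional exponent `alpha`
#' that together define the family of fractional-order shifted Vieta-Lucas
#' functions (FSVLFs) used throughout the package.  The truncated series has
#' `K + 1` terms and spans the fractional monomials `r^(l*alpha)`,
#' `l = 0, ..., K`, on `[0, 1]`.
#'
#' @param K Nonnegative integer truncation degree.
#' @param alpha Positive real basis exponent; `alpha = 1` recovers the
#'   ordinary shifted Vieta-Lucas polynomials.
#' @return An object of class `"fsvlf_basis"`, a list with elements `K` and
#'   `alpha`.
#' @examples
#' basis_params(6, 1.7)
#' @export
basis_params <- function(K, alpha = 1) {
  if (length(K) != 1L || !is.finite(K) || K < 0 || K != floor(K))
    stop("'K' must be a single nonnegative integer")
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive number")
  structure(list(K = as.integer(K), alpha = as.numeric(alpha)),
            class = "fsvlf_basis")
}

#' @export
print.fsvlf_basis <- function(x, ...) {
  cat(sprintf("FSVLF basis: K = %d (%d terms), alpha = %g\n",
              x$K, x$K + 1L, x$alpha))
  invisible(x)
}

#' Shifted Vieta-Lucas function values
#'
#' Evaluates the shifted Vieta-Lucas function of degree `k` on `[0, 1]` by
#' the three-term recurrence seeded with `V0 = 2`, `V1 = 4 r - 2`:
#' `V[k+1](r) = (4 r - 2) V[k](r) - V[k-1](r)`.
#'
#' @param k Nonnegative integer degree (scalar).
#' @param r Numeric vector of evaluation points in `[0, 1]`.
#' @return Numeric vector of values; special values are `V[k](0) = (-2)^k`
#'   and `V[k](1) = 2`.
#' @examples
#' svlf_value(2, 0.25)  # -1
#' svlf_value(3, 0)     # -8
#' @export
svlf_value <- function(k, r) {
  if (length(k) != 1L || !is.finite(k) || k < 0 || k != floor(k))
    stop("'k' must be a single nonnegative integer")
  if (any(r < 0 | r > 1)) stop("'r' must lie in [0, 1]")
  v_prev <- rep(2, length(r))
  if (k == 0) return(v_prev)
  v <- 4 * r - 2
  if (k == 1) return(v)
  for (j in seq_len(k - 1)) {
    v_new <- (4 * r - 2) * v - v_prev
    v_prev <- v
    v <- v_new
  }
  v
}

#' Fractional-order shifted Vieta-Lucas function values
#'
#' Evaluates `V[k](r^alpha)`, the fractional-order generalization of the
#' shifted Vieta-Lucas function obtained by the change of variable
#' `r -> r^alpha`.  For `alpha = 1` this is identical to [svlf_value()].
#'
#' @inheritParams svlf_value
#' @param alpha Positive basis exponent.
#' @return Numeric vector of values, bounded by 2 in absolute value.
#' @export
fsvlf_value <- function(k, alpha, r) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive number")
  if (any(r < 0 | r > 1)) stop("'r' must lie in [0, 1]")
  svlf_value(k, r^alpha)
}

#' Explicit monomial coefficients of a shifted Vieta-Lucas function
#'
#' Returns the coefficients `c[l]`, `l = 0, ..., k`, such that
#' `V[k](r) = sum_l c[l] r^l`, from the closed form
#' `c[l] = 2 k (-1)^(k-l) 4^l (k+l-1)! / ((k-l)! (2 l)!)` for `k >= 1`
#' (and the single coefficient 2 for `k = 0`).  In the fractional basis the
#' same coefficients multiply `r^(l*alpha)`.
#'
#' The factorial ratio is evaluated through exact binomial coefficients
#' (`c[l] = 2 k 4^l choose(k+l-1, 2l) / (k-l)` for `l < k`, `c[k] = 4^k`),
#' which keeps every intermediate an exactly representable integer for the
#' degrees used here; the coefficients themselves reach ~4e9 at `k = 16`.
#'
#' @param k Nonnegative integer degree.
#' @return Numeric vector of length `k + 1` of exact integer-valued
#'   coefficients, constant term first.
#' @examples
#' svlf_coefficients(2)  # 2 -16  16
#' svlf_coefficients(3)  # -2  36 -96  64
#' @export
svlf_coefficients <- function(k) {
  if (length(k) != 1L || !is.finite(k) || k < 0 || k != floor(k))
    stop("'k' must be a single nonnegative integer")
  if (k == 0) return(2)
  l <- 0:k
  co <- numeric(k + 1)
  head_l <- l[l < k]
  co[head_l + 1] <- round(2 * k * (-1)^(k - head_l) * 4^head_l *
                            choose(k + head_l - 1, 2 * head_l) / (k - head_l))
  co[k + 1] <- 4^k
  co
}

#' Change-of-basis matrix from fractional monomials to FSVLFs
#'
#' Builds the upper-triangular matrix `N_K` whose column `k` holds the
#' monomial coefficients of the degree-`k` shifted Vieta-Lucas function, so
#' that the row vector of fractional monomials `[1, r^alpha, ..., r^(K*alpha)]`
#' times `N_K` reproduces the row vector of FSVLFs.
#'
#' @param params An [basis_params()] object.
#' @return A `(K+1) x (K+1)` numeric matrix; rows index monomial degree `l`,
#'   columns index basis degree `k`.  The first row is `2 * (-1)^k`.
#' @export
basis_matrix <- function(params) {
  stopifnot(inherits(params, "fsvlf_basis"))
  K <- params$K
  N <- matrix(0, K + 1, K + 1)
  for (k in 0:K) N[seq_len(k + 1), k + 1] <- svlf_coefficients(k)
  N
}

#' Roots of a fractional shifted Vieta-Lucas function
#'
#' The degree-`k` FSVLF has `k` simple roots, all strictly inside `(0, 1)`:
#' `r_p = (1/2 + s_p/4)^(1/alpha)` with `s_p = 2 cos((2p - 1) pi / (2k))`.
#' These are the collocation nodes used by the solver (with degree `K + 1`).
#'
#' @param k Positive integer degree (the constant `k = 0` has no roots).
#' @param alpha Positive basis exponent.
#' @return Numeric vector of the `k` roots, sorted ascending.
#' @examples
#' fsvlf_roots(2, 1)  # 0.5 -+ sqrt(2)/4
#' @export
fsvlf_roots <- function(k, alpha = 1) {
  if (length(k) != 1L || !is.finite(k) || k < 1 || k != floor(k))
    stop("'k' must be a single positive integer (k = 0 has no roots)")
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive number")
  p <- seq_len(k)
  s <- 2 * cos((2 * p - 1) * pi / (2 * k))
  sort((0.5 + s / 4)^(1 / alpha))
}

#' Orthogonal projection onto the truncated FSVLF basis
#'
#' Computes the coefficients `beta_k`, `k = 0, ..., K`, of the weighted
#' least-squares projection of `g` onto the span of the first `K + 1`
#' FSVLFs:
#' `beta_k = alpha / (pi eta_k) * integral V_k^alpha(r) g(r) w_alpha(r) dr`
#' with weight `w_alpha(r) = r^(alpha-1) / sqrt(r^alpha - r^(2*alpha))` and
#' normalization `eta_0 = 4`, `eta_k = 2` for `k >= 1`.
#'
#' The substitution `r^alpha = (1 + cos s)/2` turns each integral into
#' `(2 / (pi eta_k)) * integral_0^pi cos(k s) g(((1 + cos s)/2)^(1/alpha)) ds`,
#' which has no endpoint singularity; it is evaluated by an equally-weighted
#' midpoint rule in `s` (the Chebyshev-Gauss rule) with node doubling until
#' two successive coefficient vectors agree to `tol`.
#'
#' @param g A vectorized function on `[0, 1]`.
#' @param params An [basis_params()] object.
#' @param tol Convergence tolerance on successive coefficient vectors.
#' @param n_start,n_max Initial and maximal node counts for the doubling
#'   sequence.
#' @return A list of class `"fsvlf_projection"` with elements `beta`
#'   (length `K + 1`), `eta`, `quadrature_nodes` (count finally used) and
#'   `converged`.
#' @examples
#' pr <- fsvlf_project(function(r) exp(r), basis_params(8, 1))
#' pr$beta
#' @export
fsvlf_project <- function(g, params, tol = 1e-12, n_start = 64, n_max = 4096) {
  stopifnot(inherits(params, "fsvlf_basis"))
  K <- params$K
  alpha <- params$alpha
  eta <- c(4, rep(2, K))
  beta_at <- function(n) {
    s <- (seq_len(n) - 0.5) * pi / n
    gv <- g(((1 + cos(s)) / 2)^(1 / alpha))
    ks <- outer(0:K, s)            # (K+1) x n
    as.numeric((cos(ks) %*% gv) * (pi / n) * 2 / (pi * eta))
  }
  n <- n_start
  beta <- beta_at(n)
  converged <- FALSE
  while (n < n_max) {
    n <- 2L * n
    beta_new <- beta_at(n)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  if (!converged && n >= n_max)
    warning("projection quadrature did not converge to tol at n_max nodes")
  structure(list(beta = beta, eta = eta, quadrature_nodes = n,
                 converged = converged, params = params),
            class = "fsvlf_projection")
}

#' Theoretical decay and truncation-error bounds for FSVLF expansions
#'
#' For a twice continuously differentiable function `g` with
#' `M_inf = max |g''|` on `[0, 1]`, the projection coefficients and
#' truncation errors of its shifted Vieta-Lucas expansion (`alpha = 1`)
#' obey the closed-form bounds returned here:
#' \itemize{
#'   \item coefficient decay: `|beta_k| < 4 M_inf / (pi k^4)` for `k >= 2`;
#'   \item weighted-L2 tail: `||g - g_K||_{2,w} < sqrt(8/(7 pi)) M_inf K^(-7/2)`;
#'   \item uniform tail: `||g - g_K||_inf < 8 M_inf / (3 pi) K^(-3)`;
#'   \item consecutive-truncation gap:
#'     `||g_{K+1} - g_K||_{2,w} < 2 sqrt(2) M_inf K^(-4) / sqrt(pi)`.
#' }
#' These bounds are stated for `alpha = 1`; they are reported as checkable
#' quantities, not re-derived here.
#'
#' @param M_inf Nonnegative bound on `|g''|` over `[0, 1]`.
#' @param K Positive integer truncation degree.
#' @return A list of class `"fsvlf_bounds"` with fields `M_inf`, `K`,
#'   `coeff_bounds` (named vector for `k = 1..K`), `l2_tail_bound`,
#'   `sup_tail_bound`, `consecutive_bound`.
#' @export
fsvlf_bounds <- function(M_inf, K) {
  if (length(M_inf) != 1L || !is.finite(M_inf) || M_inf < 0)
    stop("'M_inf' must be a single nonnegative number")
  if (length(K) != 1L || !is.finite(K) || K < 1 || K != floor(K))
    stop("'K' must be a single positive integer")
  k <- seq_len(K)
  structure(list(
    M_inf = M_inf, K = as.integer(K),
    coeff_bounds = stats::setNames(4 * M_inf / (pi * k^4), paste0("k=", k)),
    l2_tail_bound = sqrt(8 / (7 * pi)) * M_inf * K^(-3.5),
    sup_tail_bound = 8 * M_inf / (3 * pi) * K^(-3),
    consecutive_bound = 2 * sqrt(2) * M_inf / sqrt(pi) * K^(-4)
  ), class = "fsvlf_bounds")
}
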