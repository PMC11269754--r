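#' Residual error function (REF) of a collocation solution
#'
#' Inserts the computed approximation back into the original nonlinear
#' equation and reports the pointwise magnitude
#' `|D^gamma h(r) + (A/r) D^sigma h(r) + lambda exp(-m h(r)) - f(r)|`.
#' Both fractional derivatives are applied term-by-term to the
#' monomial-form expansion via the Caputo power rule.  Because no exact
#' solution is available for the fractional model, the REF (and its grid
#' maximum) is the accuracy surrogate.
#'
#' By convention the REF at `r = 0` is 0: the `A/r` term is singular there
#' and the symmetry condition `h'(0) = 0` removes the limit ambiguity.
#'
#' @param sol An `"fsvlf_solution"`.
#' @param r Numeric vector of points in `[0, 1]`.
#' @param model Model whose residual is evaluated; defaults to the model
#'   the solution was computed for.
#' @return Numeric vector of nonnegative residual magnitudes.
#' @export
residual <- function(sol, r, model = sol$model) {
  stopifnot(inherits(sol, "fsvlf_solution"), inherits(model, "fsvlf_model"))
  if (any(r < 0 | r > 1)) stop("'r' must lie in [0, 1]")
  a <- monomial_coefficients(sol)
  dg <- lapply(a$exponent, caputo_power, q = model$gamma)
  ds <- lapply(a$exponent, caputo_power, q = model$sigma)
  if (any(vapply(c(dg, ds), `[[`, logical(1), "divergent_flag")))
    warning("residual uses classically ill-defined power-rule derivatives (reciprocal-gamma convention)")
  term <- function(pd_list, rr) {
    acc <- numeric(length(rr))
    for (i in seq_along(pd_list)) {
      pd <- pd_list[[i]]
      if (pd$coefficient == 0 || a$coefficient[i] == 0) next
      acc <- acc + a$coefficient[i] * pd$coefficient * rr^pd$exponent
    }
    acc
  }
  out <- numeric(length(r))
  pos <- r > 0
  if (any(pos)) {
    rp <- r[pos]
    h <- predict(sol, rp)
    f <- if (is.null(model$source)) 0 else model$source(rp)
    out[pos] <- abs(term(dg, rp) + (model$A / rp) * term(ds, rp) +
                      model$lam * exp(-model$m * h) - f)
  }
  out
}

#' Maximum residual over a uniform grid
#'
#' Evaluates the REF on a uniform grid over `(0, 1]` (the left endpoint is
#' excluded and reported as 0 by convention, see [residual()]) and returns
#' the grid maximum `E_inf`, the spectral method's accuracy surrogate.
#'
#' @param sol An `"fsvlf_solution"`.
#' @param n_grid Number of grid points (default 2001, fine enough that
#'   `E_inf` is grid-stable to about three significant digits at
#'   moderate `K`).
#' @param model See [residual()].
#' @return An object of class `"fsvlf_residuals"`: list with `grid`,
#'   `ref_values`, `e_inf`, `K`, `model`, `basis`.
#' @export
max_residual <- function(sol, n_grid = 2001, model = sol$model) {
  if (n_grid < 2) stop("'n_grid' must be at least 2")
  grid <- seq(0, 1, length.out = n_grid)
  ref <- residual(sol, grid, model)
  structure(list(grid = grid, ref_values = ref, e_inf = max(ref),
                 K = sol$basis$K, model = model, basis = sol$basis),
            class = "fsvlf_residuals")
}

#' @export
print.fsvlf_residuals <- function(x, ...) {
  cat(sprintf("REF report: K = %d, alpha = %g, grid = %d points, E_inf = %.4e\n",
              x$K, x$basis$alpha, length(x$grid), x$e_inf))
  invisible(x)
}

#' Numerical order of convergence
#'
#' The log2 ratio of the maximum residuals at truncations `K` and `2K`:
#' `ord = (ln E_K - ln E_2K) / ln 2`.  Spectral (exponential) convergence
#' shows up as orders that grow with `K`.
#'
#' @param e_K,e_2K Positive maximum-residual values at `K` and `2K`.
#' @return The numerical order (real scalar).
#' @examples
#' convergence_order(8.8287e-5, 5.8803e-9)  # about 13.87
#' @export
convergence_order <- function(e_K, e_2K) {
  if (e_K <= 0 || e_2K <= 0) stop("residual norms must be positive")
  (log(e_K) - log(e_2K)) / log(2)
}

#' Residual-norm sweep over truncation degrees
#'
#' Solves the model at each `K` in `K_list`, records `E_inf`, and computes
#' the numerical order between consecutive doubling pairs present in the
#' list (`K` and `2K`).
#'
#' @param model An [model_spec()] object.
#' @param K_list Integer vector of truncation degrees.
#' @param alpha Basis exponent used for every solve.
#' @param n_grid Residual grid size.
#' @param n_iters,tol Passed to [solver_config()].
#' @return A data frame of class `"fsvlf_convergence"` with columns `K`,
#'   `e_inf`, `ord` (`NA` where no doubling partner exists).
#' @export
convergence_table <- function(model, K_list, alpha = 1, n_grid = 2001,
                              n_iters = 5, tol = 1e-14) {
  e <- vapply(K_list, function(K) {
    sol <- solve_qlm(model, solver_config(K = K, alpha = alpha,
                                          n_iters = n_iters, tol = tol))
    max_residual(sol, n_grid = n_grid)$e_inf
  }, numeric(1))
  ord <- rep(NA_real_, length(K_list))
  for (i in seq_along(K_list)) {
    j <- match(2 * K_list[i], K_list)
    if (!is.na(j) && e[i] > 0 && e[j] > 0)
      ord[j] <- convergence_order(e[i], e[j])
  }
  structure(data.frame(K = K_list, e_inf = e, ord = ord),
            class = c("fsvlf_convergence", "data.frame"))
}

#' Pointwise comparison against a reference polynomial
#'
#' Computes `|h(r) - u(r)|` on a grid, where `u` is a reference expansion
#' given by monomial coefficients and exponents (for example one of the
#' packaged polynomial least-squares comparator fits, see
#' [plsm_reference()]).
#'
#' @param sol An `"fsvlf_solution"`.
#' @param ref A list or data frame with numeric fields `exponent` and
#'   `coefficient` of equal length.
#' @param grid Numeric vector of comparison points in `[0, 1]`.
#' @return Numeric vector of absolute differences on `grid`.
#' @export
compare_to_reference <- function(sol, ref, grid = seq(0, 1, by = 0.1)) {
  stopifnot(inherits(sol, "fsvlf_solution"))
  if (is.null(ref$exponent) || is.null(ref$coefficient) ||
      length(ref$exponent) != length(ref$coefficient))
    stop("'ref' must supply matching 'exponent' and 'coefficient' vectors")
  u <- as.numeric(outer(grid, ref$exponent, `^`) %*% ref$coefficient)
  abs(predict(sol, grid) - u)
}

#' Manufactured source term for exact-solution testing
#'
#' Given a prescribed exact solution `H*(r) = sum_i c_i r^(e_i)`, builds
#' the source `f(r) = D^gamma H* + (A/r) D^sigma H* + lambda exp(-m H*)`
#' so that `H*` solves the extended equation exactly.  The boundary data
#' of `H*` are returned so a test can set the Biot number consistently:
#' the Robin condition `h'(1) = Bi (1 - h(1))` holds with
#' `Bi = h'(1) / (1 - h(1))` whenever `h(1) != 1`.
#'
#' Every exponent must be admissible for both fractional orders (i.e. the
#' Caputo power rule must not be classically ill-defined for it), and the
#' symmetry condition `H*'(0) = 0` requires all nonconstant exponents to
#' exceed 1.
#'
#' @param exponents,coefficients Numeric vectors defining `H*`.
#' @param model An [model_spec()] object supplying `gamma`, `sigma`, `A`,
#'   `lam`, `m` (its `Bi` and `source` are ignored).
#' @return List with the vectorized `source` function, `h1 = H*(1)`,
#'   `dh1 = H*'(1)`, and `Bi` (`NA` if `h1 == 1`).
#' @export
manufactured_source <- function(exponents, coefficients, model) {
  stopifnot(inherits(model, "fsvlf_model"))
  if (length(exponents) != length(coefficients))
    stop("'exponents' and 'coefficients' must have equal length")
  dg <- lapply(exponents, caputo_power, q = model$gamma)
  ds <- lapply(exponents, caputo_power, q = model$sigma)
  if (any(vapply(c(dg, ds), `[[`, logical(1), "divergent_flag")))
    stop("inadmissible exponent: Caputo power rule classically ill-defined")
  H_star <- function(r) as.numeric(outer(r, exponents, `^`) %*% coefficients)
  term <- function(pd_list, r) {
    acc <- numeric(length(r))
    for (i in seq_along(pd_list)) {
      pd <- pd_list[[i]]
      if (pd$coefficient == 0 || coefficients[i] == 0) next
      acc <- acc + coefficients[i] * pd$coefficient * r^pd$exponent
    }
    acc
  }
  src <- function(r) {
    term(dg, r) + (model$A / r) * term(ds, r) +
      model$lam * exp(-model$m * H_star(r))
  }
  h1 <- H_star(1)
  dh1 <- sum(coefficients * exponents)
  list(source = src, h1 = h1, dh1 = dh1,
       Bi = if (abs(h1 - 1) > 1e-14) dh1 / (1 - h1) else NA_real_)
}
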