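# shared helpers for the fsvlf test suite

# evaluate a truncated FSVLF series sum_k beta_k V_k^alpha(r)
fsvlf_series_eval <- function(beta, alpha, r) {
  acc <- numeric(length(r))
  for (k in seq_along(beta) - 1L)
    acc <- acc + beta[k + 1L] * fsvlf_value(k, alpha, r)
  acc
}

# weighted FSVLF inner product <V_k, V_k'>_w by the cosine midpoint rule
# (exact for trigonometric polynomials once n exceeds k + k')
fsvlf_inner <- function(k1, k2, alpha, n = 512) {
  s <- (seq_len(n) - 0.5) * pi / n
  sum(4 * cos(k1 * s) * cos(k2 * s)) * (pi / n) / alpha
}

# first derivative of a solution at r, via the package's derivative row
solution_deriv <- function(sol, r) {
  as.numeric(derivative_row(r, sol$basis, 1, warn_divergent = FALSE) %*%
               basis_matrix(sol$basis) %*% sol$B)
}

integer_model <- function(...) {
  args <- modifyList(list(gamma = 2, sigma = 1, A = 2, lam = 1, m = 1,
                          Bi = 1), list(...))
  do.call(model_spec, args)
}

fractional_model <- function(...) {
  args <- modifyList(list(gamma = 1.7, sigma = 0.7, A = 2, lam = 1, m = 1,
                          Bi = 1), list(...))
  do.call(model_spec, args)
}
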