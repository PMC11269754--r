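test_that("shifted Vieta-Lucas recurrence reproduces special values", {
  expect_equal(svlf_value(0, 0.3), 2)
  expect_equal(svlf_value(2, 0.25), -1)   # 2 - 16 r + 16 r^2 at 1/4
  # endpoint identities from the cosine form: V_k(0) = 2(-1)^k, V_k(1) = 2
  for (k in 0:8) {
    expect_equal(svlf_value(k, 0), 2 * (-1)^k)
    expect_equal(svlf_value(k, 1), 2)
  }
  expect_error(svlf_value(-1, 0.5), "nonnegative")
  expect_error(svlf_value(2, 1.5), "\\[0, 1\\]")
})

test_that("fractional-order values are the alpha-substituted recurrence values", {
  set.seed(11)
  r <- runif(20)
  for (k in c(0, 1, 4, 9)) {
    expect_equal(fsvlf_value(k, 1, r), svlf_value(k, r))
    expect_equal(fsvlf_value(k, 1.7, r), svlf_value(k, r^1.7))
  }
  expect_equal(fsvlf_value(1, 0.5, 0.25), 0)   # 4 * 0.5 - 2
  expect_equal(fsvlf_value(5, 1.7, 1), 2)
})

test_that("explicit monomial coefficients agree with printed forms and the recurrence", {
  expect_equal(svlf_coefficients(0), 2)
  expect_equal(svlf_coefficients(2), c(2, -16, 16))
  expect_equal(svlf_coefficients(3), c(-2, 36, -96, 64))
  # recurrence as independent oracle, k <= 12 (coefficients reach ~1e9,
  # so the comparison is relative)
  set.seed(21)
  r <- runif(50)
  for (k in 0:12) {
    co <- svlf_coefficients(k)
    poly <- as.numeric(outer(r, 0:k, `^`) %*% co)
    # cancellation scale: coefficients alternate and reach ~1e9 at k = 12
    expect_lt(max(abs(poly - svlf_value(k, r))) / max(abs(co)), 1e-9)
  }
  expect_error(svlf_coefficients(-2), "nonnegative")
})

test_that("change-of-basis matrix maps monomials onto FSVLFs", {
  expect_equal(basis_matrix(basis_params(1)), cbind(c(2, 0), c(-2, 4)))
  N6 <- basis_matrix(basis_params(6))
  expect_equal(N6[1, ], 2 * (-1)^(0:6))
  expect_true(all(N6[lower.tri(N6)] == 0))
  # monomial row times N reproduces fsvlf_value, fractional case
  set.seed(31)
  params <- basis_params(6, 1.7)
  N <- basis_matrix(params)
  r <- runif(20)
  V <- outer(r, (0:6) * 1.7, `^`) %*% N
  for (k in 0:6)
    expect_equal(V[, k + 1], fsvlf_value(k, 1.7, r), tolerance = 1e-12)
})

test_that("FSVLF roots are interior, sorted, and genuine zeros", {
  expect_equal(fsvlf_roots(1, 1), 0.5)
  expect_equal(fsvlf_roots(2, 1), c(0.5 - sqrt(2) / 4, 0.5 + sqrt(2) / 4))
  for (alpha in c(1, 1.7)) {
    for (k in 1:10) {
      ro <- fsvlf_roots(k, alpha)
      expect_length(ro, k)
      expect_true(all(ro > 0 & ro < 1))
      expect_true(all(diff(ro) > 0))
      expect_true(all(abs(fsvlf_value(k, alpha, ro)) < 1e-10))
    }
  }
  expect_error(fsvlf_roots(0, 1), "positive integer")
})

test_that("FSVLFs are orthogonal under the fractional weight", {
  for (alpha in c(1, 1.7)) {
    for (k1 in 0:8) for (k2 in k1:8) {
      expected <- if (k1 != k2) 0 else if (k1 == 0) 4 * pi / alpha
                  else 2 * pi / alpha
      expect_equal(fsvlf_inner(k1, k2, alpha), expected, tolerance = 1e-8)
    }
  }
})

test_that("FSVLFs are uniformly bounded by 2", {
  r <- seq(0, 1, length.out = 2001)
  for (k in 0:12) {
    expect_true(all(abs(fsvlf_value(k, 1, r)) <= 2 + 1e-12))
    expect_true(all(abs(fsvlf_value(k, 1.7, r)) <= 2 + 1e-12))
  }
})

test_that("projection recovers basis functions and span members exactly", {
  params <- basis_params(5, 1.7)
  pr <- fsvlf_project(function(r) rep(2, length(r)), params)
  expect_equal(pr$beta, c(1, rep(0, 5)), tolerance = 1e-12)
  expect_equal(pr$eta, c(4, rep(2, 5)))
  # orthogonality: projecting V_3^alpha picks out beta_3 = 1
  pr3 <- fsvlf_project(function(r) fsvlf_value(3, 1.7, r), params)
  expect_equal(pr3$beta[4], 1, tolerance = 1e-10)
  expect_true(all(abs(pr3$beta[-4]) < 1e-10))
  # exactness on the span: a random polynomial in r^alpha round-trips
  set.seed(41)
  co <- rnorm(6)
  g <- function(r) as.numeric(outer(r, (0:5) * 1.7, `^`) %*% co)
  prg <- fsvlf_project(g, params)
  r <- seq(0, 1, length.out = 101)
  expect_equal(fsvlf_series_eval(prg$beta, 1.7, r), g(r), tolerance = 1e-10)
})

test_that("projection coefficients of a smooth function obey the quartic decay bound", {
  params <- basis_params(16, 1)
  pr <- fsvlf_project(exp, params)
  M <- exp(1)  # max |g''| for g = e^r on [0, 1]
  for (k in 2:16)
    expect_lt(abs(pr$beta[k + 1]), 4 * M / (pi * k^4))
})

test_that("truncation error of e^r respects the cubic uniform bound", {
  M <- exp(1)
  r <- seq(0, 1, length.out = 501)
  for (K in c(4, 8, 16)) {
    pr <- fsvlf_project(exp, basis_params(K, 1))
    sup_err <- max(abs(exp(r) - fsvlf_series_eval(pr$beta, 1, r)))
    expect_lt(sup_err, 8 * M / (3 * pi * K^3))
  }
})

test_that("closed-form bound report is consistent and scales correctly", {
  b <- fsvlf_bounds(exp(1), 2)
  expect_equal(unname(b$coeff_bounds["k=2"]), 4 * exp(1) / (16 * pi))
  expect_equal(b$coeff_bounds[["k=2"]], 0.21632, tolerance = 1e-4)
  # K^-3 scaling of the uniform tail bound
  expect_equal(fsvlf_bounds(1, 8)$sup_tail_bound * 8,
               fsvlf_bounds(1, 4)$sup_tail_bound)
  z <- fsvlf_bounds(0, 5)
  expect_true(all(c(z$coeff_bounds, z$l2_tail_bound, z$sup_tail_bound,
                    z$consecutive_bound) == 0))
  # every bound decreasing in K
  for (f in c("l2_tail_bound", "sup_tail_bound", "consecutive_bound")) {
    vals <- vapply(1:10, function(K) fsvlf_bounds(1, K)[[f]], numeric(1))
    expect_true(all(diff(vals) < 0))
  }
})
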