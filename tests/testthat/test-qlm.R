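test_that("model and solver constructors validate their domains", {
  expect_error(model_spec(gamma = 3), "gamma")
  expect_error(model_spec(sigma = 0), "sigma")
  expect_error(model_spec(Bi = -1), "Bi")
  expect_error(solver_config(n_iters = 0), "n_iters")
  # a manufactured source lifts the Bi sign restriction
  expect_s3_class(model_spec(Bi = -2, source = function(r) r), "fsvlf_model")
})

test_that("quasilinearization coefficients match the closed forms", {
  m <- model_spec(A = 2, lam = 1, m = 1)
  nodes <- c(0.25, 0.5, 0.75)
  lin <- qlm_linearize(rep(0, 3), nodes, m)
  expect_equal(lin$xi1, rep(-1, 3))
  expect_equal(lin$theta, rep(-1, 3))
  expect_equal(lin$xi2, 2 / nodes)
  # m = 0: problem already linear, xi1 vanishes regardless of H_prev
  m0 <- model_spec(lam = 2, m = 0)
  lin0 <- qlm_linearize(c(5, -3, 0.2), nodes, m0)
  expect_equal(lin0$xi1, rep(0, 3))
  expect_equal(lin0$theta, rep(-2, 3))
  expect_error(qlm_linearize(0, 0, m), "positive")
})

test_that("FSVLF-root collocation nodes follow the closed form", {
  expect_equal(collocation_nodes(basis_params(0), rule = "fsvlf"), 0.5)
  expect_equal(collocation_nodes(basis_params(1), rule = "fsvlf"),
               c(0.5 - sqrt(2) / 4, 0.5 + sqrt(2) / 4))
  # exponent 1/alpha acts elementwise on the alpha = 1 nodes
  for (rule in c("fsvlf", "fourth-kind")) {
    n1 <- collocation_nodes(basis_params(5, 1), rule = rule)
    n2 <- collocation_nodes(basis_params(5, 2), rule = rule)
    expect_equal(n2, sqrt(n1))
    expect_true(all(n1 > 0 & n1 < 1))
  }
})

test_that("assembled systems are square with the documented boundary rows", {
  m <- integer_model()
  cfg <- solver_config(K = 2)
  sys <- qlm_assemble(m, cfg, rep(0, 3))
  expect_equal(dim(sys$X_tilde), c(3, 3))
  expect_length(sys$Theta_tilde, 3)
  # r -> 0 boundary row is the second row of N_K for alpha = 1
  expect_equal(sys$X_tilde[1, ], c(0, 4, -16))
  expect_equal(sys$Theta_tilde[1], 0)
  expect_equal(sort(sys$replaced_rows), c(1L, 2L))
  # lambda = 0: the constant h = 1 (beta_0 = 1/2) solves the system exactly
  m0 <- model_spec(gamma = 1.8, sigma = 0.6, A = 2, lam = 0, m = 1, Bi = 3)
  cfg <- solver_config(K = 4, alpha = 1.8)
  sys0 <- qlm_assemble(m0, cfg, rep(0, 5))
  B1 <- c(0.5, rep(0, 4))
  expect_equal(as.numeric(sys0$X_tilde %*% B1), sys0$Theta_tilde,
               tolerance = 1e-12)
})

test_that("zero thermogenesis gives the exact constant solution", {
  for (alpha in c(1, 1.7)) {
    m0 <- model_spec(gamma = 1.7, sigma = 0.7, A = 2, lam = 0, m = 1, Bi = 1)
    sol <- solve_qlm(m0, solver_config(K = 5, alpha = alpha))
    r <- seq(0, 1, length.out = 21)
    expect_equal(predict(sol, r), rep(1, 21), tolerance = 1e-12)
    a <- monomial_coefficients(sol)$coefficient
    expect_equal(a, c(1, rep(0, 5)), tolerance = 1e-12)
  }
})

test_that("converged solutions satisfy the boundary conditions", {
  runs <- list(
    list(model = integer_model(), alpha = 1, K = 6),
    list(model = integer_model(), alpha = 1, K = 10),
    list(model = fractional_model(), alpha = 1, K = 6),
    list(model = fractional_model(), alpha = 1.7, K = 6))
  for (ru in runs) {
    sol <- solve_qlm(ru$model, solver_config(K = ru$K, alpha = ru$alpha))
    h1 <- predict(sol, 1)
    dh1 <- solution_deriv(sol, 1)
    expect_lt(abs(dh1 - ru$model$Bi * (1 - h1)), 1e-8)
    if (ru$alpha == 1) expect_lt(abs(solution_deriv(sol, 0)), 1e-8)
  }
})

test_that("the quasilinearization iteration contracts quadratically", {
  for (setup in list(list(integer_model(), 1), list(fractional_model(), 1.7))) {
    sol <- solve_qlm(setup[[1]], solver_config(K = 8, alpha = setup[[2]]))
    ch <- sol$history$changes
    expect_true(all(diff(ch[-1]) < 0))       # monotone after the first sweep
    expect_lt(ch[length(ch)], 1e-12)         # converged within 5 sweeps
  }
})

test_that("a linear problem converges in a single sweep", {
  m0 <- model_spec(gamma = 2, sigma = 1, A = 2, lam = 1, m = 0, Bi = 1)
  sol <- solve_qlm(m0, solver_config(K = 6, n_iters = 3))
  it <- sol$history$iterates
  expect_gte(length(it), 2)
  expect_equal(it[[1]], it[[2]], tolerance = 1e-13)
})

test_that("manufactured solutions are recovered to solver accuracy", {
  set.seed(5)
  r <- runif(50)
  for (alpha in c(1, 1.7)) {
    expo <- c(0, 2, 3) * alpha
    co <- c(1, 1, 1)                       # H* = 1 + r^(2a) + r^(3a)
    base <- model_spec(gamma = 2 * min(alpha, 1), sigma = min(alpha, 1) * 0.9,
                       A = 2, lam = 1, m = 1, Bi = 1)
    ms <- manufactured_source(expo, co, base)
    model <- model_spec(gamma = base$gamma, sigma = base$sigma, A = 2,
                        lam = 1, m = 1, Bi = ms$Bi, source = ms$source)
    sol <- solve_qlm(model, solver_config(K = 4, alpha = alpha))
    H_star <- as.numeric(outer(r, expo, `^`) %*% co)
    expect_equal(predict(sol, r), H_star, tolerance = 1e-9)
  }
})

test_that("evaluation and monomial views are mutually consistent", {
  sol <- solve_qlm(integer_model(), solver_config(K = 6))
  a <- monomial_coefficients(sol)
  # value at 1 is the coefficient sum; generic r matches the explicit sum
  expect_equal(predict(sol, 1), sum(a$coefficient))
  r <- c(0, 0.3, 0.9)
  expect_equal(predict(sol, r),
               as.numeric(outer(r, a$exponent, `^`) %*% a$coefficient))
  expect_equal(a$exponent, 0:6)
})
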