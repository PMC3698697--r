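test_that("zero data with positive penalties gives the zero spectrum", {
  fx <- small_fixture()
  model <- inversion_model(fx$K, numeric(200), 0.1, 0.05)
  sp <- solve_inversion(model, solver_options(tol = 1e-9, maxit = 200))
  expect_lt(max(abs(sp$f)), 1e-5)
  expect_lt(kkt_residual(sp, model), 1e-6)
})

test_that("a noise-free grid delta is recovered at its bin", {
  fx <- small_fixture(bins = 17)
  model <- inversion_model(fx$K, fx$s, 1e-8, 1e-8)
  sp <- solve_inversion(model, solver_options(tol = 1e-9, maxit = 200))
  expect_true(sp$diagnostics$converged)
  expect_gt(sum(sp$f[16:18]) / sum(sp$f), 0.99)
  ## agrees with the exhaustive active-set oracle on a reduced instance
  fx2 <- small_fixture(m = 60, n = 8, bins = 5)
  or <- enum_nnqp_oracle(fx2$K$matrix, fx2$s, 1e-8, 1e-8)
  model2 <- inversion_model(fx2$K, fx2$s, 1e-8, 1e-8)
  sp2 <- solve_inversion(model2, solver_options(tol = 1e-9, maxit = 200))
  expect_lt(max(abs(sp2$f - or$f)), 1e-3)
  ## both objectives are ~1e-8 here; compare the suboptimality gap absolutely
  expect_lt(inversion_objective(sp2$f, model2) - or$objective, 1e-8)
})

test_that("objective matches the enumeration oracle on toy instances", {
  set.seed(3)
  K <- matrix(runif(20), 5, 4)
  s <- rnorm(5)
  model <- inversion_model(K, s, 0.1, 0.05)
  sp <- solve_inversion(model, solver_options(tol = 1e-9, maxit = 200))
  or <- enum_nnqp_oracle(K, s, 0.1, 0.05)
  expect_equal(inversion_objective(sp$c, model), or$objective,
               tolerance = 1e-6)
})

test_that("penalty monotonicity: larger weights shrink the solution norms", {
  fx <- small_fixture(m = 120, n = 24, bins = c(8, 16))
  s <- fx$s + with_seed_noise(fx$s, 42, sd = 0.01 * max(fx$s))
  l1_grid <- c(0.001, 0.01, 0.1, 0.5, 2)
  norms1 <- vapply(l1_grid, function(l1) {
    sum(abs(solve_inversion(inversion_model(fx$K, s, l1, 0.05))$f))
  }, 0)
  expect_true(all(diff(norms1) <= 1e-6 * max(norms1)))
  l2_grid <- c(0.001, 0.01, 0.1, 0.5, 2)
  norms2 <- vapply(l2_grid, function(l2) {
    sqrt(sum(solve_inversion(inversion_model(fx$K, s, 0.01, l2))$f^2))
  }, 0)
  expect_true(all(diff(norms2) <= 1e-6 * max(norms2)))
})

test_that("solutions are non-negative and the duality gap shrinks", {
  fx <- small_fixture()
  s <- fx$s + with_seed_noise(fx$s, 7, sd = 0.005 * max(fx$s))
  for (lam in list(c(0.1, 0.05), c(1e-6, 1e-6), c(2, 1))) {
    sp <- solve_inversion(inversion_model(fx$K, s, lam[1], lam[2]))
    expect_gte(min(sp$f), -1e-9 * max(sp$f))
    gaps <- sp$diagnostics$gap_history
    last5 <- tail(gaps, 5)
    expect_true(all(diff(last5) <= 1e-8 + 1e-6 * last5[-length(last5)]))
  }
})

test_that("the L2-only unconstrained solution equals the filtered SVD formula", {
  set.seed(5)
  for (i in 1:5) {
    K <- matrix(rnorm(200), 20, 10)
    s <- rnorm(20)
    lam <- 10^runif(1, -4, 0)
    sp <- solve_inversion(inversion_model(K, s, 0, lam, nonneg_c = FALSE),
                          solver_options(tol = 1e-12, maxit = 60))
    ref <- tikhonov_solve(K, s, lam)
    expect_equal(sp$f, ref, tolerance = 1e-8)
    ## and the filter-factor identity: coefficients damped by w(sigma)
    sv <- svd(K)
    ref2 <- drop(sv$v %*% (tikhonov_weights(sv$d, lam) / sv$d *
                             crossprod(sv$u, s)))
    expect_equal(ref, ref2, tolerance = 1e-10)
  }
})

test_that("dictionary splitting encodes the model faithfully", {
  fx <- small_fixture(m = 40, n = 6, bins = 3)
  model <- inversion_model(fx$K, fx$s, 0.2, 0.1)
  enc <- split_dictionary_problem(model)
  ## identity + nonneg: no variable doubling, linear cost lambda1
  expect_identical(enc$layout, "identity_nonneg")
  expect_equal(ncol(enc$problem$A), 6)
  expect_equal(enc$problem$phi, rep(0.2, 6))
  ## round trip: a feasible (x, r) has zero constraint residual
  x <- c(0.3, 0, 1, 0, 0.2, 0)
  r <- fx$s - drop(fx$K$matrix %*% x)
  expect_equal(drop(enc$problem$A %*% x) + enc$problem$d2 * r, enc$problem$b,
               tolerance = 1e-12)

  ## general dictionary with a negative coefficient: sign splitting finds it
  B <- cbind(c(1, 1), c(0, 1))
  tg <- build_time_grid(0.5, 50)
  t2g <- build_t2_grid(5, 50, 2)
  K2 <- build_kernel(tg, t2g)
  f_true <- c(1, 0.5)                      # = 1*B[,1] - 0.5*B[,2]
  s2 <- drop(K2$matrix %*% f_true)
  model2 <- inversion_model(K2, s2, 1e-8, 1e-8, B = B, nonneg_c = FALSE)
  enc2 <- split_dictionary_problem(model2)
  expect_identical(enc2$layout, "dict_split")
  sol2 <- interior_point_solve(enc2$problem, solver_options(tol = 1e-9, maxit = 300))
  expect_true(sol2$converged)
  expect_gt(sol2$x[enc2$idx_c2][2], 0.4)   # c2 carries the negative part
  expect_equal(sol2$x[enc2$idx_c1] - sol2$x[enc2$idx_c2], c(1, -0.5),
               tolerance = 1e-4)
  expect_equal(sol2$x[enc2$idx_f], f_true, tolerance = 1e-4)
  ## the high-level wrapper extracts the same solution
  sp2 <- solve_inversion(model2, solver_options(tol = 1e-9, maxit = 300))
  expect_equal(sp2$c, c(1, -0.5), tolerance = 1e-4)
})

test_that("interior point handles quadratics, active bounds and infeasible starts", {
  ## unconstrained strictly convex quadratic: matches the normal equations
  set.seed(9)
  A <- matrix(rnorm(30), 10, 3)
  b <- rnorm(10)
  prob <- ip_problem(A, b, -Inf, Inf, d1 = 0.3, d2 = 1)
  sol <- interior_point_solve(prob, solver_options(tol = 1e-10))
  ref <- solve(crossprod(A) + diag(0.3^2, 3), crossprod(A, b))
  expect_equal(sol$x, drop(ref), tolerance = 1e-8)

  ## 3-variable NNLS with an active bound: matches enumeration
  K <- rbind(c(1, 1, 0), c(0, 1, 1), c(1, 0, 1), c(1, 1, 1))
  s <- c(1, -0.5, 0.4, 0.2)
  or <- enum_nnqp_oracle(K, s, 0, 1e-10)
  prob2 <- ip_problem(K, s, 0, Inf, d1 = 1e-5, d2 = 1)
  sol2 <- interior_point_solve(prob2, solver_options(tol = 1e-10, maxit = 200))
  expect_equal(sol2$x, or$f, tolerance = 1e-5)
  expect_true(any(or$f == 0))              # a bound really is active

  ## start violating A x = b only: final residual small (soft constraint rows)
  A3 <- rbind(c(1, 1))
  prob3 <- ip_problem(A3, b = 2, bl = 0, bu = Inf, d1 = 1e-4, d2 = 1e-4,
                      phi = c(1, 2))
  sol3 <- interior_point_solve(prob3, solver_options(tol = 1e-9, maxit = 200))
  expect_lt(abs(sum(sol3$x) - 2), 1e-5)
  ## cheapest coordinate takes the mass
  expect_gt(sol3$x[1], 1.9)
  expect_lt(sol3$x[2], 1e-4)
})

test_that("the KKT residual certifies optimality and detects perturbations", {
  fx <- small_fixture(m = 60, n = 8, bins = 5)
  model <- inversion_model(fx$K, fx$s, 0.05, 0.02)
  or <- enum_nnqp_oracle(fx$K$matrix, fx$s, 0.05, 0.02)
  expect_lt(kkt_residual(or$f, model), 1e-6)
  bumped <- or$f
  bumped[3] <- bumped[3] + 0.1
  expect_gt(kkt_residual(bumped, model), kkt_residual(or$f, model))
  ## origin is optimal for zero data
  model0 <- inversion_model(fx$K, numeric(60), 0.05, 0.02)
  expect_lt(kkt_residual(numeric(8), model0), 1e-12)
  expect_error(kkt_residual(or$f, inversion_model(fx$K, fx$s, 0, 0.1,
                                                  nonneg_c = FALSE)),
               "identity-dictionary")
})
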