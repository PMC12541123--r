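test_that("X* transform reduces correctly in special cases", {
  p <- theory_params(3, 36, 0.02, c(0.5, 0.5, 0.5))
  # constant utility u: X* = u * min(xi, T)
  expect_equal(xstar_value(c(1, 3, 10, 36, 50), p),
               0.5 * pmin(c(1, 3, 10, 36, 50), 36))
  # xi <= C: X2 = 0 and X* = A1 xi + (A2 - A1) xi^2 / (2C)
  p2 <- theory_params(3, 36, 0.02, c(0.8, 0.5, 0.8))
  xi <- c(0.4, 1.7, 3)
  expect_equal(xstar_value(xi, p2), 0.8 * xi + (0.5 - 0.8) * xi^2 / 6)
  # general value against an independently coded expansion of the transform
  p3 <- theory_params(3, 36, 0.02, c(0.8, 0.5, 0.8))
  X1 <- 3; X2 <- 7  # xi = 10
  A1 <- 0.8; A2 <- 0.5; A3 <- 0.8; C <- 3; Tt <- 36
  manual <- A1 * X1 + (Tt * A2 - C * A3) / (Tt - C) * X2 +
    (A2 - A1) / (2 * C) * X1^2 + (A3 - A2) / (2 * (Tt - C)) * X2^2 +
    (A3 - A2) / (Tt - C) * X1 * X2
  expect_equal(xstar_value(10, p3), manual)
  expect_error(xstar_value(-1, p3))
})

test_that("E(X*) equals the survival-utility integral (closed form and quadrature)", {
  # constant utility, single hazard: M = u (1 - exp(-hT)) / h
  p <- theory_params(3, 36, 0.02, c(1, 1, 1))
  m <- xstar_moments(p)
  expect_equal(m$M, (1 - exp(-0.02 * 36)) / 0.02, tolerance = 1e-8)
  expect_equal(m$M, 25.658, tolerance = 1e-3)

  # identity M = int S(t) U0(t) dt on 100 random parameter sets
  set.seed(23)
  for (i in 1:100) {
    p <- random_theory_params()
    m <- xstar_moments(p)
    direct <- integrate(function(t)
      hussurv:::surv_theory(t, p) * base_utility(t, p), 0, p$C,
      rel.tol = 1e-12)$value +
      integrate(function(t)
        hussurv:::surv_theory(t, p) * base_utility(t, p), p$C, p$T,
        rel.tol = 1e-12)$value
    expect_equal(m$M, direct, tolerance = 1e-8)
    expect_gte(m$var_xstar, 0)
  }
})

test_that("scenario-1 mean difference matches the reported true effect scale", {
  sc <- scenario_preset("scenario1")
  m1 <- xstar_moments(hussurv:::scenario_theory_params(sc, 1))
  m2 <- xstar_moments(hussurv:::scenario_theory_params(sc, 2))
  expect_equal(m1$M - m2$M, 3.12, tolerance = 0.01)
})

test_that("Monte-Carlo mean of X* matches M within sampling error", {
  set.seed(31)
  p <- theory_params(3, 36, 0.02, c(0.8, 0.5, 0.8))
  xi <- rexp(1e6, 0.02)
  xs <- xstar_value(xi, p)
  m <- xstar_moments(p)
  expect_lt(abs(mean(xs) - m$M), 3 * sd(xs) / sqrt(length(xs)))
  expect_lt(abs(var(xs) - m$var_xstar), 3 * var(xs) * sqrt(2 / length(xs)))
})

test_that("analytic decision rule is a strict one-sided z-test", {
  expect_false(analytic_decision(0, 1, 0.05))
  z <- qnorm(0.95)
  expect_false(analytic_decision(z, 1, 0.05))       # boundary: strict
  expect_true(analytic_decision(z + 1e-9, 1, 0.05))
  expect_error(analytic_decision(1, 0, 0.05), "positive")
})

test_that("power formula: limits, monotonicity, and the sample-size round trip", {
  ph <- structure(list(phi1 = 1.1, phi2 = 1.15, T_true = 3,
                       var_xstar1 = 70, var_xstar2 = 47,
                       M1 = 16, M2 = 13, n_used = 200, reps = 1000,
                       seed = 1), class = "phi_estimate")
  # T_true = 0 gives power exactly alpha
  ph0 <- ph; ph0$T_true <- 0
  expect_warning(w0 <- hus_power(ph0, 100), "T_true")
  expect_equal(w0$power, 0.05)
  expect_error(hus_sample_size(ph0, 0.8), "T_true")
  # strictly increasing in n1
  pw <- vapply(c(50, 100, 200, 400), function(n)
    hus_power(ph, n)$power, numeric(1))
  expect_true(all(diff(pw) > 0))
  # round trip: power at the returned n is >= target, at n-1 below
  for (target in c(0.7, 0.8, 0.9)) {
    n <- hus_sample_size(ph, target)$n
    expect_gte(hus_power(ph, n)$power, target)
    expect_lt(hus_power(ph, n - 1)$power, target)
  }
  # halving T_true quadruples the exact sample size
  ph_half <- ph; ph_half$T_true <- 1.5
  expect_equal(hus_sample_size(ph_half, 0.8)$n_exact,
               4 * hus_sample_size(ph, 0.8)$n_exact)
})

test_that("phi estimates are stable in the calibration sample size", {
  sc <- scenario_preset("scenario1")
  a <- estimate_phi(sc, n_per_arm = 200, reps = 4000, seed = 51)
  b <- estimate_phi(sc, n_per_arm = 500, reps = 4000, seed = 52)
  expect_lt(abs(a$phi1 - b$phi1), 0.03)
  expect_lt(abs(a$phi2 - b$phi2), 0.03)
  expect_gte(min(a$phi1, a$phi2), 1)
  # null scenario: T_true is indistinguishable from 0
  p0 <- estimate_phi(scenario_preset("scenario0"), n_per_arm = 100,
                     reps = 800, seed = 53)
  expect_lt(abs(p0$T_true), 0.1)
})
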