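# Efficiency formulas of the limiting chain: quadrature, Monte Carlo,
# closed-form oracles and limits.

test_that("matched acceptance agrees with the Student-t closed form", {
  # 2 E[Phi(-(ell/(2 sqrt(d))) chi_d)] = 2 F_{t_d}(-ell/2): the ratio of a
  # standard normal to chi_d/sqrt(d) is Student-t with d df
  for (ell in c(0.5, 1, 2.38, 2.42, 4)) {
    for (d in c(1, 2, 5, 9, 50)) {
      expect_equal(acceptance_matched(ell, d)$value, 2 * pt(-ell / 2, d),
                   tolerance = 1e-8)
    }
  }
})

test_that("quadrature and Monte Carlo backends agree within 3 SE", {
  cases <- list(c(2.42, 1), c(2.40, 10), c(1.0, 5))
  for (cs in cases) {
    q_a <- acceptance_matched(cs[1], cs[2])
    m_a <- acceptance_matched(cs[1], cs[2], "monte_carlo",
                              n_samples = 2e5, seed = 101)
    expect_lt(abs(q_a$value - m_a$value), 3 * m_a$std_error)
    q_e <- esjd_matched(cs[1], cs[2])
    m_e <- esjd_matched(cs[1], cs[2], "monte_carlo",
                        n_samples = 2e5, seed = 102)
    expect_lt(abs(q_e$value - m_e$value), 3 * m_e$std_error)
  }
})

test_that("identity-proposal forms reduce to the matched forms", {
  d <- 4
  # identity metric: lambda = ell/sqrt(d) reproduces the matched curves
  expect_equal(acceptance_identity(2.4 / sqrt(d), diag(d), "quadrature")$value,
               acceptance_matched(2.4, d)$value, tolerance = 1e-10)
  expect_equal(esjd_identity(2.4 / sqrt(d), diag(d), "quadrature")$value,
               esjd_matched(2.4, d)$value, tolerance = 1e-10)
  # scalar metric [[4]]: ||eps||_I = 2|eps|, so lambda = 1 matches ell = 2
  expect_equal(acceptance_identity(1, matrix(4), "quadrature")$value,
               acceptance_matched(2, 1)$value, tolerance = 1e-10)
  # general metric: Monte Carlo vs the matched quadrature is only equal for
  # matched metrics, but MC with an identity metric must agree with itself
  m <- acceptance_identity(2.4 / sqrt(d), diag(d), "monte_carlo",
                           n_samples = 2e5, seed = 7)
  expect_lt(abs(m$value - acceptance_matched(2.4, d)$value),
            3 * m$std_error)
  # a genuinely correlated metric shifts the curve
  info <- ar1_info(0.8, d)
  v <- acceptance_identity(2.4 / sqrt(d), info, "monte_carlo",
                           n_samples = 2e5, seed = 8)
  expect_lt(v$value, acceptance_matched(2.4, d)$value)
  expect_error(acceptance_identity(1, info, "quadrature"), "scalar")
})

test_that("limits, degenerate inputs and input validation", {
  expect_equal(acceptance_matched(0, 5)$value, 1)
  expect_equal(esjd_matched(0, 5)$value, 0)
  expect_equal(acceptance_identity(0, diag(3))$value, 1)
  expect_equal(asymptotic_esjd(0), 0)
  expect_equal(asymptotic_acceptance(0), 1)
  expect_error(acceptance_matched(-1, 5), "nonnegative")
  expect_error(acceptance_matched(1, 0), "positive integer")
  expect_error(asymptotic_esjd(-0.1), "nonnegative")
  expect_error(acceptance_matched(1, 5, "monte_carlo"), "seed")
  # tiny step size: acceptance approaches 1 from below
  expect_gt(acceptance_matched(1e-4, 50)$value, 0.9999)
})

test_that("asymptotic ESJD is maximized near 2.38 with 23.4% acceptance", {
  opt <- optimize(asymptotic_esjd, c(0.1, 10), maximum = TRUE, tol = 1e-9)
  expect_equal(round(opt$maximum, 2), 2.38)
  expect_equal(round(asymptotic_acceptance(2.38), 3), 0.234)
  expect_equal(round(100 * asymptotic_acceptance(opt$maximum), 2), 23.38)
  # frozen direct evaluation: 2 * 2.38^2 * pnorm(-1.19)
  expect_equal(asymptotic_esjd(2.38), 1.3257319, tolerance = 1e-6)
})

test_that("generalized limit rescales the optimum by sqrt(L')", {
  expect_identical(esjd_limit(c(0.5, 2.38, 4), L_prime = 1),
                   asymptotic_esjd(c(0.5, 2.38, 4)))
  grid <- seq(0.5, 4, by = 0.001)
  am <- grid[which.max(esjd_limit(grid, L_prime = 4))]
  expect_equal(am, 2.381 / 2, tolerance = 2e-3)
  expect_error(esjd_limit(1, L_prime = 0), "positive")
})

test_that("finite-d curves converge to the asymptotic ones", {
  d <- 1e4
  expect_lt(abs(acceptance_matched(2.38, d)$value -
                  asymptotic_acceptance(2.38)), 0.002)
  expect_lt(abs(esjd_matched(2.38, d)$value - asymptotic_esjd(2.38)), 0.002)
})

test_that("acceptance decreases in step size and in dimension", {
  ells <- seq(0.2, 5, by = 0.2)
  acc <- vapply(ells, function(l) acceptance_matched(l, 3)$value, 0)
  expect_true(all(diff(acc) < 0))
  for (ell in c(1, 2.42)) {
    by_d <- vapply(1:10, function(d) acceptance_matched(ell, d)$value, 0)
    expect_true(all(diff(by_d) <= 1e-10))
  }
})

test_that("AR(1) L-prime matches the numeric trace of the inverse", {
  expect_equal(ar1_L_prime(0), 1)
  expect_equal(ar1_L_prime(0.5), 5 / 3, tolerance = 1e-12)
  d <- 1000
  for (rho in c(0.3, 0.5)) {
    tr_d <- sum(diag(solve(ar1_covariance(rho, d)))) / d
    expect_lt(abs(ar1_L_prime(rho) - tr_d), 1e-3)
  }
  # the information matrix of the AR(1) covariance is tridiagonal
  Q <- ar1_info(0.6, 8)$matrix
  off <- abs(Q[abs(row(Q) - col(Q)) > 1])
  expect_lt(max(off), 1e-8)
  expect_error(ar1_L_prime(1), "\\[0, 1\\)")
})
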