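# Bayesian logistic regression: posterior, MAP fit, observed information,
# preconditioned posterior sampling.

test_that("log posterior value, gradient and Hessian are consistent", {
  dat <- generate_logistic(logistic_gen_spec(n = 200, d = 4, seed = 3))
  # at theta = 0 the likelihood of every observation is 1/2
  expect_equal(log_posterior(numeric(4), dat), -200 * log(2))

  f <- function(th) log_posterior(th, dat)
  set.seed(9)
  for (i in 1:3) {
    th <- rnorm(4, 0, 0.7)
    lp <- log_posterior(th, dat, derivatives = TRUE)
    g <- attr(lp, "gradient")
    H <- attr(lp, "hessian")
    expect_equal(g, fd_gradient(f, th), tolerance = 1e-6)
    expect_equal(H, fd_hessian(f, th), tolerance = 1e-4)
    # data part of the negative Hessian is sum_i p_i (1 - p_i) x_i x_i'
    p <- plogis(drop(dat$X %*% th))
    expect_equal(-H - diag(4) / 100,
                 unname(crossprod(dat$X * (p * (1 - p)), dat$X)),
                 tolerance = 1e-8)
  }
})

test_that("MAP solves the balanced toy exactly; obs_info is n-invariant", {
  X <- cbind(1, c(0, 0, 1, 1))
  r <- c(0, 1, 0, 1)
  dat <- logistic_data(X, r)
  fit <- fit_map(dat)
  expect_equal(coef(fit), c(0, 0), tolerance = 1e-9)
  expect_true(fit$converged)

  # doubling every observation leaves the standardized information unchanged
  dat2 <- logistic_data(rbind(X, X), c(r, r))
  expect_equal(fit_map(dat2)$obs_info, fit$obs_info, tolerance = 1e-9)

  expect_error(logistic_data(X[, 2:1], r), "ones")
  expect_error(logistic_data(X, c(0, 1, 2, 1)), "binary")
})

test_that("MAP and observed information are consistent on synthetic data", {
  spec <- logistic_gen_spec(n = 4866, d = 9, seed = 23)
  dat <- generate_logistic(spec)
  fit <- fit_map(dat)
  expect_true(fit$converged)
  expect_lt(sqrt(sum((coef(fit) - spec$theta0)^2)), 0.3)

  fisher <- true_fisher_information(spec, n_mc = 2e5)$info$matrix
  rel_frob <- norm(fit$obs_info - fisher, "F") / norm(fisher, "F")
  expect_lt(rel_frob, 0.15)
})

test_that("complete separation is detected as a divergent fit", {
  X <- cbind(1, c(-2, -1.5, -1, 1, 1.5, 2))
  r <- c(0, 0, 0, 1, 1, 1)
  dat <- logistic_data(X, r)
  expect_error(fit_map(dat, prior_sd = 1e8), "separat|converge")
  # with a proper prior the MAP exists and is finite
  fit <- fit_map(dat, prior_sd = 10)
  expect_true(fit$converged)
  expect_true(all(is.finite(coef(fit))))
})

test_that("posterior chain acceptance matches the limiting chain", {
  dat <- generate_logistic(logistic_gen_spec(n = 2000, d = 5, seed = 11))
  res <- tune_and_sample_posterior(dat, "cholesky", n_steps = 2e4, seed = 7)
  lim <- acceptance_matched(res$ell, 5)$value
  expect_lt(abs(res$summary$acceptance_rate - lim), 0.03)
  # standardized metric ESJD is near the limiting ESJD as well
  expect_lt(abs(res$summary$esjd - esjd_matched(res$ell, 5)$value),
            max(0.1, 5 * res$summary$esjd_se))

  res_i <- tune_and_sample_posterior(dat, "identity", n_steps = 2e4,
                                     seed = 7, mc_samples = 5e4)
  expect_lt(res_i$summary$min_ess_per_iter, res$summary$min_ess_per_iter)
})

test_that("posterior acceptance error shrinks as n grows", {
  # weak-convergence check: the finite-n posterior chain approaches the
  # limiting Gaussian chain; sample sizes are chosen so the large-sample
  # bias at the smallest n clearly dominates chain Monte Carlo noise
  lim <- acceptance_matched(2.39, 9)$value
  errs <- vapply(c(30, 100, 1000), function(n) {
    med <- vapply(1:5, function(s) {
      dat <- generate_logistic(
        logistic_gen_spec(n = n, d = 9, seed = 100 + s)
      )
      res <- tune_and_sample_posterior(dat, "cholesky", ell = 2.39,
                                       n_steps = 2e4, seed = 200 + s)
      abs(res$summary$acceptance_rate - lim)
    }, 0)
    median(med)
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("logistic CSV round trip preserves the dataset", {
  dat <- generate_logistic(logistic_gen_spec(n = 150, d = 4, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_logistic_csv(dat, path)
  back <- read_logistic_csv(path)
  expect_equal(unname(back$X), unname(dat$X), tolerance = 1e-10)
  expect_equal(back$r, dat$r)
  expect_error(read_logistic_csv({
    p <- withr::local_tempfile(fileext = ".csv")
    write.csv(data.frame(a = 1:3), p, row.names = FALSE)
    p
  }), "'r'")
})
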