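# ---------------------------------------------------------------------------
# Synthetic-data generators: logistic-regression datasets with an intercept
# and AR(1)-correlated Gaussian covariates, and the matching Fisher
# information. The defaults (n = 4866, d = 9, moderate covariate
# correlation) emulate the shape of a realistic moderate-dimensional
# regression study.
# ---------------------------------------------------------------------------

#' Specification of a synthetic logistic-regression generator
#'
#' Covariates 2..d are zero-mean unit-variance Gaussians with AR(1)
#' correlation `covariate_rho` (inducing the non-negligible posterior
#' correlation that separates isotropic from preconditioned proposals);
#' responses are Bernoulli with success probability
#' \eqn{\mathrm{logit}^{-1}(x_i^T\theta_0)}.
#'
#' @param n number of observations.
#' @param d number of coefficients including the intercept.
#' @param covariate_rho AR(1) correlation of the covariates, in `[0, 1)`.
#' @param theta0 true coefficients; if `NULL`, drawn once from
#'   N(0, 0.5^2) per coordinate under `seed`.
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return an object of class `"logistic_gen_spec"`.
#' @export
logistic_gen_spec <- function(n = 4866, d = 9, covariate_rho = 0.5,
                              theta0 = NULL, seed = 1) {
  stopifnot(n >= 2, d >= 1, covariate_rho >= 0, covariate_rho < 1)
  if (is.null(theta0)) {
    set.seed(derive_seed(seed, 777L))
    theta0 <- stats::rnorm(d, 0, 0.5)
  }
  if (length(theta0) != d) stop("theta0 has wrong length")
  structure(
    list(n = as.integer(n), d = as.integer(d),
         covariate_rho = covariate_rho, theta0 = theta0,
         seed = as.integer(seed)),
    class = "logistic_gen_spec"
  )
}

# n x d design matrix: intercept column + AR(1)-correlated covariates
simulate_design <- function(n, d, rho) {
  if (d == 1L) return(matrix(1, n, 1))
  Rc <- chol(ar1_covariance(rho, d - 1L))
  cbind(1, matrix(stats::rnorm(n * (d - 1L)), n, d - 1L) %*% Rc)
}

#' Generate a synthetic logistic-regression dataset
#'
#' @param spec a [logistic_gen_spec()] (or arguments forwarded to it).
#' @param ... forwarded to [logistic_gen_spec()] when `spec` is missing.
#' @return a [logistic_data] carrying `theta0`.
#' @examples
#' dat <- generate_logistic(logistic_gen_spec(n = 500, d = 3, seed = 42))
#' mean(dat$r)
#' @export
generate_logistic <- function(spec = NULL, ...) {
  if (is.null(spec)) spec <- logistic_gen_spec(...)
  stopifnot(inherits(spec, "logistic_gen_spec"))
  set.seed(spec$seed)
  X <- simulate_design(spec$n, spec$d, spec$covariate_rho)
  p <- stats::plogis(drop(X %*% spec$theta0))
  r <- as.numeric(stats::runif(spec$n) < p)
  colnames(X) <- paste0("x", seq_len(spec$d))
  logistic_data(X, r, theta0 = spec$theta0)
}

#' Fisher information of the synthetic logistic generator
#'
#' Monte Carlo estimate of \eqn{E[p(1-p)\, X X^T]} at the true coefficients,
#' from fresh covariate draws — the population counterpart of the
#' standardized observed information that [fit_map()] reports. Standard
#' errors are computed entrywise by batch means and returned alongside.
#'
#' @param spec a [logistic_gen_spec()].
#' @param n_mc number of Monte Carlo covariate draws.
#' @param seed seed for the fresh draws (defaults to a derivation of
#'   `spec$seed` so it is decoupled from the dataset itself).
#' @return a list with `info` (an [info_metric]), `se` (d x d entrywise
#'   standard errors), and `n_mc`.
#' @export
true_fisher_information <- function(spec, n_mc = 1e6, seed = NULL) {
  stopifnot(inherits(spec, "logistic_gen_spec"))
  if (is.null(seed)) seed <- derive_seed(spec$seed, 88888L)
  set.seed(seed)
  d <- spec$d
  n_batch <- 50L
  bsize <- ceiling(n_mc / n_batch)
  acc <- matrix(0, d, d)
  acc2 <- matrix(0, d, d)
  for (b in seq_len(n_batch)) {
    X <- simulate_design(bsize, d, spec$covariate_rho)
    p <- stats::plogis(drop(X %*% spec$theta0))
    w <- p * (1 - p)
    Fb <- crossprod(X * w, X) / bsize
    acc <- acc + Fb
    acc2 <- acc2 + Fb^2
  }
  fisher <- acc / n_batch
  se <- sqrt(pmax(acc2 / n_batch - fisher^2, 0) / n_batch)
  list(info = info_metric(fisher), se = se, n_mc = n_batch * bsize)
}
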