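#' Information metric for ESJD norms and proposal preconditioning
#'
#' Wraps a symmetric positive-definite matrix, interpreted as the Fisher
#' information \eqn{I(\theta_0)} of the target (or an estimate such as the
#' standardized observed information). The object carries the matrix itself,
#' its inverse (the limiting target covariance under a Bernstein-von Mises
#' approximation) and the lower Cholesky factor \eqn{M} of the inverse, so
#' that \eqn{M M^T = I(\theta_0)^{-1}}. The matrix defines the norm
#' \eqn{\|v\|_I^2 = v^T I v} used in squared-jump-distance computations, and
#' \eqn{M} is the natural proposal preconditioner.
#'
#' @param matrix a d x d symmetric positive-definite numeric matrix.
#' @param tol relative symmetry tolerance.
#'
#' @return An object of class `"info_metric"`: a list with elements
#'   `matrix`, `inverse`, `chol_factor` (lower triangular), and `d`.
#' @examples
#' im <- info_metric(diag(2))
#' im$chol_factor %*% t(im$chol_factor)  # reproduces the inverse
#' @export
info_metric <- function(matrix, tol = 1e-10) {
  if (inherits(matrix, "info_metric")) return(matrix)
  m <- as.matrix(matrix)
  if (!is.numeric(m) || nrow(m) != ncol(m)) {
    stop("`matrix` must be a square numeric matrix")
  }
  sc <- max(abs(m), 1e-300)
  if (max(abs(m - t(m))) > tol * sc) {
    stop("`matrix` is not symmetric to within tolerance ", tol)
  }
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf(
      "information matrix is not positive definite: smallest eigenvalue %.6g",
      min(ev)
    ))
  }
  R <- chol(m)                 # m = R'R, R upper triangular
  inv <- chol2inv(R)
  structure(
    list(
      matrix = m,
      inverse = inv,
      chol_factor = t(chol(inv)),
      d = nrow(m)
    ),
    class = "info_metric"
  )
}

#' @export
print.info_metric <- function(x, ...) {
  cat(sprintf("Information metric (d = %d)\n", x$d))
  cat(sprintf(
    "  eigenvalue range of I: [%.4g, %.4g]\n",
    min(eigen(x$matrix, symmetric = TRUE, only.values = TRUE)$values),
    max(eigen(x$matrix, symmetric = TRUE, only.values = TRUE)$values)
  ))
  invisible(x)
}

#' @export
dim.info_metric <- function(x) c(x$d, x$d)

# squared metric norms of the rows of a matrix: ||e_k||_I^2 = e_k' I e_k
metric_quadform <- function(E, info) {
  rowSums((E %*% info$matrix) * E)
}

#' Autoregressive-of-order-1 covariance and its information metric
#'
#' `ar1_covariance()` builds the d x d matrix with entries
#' \eqn{\rho^{|i-j|}} (unit marginal variances, exponentially decaying
#' correlation). Its inverse is tridiagonal. `ar1_info()` returns the
#' [info_metric] whose *inverse* (the target covariance) is this matrix.
#'
#' @param rho correlation parameter, `|rho| < 1`.
#' @param d dimension.
#' @return a d x d matrix, or an `info_metric` for `ar1_info()`.
#' @examples
#' ar1_covariance(0.5, 3)
#' @export
ar1_covariance <- function(rho, d) {
  if (abs(rho) >= 1) stop("`rho` must satisfy |rho| < 1")
  rho^abs(outer(seq_len(d), seq_len(d), "-"))
}

#' @rdname ar1_covariance
#' @export
ar1_info <- function(rho, d) {
  sigma <- ar1_covariance(rho, d)
  info_metric(chol2inv(chol(sigma)))
}
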