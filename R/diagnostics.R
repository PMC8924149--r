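# ---------------------------------------------------------------------------
# Chain diagnostics: acceptance rate, empirical ESJD in an information
# metric, and minimum marginal effective sample size per iteration.
# ---------------------------------------------------------------------------

chain_states <- function(x) {
  if (inherits(x, "rwm_chain")) x$states
  else if (is.matrix(x)) x
  else as.matrix(x)
}

#' Empirical expected squared jumping distance of a chain
#'
#' Averages \eqn{\|Z_{k+1} - Z_k\|_I^2} over the chain, the empirical
#' counterpart of the stationary ESJD of the limiting theory. The standard
#' error is computed by non-overlapping batch means with about \eqn{\sqrt T}
#' batches (the per-step squared jumps are autocorrelated).
#'
#' @param chain an `rwm_chain` or a T x d matrix of states.
#' @param metric an [info_metric] (or SPD matrix); identity if `NULL`.
#' @return an [efficiency_value] with `method = "monte_carlo"`.
#' @export
empirical_esjd <- function(chain, metric = NULL) {
  X <- chain_states(chain)
  if (nrow(X) < 2L) stop("chain length must be >= 2")
  d <- ncol(X)
  if (is.null(metric)) metric <- info_metric(diag(d))
  metric <- info_metric(metric)
  if (metric$d != d) stop("metric dimension does not match chain")
  D <- X[-1L, , drop = FALSE] - X[-nrow(X), , drop = FALSE]
  q <- metric_quadform(D, metric)
  nb <- max(2L, floor(sqrt(length(q))))
  bsize <- floor(length(q) / nb)
  bm <- colMeans(matrix(q[seq_len(nb * bsize)], nrow = bsize))
  se <- stats::sd(bm) / sqrt(nb)
  efficiency_value(mean(q), std_error = max(se, .Machine$double.xmin),
                   method = "monte_carlo", n_samples = length(q))
}

# autocovariance function (biased, 1/T normalisation) via FFT
autocov_fft <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  m <- stats::nextn(2L * n, 2L)
  f <- stats::fft(c(xc, rep(0, m - n)))
  Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] /
    (as.numeric(m) * n)
}

#' Effective sample size of a scalar series
#'
#' Geyer's initial monotone positive sequence estimator: autocovariances are
#' summed in adjacent pairs, the sum is truncated at the first nonpositive
#' pair and the pair sequence is forced nonincreasing, giving the integrated
#' autocorrelation time \eqn{\tau} and \eqn{ESS = T/\tau}. A constant series
#' has no information and returns 0 with a warning.
#'
#' @param x numeric vector (one chain coordinate).
#' @return the effective sample size (can slightly exceed `length(x)` for
#'   anticorrelated series).
#' @examples
#' ess(rnorm(1000))  # close to 1000
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 10L) stop("series too short for an ESS estimate")
  ac <- autocov_fft(x)
  if (ac[1] <= 0 || !is.finite(ac[1])) {
    warning("constant coordinate: ESS reported as 0")
    return(0)
  }
  rho <- ac / ac[1]
  # pair sums Gamma_m = rho_{2m} + rho_{2m+1}: nonnegative and nonincreasing
  # for a reversible chain; truncate at the first violation
  gsum <- 0
  prev <- Inf
  m <- 0L
  while (2L * m + 2L <= n) {
    g <- rho[2L * m + 1L] + rho[2L * m + 2L]
    if (!is.finite(g) || g <= 0) break
    g <- min(g, prev)
    gsum <- gsum + g
    prev <- g
    m <- m + 1L
  }
  tau <- max(2 * gsum - 1, .Machine$double.eps)  # = 1 + 2 sum_k rho_k
  n / tau
}

#' Chain summary: acceptance, metric ESJD, minimum marginal ESS/iteration
#'
#' Computes the per-coordinate effective sample sizes (via [ess()]) of a
#' chain, their minimum divided by the chain length (the scale-free
#' performance measure used for cross-correlation comparisons, since the
#' metric ESJD is standardized by construction), the acceptance rate, and,
#' when `metric` is supplied, the empirical metric ESJD with its batch-means
#' standard error.
#'
#' @param chain an `rwm_chain`, or a T x d matrix of (possibly IID) draws.
#' @param metric optional [info_metric] for the ESJD.
#' @return an object of class `"chain_summary"`: list with
#'   `acceptance_rate` (NA for a bare matrix), `esjd`, `esjd_se`,
#'   `min_ess_per_iter`, `ess_per_coordinate`, `n_steps`.
#' @export
chain_summary <- function(chain, metric = NULL) {
  X <- chain_states(chain)
  if (nrow(X) < 100L) stop("chain length must be >= 100 for a summary")
  ess_j <- vapply(seq_len(ncol(X)), function(j) ess(X[, j]), 0)
  ej <- if (is.null(metric)) list(value = NA_real_, std_error = NA_real_)
        else empirical_esjd(X, metric)
  structure(
    list(
      acceptance_rate = if (inherits(chain, "rwm_chain"))
        chain$acceptance_rate else NA_real_,
      esjd = ej$value, esjd_se = ej$std_error,
      min_ess_per_iter = min(ess_j) / nrow(X),
      ess_per_coordinate = ess_j,
      n_steps = nrow(X)
    ),
    class = "chain_summary"
  )
}

#' @rdname chain_summary
#' @export
ess_min_per_iteration <- function(chain) chain_summary(chain)

#' @export
summary.rwm_chain <- function(object, metric = NULL, ...) {
  chain_summary(object, metric = metric)
}

#' @export
print.chain_summary <- function(x, ...) {
  cat(sprintf("Chain summary (%d steps)\n", x$n_steps))
  if (!is.na(x$acceptance_rate)) {
    cat(sprintf("  acceptance rate  : %.4f\n", x$acceptance_rate))
  }
  if (!is.na(x$esjd)) {
    cat(sprintf("  metric ESJD      : %.4f (se %.2g)\n", x$esjd, x$esjd_se))
  }
  cat(sprintf("  min ESS/iteration: %.4f\n", x$min_ess_per_iter))
  invisible(x)
}

#' JSON summary of a chain
#'
#' @param chain an `rwm_chain`.
#' @param path output file.
#' @param metric optional [info_metric] for the ESJD entry.
#' @return `path`, invisibly.
#' @export
write_chain_summary_json <- function(chain, path, metric = NULL) {
  s <- chain_summary(chain, metric = metric)
  jsonlite::write_json(
    list(acceptance_rate = s$acceptance_rate, esjd = s$esjd,
         esjd_se = s$esjd_se, min_ess_per_iter = s$min_ess_per_iter,
         seed = chain$seed),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}
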