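# ---------------------------------------------------------------------------
# Generic seeded random walk Metropolis: theta' = theta + S eps,
# accepted with probability min{1, pi(theta')/pi(theta)} (log-domain).
# ---------------------------------------------------------------------------

#' Target distribution for random walk Metropolis
#'
#' @param dim dimension of the state space.
#' @param log_density function mapping a length-`dim` numeric vector to the
#'   log target density (up to an additive constant); must return `-Inf`
#'   outside the support and a finite value at any valid chain state.
#' @param exact_sampler optional function `function(n)` returning an
#'   `n x dim` matrix of exact stationary draws (available for Gaussian
#'   targets); enables `init = "stationary"` in [run_chain()].
#' @param name descriptor stored with chains.
#' @return an object of class `"target_density"`.
#' @export
target_density <- function(dim, log_density, exact_sampler = NULL,
                           name = "target") {
  stopifnot(is.numeric(dim), length(dim) == 1L, dim >= 1,
            is.function(log_density),
            is.null(exact_sampler) || is.function(exact_sampler))
  structure(
    list(dim = as.integer(dim), log_density = log_density,
         exact_sampler = exact_sampler, name = name),
    class = "target_density"
  )
}

#' Zero-mean Gaussian target with exact stationary sampler
#'
#' @param sigma covariance matrix (SPD).
#' @param name descriptor.
#' @return a [target_density].
#' @examples
#' tg <- gaussian_target(ar1_covariance(0.5, 3))
#' @export
gaussian_target <- function(sigma, name = "gaussian") {
  sigma <- as.matrix(sigma)
  R <- chol(sigma)             # sigma = R'R
  Q <- chol2inv(R)
  d <- nrow(sigma)
  target_density(
    dim = d,
    log_density = function(z) -0.5 * sum(z * (Q %*% z)),
    exact_sampler = function(n) {
      matrix(stats::rnorm(n * d), n, d) %*% R
    },
    name = name
  )
}

#' One random walk Metropolis step
#'
#' Proposes `state + scaling$matrix %*% eps` with standard normal `eps` and
#' accepts in the log domain (`log U < log pi(theta') - log pi(theta)`); a
#' proposal with `-Inf` log density is never accepted. Uses the current R
#' random number stream.
#'
#' @param state current state (finite log density required).
#' @param target a [target_density].
#' @param scaling a [proposal_scaling].
#' @param lp log density at `state`, if already known.
#' @return list with `state`, `accepted`, `log_density`.
#' @export
rwm_step <- function(state, target, scaling, lp = NULL) {
  if (is.null(lp)) lp <- target$log_density(state)
  if (!is.finite(lp)) stop("log density at the current state is not finite")
  prop <- state + as.vector(scaling$matrix %*% stats::rnorm(target$dim))
  lp_prop <- target$log_density(prop)
  if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
    list(state = prop, accepted = TRUE, log_density = lp_prop)
  } else {
    list(state = state, accepted = FALSE, log_density = lp)
  }
}

#' Run a seeded random walk Metropolis chain
#'
#' Simulates `n_steps` RWM transitions with proposal increments
#' \eqn{S\epsilon}. All randomness (initial state, proposal increments,
#' acceptance uniforms) derives from `seed`, so identical seeds give bitwise
#' identical chains. `init = "stationary"` draws the initial state from the
#' target's exact sampler (required for stationary-expectation comparisons);
#' otherwise supply a numeric starting vector, e.g. a posterior mode, and a
#' positive `burn_in` to discard the transient.
#'
#' @param target a [target_density].
#' @param scaling a [proposal_scaling] with matching dimension.
#' @param n_steps number of retained transitions (>= 1).
#' @param init `"stationary"` or a length-d numeric vector.
#' @param seed integer seed (mandatory).
#' @param burn_in number of initial transitions to simulate and discard
#'   before recording (default 0).
#' @return an object of class `"rwm_chain"`: list with `states`
#'   (`n_steps x d`), `accepted` (logical), `acceptance_rate`, `seed`,
#'   `scaling`, `target_name`, `init`, `burn_in`.
#' @examples
#' tg <- gaussian_target(diag(1))
#' ch <- run_chain(tg, build_scaling(2.42, 1, mode = "identity"),
#'                 n_steps = 1000, seed = 1)
#' mean(ch$accepted)
#' @export
run_chain <- function(target, scaling, n_steps, init = "stationary", seed,
                      burn_in = 0L) {
  stopifnot(inherits(target, "target_density"),
            inherits(scaling, "proposal_scaling"))
  if (scaling$d != target$dim) {
    stop("dimension mismatch between target and scaling")
  }
  if (!is.numeric(n_steps) || n_steps < 1) stop("`n_steps` must be >= 1")
  if (missing(seed) || !is.finite(seed)) stop("`seed` is required")
  n_steps <- as.integer(n_steps)
  burn_in <- as.integer(burn_in)
  d <- target$dim

  set.seed(seed)
  if (identical(init, "stationary")) {
    if (is.null(target$exact_sampler)) {
      stop("`init = \"stationary\"` requires a target with an exact_sampler")
    }
    x <- as.vector(target$exact_sampler(1L))
  } else {
    x <- as.numeric(init)
    if (length(x) != d) stop("`init` has wrong length")
  }
  lp <- target$log_density(x)
  if (!is.finite(lp)) stop("log density at the initial state is not finite")

  total <- burn_in + n_steps
  # pre-drawn proposal increments and log-uniforms: one stream per chain
  inc <- matrix(stats::rnorm(total * d), total, d) %*% t(scaling$matrix)
  logu <- log(stats::runif(total))

  states <- matrix(0, n_steps, d)
  accepted <- logical(n_steps)
  logd <- target$log_density
  for (k in seq_len(total)) {
    xp <- x + inc[k, ]
    lpp <- logd(xp)
    if (is.finite(lpp) && logu[k] < lpp - lp) {
      x <- xp
      lp <- lpp
      acc <- TRUE
    } else {
      acc <- FALSE
    }
    if (k > burn_in) {
      states[k - burn_in, ] <- x
      accepted[k - burn_in] <- acc
    }
  }
  structure(
    list(states = states, accepted = accepted,
         acceptance_rate = mean(accepted),
         seed = seed, scaling = scaling, target_name = target$name,
         init = if (identical(init, "stationary")) "stationary" else "fixed",
         burn_in = burn_in),
    class = "rwm_chain"
  )
}

#' @export
print.rwm_chain <- function(x, ...) {
  cat(sprintf(
    "RWM chain: %d steps, d = %d, target '%s' (%s init, burn-in %d)\n",
    nrow(x$states), ncol(x$states), x$target_name, x$init, x$burn_in
  ))
  cat(sprintf("  seed %d, %s proposal, ell = %.3g\n",
              x$seed, x$scaling$mode, x$scaling$ell))
  cat(sprintf("  acceptance rate: %.4f\n", x$acceptance_rate))
  invisible(x)
}

#' @export
plot.rwm_chain <- function(x, coords = seq_len(min(ncol(x$states), 4L)),
                           ...) {
  op <- graphics::par(mfrow = c(length(coords), 1),
                      mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  for (j in coords) {
    graphics::plot(x$states[, j], type = "l",
                   ylab = bquote(theta[.(j)]), xlab = "", ...)
  }
  invisible(x)
}

#' @export
as.data.frame.rwm_chain <- function(x, ...) {
  df <- as.data.frame(x$states)
  names(df) <- paste0("theta", seq_len(ncol(x$states)))
  df$accepted <- x$accepted
  df
}

#' Export a chain to CSV, one row per iteration
#'
#' @param chain an [run_chain()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_chain_csv <- function(chain, path) {
  utils::write.csv(as.data.frame(chain), path, row.names = FALSE)
  invisible(path)
}
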