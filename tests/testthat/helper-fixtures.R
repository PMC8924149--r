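# shared helpers: batch-means standard errors, hand-built chains, and
# finite-difference derivatives used as independent oracles

batch_se <- function(x) {
  nb <- max(2L, floor(sqrt(length(x))))
  bs <- floor(length(x) / nb)
  bm <- colMeans(matrix(x[seq_len(nb * bs)], bs))
  stats::sd(bm) / sqrt(nb)
}

# rwm_chain object with prescribed states, bypassing the sampler
fake_chain <- function(states, accepted = rep(TRUE, nrow(states))) {
  structure(
    list(states = states, accepted = accepted,
         acceptance_rate = mean(accepted), seed = 0L,
         scaling = NULL, target_name = "manual", init = "fixed",
         burn_in = 0L),
    class = "rwm_chain"
  )
}

fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, 0)
}

fd_hessian <- function(f, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  for (i in seq_len(d)) {
    ei <- numeric(d); ei[i] <- h
    H[, i] <- (fd_gradient(f, x + ei, h) - fd_gradient(f, x - ei, h)) / (2 * h)
  }
  (H + t(H)) / 2
}
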