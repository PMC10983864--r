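# shared fixture builders (generated in code; no stored data)

# ensemble of 1-D logistic maps started from jittered initial
# conditions; rows = iterations, columns = replicates
logistic_ensemble <- function(r, n_reps, n_iter, x0 = 0.3,
                              jitter = 1e-7) {
  sapply(seq_len(n_reps), function(j) {
    x <- x0 + jitter * stats::runif(1)
    out <- numeric(n_iter)
    for (i in seq_len(n_iter)) {
      out[i] <- x
      x <- r * x * (1 - x)
    }
    out
  })
}

# linear (non-chaotic) dynamics with additive observation noise
linear_noise_ensemble <- function(n_reps, n_iter, slope = 0.01,
                                  noise_sd = 0.005, x0 = 0.3) {
  sapply(seq_len(n_reps), function(j) {
    x0 + slope * (seq_len(n_iter) - 1) +
      stats::rnorm(n_iter, 0, noise_sd)
  })
}

# diffusive (drift-like) ensemble: between-replicate variance grows
# linearly in time, the non-chaotic alternative to exponential growth
random_walk_ensemble <- function(n_reps, n_iter, step_sd = 0.01,
                                 x0 = 0.3) {
  sapply(seq_len(n_reps), function(j)
    x0 + c(0, cumsum(stats::rnorm(n_iter - 1, 0, step_sd))))
}

# standing symmetric covariance structure used across tests
sym_cov <- function(c1 = 0.005, rho = 0.5, drift = 1) {
  cov_structure(c0A = drift + c1, c0B = drift + c1,
                c1A = c1, c1B = c1, cAB = rho * c1)
}
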