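#' Parameters for the correlated-noise Langevin simulator
#'
#' Two-genotype logistic abundance dynamics with demographic noise and
#' correlated multiplicative (environment-like) noise:
#' \deqn{\frac{dN_i}{dt} = \left(\mu_i - \frac{N_{tot}}{K}\right) N_i
#'   + N_i \xi_i(t) + \sqrt{N_i \left(\mu_i + \frac{N_{tot}}{K}\right)}\,
#'   \eta_i(t),}
#' where \eqn{\eta_i} is standard Gaussian white noise and
#' \eqn{(\xi_A, \xi_B)} is Gaussian white noise with covariance
#' `c1A`, `c1B` on the diagonal and
#' \eqn{\rho_{AB}\sqrt{c_{1A} c_{1B}}} off-diagonal.
#'
#' In the diffusion limit this maps onto the frequency process with
#' effective population size \eqn{N_e = K/2}, fitness effect
#' \eqn{s = \mu_A - \mu_B} and decoupling parameter
#' \eqn{\delta = c_{1A} + c_{1B} - 2\rho_{AB}\sqrt{c_{1A} c_{1B}}}.
#'
#' Defaults follow the standing simulation conditions used throughout
#' the package: \eqn{K/2 = 10^3}, \eqn{\mu_A = 1},
#' \eqn{\rho_{AB} = 0.5}, \eqn{\Delta t = 0.1}, initial abundances
#' \eqn{N_A = 10^{-3} K}, \eqn{N_B = K}.
#'
#' @param muA,muB Per-capita growth rates (1/time).
#' @param K Carrying-capacity scale (individuals, > 0).
#' @param c1A,c1B Correlated-noise amplitudes (1/time, >= 0).
#' @param rhoAB Correlation of the two noise components, in [-1, 1].
#' @param dt Integration step (time, > 0).
#' @param demographic_noise Set `FALSE` to disable the
#'   \eqn{\sqrt{N(\mu + N_{tot}/K)}} demographic term (deterministic
#'   oracle mode for checking fixed points and the correlated-noise
#'   term in isolation).
#' @return An object of class `"langevin_params"`.
#' @export
langevin_params <- function(muA = 1, muB = 1, K = 2000,
                            c1A = 0, c1B = 0, rhoAB = 0.5, dt = 0.1,
                            demographic_noise = TRUE) {
  stopifnot(K > 0, dt > 0, abs(rhoAB) <= 1, c1A >= 0, c1B >= 0)
  structure(list(muA = muA, muB = muB, K = K, c1A = c1A, c1B = c1B,
                 rhoAB = rhoAB, dt = dt,
                 demographic_noise = isTRUE(demographic_noise),
                 s = muA - muB,
                 delta = c1A + c1B - 2 * rhoAB * sqrt(c1A * c1B)),
            class = "langevin_params")
}

#' @export
print.langevin_params <- function(x, ...) {
  cat(sprintf(
    "Langevin parameters: muA=%g muB=%g K=%g c1A=%g c1B=%g rhoAB=%g dt=%g\n",
    x$muA, x$muB, x$K, x$c1A, x$c1B, x$rhoAB, x$dt))
  cat(sprintf("  implied s=%g, delta=%g, Ne=K/2=%g\n", x$s, x$delta, x$K / 2))
  invisible(x)
}

# One Euler-Maruyama step for vectors of replicate states.
# NA_, NB_ are abundance vectors; returns clamped next abundances.
# Extinct (zero) genotypes stay extinct: both noise amplitudes and the
# deterministic term vanish at N = 0.
step_langevin_vec <- function(NA_, NB_, p) {
  n <- length(NA_)
  Ntot <- NA_ + NB_
  sdt <- sqrt(p$dt)
  # correlated multiplicative noise
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  xiA <- sqrt(p$c1A) * z1
  xiB <- sqrt(p$c1B) * (p$rhoAB * z1 + sqrt(1 - p$rhoAB^2) * z2)
  demog <- if (isTRUE(p$demographic_noise) || is.null(p$demographic_noise))
    1 else 0
  etaA <- stats::rnorm(n); etaB <- stats::rnorm(n)
  dNA <- (p$muA - Ntot / p$K) * NA_ * p$dt + NA_ * xiA * sdt +
    demog * sqrt(pmax(NA_ * (p$muA + Ntot / p$K), 0)) * etaA * sdt
  dNB <- (p$muB - Ntot / p$K) * NB_ * p$dt + NB_ * xiB * sdt +
    demog * sqrt(pmax(NB_ * (p$muB + Ntot / p$K), 0)) * etaB * sdt
  list(N_A = pmax(NA_ + dNA, 0), N_B = pmax(NB_ + dNB, 0))
}

#' One Langevin step
#'
#' Advances a single two-genotype abundance state by one Euler-Maruyama
#' step of the correlated-noise Langevin dynamics (see
#' [langevin_params()]).  Negative abundances are clamped at zero,
#' which is treated as absorbing.
#'
#' @param state Named list or vector with `N_A`, `N_B` (>= 0).
#' @param params A [langevin_params()].
#' @return List with next `N_A`, `N_B`.
#' @export
step_langevin <- function(state, params) {
  stopifnot(inherits(params, "langevin_params"))
  state <- as.list(state)
  stopifnot(state$N_A >= 0, state$N_B >= 0)
  out <- step_langevin_vec(state$N_A, state$N_B, params)
  if (!is.finite(out$N_A) || !is.finite(out$N_B))
    stop("non-finite abundance produced: contract violation")
  out
}

#' Simulate a Langevin abundance trajectory
#'
#' @param params A [langevin_params()].
#' @param n_steps Number of steps.
#' @param N_A0,N_B0 Initial abundances; defaults follow the standing
#'   conditions (`1e-3 * K` and `K`).
#' @return A data.frame with columns `time`, `N_A`, `N_B`, `f`
#'   (frequency of A, `NA` where the population is extinct).
#' @export
simulate_langevin <- function(params, n_steps,
                              N_A0 = 1e-3 * params$K, N_B0 = params$K) {
  stopifnot(inherits(params, "langevin_params"), n_steps >= 1)
  NA_ <- numeric(n_steps + 1); NB <- numeric(n_steps + 1)
  NA_[1] <- N_A0; NB[1] <- N_B0
  for (i in seq_len(n_steps)) {
    st <- step_langevin_vec(NA_[i], NB[i], params)
    NA_[i + 1] <- st$N_A; NB[i + 1] <- st$N_B
  }
  Ntot <- NA_ + NB
  data.frame(time = (0:n_steps) * params$dt, N_A = NA_, N_B = NB,
             f = ifelse(Ntot > 0, NA_ / Ntot, NA_real_))
}

#' Monte-Carlo fixation probability under the Langevin dynamics
#'
#' Runs `n_reps` independent trajectories from initial abundances
#' `(N_A0, N_B0)` until one genotype fixes.  A genotype is considered
#' fixed when the other genotype's abundance drops below
#' `extinction_threshold` (default 0.1 individuals).  Returns the
#' fraction of replicates in which genotype A fixed, with a Wilson
#' binomial confidence interval.
#'
#' @param params A [langevin_params()].
#' @param n_reps Number of independent replicates (>= 1).
#' @param N_A0,N_B0 Initial abundances.
#' @param extinction_threshold Abundance below which a genotype is
#'   considered extinct.
#' @param max_steps Horizon; exceeding it raises a non-termination
#'   error rather than returning a biased estimate.
#' @param conf Confidence level for the interval.
#' @return List with `pfix`, `ci` (length-2), `n_fixed`, `n_reps`.
#' @export
estimate_fixation_probability <- function(params, n_reps = 1e5,
                                          N_A0 = 1e-3 * params$K,
                                          N_B0 = params$K,
                                          extinction_threshold = 0.1,
                                          max_steps = 1e7,
                                          conf = 0.95) {
  stopifnot(inherits(params, "langevin_params"), n_reps >= 1)
  NA_ <- rep(N_A0, n_reps); NB <- rep(N_B0, n_reps)
  fixedA <- 0L; done <- 0L
  steps <- 0L
  while (length(NA_) > 0) {
    st <- step_langevin_vec(NA_, NB, params)
    NA_ <- st$N_A; NB <- st$N_B
    steps <- steps + 1L
    if (steps > max_steps)
      stop("non-termination: trajectory exceeded max_steps = ", max_steps)
    aWins <- NB < extinction_threshold & NA_ >= extinction_threshold
    bWins <- NA_ < extinction_threshold & !aWins
    absorbed <- aWins | bWins
    if (any(absorbed)) {
      fixedA <- fixedA + sum(aWins)
      done <- done + sum(absorbed)
      keep <- !absorbed
      NA_ <- NA_[keep]; NB <- NB[keep]
    }
  }
  p <- fixedA / n_reps
  z <- stats::qnorm(1 - (1 - conf) / 2)
  den <- 1 + z^2 / n_reps
  centre <- (p + z^2 / (2 * n_reps)) / den
  half <- z * sqrt(p * (1 - p) / n_reps + z^2 / (4 * n_reps^2)) / den
  list(pfix = p, ci = c(max(centre - half, 0), min(centre + half, 1)),
       n_fixed = fixedA, n_reps = n_reps)
}

#' Monte-Carlo site-frequency spectrum under the Langevin dynamics
#'
#' Runs `n_reps` trajectories from a low initial frequency `f0` until
#' fixation (as in [estimate_fixation_probability()]), recording the
#' genotype-A frequency at every timestep, and bins the accumulated
#' sojourn time.  The returned density is the per-bin sojourn-time
#' density divided by \eqn{2 f_0 N_e} (with \eqn{N_e = K/2}), which
#' estimates \eqn{p_{SFS}(f)/\theta}: the normalization under which a
#' neutral drift-only process gives \eqn{1/f}.  The same convention is
#' used by [sfs()] so simulation and quadrature are directly
#' comparable.
#'
#' @param params A [langevin_params()].
#' @param n_reps Number of replicates.
#' @param breaks Bin boundaries for frequency (strictly increasing,
#'   inside (0,1)); defaults to 20 logit-spaced bins.
#' @param N_A0,N_B0 Initial abundances.
#' @param extinction_threshold,max_steps As in
#'   [estimate_fixation_probability()].
#' @return A data.frame with `f_mid`, `density` (estimate of
#'   \eqn{p_{SFS}/\theta}), and `se` (binomial-style Monte-Carlo
#'   standard error from between-replicate variation).
#' @export
estimate_sfs <- function(params, n_reps = 2e4,
                         breaks = plogis(seq(qlogis(1e-3), qlogis(0.999),
                                             length.out = 21)),
                         N_A0 = 1e-3 * params$K, N_B0 = params$K,
                         extinction_threshold = 0.1, max_steps = 1e7) {
  stopifnot(inherits(params, "langevin_params"), n_reps >= 1,
            all(diff(breaks) > 0))
  nb <- length(breaks) - 1
  f0 <- N_A0 / (N_A0 + N_B0)
  Ne <- params$K / 2
  occ <- matrix(0, nrow = n_reps, ncol = nb)  # sojourn time per rep/bin
  NA_ <- rep(N_A0, n_reps); NB <- rep(N_B0, n_reps)
  idx <- seq_len(n_reps)
  steps <- 0L
  while (length(NA_) > 0) {
    st <- step_langevin_vec(NA_, NB, params)
    NA_ <- st$N_A; NB <- st$N_B
    steps <- steps + 1L
    if (steps > max_steps)
      stop("non-termination: trajectory exceeded max_steps = ", max_steps)
    f <- NA_ / (NA_ + NB)
    bin <- findInterval(f, breaks, rightmost.closed = TRUE)
    inb <- bin >= 1 & bin <= nb
    if (any(inb)) {
      ij <- cbind(idx[inb], bin[inb])
      # accumulate dt of sojourn
      occ[ij] <- occ[ij] + params$dt
    }
    aWins <- NB < extinction_threshold & NA_ >= extinction_threshold
    bWins <- NA_ < extinction_threshold & !aWins
    keep <- !(aWins | bWins)
    if (!all(keep)) {
      NA_ <- NA_[keep]; NB <- NB[keep]; idx <- idx[keep]
    }
  }
  width <- diff(breaks)
  norm <- 2 * f0 * Ne
  dens <- colMeans(occ) / width / norm
  se <- apply(occ, 2, stats::sd) / sqrt(n_reps) / width / norm
  mids <- plogis((qlogis(breaks[-1]) + qlogis(breaks[-(nb + 1)])) / 2)
  data.frame(f_mid = mids, density = dens, se = se)
}
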