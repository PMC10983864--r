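#' Diffusion parameters for drift plus decoupling noise
#'
#' Parameter container for the frequency diffusion
#' \deqn{df = a(f)\,dt + \sqrt{v(f)}\,dW,}
#' with variance \eqn{v(f) = f(1-f)/N_e + \delta f^2(1-f)^2} and drift
#' \eqn{a(f) = f(1-f)\,[s_e + \delta(1/2 - f)]}, obtained by Ito
#' reduction of the correlated-noise Langevin abundance dynamics (see
#' [langevin_params()]).  The effective fitness is
#' \eqn{s_e = s + (c_{1B} - c_{1A})/2}; the frequency-dependent drift
#' term \eqn{\delta(1/2 - f)} gives an otherwise-neutral mutant an
#' effective advantage when rare and a disadvantage when common.
#'
#' Either pass the correlated-noise amplitudes `c1A`, `c1B`, `cAB`
#' (from which `delta` and `se` are derived) or pass `delta` directly
#' (in which case `se = s`, the symmetric-noise case).
#'
#' @param Ne Effective population size (> 0).
#' @param s Genuine (constant) fitness effect per generation.
#' @param delta Decoupling parameter (>= 0); ignored if `c1A` given.
#' @param c1A,c1B,cAB Optional correlated-noise covariances.
#' @param theta Population mutation rate (> 0), used by [sfs()].
#' @return An object of class `"diffusion_params"` with fields `Ne`,
#'   `s`, `se`, `delta`, `theta`.
#' @export
diffusion_params <- function(Ne, s = 0, delta = 0,
                             c1A = NULL, c1B = NULL, cAB = NULL,
                             theta = 1) {
  stopifnot(Ne > 0, theta > 0)
  if (!is.null(c1A)) {
    stopifnot(!is.null(c1B), !is.null(cAB), c1A >= 0, c1B >= 0)
    delta <- c1A + c1B - 2 * cAB
    se <- effective_fitness(s, c1A, c1B)
  } else {
    se <- s
  }
  if (delta < 0) stop("decoupling parameter delta must be nonnegative")
  structure(list(Ne = Ne, s = s, se = se, delta = delta, theta = theta),
            class = "diffusion_params")
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat(sprintf("Diffusion parameters: Ne=%g s=%g se=%g delta=%g (deltaNe=%g) theta=%g\n",
              x$Ne, x$s, x$se, x$delta, x$delta * x$Ne, x$theta))
  invisible(x)
}

#' Effective fitness effect
#'
#' \eqn{s_e = s + (c_{1B} - c_{1A})/2}: asymmetry in the
#' within-genotype offspring covariances acts as selection.  A genotype
#' whose offspring numbers fluctuate more coherently (larger `c1A`) is
#' effectively disfavoured.
#'
#' @param s Genuine fitness effect.
#' @param c1A,c1B Within-genotype offspring covariances.
#' @return Effective fitness effect per generation.
#' @export
effective_fitness <- function(s, c1A, c1B) {
  s + (c1B - c1A) / 2
}

#' Infinitesimal drift and variance of the frequency diffusion
#'
#' @param f Frequencies in (0, 1).
#' @param params A [diffusion_params()].
#' @return List with vectors `a` and `v`.
#' @export
drift_and_variance <- function(f, params) {
  stopifnot(inherits(params, "diffusion_params"), all(f > 0), all(f < 1))
  d <- params$delta
  list(a = f * (1 - f) * (params$se + d * (0.5 - f)),
       v = f * (1 - f) / params$Ne + d * f^2 * (1 - f)^2)
}

# G(x) = 2 * integral_0^x a(u)/v(u) du, in closed form.
# 2a/v = (2 se + delta (1 - 2u)) / D(u) with D(u) = 1/Ne + delta u (1-u),
# so G(x) = 2 se I1(x) + log(Ne D(x)), where I1 is the integral of 1/D.
G_exponent <- function(x, params) {
  Ne <- params$Ne; d <- params$delta; se <- params$se
  if (d == 0) return(2 * se * Ne * x)
  R <- sqrt(1 + 4 / (d * Ne))
  up <- (1 + R) / 2
  um <- (1 - R) / 2
  I1 <- (log((x - um) / (up - x)) - log(-um / up)) / (d * R)
  2 * se * I1 + log(Ne * (1 / Ne + d * x * (1 - x)))
}

# scaled integral of psi(u) = exp(-G(u)) over [lo, hi], divided by
# exp(-shift); adaptive quadrature.
integrate_psi <- function(lo, hi, params, shift = 0) {
  if (hi <= lo) return(0)
  fun <- function(u) {
    e <- -G_exponent(u, params) - shift
    if (any(e > 700)) stop("quadrature overflow: parameter regime too extreme")
    exp(e)
  }
  out <- tryCatch(
    stats::integrate(fun, lo, hi, rel.tol = 1e-10, abs.tol = 0,
                     subdivisions = 400L),
    error = function(e) stop("quadrature failure: ", conditionMessage(e)))
  out$value
}

regime_warning <- function(params, warn_deltaNe) {
  if (params$delta * params$Ne > warn_deltaNe)
    warning(sprintf(
      "deltaNe = %g exceeds %g: the first-order diffusion becomes unreliable here",
      params$delta * params$Ne, warn_deltaNe), call. = FALSE)
}

#' Fixation probability under drift plus decoupling noise
#'
#' Evaluates \eqn{p_{fix}(f_0) = \int_0^{f_0}\psi(x)dx /
#' \int_0^1\psi(x)dx} with
#' \eqn{\psi(x) = \exp(-2\int_0^x a(u)/v(u)\,du)} by quadrature over an
#' exact antiderivative of the inner integrand.  When `delta -> 0` this
#' reduces to the classical constant-selection fixation probability
#' \eqn{(1 - e^{-2 s_e N_e f_0})/(1 - e^{-2 s_e N_e})}; when additionally
#' `se = 0` it equals `f0`.  For `se = 0` and `delta > 0` the
#' frequency-dependent effective selection makes
#' \eqn{p_{fix}(f_0) > f_0} at small `f0`.
#'
#' @param f0 Initial frequencies in (0, 1).
#' @param params A [diffusion_params()].
#' @param warn_deltaNe Warn above this value of `delta * Ne`, where the
#'   first-order diffusion starts to diverge from direct simulation.
#' @return Fixation probabilities in [0, 1].
#' @export
fixation_probability <- function(f0, params, warn_deltaNe = 100) {
  stopifnot(inherits(params, "diffusion_params"), all(f0 > 0), all(f0 < 1))
  regime_warning(params, warn_deltaNe)
  # common scale so numerator and denominator share the same offset
  grid <- c(1e-9, seq(0.001, 0.999, length.out = 101), 1 - 1e-9)
  shift <- max(-G_exponent(grid, params))
  total <- integrate_psi(0, 1, params, shift = shift)
  vapply(f0, function(x)
    min(max(integrate_psi(0, x, params, shift = shift) / total, 0), 1),
    numeric(1))
}

#' Decoupling-drift barrier
#'
#' The transition point
#' \eqn{s_e^* \approx \delta / (2\log(\delta N_e))}
#' between the decoupling-dominated and selection-dominated regimes of
#' the fixation probability.  Below \eqn{s_e^*} selection cannot
#' efficiently sort genotypes; the barrier exceeds the classical drift
#' barrier \eqn{1/N_e} by a factor \eqn{\delta N_e / (2\log\delta N_e)}.
#' Defined in the strong-decoupling regime \eqn{\delta N_e > 1} (the
#' asymptotic form requires \eqn{\log\delta N_e} appreciably positive).
#'
#' This form is fixed by the exact neutral limit: with \eqn{s_e = 0}
#' and strong decoupling the fixation probability is
#' \eqn{f_0\,\delta N_e/(2\log \delta N_e) = f_0 N_e s_e^*}, which the
#' quadrature in [fixation_probability()] reproduces.
#'
#' @param delta Decoupling parameter (> 0).
#' @param Ne Effective population size.
#' @return The barrier \eqn{s_e^*} (per generation).
#' @export
transition_point <- function(delta, Ne) {
  if (delta * Ne <= 1)
    stop("out of regime: transition point defined for delta * Ne > 1")
  delta / (2 * log(delta * Ne))
}

#' Piecewise approximation to the fixation probability
#'
#' Strong-decoupling (`delta >> 1/Ne`), small-`f0` approximation:
#' \eqn{p_{fix} \approx f_0 N_e s_e^*} for \eqn{s_e \ll s_e^*} and the
#' classical \eqn{f_0\, 2 s_e N_e/(1 - e^{-2 s_e N_e})} for
#' \eqn{s_e \gg s_e^*}, with the branch switched at \eqn{s_e^*}.
#'
#' @param f0 Initial frequency, small (the approximation requires
#'   \eqn{f_0 \ll (s_e N_e + \delta N_e / 2)^{-1}}).
#' @param params A [diffusion_params()].
#' @return Approximate fixation probability.
#' @export
fixation_probability_piecewise <- function(f0, params) {
  stopifnot(inherits(params, "diffusion_params"), all(f0 > 0), all(f0 < 1))
  d <- params$delta; Ne <- params$Ne; se <- params$se
  if (d * Ne <= 1)
    stop("regime violation: piecewise form requires delta * Ne > 1")
  bound <- 1 / (abs(se) * Ne + d * Ne / 2)
  if (any(f0 > bound))
    stop(sprintf(
      "regime violation: f0 must be below the small-frequency bound %g", bound))
  sstar <- transition_point(d, Ne)
  ifelse(se < sstar,
         f0 * Ne * sstar,
         f0 * 2 * se * Ne / (1 - exp(-2 * se * Ne)))
}

#' Site frequency spectrum under drift plus decoupling noise
#'
#' Expected density of derived alleles at frequency `f`, scaled by the
#' population mutation rate `theta`, from the standard sojourn-time
#' construction for a diffusion with drift `a` and variance `v`:
#' \deqn{p_{SFS}(f) = \frac{\theta}{N_e\,v(f)\,\psi(f)}
#'       \cdot \frac{S(1) - S(f)}{S(1)},}
#' where \eqn{S(x) = \int_0^x \psi} and \eqn{\psi = e^{-G}} as in
#' [fixation_probability()].  The influx constant is calibrated so the
#' neutral drift-only case gives \eqn{\theta/f}; the simulation
#' estimator [estimate_sfs()] uses the same convention.
#'
#' Known limits: neutral `delta = 0, s = 0` gives \eqn{\theta/f};
#' classical strong selection has minimum \eqn{4\theta} at `f = 0.5`
#' and plateau \eqn{2 s_e N_e \theta} near fixation; strong decoupling
#' with `s = 0` gives \eqn{2\theta} at `f = 0.5` and an uptick toward a
#' \eqn{\theta\,\delta N_e/(2\log\delta N_e)} plateau at high `f`.
#'
#' @param f Frequencies in (0, 1), vectorized.
#' @param params A [diffusion_params()] (uses `theta`).
#' @param warn_deltaNe Regime warning threshold as in
#'   [fixation_probability()]; the SFS quadrature itself remains
#'   accurate, the warning concerns agreement with the underlying
#'   abundance dynamics.
#' @return Vector of SFS densities (same units as `theta`).
#' @export
sfs <- function(f, params, warn_deltaNe = Inf) {
  stopifnot(inherits(params, "diffusion_params"), all(f > 0), all(f < 1))
  regime_warning(params, warn_deltaNe)
  v <- drift_and_variance(f, params)$v
  Gf <- vapply(f, G_exponent, 0, params = params)
  # pSFS = theta * A / (Ne * v * S(1)) with
  # A = (S(1) - S(f)) / psi(f) = int_f^1 exp(G(f) - G(u)) du,
  # S(1) computed once on its own stable scale
  grid <- c(1e-9, seq(0.001, 0.999, length.out = 101), 1 - 1e-9)
  shiftB <- max(-G_exponent(grid, params))
  logB <- log(integrate_psi(0, 1, params, shift = shiftB)) + shiftB
  out <- numeric(length(f))
  for (i in seq_along(f)) {
    A <- integrate_psi(f[i], 1, params, shift = -Gf[i])
    out[i] <- exp(log(params$theta) + log(A) -
                    log(params$Ne * v[i]) - logB)
  }
  out
}

#' Closed-form SFS asymptotics
#'
#' Closed-form limiting values of the site frequency spectrum in named
#' parameter regimes:
#' \describe{
#'   \item{`"high_f_strong_decoupling"`}{plateau
#'     \eqn{\theta\,\delta N_e / (2 \log \delta N_e)} for
#'     \eqn{(1-f) \ll (\delta N_e)^{-1}}, requires
#'     \eqn{\delta N_e \gg 1} and weak selection.}
#'   \item{`"high_f_strong_selection"`}{plateau \eqn{2 s_e N_e \theta}
#'     for \eqn{(1-f) \ll (N_e s_e)^{-1}}, requires \eqn{N_e s_e \gg 1}
#'     and \eqn{\delta \ll 1/N_e}.}
#'   \item{`"intermediate_high_classical"`}{\eqn{\theta /
#'     [(1-f)(1 - e^{-2 N_e s_e})]} on
#'     \eqn{(N_e s_e)^{-1} \ll (1-f) \ll 1} (requires `f`).}
#'   \item{`"intermediate_high_decoupling"`}{\eqn{\frac{\theta}{2(1-f)}
#'     \left[\frac{\log(1-f)}{\log \delta N_e} + 1\right]} on
#'     \eqn{(\delta N_e)^{-1} \ll (1-f) \ll 1} (requires `f`).}
#'   \item{`"midpoint"`}{\eqn{4\theta\,(1 + \delta N_e)^{-2 s_e/\delta}}
#'     at `f = 0.5`; only its limits (4\eqn{\theta} as
#'     \eqn{\delta \to 0^+} under strong selection, 2\eqn{\theta} as
#'     \eqn{\delta \to \infty} at `s = 0`) are asserted by the package
#'     tests; between the limits only monotone interpolation is
#'     guaranteed.}
#' }
#'
#' @param params A [diffusion_params()].
#' @param regime One of the regime names above.
#' @param f Frequency, required for the two intermediate regimes.
#' @return The asymptotic SFS value.
#' @export
sfs_asymptotics <- function(params,
                            regime = c("high_f_strong_decoupling",
                                       "high_f_strong_selection",
                                       "intermediate_high_classical",
                                       "intermediate_high_decoupling",
                                       "midpoint"),
                            f = NULL) {
  stopifnot(inherits(params, "diffusion_params"))
  regime <- match.arg(regime)
  Ne <- params$Ne; d <- params$delta; se <- params$se; th <- params$theta
  dNe <- d * Ne
  switch(regime,
    high_f_strong_decoupling = {
      if (dNe <= 1)
        stop("regime mismatch: requires delta * Ne >> 1")
      th * dNe / (2 * log(dNe))
    },
    high_f_strong_selection = {
      if (se * Ne <= 1)
        stop("regime mismatch: requires Ne * se >> 1")
      2 * se * Ne * th
    },
    intermediate_high_classical = {
      if (is.null(f)) stop("regime requires a frequency f")
      if (se == 0) stop("regime mismatch: requires se != 0")
      th / ((1 - f) * (1 - exp(-2 * Ne * se)))
    },
    intermediate_high_decoupling = {
      if (is.null(f)) stop("regime requires a frequency f")
      if (dNe <= 1) stop("regime mismatch: requires delta * Ne >> 1")
      th / (2 * (1 - f)) * (log(1 - f) / log(dNe) + 1)
    },
    midpoint = {
      if (d <= 0) stop("regime mismatch: requires delta > 0")
      4 * th * (1 + dNe)^(-2 * se / d)
    })
}

#' Low-frequency SFS decay exponent
#'
#' Fits the log-log slope of the site frequency spectrum over a low
#' frequency window; the density decays as \eqn{1/f} there (slope -1)
#' both with and without decoupling noise.
#'
#' @param params A [diffusion_params()].
#' @param f_range Frequency window (default `c(1e-3, 1e-2)`).
#' @param n_points Log-spaced evaluation points.
#' @return The fitted slope (negative for a decaying spectrum).
#' @export
sfs_lowfreq_slope <- function(params, f_range = c(1e-3, 1e-2),
                              n_points = 20) {
  f <- exp(seq(log(f_range[1]), log(f_range[2]), length.out = n_points))
  y <- sfs(f, params)
  unname(stats::coef(stats::lm(log(y) ~ log(f)))[2])
}
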