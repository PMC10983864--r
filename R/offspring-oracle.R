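#' Individual-level correlated-offspring sampler
#'
#' Brute-force one-generation oracle for the offspring-covariance model.
#' Each of the `N_A` genotype-A individuals and `N_B` genotype-B
#' individuals leaves a Gaussian number of net offspring with unit mean,
#' variance `c0` and the within/between-genotype covariances of `cov`.
#' The effective model constrains only first and second moments, so any
#' offspring distribution with this covariance validates the moment
#' formulas; Gaussian marginals are used for convenience.
#'
#' Two modes:
#' * `mode = "aggregate"` (default): the genotype totals
#'   \eqn{(N'_A, N'_B)} are drawn directly from the exactly implied
#'   bivariate normal of sums (means \eqn{N_\mu}, variances
#'   \eqn{(c_{0\mu}-c_{1\mu})N_\mu + c_{1\mu}N_\mu^2}, covariance
#'   \eqn{c_{AB} N_A N_B}), which is fast for any population size.
#' * `mode = "individual"`: the full individual-level multivariate
#'   normal is sampled via its three-factor decomposition (shared
#'   global factor, per-genotype shared factors, independent residuals),
#'   exercising the model at the level at which it is defined.
#'
#' Totals are returned real-valued (no rounding) to avoid discretization
#' bias in moment comparisons; negative totals are possible for tiny
#' populations and are likewise returned as-is in oracle use.
#'
#' @param cov A [cov_structure()].
#' @param N_A,N_B Nonnegative integer abundances.
#' @param n Number of independent one-generation transitions to draw.
#' @return A list with numeric vectors `N_A` and `N_B` of length `n`
#'   (next-generation totals).
#' @export
sample_correlated_offspring <- function(cov, N_A, N_B, n = 1,
                                        mode = c("aggregate", "individual")) {
  cov <- as_cov_structure(cov)
  mode <- match.arg(mode)
  stopifnot(N_A >= 0, N_B >= 0, N_A == round(N_A), N_B == round(N_B),
            n >= 1)
  check_individual_psd(cov, N_A, N_B)
  if (mode == "individual")
    return(sample_offspring_individual(cov, N_A, N_B, n))
  m <- predict_abundance_moments(cov, N_A, N_B)
  vA <- m$varN_A; vB <- m$varN_B; cAB <- m$covN_AB
  if (N_A == 0) {
    TA <- rep(0, n)
    TB <- N_B + sqrt(max(vB, 0)) * stats::rnorm(n)
    return(list(N_A = TA, N_B = TB))
  }
  if (N_B == 0) {
    TA <- N_A + sqrt(max(vA, 0)) * stats::rnorm(n)
    return(list(N_A = TA, N_B = rep(0, n)))
  }
  # Cholesky of the 2x2 aggregate covariance
  sA <- sqrt(vA)
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  if (sA > 0) {
    b <- cAB / sA
    resid <- vB - b^2
    if (resid < 0) {
      if (resid < -1e-8 * max(vB, 1)) stop("aggregate covariance not PSD")
      resid <- 0
    }
    TA <- N_A + sA * z1
    TB <- N_B + b * z1 + sqrt(resid) * z2
  } else {
    TA <- rep(N_A, n)
    TB <- N_B + sqrt(max(vB, 0)) * z2
  }
  list(N_A = TA, N_B = TB)
}

# PSD requirements of the individual-level covariance matrix:
# within-genotype blocks need c0 >= c1 and c0 + (N-1) c1 >= 0;
# the cross block needs the 2x2 matrix of shared-factor loadings
# to be PSD, i.e. cAB^2 <= c1A * c1B when both are nonnegative.
check_individual_psd <- function(cov, N_A, N_B) {
  if (cov$c0A < cov$c1A || cov$c0B < cov$c1B)
    stop("individual-level covariance not PSD: c0 < c1")
  if (N_A > 1 && cov$c0A + (N_A - 1) * cov$c1A < -1e-12)
    stop("individual-level covariance not PSD: c0A + (N_A-1) c1A < 0")
  if (N_B > 1 && cov$c0B + (N_B - 1) * cov$c1B < -1e-12)
    stop("individual-level covariance not PSD: c0B + (N_B-1) c1B < 0")
  if (N_A > 0 && N_B > 0 && cov$cAB != 0) {
    if (cov$c1A < 0 || cov$c1B < 0 || cov$cAB^2 > cov$c1A * cov$c1B + 1e-12)
      stop("individual-level covariance not PSD: cAB^2 > c1A * c1B")
  }
  invisible(TRUE)
}

# Factor decomposition: n'_{mu,i} = 1 + a_mu * g + b_mu * h_mu + e_i,
# with g, h_mu, e_i independent standard normals;
# cAB = aA * aB, c1mu = a_mu^2 + b_mu^2, c0mu = c1mu + var(e).
sample_offspring_individual <- function(cov, N_A, N_B, n) {
  aA <- if (cov$c1A > 0 && cov$c1B > 0 && cov$cAB != 0)
    sqrt(abs(cov$cAB) * sqrt(cov$c1A / cov$c1B)) else 0
  aB <- if (aA > 0) cov$cAB / aA else 0
  bA <- sqrt(max(cov$c1A - aA^2, 0))
  bB <- sqrt(max(cov$c1B - aB^2, 0))
  sdeA <- sqrt(cov$c0A - cov$c1A)
  sdeB <- sqrt(cov$c0B - cov$c1B)
  TA <- numeric(n); TB <- numeric(n)
  for (k in seq_len(n)) {
    g <- stats::rnorm(1)
    hA <- stats::rnorm(1); hB <- stats::rnorm(1)
    TA[k] <- if (N_A > 0)
      sum(1 + aA * g + bA * hA + sdeA * stats::rnorm(N_A)) else 0
    TB[k] <- if (N_B > 0)
      sum(1 + aB * g + bB * hB + sdeB * stats::rnorm(N_B)) else 0
  }
  list(N_A = TA, N_B = TB)
}
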