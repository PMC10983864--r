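#' Offspring-number covariance structure
#'
#' Container for the five (co)variance parameters of the effective
#' offspring-number model for a two-genotype population.  Individual
#' \eqn{i} of genotype \eqn{\mu} leaves a random number of net offspring
#' \eqn{n'_{\mu,i}} with \eqn{\mathrm{var}\, n'_{\mu,i} = c_{0\mu}},
#' within-genotype covariance
#' \eqn{\mathrm{cov}(n'_{\mu,i}, n'_{\mu,j}) = c_{1\mu}} (\eqn{i \ne j})
#' and between-genotype covariance
#' \eqn{\mathrm{cov}(n'_{A,i}, n'_{B,j}) = c_{AB}}.
#' All parameters are dimensionless, per generation.
#'
#' Validity requires \eqn{c_{0\mu} \ge c_{1\mu} \ge} (a lower bound that
#' keeps the individual-level covariance matrix positive semi-definite
#' for any abundances) and \eqn{|c_{AB}| \le \sqrt{c_{1A} c_{1B}}} when
#' both within-genotype covariances are nonnegative, so that the implied
#' correlation \eqn{\rho_{AB}} lies in \eqn{[-1, 1]}.
#'
#' @param c0A,c0B Per-individual offspring-number variances (>= 0).
#' @param c1A,c1B Within-genotype offspring-number covariances.
#' @param cAB Between-genotype offspring-number covariance.
#' @return An object of class `"cov_structure"`: a named list with the
#'   five parameters.
#' @examples
#' cov_structure(c0A = 1.05, c0B = 1.05, c1A = 0.05, c1B = 0.05,
#'               cAB = 0.045)
#' @export
cov_structure <- function(c0A, c0B, c1A, c1B, cAB) {
  vals <- c(c0A = c0A, c0B = c0B, c1A = c1A, c1B = c1B, cAB = cAB)
  if (any(!is.finite(vals)))
    stop("all covariance parameters must be finite")
  if (c0A < 0 || c0B < 0)
    stop("per-individual variances c0A, c0B must be nonnegative")
  if (c1A > c0A || c1B > c0B)
    stop("within-genotype covariance cannot exceed the individual variance")
  if (c1A >= 0 && c1B >= 0 && abs(cAB) > sqrt(c1A * c1B) + 1e-12)
    stop("|cAB| must not exceed sqrt(c1A * c1B): implied correlation outside [-1, 1]")
  structure(as.list(vals), class = "cov_structure")
}

#' @export
print.cov_structure <- function(x, ...) {
  cat("Offspring-number covariance structure\n")
  cat(sprintf("  c0A = %g, c0B = %g (individual variances)\n", x$c0A, x$c0B))
  cat(sprintf("  c1A = %g, c1B = %g (within-genotype covariances)\n",
              x$c1A, x$c1B))
  cat(sprintf("  cAB = %g (between-genotype covariance)\n", x$cAB))
  cat(sprintf("  delta = %g", decoupling_parameter(x)))
  if (x$c1A > 0 && x$c1B > 0)
    cat(sprintf(", rhoAB = %g", correlation_rho(x)))
  cat("\n")
  invisible(x)
}

as_cov_structure <- function(cov) {
  if (inherits(cov, "cov_structure")) return(cov)
  if (is.list(cov) || is.numeric(cov)) {
    cov <- as.list(cov)
    return(cov_structure(cov$c0A, cov$c0B, cov$c1A, cov$c1B, cov$cAB))
  }
  stop("cannot interpret 'cov' as a covariance structure")
}

#' Serialize / deserialize a covariance structure
#'
#' The on-disk representation is a flat JSON object with keys
#' `c0A`, `c0B`, `c1A`, `c1B`, `cAB`.
#'
#' @param cov A [cov_structure()].
#' @param path File path for the JSON object.
#' @return `write_cov_structure` returns `path` invisibly;
#'   `read_cov_structure` returns a [cov_structure()].
#' @export
write_cov_structure <- function(cov, path) {
  cov <- as_cov_structure(cov)
  txt <- sprintf(
    "{\"c0A\": %.17g, \"c0B\": %.17g, \"c1A\": %.17g, \"c1B\": %.17g, \"cAB\": %.17g}",
    cov$c0A, cov$c0B, cov$c1A, cov$c1B, cov$cAB)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_cov_structure
#' @export
read_cov_structure <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  get1 <- function(key) {
    m <- regmatches(txt, regexec(paste0("\"", key,
      "\"[[:space:]]*:[[:space:]]*(-?[0-9.eE+-]+)"), txt))[[1]]
    if (length(m) < 2) stop("key '", key, "' missing from ", path)
    as.numeric(m[2])
  }
  cov_structure(get1("c0A"), get1("c0B"), get1("c1A"), get1("c1B"),
                get1("cAB"))
}

#' Decoupling parameter
#'
#' \eqn{\delta = c_{1A} + c_{1B} - 2 c_{AB}}: the composite covariance
#' that quantifies how strongly offspring-number fluctuations of the two
#' genotypes are decoupled.  \eqn{\delta = 0} when the genotypes are
#' statistically identical (`c1A == c1B == cAB`); only then does the
#' quadratically scaling frequency-variance component vanish.
#'
#' @param cov A [cov_structure()].
#' @return The dimensionless decoupling parameter (per generation).
#' @export
decoupling_parameter <- function(cov) {
  cov <- as_cov_structure(cov)
  cov$c1A + cov$c1B - 2 * cov$cAB
}

#' Between-genotype fluctuation correlation
#'
#' \eqn{\rho_{AB} = c_{AB} / \sqrt{c_{1A} c_{1B}}}, the correlation
#' between the correlated components of A and B abundance fluctuations.
#'
#' @param cov A [cov_structure()].
#' @return Correlation in \eqn{[-1, 1]}.
#' @export
correlation_rho <- function(cov) {
  cov <- as_cov_structure(cov)
  if (cov$c1A <= 0 || cov$c1B <= 0)
    stop("rhoAB undefined: within-genotype covariances must be positive")
  cov$cAB / sqrt(cov$c1A * cov$c1B)
}

#' Effective population size
#'
#' \eqn{N_e = N_{tot} / (c_{0A} - c_{1A})}, defined when the strength of
#' genetic drift is the same for both genotypes,
#' \eqn{c_{0A} - c_{1A} = c_{0B} - c_{1B}}.  When that symmetry fails
#' beyond `tol` an error of class `"decoupnoise_asymmetric_drift"` is
#' signalled and the caller must work with the full frequency-variance
#' form (see [predict_frequency_variance()]), which does not assume it.
#'
#' @param cov A [cov_structure()].
#' @param Ntot Total population size (individuals, > 0).
#' @param tol Relative tolerance for the drift-symmetry check.  The
#'   default is tight because the symmetric form is an exact algebraic
#'   specialization, not an approximation.
#' @return Effective population size in individuals.
#' @export
effective_population_size <- function(cov, Ntot, tol = 1e-9) {
  cov <- as_cov_structure(cov)
  stopifnot(Ntot > 0)
  kA <- cov$c0A - cov$c1A
  kB <- cov$c0B - cov$c1B
  if (kA <= 0)
    stop("c0A - c1A must be positive for a finite effective population size")
  if (abs(kA - kB) > tol * max(abs(kA), abs(kB))) {
    stop(structure(
      class = c("decoupnoise_asymmetric_drift", "error", "condition"),
      list(message = sprintf(
        "drift strengths differ between genotypes (c0A-c1A = %g, c0B-c1B = %g); use the full frequency-variance form",
        kA, kB), call = sys.call(-1))))
  }
  Ntot / kA
}

#' One-generation abundance moments
#'
#' Exact second moments of next-generation abundances implied by the
#' offspring-covariance model:
#' \eqn{\mathrm{var}\,N'_\mu = (c_{0\mu}-c_{1\mu}) N_\mu + c_{1\mu} N_\mu^2}
#' and \eqn{\mathrm{cov}(N'_A, N'_B) = c_{AB} N_A N_B}.
#' The variance scales linearly at low abundance (independent,
#' drift-like fluctuations) and quadratically at high abundance
#' (correlated fluctuations, Taylor's law with exponent two).
#'
#' @param cov A [cov_structure()].
#' @param N_A,N_B Current abundances (>= 0).
#' @return Named list with `varN_A`, `varN_B`, `covN_AB`.
#' @export
predict_abundance_moments <- function(cov, N_A, N_B) {
  cov <- as_cov_structure(cov)
  stopifnot(all(N_A >= 0), all(N_B >= 0))
  list(
    varN_A  = (cov$c0A - cov$c1A) * N_A + cov$c1A * N_A^2,
    varN_B  = (cov$c0B - cov$c1B) * N_B + cov$c1B * N_B^2,
    covN_AB = cov$cAB * N_A * N_B
  )
}

#' One-generation genotype-frequency variance
#'
#' First-order variance of the genotype-A frequency after one
#' generation:
#' \deqn{\mathrm{var}\, f' \approx \frac{f(1-f)}{N_{tot}}
#'   \left[(c_{0A}-c_{1A})(1-f) + (c_{0B}-c_{1B}) f\right]
#'   + \delta f^2 (1-f)^2,}
#' with \eqn{\delta = c_{1A} + c_{1B} - 2 c_{AB}}.  Under drift symmetry
#' (`c0A - c1A == c0B - c1B`) this reduces to
#' \eqn{f(1-f)/N_e + \delta f^2(1-f)^2}; when \eqn{\delta = 0} it reduces
#' to classical genetic drift \eqn{c_0 f(1-f)/N_{tot}}.
#'
#' The formula is a first-order (small relative abundance deviation)
#' approximation; it is accurate for \eqn{N_{tot} \gtrsim 100} and
#' frequencies away from the boundaries.
#'
#' @param cov A [cov_structure()].
#' @param N_A,N_B Current abundances; `Ntot = N_A + N_B` must be > 0.
#' @return Variance of \eqn{f' = N'_A / N'_{tot}}.
#' @export
predict_frequency_variance <- function(cov, N_A, N_B) {
  cov <- as_cov_structure(cov)
  stopifnot(all(N_A >= 0), all(N_B >= 0))
  Ntot <- N_A + N_B
  if (any(Ntot <= 0)) stop("total population size must be positive")
  f <- N_A / Ntot
  delta <- decoupling_parameter(cov)
  drift <- f * (1 - f) / Ntot *
    ((cov$c0A - cov$c1A) * (1 - f) + (cov$c0B - cov$c1B) * f)
  drift + delta * f^2 * (1 - f)^2
}
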