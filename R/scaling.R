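#' Robust variance from the median absolute deviation
#'
#' \eqn{\widehat{\mathrm{var}} = 2.1981 \cdot
#' (\mathrm{med}_i |x_i - \mathrm{med}_i x_i|)^2}.  The constant is
#' \eqn{1/\Phi^{-1}(0.75)^2}, making the estimator consistent for the
#' variance of Gaussian data while damping the influence of outliers.
#'
#' @param values Numeric vector, at least 2 values.
#' @return Robust variance estimate.
#' @export
robust_variance <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2)
    stop("robust_variance needs at least two finite values")
  2.1981 * stats::median(abs(values - stats::median(values)))^2
}

#' Power-law fit of a mean-variance relationship
#'
#' Ordinary least squares of `log(variance)` on `log(mean)`, the
#' standard estimator for Taylor's-law exponents.  Confidence intervals
#' come from bootstrap resampling; the resampling unit is the replicate
#' trajectory (via `replicate_id`) when replicate structure exists,
#' otherwise the individual point.
#'
#' @param means,variances Positive numeric vectors of equal length.
#' @param replicate_id Optional vector of replicate labels; bootstrap
#'   resamples whole replicates with replacement.
#' @param bootstrap_reps Number of bootstrap resamples.
#' @param conf Confidence level.
#' @return An object of class `"scaling_fit"`: list with `exponent`,
#'   `intercept` (natural-log scale), `ci` (exponent CI), `n_points`,
#'   `n_dropped` (nonpositive pairs removed), `bootstrap_exponents`.
#' @export
fit_power_law <- function(means, variances, replicate_id = NULL,
                          bootstrap_reps = 1000, conf = 0.95) {
  stopifnot(length(means) == length(variances))
  ok <- is.finite(means) & is.finite(variances) & means > 0 & variances > 0
  n_dropped <- sum(!ok)
  x <- log(means[ok]); y <- log(variances[ok])
  if (length(x) < 3)
    stop("power-law fit needs at least 3 positive (mean, variance) pairs")
  rid <- if (is.null(replicate_id)) seq_along(x) else replicate_id[ok]
  fit <- stats::lm(y ~ x)
  b <- unname(stats::coef(fit))
  groups <- split(seq_along(x), rid)
  bs <- rep(NA_real_, bootstrap_reps)
  for (r in seq_len(bootstrap_reps)) {
    idx <- unlist(groups[sample(length(groups), replace = TRUE)],
                  use.names = FALSE)
    if (length(unique(x[idx])) < 2) next
    bs[r] <- unname(stats::coef(stats::lm(y[idx] ~ x[idx]))[2])
  }
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(bs, c(alpha, 1 - alpha), na.rm = TRUE))
  structure(list(exponent = b[2], intercept = b[1], ci = ci,
                 n_points = length(x), n_dropped = n_dropped,
                 conf = conf, bootstrap_exponents = bs),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit: exponent %.4f [%.4f, %.4f] (%d%% CI), intercept %.4f, n = %d\n",
    x$exponent, x$ci[1], x$ci[2], round(100 * x$conf), x$intercept,
    x$n_points))
  if (x$n_dropped > 0)
    cat(sprintf("  (%d nonpositive pairs excluded from the log fit)\n",
                x$n_dropped))
  invisible(x)
}

#' Moving average with a multiplicative window
#'
#' Smooths `y` as a function of positive `x` using a window of constant
#' size on `log(x)`: at each evaluation point \eqn{x_0} the smoothed
#' value is the mean of `y` over
#' \eqn{x \in [x_0(1-w),\; x_0(1+w)]}.  Used to extract the
#' mean-variance curve from noisy per-lineage scatter spanning several
#' decades of frequency.
#'
#' @param x Positive abscissa values.
#' @param y Values to smooth.
#' @param w Relative half-width of the window (default 0.3).
#' @param x_out Evaluation points (default `sort(x)`).
#' @return A data.frame with `x`, `smoothed` (NA where the window is
#'   empty), and `n_window`.
#' @export
moving_average_multiplicative <- function(x, y, w = 0.3, x_out = NULL) {
  stopifnot(length(x) == length(y), all(x > 0), w > 0, w < 1)
  if (is.null(x_out)) x_out <- sort(x)
  sm <- vapply(x_out, function(x0) {
    inw <- x >= x0 * (1 - w) & x <= x0 * (1 + w)
    if (!any(inw)) NA_real_ else mean(y[inw], na.rm = TRUE)
  }, numeric(1))
  nw <- vapply(x_out, function(x0)
    sum(x >= x0 * (1 - w) & x <= x0 * (1 + w)), integer(1))
  data.frame(x = x_out, smoothed = sm, n_window = nw)
}

#' Expected variance accumulation under classical drift
#'
#' Recursion for the between-replicate frequency variance expected from
#' bottleneck genetic drift alone:
#' \eqn{\mathrm{var} f_1 = f_0(1-f_0)/N_e}, then
#' \eqn{\mathrm{var} f_{t+1} = \mathrm{var} f_t + f_t(1-f_t)/N_e},
#' with the frequency propagated as its mean.  Used as the null
#' expectation against which giant fluctuations are judged.
#'
#' @param f0 Initial frequency in (0, 1), or a vector of per-cycle mean
#'   frequencies of length `T` (first element used for the first step).
#' @param Ne Effective (bottleneck) population size.
#' @param T Number of cycles.
#' @return Numeric vector of length `T`: variance after each cycle.
#' @export
drift_variance_recursion <- function(f0, Ne, T) {
  stopifnot(Ne > 0, T >= 1, all(f0 > 0), all(f0 < 1))
  fbar <- if (length(f0) == 1) rep(f0, T) else {
    stopifnot(length(f0) == T)
    f0
  }
  v <- numeric(T)
  v[1] <- fbar[1] * (1 - fbar[1]) / Ne
  if (T > 1)
    for (t in 2:T) v[t] <- v[t - 1] + fbar[t] * (1 - fbar[t]) / Ne
  v
}
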