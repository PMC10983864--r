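#' Between-replicate variance timecourse
#'
#' Computes the variance across replicate cultures at each nominal
#' timepoint.  When replicates were measured in batches at slightly
#' different actual times, the within-batch variances are computed
#' first and then averaged across batches sharing a nominal time.
#' Confidence intervals use the standard asymptotic formula
#' \eqn{\mathrm{var} \pm z\,\mathrm{var}\sqrt{2/(n-1)}}.
#'
#' @param timecourse Data frame with columns `time`, `replicate`,
#'   `frequency`, and optionally `batch` (defaults to a single batch).
#' @param conf Confidence level.
#' @return Data frame with `time`, `variance`, `lo`, `hi`,
#'   `n_replicates` (summed over batches).
#' @export
replicate_variance_timecourse <- function(timecourse, conf = 0.95) {
  stopifnot(all(c("time", "replicate", "frequency") %in% names(timecourse)))
  if (is.null(timecourse$batch)) timecourse$batch <- 1L
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- lapply(split(timecourse, timecourse$time), function(d) {
    per_batch <- vapply(split(d$frequency, d$batch), function(fr) {
      if (length(fr) < 2)
        stop("insufficient replicates: need >= 2 per timepoint per batch")
      c(stats::var(fr), length(fr))
    }, numeric(2))
    v <- mean(per_batch[1, ])
    n <- min(per_batch[2, ])
    half <- z * v * sqrt(2 / (n - 1))
    data.frame(time = d$time[1], variance = v,
               lo = max(v - half, 0), hi = v + half,
               n_replicates = sum(per_batch[2, ]))
  })
  out <- do.call(rbind, out)
  out[order(out$time), , drop = FALSE]
}

# model definitions for the variance-growth comparison, all fit on the
# log-variance scale (approximate variance-stabilizing transform)
vg_models <- list(
  exponential = list(p = 2, fit = function(t, lv) {
    fit <- stats::lm(lv ~ t)
    list(pred = stats::fitted(fit), coef = stats::coef(fit))
  }),
  linear = list(p = 2, fit = function(t, lv) {
    # v = a + b t fitted on the log scale; direct minimization is
    # robust where a Gauss-Newton step fails on steep data
    v <- exp(lv)
    st <- stats::coef(stats::lm(v ~ t))
    a0 <- max(st[1], min(v) / 2)
    b0 <- if (any(a0 + st[2] * t <= 0)) 0 else unname(st[2])
    obj <- function(par) {
      m <- par[1] + par[2] * t
      if (any(m <= 0)) return(1e10)
      sum((lv - log(m))^2)
    }
    o <- stats::optim(c(a0, b0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    par <- stats::setNames(o$par, c("a", "b"))
    list(pred = log(pmax(par[1] + par[2] * t, 1e-300)), coef = par)
  }),
  power = list(p = 3, fit = function(t, lv) {
    st <- stats::coef(stats::lm(lv ~ t))
    fit <- stats::nls(lv ~ logc + a * t^b,
                      start = list(logc = st[1], a = st[2], b = 1),
                      control = stats::nls.control(warnOnly = TRUE))
    list(pred = stats::fitted(fit), coef = stats::coef(fit))
  }),
  quadratic = list(p = 3, fit = function(t, lv) {
    fit <- stats::lm(lv ~ t + I(t^2))
    list(pred = stats::fitted(fit), coef = stats::coef(fit))
  })
)

vg_aic <- function(lv, pred, p) {
  n <- length(lv)
  n * log(mean((pred - lv)^2)) + 2 * p
}

fit_vg_all <- function(t, lv) {
  lapply(vg_models, function(m) {
    res <- tryCatch(suppressWarnings(m$fit(t, lv)),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    list(coef = res$coef, aic = vg_aic(lv, res$pred, m$p), p = m$p)
  })
}

#' Variance-growth model comparison
#'
#' Fits four growth models to a between-replicate variance timecourse
#' on the log-variance scale -- exponential
#' (\eqn{\log v = \log a + b t}), linear (\eqn{v = a + b t}),
#' generalized power (\eqn{\log v = \log c + a t^b}) and quadratic
#' (\eqn{\log v = \log c + a t + b t^2}) -- and ranks them by
#' \eqn{AIC = n \log(\mathrm{MSE}) + 2p}.  Exponentially growing
#' variance between initially close replicates is the signature of
#' chaotic divergence.
#'
#' One-sided paired bootstrap p-values against the best model are
#' computed by resampling replicate trajectories with replacement
#' (when `trajectories` is given) or time points otherwise, refitting,
#' and recording how often the competitor beats the winner.
#'
#' @param times Timepoints (>= 4).
#' @param variances Positive variances at those timepoints.
#' @param trajectories Optional matrix (rows = `times`, columns =
#'   replicates) of the underlying replicate measurements; enables the
#'   trajectory-level bootstrap.
#' @param bootstrap_reps Bootstrap resamples for the p-values.
#' @return An object of class `"variance_growth_fit"`: list of per-model
#'   fits (`coef`, `aic`, `p_value`), sorted by AIC; attribute `best`.
#' @export
fit_variance_growth_models <- function(times, variances,
                                       trajectories = NULL,
                                       bootstrap_reps = 200) {
  stopifnot(length(times) == length(variances))
  ok <- is.finite(variances) & variances > 0
  t <- times[ok]; lv <- log(variances[ok])
  if (length(t) < 4)
    stop("need at least 4 positive variance points")
  fits <- fit_vg_all(t, lv)
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) < 2) stop("degenerate fit: fewer than two models converged")
  aics <- vapply(fits, `[[`, 0, "aic")
  best <- names(which.min(aics))
  # bootstrap AIC differences vs the best model
  nboot <- matrix(NA_real_, bootstrap_reps, length(fits),
                  dimnames = list(NULL, names(fits)))
  for (r in seq_len(bootstrap_reps)) {
    if (!is.null(trajectories)) {
      idx <- sample(ncol(trajectories), replace = TRUE)
      vb <- apply(trajectories[ok, idx, drop = FALSE], 1, stats::var)
      okb <- vb > 0
      if (sum(okb) < 4) next
      fb <- fit_vg_all(t[okb], log(vb[okb]))
    } else {
      idx <- sample(length(t), replace = TRUE)
      if (length(unique(t[idx])) < 4) next
      fb <- fit_vg_all(t[idx], lv[idx])
    }
    for (m in names(fits))
      if (!is.null(fb[[m]])) nboot[r, m] <- fb[[m]]$aic
  }
  for (m in names(fits)) {
    fits[[m]]$p_value <- if (m == best) NA_real_ else
      mean(nboot[, m] <= nboot[, best], na.rm = TRUE)
    fits[[m]]$boot_coef1 <- NULL
  }
  # keep bootstrap slopes of the exponential model for downstream CIs
  exp_slopes <- rep(NA_real_, bootstrap_reps)
  for (r in seq_len(bootstrap_reps)) {
    if (!is.null(trajectories)) {
      idx <- sample(ncol(trajectories), replace = TRUE)
      vb <- apply(trajectories[ok, idx, drop = FALSE], 1, stats::var)
      okb <- vb > 0
      if (sum(okb) < 3) next
      exp_slopes[r] <- stats::coef(stats::lm(log(vb[okb]) ~ t[okb]))[2]
    } else {
      idx <- sample(length(t), replace = TRUE)
      if (length(unique(t[idx])) < 2) next
      exp_slopes[r] <- stats::coef(stats::lm(lv[idx] ~ t[idx]))[2]
    }
  }
  fits$exponential$boot_slopes <- exp_slopes
  fits <- fits[order(aics)]
  structure(fits, class = "variance_growth_fit", best = best)
}

#' @export
print.variance_growth_fit <- function(x, ...) {
  cat("Variance-growth model comparison (lower AIC is better)\n")
  for (m in names(x)) {
    cat(sprintf("  %-12s AIC = %8.3f", m, x[[m]]$aic))
    if (!is.na(x[[m]]$p_value))
      cat(sprintf("  p(beats %s) = %.3f", attr(x, "best"), x[[m]]$p_value))
    cat("\n")
  }
  invisible(x)
}

new_lyapunov_estimate <- function(lambda, method, ci, p_value,
                                  dim = NA_integer_, lag = NA_integer_) {
  structure(list(lambda = lambda, method = method, ci = sort(ci),
                 p_value = p_value, dim = dim, lag = lag,
                 chaotic = is.finite(lambda) && lambda > 0),
            class = "lyapunov_estimate")
}

#' @export
print.lyapunov_estimate <- function(x, ...) {
  cat(sprintf(
    "Lyapunov exponent (%s method): lambda = %.4f [%.4f, %.4f]",
    x$method, x$lambda, x$ci[1], x$ci[2]))
  if (!is.na(x$p_value)) cat(sprintf(", p(lambda>0) = %.4g", x$p_value))
  cat(if (x$chaotic) "  [divergent]" else "  [non-chaotic]", "\n")
  invisible(x)
}

#' Lyapunov exponent from exponential variance growth
#'
#' If the between-replicate variance grows as
#' \eqn{\mathrm{var} f \propto e^{2\lambda t}}, the largest Lyapunov
#' exponent is half the fitted exponential rate, \eqn{\lambda = b/2}.
#' A nonpositive rate is flagged as non-chaotic.
#'
#' @param fit A `"variance_growth_fit"` from
#'   [fit_variance_growth_models()] (its exponential component and
#'   bootstrap slopes are used).
#' @param conf Confidence level for the propagated CI.
#' @return A `"lyapunov_estimate"` with `lambda`, `ci`, and a
#'   one-sided bootstrap `p_value` for \eqn{\lambda > 0}.
#' @export
lyapunov_from_variance <- function(fit, conf = 0.95) {
  stopifnot(inherits(fit, "variance_growth_fit"))
  b <- unname(fit$exponential$coef[2])
  slopes <- fit$exponential$boot_slopes / 2
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(slopes, c(alpha, 1 - alpha), na.rm = TRUE))
  pval <- mean(slopes <= 0, na.rm = TRUE)
  new_lyapunov_estimate(b / 2, "variance", ci, pval)
}

# delay-embed one trajectory: rows are times, columns the dim coords
embed_trajectory <- function(x, dim, lag) {
  n <- length(x) - (dim - 1) * lag
  if (n < 2) stop("trajectory too short for this embedding")
  sapply(seq_len(dim), function(k) x[(1 + (k - 1) * lag):((k - 1) * lag + n)])
}

# log pairwise nearest-neighbour distances pooled over time
nnd_points <- function(traj, times, dim, lag, transform) {
  stopifnot(is.matrix(traj), ncol(traj) >= 3)
  x <- if (transform == "logit") stats::qlogis(pmin(pmax(traj, 1e-12),
                                                    1 - 1e-12)) else traj
  emb <- lapply(seq_len(ncol(x)), function(j)
    embed_trajectory(x[, j], dim, lag))
  nT <- nrow(emb[[1]])
  tgrid <- times[seq_len(nT)]
  init <- t(vapply(emb, function(e) e[1, , drop = TRUE], numeric(dim)))
  init <- matrix(init, ncol = dim)
  D0 <- as.matrix(stats::dist(init))
  diag(D0) <- Inf
  D0[D0 == 0] <- Inf       # exclude exact ties (duplicate trajectories)
  rows <- list()
  for (i in seq_len(ncol(x))) {
    j <- unname(which.min(D0[i, ]))
    if (!is.finite(D0[i, j])) next
    d <- unname(sqrt(rowSums((emb[[i]] - emb[[j]])^2)))
    keep <- d > 0
    rows[[length(rows) + 1]] <- data.frame(
      i = i, j = j, t = unname(tgrid[keep] - tgrid[1]),
      logd = log(d[keep]))
  }
  if (!length(rows)) stop("no usable nearest-neighbour pairs")
  do.call(rbind, rows)
}

#' Lyapunov exponent from nearest-neighbour divergence
#'
#' Rosenstein-style estimator adapted to many short replicate
#' trajectories: each trajectory is delay-embedded, its nearest
#' neighbour at the initial timepoint found (Euclidean distance), the
#' log pairwise distance tracked over time, and
#' \eqn{\log d_{i,j}(t) = \lambda t + b} fit by least squares pooled
#' over all pairs with equal weighting.  Distances are computed on
#' logit-transformed frequencies by default, since genotype
#' frequencies live on (0, 1); use `transform = "raw"` for
#' general-scale data.
#'
#' @param trajectories Numeric matrix, rows = common timepoints,
#'   columns = replicate trajectories (>= 3).
#' @param times Timepoints (defaults to row index).
#' @param dim,lag Embedding dimension and lag.
#' @param transform `"logit"` (default) or `"raw"`.
#' @param bootstrap_reps Bootstrap over trajectories for the CI and
#'   the one-sided p-value for \eqn{\lambda > 0}.
#' @param conf Confidence level.
#' @return A `"lyapunov_estimate"`.
#' @export
lyapunov_nnd <- function(trajectories, times = seq_len(nrow(trajectories)),
                         dim = 1, lag = 1, transform = c("logit", "raw"),
                         bootstrap_reps = 200, conf = 0.95) {
  transform <- match.arg(transform)
  stopifnot(ncol(trajectories) >= 3, nrow(trajectories) >= 2,
            length(times) == nrow(trajectories))
  pts <- nnd_points(trajectories, times, dim, lag, transform)
  lambda <- unname(stats::coef(stats::lm(logd ~ t, data = pts))[2])
  bs <- rep(NA_real_, bootstrap_reps)
  for (r in seq_len(bootstrap_reps)) {
    idx <- sample(ncol(trajectories), replace = TRUE)
    idx <- unique(idx)   # duplicated trajectories are exact ties
    if (length(idx) < 3) next
    pb <- tryCatch(
      nnd_points(trajectories[, idx, drop = FALSE], times, dim, lag,
                 transform),
      error = function(e) NULL)
    if (is.null(pb)) next
    bs[r] <- unname(stats::coef(stats::lm(logd ~ t, data = pb))[2])
  }
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(bs, c(alpha, 1 - alpha), na.rm = TRUE))
  pval <- mean(bs <= 0, na.rm = TRUE)
  new_lyapunov_estimate(lambda, "NND", ci, pval, dim = dim, lag = lag)
}

#' Select embedding hyperparameters by shuffle-split cross-validation
#'
#' For each candidate (dimension, lag) pair the pooled
#' nearest-neighbour log-distance points are split `n_splits` times
#' into `n_insample` points used to fit the divergence line and the
#' remainder used to score out-of-sample mean squared error; the
#' candidate with the lowest average out-of-sample MSE is returned.
#'
#' @param trajectories,times,transform As in [lyapunov_nnd()].
#' @param candidate_dims,candidate_lags Candidate values.
#' @param n_splits Number of shuffle splits (default 1000).
#' @param n_insample In-sample points per split (default 30).
#' @return List with `dim`, `lag`, and the full `mse` table.
#' @export
select_embedding <- function(trajectories,
                             times = seq_len(nrow(trajectories)),
                             candidate_dims = 1:3, candidate_lags = 1,
                             transform = c("logit", "raw"),
                             n_splits = 1000, n_insample = 30) {
  transform <- match.arg(transform)
  stopifnot(length(candidate_dims) >= 1, length(candidate_lags) >= 1)
  grid <- expand.grid(dim = candidate_dims, lag = candidate_lags)
  if (nrow(grid) == 1)
    return(list(dim = grid$dim[1], lag = grid$lag[1], mse = NULL))
  grid$mse <- NA_real_
  for (g in seq_len(nrow(grid))) {
    pts <- tryCatch(
      nnd_points(trajectories, times, grid$dim[g], grid$lag[g], transform),
      error = function(e) NULL)
    if (is.null(pts) || nrow(pts) <= n_insample + 2) next
    mses <- numeric(n_splits)
    for (s in seq_len(n_splits)) {
      ins <- sample(nrow(pts), n_insample)
      fit <- stats::lm(logd ~ t, data = pts[ins, ])
      pred <- stats::predict(fit, newdata = pts[-ins, ])
      mses[s] <- mean((pred - pts$logd[-ins])^2)
    }
    grid$mse[g] <- mean(mses)
  }
  if (all(is.na(grid$mse))) stop("insufficient data for embedding selection")
  k <- which.min(grid$mse)
  list(dim = grid$dim[k], lag = grid$lag[k], mse = grid)
}
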