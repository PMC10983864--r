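test_that("replicate variance timecourse averages within batches", {
  tc <- data.frame(time = rep(c(0, 1), each = 4),
                   replicate = rep(1:4, 2),
                   frequency = c(rep(0.3, 4), 0.1, 0.3, 0.2, 0.4),
                   batch = rep(c(1, 1, 2, 2), 2))
  out <- replicate_variance_timecourse(tc)
  expect_equal(out$variance[out$time == 0], 0)
  expect_equal(out$variance[out$time == 1],
               mean(c(var(c(0.1, 0.3)), var(c(0.2, 0.4)))))
  expect_error(
    replicate_variance_timecourse(
      data.frame(time = 0, replicate = 1, frequency = 0.5)),
    "insufficient")
})

test_that("AIC follows n log(MSE) + 2p", {
  lv <- rnorm(10)
  expect_equal(decoupnoise:::vg_aic(lv, lv + 1, p = 2),
               10 * log(1) + 4)
})

test_that("model comparison identifies exponential variance growth", {
  set.seed(14)
  t <- seq(0, 8, length.out = 9)
  wins <- 0; beats_linear <- 0; pvals <- numeric(0)
  for (i in 1:10) {
    v <- 1e-4 * exp(0.8 * t) * exp(rnorm(9, 0, 0.08))
    fit <- fit_variance_growth_models(t, v, bootstrap_reps = 200)
    if (attr(fit, "best") == "exponential") wins <- wins + 1
    if (fit$exponential$aic < fit$linear$aic)
      beats_linear <- beats_linear + 1
    pv <- fit$linear$p_value
    if (length(pv) == 1 && !is.na(pv)) pvals <- c(pvals, pv)
  }
  # exponential always dominates linear (the decisive comparison);
  # the nested 3-parameter forms overtake it by AIC only occasionally
  expect_equal(beats_linear, 10)
  expect_gte(wins, 6)
  expect_lt(median(pvals), 0.05)
})

test_that("model comparison identifies linear variance growth", {
  set.seed(15)
  t <- seq(0, 8, length.out = 9)
  lin_beats_exp <- 0
  for (i in 1:10) {
    v <- (2e-4 + 3e-4 * t) * exp(rnorm(9, 0, 0.08))
    fit <- fit_variance_growth_models(t, v, bootstrap_reps = 50)
    if (fit$linear$aic < fit$exponential$aic) lin_beats_exp <- lin_beats_exp + 1
  }
  expect_gte(lin_beats_exp, 8)
})

test_that("variance-method Lyapunov exponent is half the fitted rate", {
  set.seed(16)
  t <- 0:8
  v <- 1e-6 * exp(1.0 * t) * exp(rnorm(9, 0, 0.05))
  fit <- fit_variance_growth_models(t, v, bootstrap_reps = 100)
  ly <- lyapunov_from_variance(fit)
  expect_equal(ly$lambda, unname(fit$exponential$coef[2]) / 2)
  expect_equal(ly$lambda, 0.5, tolerance = 0.1)
  expect_true(ly$chaotic)
  # decaying variance flags non-chaotic
  vdec <- 1e-3 * exp(-0.5 * t) * exp(rnorm(9, 0, 0.05))
  fit2 <- fit_variance_growth_models(t, vdec, bootstrap_reps = 100)
  ly2 <- lyapunov_from_variance(fit2)
  expect_lt(ly2$lambda, 0)
  expect_false(ly2$chaotic)
})

test_that("r=4 logistic ensemble yields lambda near ln 2 by both methods", {
  set.seed(17)
  traj <- logistic_ensemble(r = 4, n_reps = 20, n_iter = 15)
  tv <- apply(traj, 1, var)
  fit <- fit_variance_growth_models(0:14, tv, trajectories = traj,
                                    bootstrap_reps = 100)
  expect_identical(attr(fit, "best"), "exponential")
  lv <- lyapunov_from_variance(fit)
  ln <- lyapunov_nnd(traj, transform = "raw", bootstrap_reps = 100)
  expect_equal(lv$lambda, log(2), tolerance = 0.08)
  expect_equal(ln$lambda, log(2), tolerance = 0.08)
  # cross-method concordance
  expect_lt(abs(lv$lambda - ln$lambda), 0.05)
})

test_that("NND method classifies contraction and pure noise correctly", {
  set.seed(18)
  # trajectories converging to a shared fixed point
  tgrid <- 0:10
  conv <- sapply(1:6, function(j) 0.5 + (runif(1) - 0.5) * exp(-0.7 * tgrid))
  ly <- lyapunov_nnd(conv, transform = "raw", bootstrap_reps = 50)
  expect_lt(ly$lambda, 0)
  # independent noise around a common path: no systematic divergence
  noise <- sapply(1:8, function(j) 0.3 + rnorm(11, 0, 0.01))
  ly2 <- lyapunov_nnd(noise, transform = "raw", bootstrap_reps = 100)
  expect_lt(ly2$ci[1], 0.05)
  expect_gt(ly2$ci[2], -0.05)
  # duplicated trajectories (exact ties) are excluded, not fatal
  dup <- cbind(noise, noise[, 1])
  expect_s3_class(lyapunov_nnd(dup, transform = "raw",
                               bootstrap_reps = 20),
                  "lyapunov_estimate")
})

test_that("chaos pipeline does not flag linear noisy dynamics", {
  set.seed(19)
  false_pos <- 0; reps <- 20
  for (i in seq_len(reps)) {
    traj <- linear_noise_ensemble(n_reps = 10, n_iter = 12)
    ly <- lyapunov_nnd(traj, transform = "raw", bootstrap_reps = 100)
    if (ly$ci[1] > 0) false_pos <- false_pos + 1
  }
  expect_lte(false_pos / reps, 0.1)
})

test_that("embedding selection scores candidates and lambda is stable", {
  set.seed(20)
  traj <- logistic_ensemble(r = 3.9, n_reps = 15, n_iter = 20,
                            jitter = 1e-6)
  single <- select_embedding(traj, candidate_dims = 2, candidate_lags = 1)
  expect_equal(single$dim, 2)
  sel <- select_embedding(traj, candidate_dims = 1:3,
                          candidate_lags = 1, transform = "raw",
                          n_splits = 200, n_insample = 30)
  expect_true(sel$dim %in% 1:3)
  expect_true(all(is.finite(sel$mse$mse)))
  expect_equal(sel$mse$mse[sel$mse$dim == sel$dim],
               min(sel$mse$mse))
  # the Lyapunov estimate barely moves across candidate embeddings
  # (the robustness that makes the choice of dimension uncritical)
  l1 <- lyapunov_nnd(traj, dim = 1, transform = "raw",
                     bootstrap_reps = 50)
  l2 <- lyapunov_nnd(traj, dim = 2, transform = "raw",
                     bootstrap_reps = 50)
  l3 <- lyapunov_nnd(traj, dim = 3, transform = "raw",
                     bootstrap_reps = 50)
  expect_lt(abs(l1$lambda - l2$lambda), 0.05)
  expect_lt(abs(l1$lambda - l3$lambda), 0.05)
})
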