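test_that("displacements carry delta-method measurement variances", {
  tc <- data.frame(culture = "a", day = 0:2,
                   frequency = c(0.5, 0.5, 0.5), events = c(Inf, Inf, Inf))
  recs <- compute_displacements(tc)
  expect_equal(recs$displacement, c(0, 0))
  expect_equal(recs$meas_var, c(0, 0))
  tc$events <- 1000
  recs <- compute_displacements(tc)
  # logit-scale binomial variance: 1/(f(1-f)n) at each endpoint
  expect_equal(recs$meas_var[1], 2 / (0.25 * 1000))
  # boundary frequencies are dropped and counted
  tc2 <- data.frame(culture = "b", day = 0:2,
                    frequency = c(0.4, 0, 0.3), events = 100)
  r2 <- compute_displacements(tc2)
  expect_equal(nrow(r2), 0)
  expect_equal(attr(r2, "n_dropped"), 2)
})

test_that("binomial-only displacements match their measurement variance", {
  set.seed(23)
  n <- 5e3; f <- 0.07; depth <- 2e4
  fhat <- rbinom(2 * n, depth, f) / depth
  tc <- data.frame(culture = rep(seq_len(n), each = 2),
                   day = rep(0:1, n),
                   frequency = fhat, events = depth)
  recs <- compute_displacements(tc)
  expect_equal(var(recs$displacement), mean(recs$meas_var),
               tolerance = 0.05)
})

test_that("hierarchical model recovers the generative partition", {
  g <- generate_split_experiment(seed = 31)
  recs <- compute_displacements(g$observed, mode = "logit")
  fit <- fit_hierarchical_model(recs, seed = 32)
  s <- fit$summary
  # defaults: alpha = 0.5, beta = -10, deltaI = 0.01, deltaE = 0.02
  expect_gt(s["alpha", "q97.5"], 0.5 * 0.5)
  expect_lt(s["beta", "median"], -4)
  expect_gt(s["deltaI", "q97.5"], 0.005)
  expect_lt(s["deltaI", "q2.5"], 0.015)
  expect_gt(s["deltaE", "q97.5"], 0.02)
  # truth vM = 0: posterior hugs zero
  expect_lt(s["vM", "q97.5"], s["deltaI", "median"] / 2)
  expect_true(all(fit$draws[, c("deltaI", "deltaE", "vM")] >= 0))
})

test_that("null environmental component concentrates near zero", {
  g <- generate_split_experiment(seed = 33, alpha = 0, beta = 0,
                                 deltaI = 0.01, deltaE = 0, vM = 0)
  recs <- compute_displacements(g$observed, mode = "logit")
  fit <- fit_hierarchical_model(recs, seed = 34)
  q99 <- quantile(fit$draws[, "deltaE"], 0.99)
  expect_lt(q99, fit$summary["deltaI", "median"] / 2)
  # total-variance accounting: posterior means plus measurement noise
  # match the empirical displacement variance within 20%
  tot <- mean(fit$draws[, "deltaI"]) + mean(fit$draws[, "deltaE"]) +
    mean(fit$draws[, "vM"]) + mean(recs$meas_var)
  expect_lt(abs(tot / var(recs$displacement) - 1), 0.2)
})

test_that("pure measurement noise leaves no excess variance components", {
  set.seed(35)
  # constant latent frequencies, spread across cultures so that the
  # fitness intercept and slope stay separately identified
  n_cult <- 12; n_days <- 10; depth <- 5e3
  fs <- seq(0.05, 0.3, length.out = n_cult)
  rows <- lapply(seq_len(n_cult), function(cu) data.frame(
    culture = cu, day = 0:n_days,
    frequency = rbinom(n_days + 1, depth, fs[cu]) / depth,
    events = depth))
  recs <- compute_displacements(do.call(rbind, rows))
  fit <- fit_hierarchical_model(recs, seed = 36)
  mu <- mean(recs$meas_var)
  expect_lt(fit$summary["deltaI", "q97.5"], 2 * mu)
  expect_lt(fit$summary["deltaE", "q97.5"], 2 * mu)
})

test_that("kappa is the centred, rescaled MAD variance of log changes", {
  # noiseless constant frequencies
  d <- expand.grid(barcode = paste0("b", 1:30), replicate = 1:3,
                   timepoint = 1:4)
  d$frequency <- 1e-3
  kt <- estimate_kappa(d, dt_set = 1, bootstrap_reps = 20)
  expect_true(all(kt$kappa == 0))

  # pure measurement noise zeta at both ends: kappa ~ zeta_t + zeta_s
  set.seed(37)
  zeta <- 0.004
  d2 <- expand.grid(barcode = paste0("b", 1:400), replicate = 1:3,
                    timepoint = 1:3)
  d2$frequency <- 1e-3 * exp(rnorm(nrow(d2), 0, sqrt(zeta)))
  kt2 <- estimate_kappa(d2, dt_set = c(1, 2), bootstrap_reps = 50)
  expect_equal(mean(kt2$kappa), 2 * zeta, tolerance = 0.15)

  # delta = 0.005 with zeta = 0.002: kappa(1) ~ 0.009, kappa(2) ~ 0.014
  set.seed(38)
  nb <- 600; tps <- 4
  lw <- matrix(0, nb, tps)  # latent log-frequency walk, shared origin
  for (t in 2:tps) lw[, t] <- lw[, t - 1] + rnorm(nb, 0, sqrt(0.005))
  d3 <- do.call(rbind, lapply(1:3, function(r) {
    w <- lw
    for (t in 2:tps) w[, t] <- w[, t - 1] +
      rnorm(nb, 0, sqrt(0.005))
    do.call(rbind, lapply(1:tps, function(t) data.frame(
      barcode = paste0("b", 1:nb), replicate = r, timepoint = t,
      frequency = 1e-3 * exp(w[, t] + rnorm(nb, 0, sqrt(0.002))))))
  }))
  kt3 <- estimate_kappa(d3, dt_set = c(1, 2), bootstrap_reps = 50)
  k1 <- mean(kt3$kappa[kt3$dt == 1])
  k2 <- mean(kt3$kappa[kt3$dt == 2])
  expect_equal(k1, 0.009, tolerance = 0.2)
  expect_equal(k2, 0.014, tolerance = 0.2)
  expect_error(estimate_kappa(d[d$barcode %in% paste0("b", 1:3), ]),
               "too few")
})

test_that("MSD deconvolution separates accumulation from measurement", {
  # exact linear kappa with zeta = 0 recovers delta exactly
  kt <- data.frame(t = c(2, 3, 4, 3, 4), dt = c(1, 1, 1, 2, 2))
  kt$kappa <- 0.005 * kt$dt
  kt$se <- 0.0005
  est <- deconvolve_msd(kt, bootstrap_reps = 50)
  expect_equal(est$delta, 0.005, tolerance = 1e-5)
  expect_equal(est$msd$msd, 0.005 * c(1, 2), tolerance = 1e-5)
  expect_true(all(abs(est$zeta) < 1e-6))
  # single-dt design is unidentifiable
  expect_error(deconvolve_msd(kt[kt$dt == 1, ]), "identifiability")
})

test_that("deconvolution recovers delta with heterogeneous zeta", {
  set.seed(39)
  hits <- 0; reps <- 12
  for (i in seq_len(reps)) {
    g <- generate_barcode_batches(
      n_batches = 1, n_barcodes = 350, n_timepoints = 5, Ne = 1e9,
      deltaI = 0.005, deltaE = 0, sd_fitness = 0.02,
      depth = round(c(2e5, 3e5, 1.2e6, 2e5, 6e5)))
    kt <- estimate_kappa(g$observed, bootstrap_reps = 60)
    est <- deconvolve_msd(kt, bootstrap_reps = 100)
    hits <- hits +
      (est$delta_ci[1] <= 0.005 && 0.005 <= est$delta_ci[2])
  }
  expect_gte(hits / reps, 0.75)
})

test_that("barcode-mode model partitions intrinsic and extrinsic noise", {
  g <- generate_barcode_batches(n_batches = 1, n_barcodes = 200,
                                seed = 40)
  kt <- estimate_kappa(g$observed, bootstrap_reps = 50)
  msd <- deconvolve_msd(kt, bootstrap_reps = 100)
  recs <- barcode_displacements(g$observed)
  fit <- fit_barcode_model(recs, msd$zeta, seed = 41)
  s <- fit$summary
  # intrinsic component near the generative value (drift adds ~1e-3 at
  # these frequencies with Ne = 1e6)
  expect_gt(s["deltaI", "q97.5"], 0.004)
  expect_lt(s["deltaI", "q2.5"], 0.009)
  expect_gt(s["deltaE", "q97.5"], 0.001)
  # per-barcode fitness effects track the truth
  keep <- fit$barcodes
  truth_alpha <- g$truth$alpha[[1]][
    match(keep, paste0("b1_", seq_along(g$truth$alpha[[1]])))]
  post_alpha <- colMeans(fit$draws[, paste0("a[", seq_along(keep), "]"),
                                   drop = FALSE])
  expect_gt(cor(post_alpha, truth_alpha), 0.5)
})
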