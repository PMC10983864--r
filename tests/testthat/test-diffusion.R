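test_that("effective fitness combines selection and noise asymmetry", {
  expect_equal(effective_fitness(0.01, 0.02, 0.02), 0.01)
  expect_equal(effective_fitness(0.01, 0.02, 0.04), 0.02)
  expect_equal(effective_fitness(0, 0.04, 0.02), -0.01)
})

test_that("drift and variance have the classical and symmetric limits", {
  p <- diffusion_params(Ne = 1e3, s = 0.01, delta = 0)
  dv <- drift_and_variance(0.3, p)
  expect_equal(dv$a, 0.01 * 0.3 * 0.7)
  expect_equal(dv$v, 0.3 * 0.7 / 1e3)
  # symmetric decoupling: drift vanishes at f = 1/2 and favours the
  # rare genotype
  p2 <- diffusion_params(Ne = 1e3, s = 0, delta = 0.02)
  expect_equal(drift_and_variance(0.5, p2)$a, 0)
  expect_gt(drift_and_variance(0.2, p2)$a, 0)
  expect_lt(drift_and_variance(0.8, p2)$a, 0)
})

test_that("closed-form exponent integral matches numerical quadrature", {
  for (prm in list(c(0.01, 0.005), c(0, 0.02), c(-0.003, 0.001))) {
    p <- diffusion_params(Ne = 1e3, s = prm[1], delta = prm[2])
    integrand <- function(u) {
      dv <- drift_and_variance(u, p)
      2 * dv$a / dv$v
    }
    for (x in c(0.1, 0.5, 0.9)) {
      num <- integrate(integrand, 1e-12, x, rel.tol = 1e-10)$value
      expect_equal(decoupnoise:::G_exponent(x, p), num,
                   tolerance = 1e-6)
    }
  }
})

test_that("short-time Langevin moments match the diffusion coefficients", {
  set.seed(77)
  c1 <- 0.02
  lp <- langevin_params(muA = 1.003, muB = 1, K = 2000, c1A = c1,
                        c1B = c1, rhoAB = 0.5)
  dp <- diffusion_params(Ne = 1e3, s = 0.003, delta = lp$delta)
  f0 <- 0.2
  n <- 2e5; nstep <- 5; tt <- nstep * lp$dt
  NA_ <- rep(f0 * 2000, n); NB <- rep((1 - f0) * 2000, n)
  for (i in seq_len(nstep)) {
    st <- decoupnoise:::step_langevin_vec(NA_, NB, lp)
    NA_ <- st$N_A; NB <- st$N_B
  }
  f <- NA_ / (NA_ + NB)
  dv <- drift_and_variance(f0, dp)
  se_mean <- sd(f) / sqrt(n)
  expect_lt(abs(mean(f) - f0 - dv$a * tt), 4 * se_mean + 0.1 * abs(dv$a) * tt)
  expect_lt(abs(var(f) - dv$v * tt), 4 * var(f) * sqrt(2 / n) + 0.05 * dv$v * tt)
})

test_that("fixation probability has its classical and neutral limits", {
  expect_equal(fixation_probability(0.3, diffusion_params(Ne = 1e3)),
               0.3, tolerance = 1e-8)
  p <- diffusion_params(Ne = 1e3, s = 0.01, delta = 0)
  cl <- (1 - exp(-2 * 0.01 * 1e3 * 1e-3)) / (1 - exp(-2 * 0.01 * 1e3))
  expect_equal(fixation_probability(1e-3, p), cl, tolerance = 1e-7)
  # delta -> 0 continuity
  p_eps <- diffusion_params(Ne = 1e3, s = 0.01, delta = 1e-9)
  for (f0 in c(1e-3, 0.1, 0.6))
    expect_equal(fixation_probability(f0, p_eps),
                 fixation_probability(f0, p), tolerance = 1e-4)
})

test_that("decoupling noise raises pfix above f0 for neutral mutants", {
  p <- diffusion_params(Ne = 1e3, s = 0, delta = 0.01)
  expect_gt(fixation_probability(1e-3, p), 1e-3)
  # the neutral plateau equals f0 * Ne * se* up to small-f0 corrections
  approx <- 1e-3 * 1e3 * transition_point(0.01, 1e3)
  expect_lt(abs(fixation_probability(1e-3, p) / approx - 1), 0.15)
})

test_that("pfix is monotone in f0 with absorbing limits", {
  p <- diffusion_params(Ne = 500, s = 0.002, delta = 0.005)
  f0 <- c(1e-4, 1e-3, 0.01, 0.1, 0.5, 0.9, 0.999)
  pf <- fixation_probability(f0, p)
  expect_true(all(diff(pf) > 0))
  expect_lt(pf[1], 1e-2)
  expect_gt(tail(pf, 1), 0.99)
  expect_true(all(pf >= 0 & pf <= 1))
})

test_that("transition point follows delta / (2 log(delta Ne))", {
  expect_equal(transition_point(0.01, 1e3), 0.01 / (2 * log(10)))
  expect_gt(transition_point(0.1, 1e3), 1 / 1e3)  # exceeds drift barrier
  # barrier shrinks as the population grows
  expect_gt(transition_point(0.01, 1e3), transition_point(0.01, 1e5))
  expect_error(transition_point(1e-4, 1e3), "out of regime")
  expect_error(transition_point(1e-3, 1e3), "out of regime")
})

test_that("piecewise pfix branches are consistent with quadrature", {
  for (dNe in c(10, 100)) {
    d <- dNe / 1e3
    sstar <- transition_point(d, 1e3)
    # flat branch below the barrier, classical branch above
    p_lo <- diffusion_params(Ne = 1e3, s = sstar / 20, delta = d)
    p_hi <- diffusion_params(Ne = 1e3, s = 5 * sstar, delta = d)
    f0 <- 1e-4
    expect_equal(fixation_probability_piecewise(f0, p_lo),
                 f0 * 1e3 * sstar)
    expect_equal(
      fixation_probability_piecewise(f0, p_hi),
      f0 * 2 * p_hi$se * 1e3 / (1 - exp(-2 * p_hi$se * 1e3)))
    # 30% agreement with quadrature away from the crossover
    expect_lt(abs(fixation_probability_piecewise(f0, p_lo) /
                    fixation_probability(f0, p_lo) - 1), 0.3)
    expect_lt(abs(fixation_probability_piecewise(f0, p_hi) /
                    fixation_probability(f0, p_hi) - 1), 0.3)
    # the two branch formulas intersect near se*
    branch_gap <- function(se) {
      f0 * 1e3 * sstar -
        f0 * 2 * se * 1e3 / (1 - exp(-2 * se * 1e3))
    }
    root <- uniroot(branch_gap, c(sstar / 10, 10 * sstar))$root
    expect_lt(abs(log(root / sstar)), log(2.5))
  }
  expect_error(
    fixation_probability_piecewise(
      0.5, diffusion_params(Ne = 1e3, s = 0, delta = 0.01)),
    "regime violation")
  expect_error(
    fixation_probability_piecewise(
      1e-4, diffusion_params(Ne = 1e3, s = 0, delta = 1e-5)),
    "regime violation")
})

test_that("halving dt leaves Monte-Carlo pfix within its CI", {
  set.seed(61)
  c1 <- 0.01
  base <- list(muA = 1, muB = 1 - 0.005, K = 2000, c1A = c1, c1B = c1,
               rhoAB = 0.5)
  e1 <- estimate_fixation_probability(
    do.call(langevin_params, c(base, dt = 0.1)), n_reps = 4000)
  e2 <- estimate_fixation_probability(
    do.call(langevin_params, c(base, dt = 0.05)), n_reps = 4000)
  expect_lt(max(e1$ci[1], e2$ci[1]), min(e1$ci[2], e2$ci[2]))
})

test_that("SFS has the neutral, selective and decoupling signatures", {
  # neutral: theta / f at low f
  p0 <- diffusion_params(Ne = 1e3, s = 0, delta = 0, theta = 1)
  f <- c(1e-3, 0.01, 0.05)
  expect_equal(sfs(f, p0), 1 / f, tolerance = 1e-3)
  # theta scales the spectrum linearly
  p0b <- diffusion_params(Ne = 1e3, s = 0, delta = 0, theta = 2.5)
  expect_equal(sfs(0.2, p0b), 2.5 * sfs(0.2, p0), tolerance = 1e-8)
  # classical strong selection: minimum 4 theta at f = 0.5
  ps <- diffusion_params(Ne = 1e3, s = 0.05, delta = 0)
  fg <- seq(0.05, 0.95, by = 0.05)
  y <- sfs(fg, ps)
  expect_equal(fg[which.min(y)], 0.5)
  expect_equal(min(y), 4, tolerance = 1e-3)
  # strong selection plateau near fixation (Ne se >> 1)
  expect_equal(sfs(1 - 1e-4, ps),
               sfs_asymptotics(ps, "high_f_strong_selection"),
               tolerance = 0.01)
  # strong decoupling: 2 theta at the midpoint, high-f uptick
  pd <- diffusion_params(Ne = 1e3, s = 0, delta = 0.1)
  expect_equal(sfs(0.5, pd), 2, tolerance = 1e-3)
  expect_equal(sfs(1 - 1e-3, pd),
               sfs_asymptotics(pd, "high_f_strong_decoupling"),
               tolerance = 0.2)
  # intermediate-regime scalings within their validity windows
  expect_equal(sfs(0.95, ps),
               sfs_asymptotics(ps, "intermediate_high_classical",
                               f = 0.95), tolerance = 0.1)
  pd2 <- diffusion_params(Ne = 1e3, s = 0, delta = 1)
  expect_equal(sfs(0.95, pd2),
               sfs_asymptotics(pd2, "intermediate_high_decoupling",
                               f = 0.95), tolerance = 0.15)
  # midpoint interpolates monotonically between 4 and 2 theta under
  # strong selection as decoupling grows
  mids <- vapply(c(1e-4, 1e-2, 1), function(d)
    sfs(0.5, diffusion_params(Ne = 1e3, s = 0.05, delta = d)),
    numeric(1))
  expect_true(all(diff(mids) < 0))
  expect_lt(mids[3], 4)
  expect_gt(mids[1], 3.9)
})

test_that("low-frequency SFS decays as 1/f with and without decoupling", {
  expect_equal(sfs_lowfreq_slope(diffusion_params(Ne = 1e3)), -1,
               tolerance = 0.02)
  expect_equal(
    sfs_lowfreq_slope(diffusion_params(Ne = 1e3, s = 0, delta = 0.01)),
    -1, tolerance = 0.06)
})

test_that("SFS asymptotics validate their regimes", {
  expect_equal(
    sfs_asymptotics(diffusion_params(Ne = 1e3, s = 0.05, delta = 0),
                    "high_f_strong_selection"), 100)
  expect_equal(
    sfs_asymptotics(diffusion_params(Ne = 1e3, s = 0, delta = 0.1),
                    "high_f_strong_decoupling"), 100 / (2 * log(100)))
  expect_error(
    sfs_asymptotics(diffusion_params(Ne = 1e3, s = 0, delta = 1e-5),
                    "high_f_strong_decoupling"), "regime")
  expect_error(
    sfs_asymptotics(diffusion_params(Ne = 1e3, s = 0, delta = 0.1),
                    "high_f_strong_selection"), "regime")
})

test_that("simulated SFS matches quadrature under decoupling", {
  set.seed(88)
  lp <- langevin_params(muA = 1, muB = 1, K = 2000, c1A = 0.01,
                        c1B = 0.01, rhoAB = 0.5)
  sim <- estimate_sfs(lp, n_reps = 6000, N_A0 = 20, N_B0 = 1980)
  th <- sfs(sim$f_mid, diffusion_params(Ne = 1e3, s = 0, delta = 0.01))
  # compare above the injection frequency (below it the sojourn
  # density of a mutant entering at f0 is flat, not ~1/f)
  keep <- sim$f_mid > 0.05
  z <- (sim$density[keep] - th[keep]) / sim$se[keep]
  expect_true(all(abs(z) < 4))
  expect_gt(cor(log(sim$density[keep]), log(th[keep])), 0.98)
})
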