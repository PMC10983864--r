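#' Synthetic serial-split coculture experiment
#'
#' Generates a multi-day two-genotype frequency timecourse with the
#' structure of a serial-splitting design: `n_initial` replicate
#' cultures split from one mother at day 0, each split again into
#' `split_factor[k]` daughters at `split_days[k]`.  Per culture and
#' day the latent logit frequency performs the generative walk
#' \deqn{\Delta \mathrm{logit} f = \alpha + \beta f + E_t + M_{g,t}
#'   + \mathcal{N}(0, \delta_I),}
#' with \eqn{E_t \sim \mathcal{N}(0,\delta_E)} shared by all cultures
#' each day and \eqn{M_{g,t} \sim \mathcal{N}(0, v_M)} shared by
#' daughters of mother `g` on the displacement leaving a split day
#' (zero elsewhere).  Observed frequencies add binomial measurement
#' noise at `events` counted cells.
#'
#' Defaults mirror the standing split-experiment design: 4 cultures at
#' day 0 splitting 3-fold at day 3 and 2-fold at day 7, 12 days,
#' frequency-dependent fitness pulling toward an equilibrium near
#' 0.05, and 1e4 events per measurement.
#'
#' @param n_initial Cultures at day 0.
#' @param n_days Number of days (displacements run 0 to `n_days`).
#' @param split_days,split_factor Days at which every culture is split
#'   and the corresponding number of daughters per culture.
#' @param f0 Initial frequency of the focal genotype.
#' @param alpha,beta Frequency-dependent fitness intercept and slope
#'   (logit displacement per day).
#' @param deltaI,deltaE,vM Intrinsic, extrinsic and shared-mother
#'   variance components (logit^2 per day).
#' @param events Cells counted per measurement (`Inf` for noiseless).
#' @param seed Optional integer seed.
#' @return List with `observed` (data.frame: `culture`, `mother`,
#'   `day`, `frequency`, `events`, `group`) and `truth` (generator
#'   parameters plus the latent `E_t`, mother effects, and true
#'   frequencies).  The `group` column labels the mother group whose
#'   shared effect acts on the displacement leaving that day.
#' @export
generate_split_experiment <- function(n_initial = 4, n_days = 12,
                                      split_days = c(3, 7),
                                      split_factor = c(3, 2),
                                      f0 = 0.1,
                                      alpha = 0.5, beta = -10,
                                      deltaI = 0.01, deltaE = 0.02,
                                      vM = 0, events = 1e4,
                                      seed = NULL) {
  stopifnot(length(split_days) == length(split_factor),
            all(split_days < n_days), all(split_factor >= 1),
            deltaI >= 0, deltaE >= 0, vM >= 0, f0 > 0, f0 < 1,
            events > 0)
  if (!is.null(seed)) set.seed(seed)
  E <- stats::rnorm(n_days, 0, sqrt(deltaE))   # E[t] acts on day t-1 -> t
  cultures <- data.frame(id = paste0("c", seq_len(n_initial)),
                         mother = NA_character_,
                         logitf = stats::qlogis(f0))
  rows <- list(); mrec <- list()
  snap <- function(day, grp) {
    f <- stats::plogis(cultures$logitf)
    fobs <- if (is.finite(events))
      stats::rbinom(length(f), events, f) / events else f
    data.frame(culture = cultures$id, mother = cultures$mother,
               day = day, frequency = fobs, true_frequency = f,
               events = if (is.finite(events)) events else NA_real_,
               group = grp)
  }
  for (day in 0:(n_days - 1)) {
    k <- match(day, split_days)
    grp <- rep(0L, nrow(cultures))
    M <- rep(0, nrow(cultures))
    if (!is.na(k)) {
      # split every culture; daughters inherit the parent's state
      fac <- split_factor[k]
      parent <- rep(seq_len(nrow(cultures)), each = fac)
      newc <- data.frame(
        id = paste0(cultures$id[parent], "_",
                    rep(seq_len(fac), times = nrow(cultures))),
        mother = cultures$id[parent],
        logitf = cultures$logitf[parent])
      gid <- parent  # one mother group per parent culture
      Mg <- stats::rnorm(nrow(cultures), 0, sqrt(vM))
      mrec[[length(mrec) + 1]] <- data.frame(
        day = day, mother = cultures$id, effect = Mg)
      cultures <- newc
      grp <- paste0("d", day, "g", gid)
      M <- Mg[gid]
    } else {
      grp <- rep("0", nrow(cultures))
    }
    rows[[length(rows) + 1]] <- snap(day, grp)
    f <- stats::plogis(cultures$logitf)
    cultures$logitf <- cultures$logitf + alpha + beta * f +
      E[day + 1] + M + stats::rnorm(nrow(cultures), 0, sqrt(deltaI))
  }
  rows[[length(rows) + 1]] <- snap(n_days, rep("0", nrow(cultures)))
  obs <- do.call(rbind, rows)
  obs$group[obs$group == "0"] <- NA_character_
  list(observed = obs[, c("culture", "mother", "day", "frequency",
                          "events", "group")],
       truth = list(alpha = alpha, beta = beta, deltaI = deltaI,
                    deltaE = deltaE, vM = vM, E = E,
                    mother_effects = if (length(mrec))
                      do.call(rbind, mrec) else NULL,
                    true_frequencies = obs[, c("culture", "day",
                                               "true_frequency")]))
}

#' Synthetic barcoded-lineage batches
#'
#' Emulates batches of barcode-frequency trajectories in which one
#' culture is sequenced at timepoint 1 and then split into
#' `n_replicates` biological replicates followed for the remaining
#' timepoints.  Per barcode `i`, replicate and timestep the latent log
#' frequency moves by
#' \deqn{\Delta\log f = \alpha_i + E_t + \mathcal{N}(0, \delta_I)
#'       + \mathcal{N}(0, (1-f)/(N_e f)),}
#' i.e. a barcode-specific fitness effect, an environmental effect
#' shared by all barcodes and replicates of a batch at a timepoint,
#' intrinsic decoupling noise (log-scale variance `deltaI`,
#' equivalently \eqn{\delta_I f^2(1-f)^2} on the natural scale), and
#' classical drift at strength `1/Ne`.  Observed counts are multinomial
#' reads at depth `depth`.
#'
#' Default barcode frequencies span >= 3 decades (log-uniform on
#' [1e-6, 5e-3]) so the between-replicate mean-variance cloud shows
#' the drift-dominated slope-1 regime at low frequency and the
#' decoupling-dominated slope-2 regime above the crossover
#' \eqn{f^* \approx 1/(N_e \delta_I)}.
#'
#' @param n_batches Number of independent batches.
#' @param n_barcodes Barcodes per batch.
#' @param n_replicates Biological replicates after the timepoint-1
#'   split.
#' @param n_timepoints Total timepoints (timepoint 1 is pre-split).
#' @param Ne Effective population size governing drift.
#' @param deltaI Intrinsic decoupling variance per cycle (log scale).
#' @param deltaE Extrinsic (batch-shared) variance per cycle.
#' @param sd_fitness SD of per-barcode fitness effects alpha_i.
#' @param depth Sequencing depth per sample; either a scalar or a
#'   vector of length `n_timepoints` (heterogeneous per-timepoint
#'   depths give heterogeneous measurement-noise scales zeta_t).
#' @param f_range Range of initial barcode frequencies (log-uniform).
#' @param seed Optional integer seed.
#' @return List with `observed` (data.frame: `batch`, `barcode`,
#'   `replicate`, `timepoint`, `count`, `depth`, `frequency`) and
#'   `truth` (parameters, per-barcode `alpha`, per-batch `E` matrix,
#'   implied measurement-noise scale).
#' @export
generate_barcode_batches <- function(n_batches = 3, n_barcodes = 300,
                                     n_replicates = 3, n_timepoints = 5,
                                     Ne = 1e6, deltaI = 0.005,
                                     deltaE = 0.002, sd_fitness = 0.03,
                                     depth = 1e7,
                                     f_range = c(5e-6, 5e-3),
                                     seed = NULL) {
  stopifnot(n_timepoints >= 2, n_replicates >= 2, deltaI >= 0,
            deltaE >= 0, Ne > 0, all(depth > 0),
            length(depth) %in% c(1L, n_timepoints),
            f_range[1] > 0, f_range[2] < 1, f_range[1] < f_range[2])
  depth <- rep(depth, length.out = n_timepoints)
  if (!is.null(seed)) set.seed(seed)
  out <- list(); truth_a <- list(); truth_E <- list()
  for (b in seq_len(n_batches)) {
    f0 <- exp(stats::runif(n_barcodes, log(f_range[1]), log(f_range[2])))
    alpha <- stats::rnorm(n_barcodes, 0, sd_fitness)
    E <- stats::rnorm(n_timepoints - 1, 0, sqrt(deltaE))
    # latent log frequencies: [barcode, replicate, timepoint]
    lf <- array(NA_real_, c(n_barcodes, n_replicates, n_timepoints))
    lf[, , 1] <- log(f0)           # shared pre-split culture
    for (t in 2:n_timepoints) {
      for (r in seq_len(n_replicates)) {
        src <- if (t == 2) lf[, 1, 1] else lf[, r, t - 1]
        f <- exp(src)
        # log-normal drift approximation, valid for f >> 1/Ne; the
        # variance cap keeps rare low-frequency excursions from
        # producing unphysical multiplicative explosions
        vdrift <- pmin(pmax(1 - f, 0) / (Ne * f), 1)
        step <- alpha + E[t - 1] +
          stats::rnorm(n_barcodes, 0, sqrt(deltaI)) +
          stats::rnorm(n_barcodes, 0, sqrt(vdrift))
        lf[, r, t] <- src + step
      }
    }
    for (r in seq_len(n_replicates)) {
      for (t in seq_len(n_timepoints)) {
        if (t == 1 && r > 1) next   # single pre-split sample
        f <- exp(lf[, r, t])
        if (sum(f) >= 1) stop("barcode frequencies exceeded 1; lower f_range")
        cnt <- stats::rmultinom(1, depth[t], c(f, 1 - sum(f)))[seq_len(n_barcodes)]
        out[[length(out) + 1]] <- data.frame(
          batch = b, barcode = paste0("b", b, "_", seq_len(n_barcodes)),
          replicate = r, timepoint = t, count = cnt, depth = depth[t],
          frequency = cnt / depth[t])
      }
    }
    truth_a[[b]] <- alpha; truth_E[[b]] <- E
  }
  list(observed = do.call(rbind, out),
       truth = list(Ne = Ne, deltaI = deltaI, deltaE = deltaE,
                    sd_fitness = sd_fitness, depth = depth,
                    alpha = truth_a, E = truth_E))
}

#' Synthetic split-replicate cytometry experiment
#'
#' Emulates the single-cycle design in which mother cocultures at a
#' grid of initial minor-genotype frequencies are each split into
#' `n_reps` replicate daughter cultures, grown for one cycle (one
#' transition of the correlated-offspring model, drawn with
#' [sample_correlated_offspring()]), and measured by counting `events`
#' cells (binomial frequency noise).
#'
#' @param cov A [cov_structure()]; the default has drift strength
#'   `c0 - c1 = 1`, within-genotype covariance 0.05 and between-
#'   genotype correlation 0.9, i.e. decoupling parameter `delta = 0.01`.
#' @param f0_grid Initial frequencies of genotype A (two decades by
#'   default).
#' @param n_reps Daughter cultures per mother (default 16).
#' @param Ntot Total population size per culture.
#' @param events Cells counted per measurement (`Inf` = noiseless).
#' @param seed Optional integer seed.
#' @return List with `observed` (data.frame: `f0`, `replicate`, `N_A`,
#'   `N_B`, `frequency`, `events`) and `truth` (the covariance
#'   structure and design).
#' @export
generate_flow_cytometry_replicates <- function(
    cov = cov_structure(c0A = 1.05, c0B = 1.05, c1A = 0.05, c1B = 0.05,
                        cAB = 0.045),
    f0_grid = exp(seq(log(0.002), log(0.2), length.out = 8)),
    n_reps = 16, Ntot = 1e5, events = 5e4, seed = NULL) {
  cov <- as_cov_structure(cov)
  stopifnot(all(f0_grid > 0), all(f0_grid < 1), n_reps >= 2, Ntot > 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (f0 in f0_grid) {
    N_A <- round(f0 * Ntot); N_B <- Ntot - N_A
    tr <- sample_correlated_offspring(cov, N_A, N_B, n = n_reps)
    NAp <- pmax(tr$N_A, 0); NBp <- pmax(tr$N_B, 0)
    f <- NAp / (NAp + NBp)
    fobs <- if (is.finite(events)) stats::rbinom(n_reps, events, f) / events
            else f
    rows[[length(rows) + 1]] <- data.frame(
      f0 = f0, replicate = seq_len(n_reps), N_A = NAp, N_B = NBp,
      frequency = fobs,
      events = if (is.finite(events)) events else NA_real_)
  }
  list(observed = do.call(rbind, rows),
       truth = list(cov = cov, Ntot = Ntot, n_reps = n_reps,
                    events = events,
                    delta = decoupling_parameter(cov)))
}
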