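---
title: "Models and methods for decoupling noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for decoupling noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decoupnoise)
```

## The effective offspring-covariance model

Classical genetic drift treats individuals' offspring numbers as
independent random variables: with per-individual variance $c_0$, the
genotype-frequency variance after one generation is
$c_0 f(1-f)/N_{tot}$, and abundance variance scales linearly with
abundance.  Many real populations instead show abundance fluctuations
with Taylor's-law exponent two, $\mathrm{var}\,N \propto N^2$, which
requires offspring numbers to be *correlated* across individuals.  The
effective model implemented here assigns five covariance parameters to
a two-genotype population: individual variances $c_{0A}, c_{0B}$,
within-genotype covariances $c_{1A}, c_{1B}$, and the between-genotype
covariance $c_{AB}$.  The exact abundance moments are

$$\mathrm{var}\,N'_\mu = (c_{0\mu}-c_{1\mu})N_\mu + c_{1\mu}N_\mu^2,
\qquad \mathrm{cov}(N'_A, N'_B) = c_{AB} N_A N_B,$$

and the frequency variance, to first order in fluctuation size, is

$$\mathrm{var}\,f' \approx \frac{f(1-f)}{N_{tot}}
\left[(c_{0A}-c_{1A})(1-f) + (c_{0B}-c_{1B})f\right]
+ \delta\, f^2(1-f)^2,
\qquad \delta = c_{1A}+c_{1B}-2c_{AB}.$$

The composite parameter $\delta$ — the *decoupling parameter* — is
zero exactly when the genotypes' offspring fluctuations are perfectly
interchangeable ($c_{1A}=c_{1B}=c_{AB}$); any excess of within- over
between-genotype correlation produces frequency fluctuations scaling
as $f^2(1-f)^2$, which can dwarf drift at moderate frequencies.  Under
symmetric drift strength, $c_{0A}-c_{1A}=c_{0B}-c_{1B}$, the first
term collapses to $f(1-f)/N_e$ with $N_e = N_{tot}/(c_{0A}-c_{1A})$.

**Validity regime.** The frequency formula is first order in the
relative fluctuation size.  Its error, measured against the
individual-level sampling oracle (`sample_correlated_offspring`),
tracks the squared relative fluctuation of the total population,
roughly $3.8\,\mathrm{var}(N'_{tot})/N_{tot}^2$ — about $+3.5\%$ at
$N_{tot}=100$ for independent offspring, falling as $1/N_{tot}$, but
with a floor of order $c_1$ that does not shrink with population size
once correlated fluctuations dominate $\mathrm{var}(N'_{tot})$
(e.g. $\approx 20\%$ at $c_1 = 0.05$).  The package asserts exact
oracle agreement (within Monte-Carlo resolution at $10^5$ draws) for
$N_{tot} \ge 600$ and $c_1 \le 10^{-3}$; outside that regime the
formulas remain useful leading-order descriptions but the quadratic
coefficient is accurate only up to a relative error of order $c_1$.
The abundance moments are exact for any parameters.

## Simulators

`sample_correlated_offspring` draws one-generation transitions either
from the exactly implied bivariate normal of genotype totals (fast,
any size) or from the full individual-level multivariate normal via
its factor decomposition (shared global factor, per-genotype shared
factors, independent residuals).  Gaussian marginals are a choice of
convenience: the effective model constrains only first and second
moments, so any distribution with the same covariances validates the
moment algebra.  Totals are returned unrounded to avoid
discretization bias in moment checks.

`simulate_langevin` integrates the two-genotype logistic Langevin
dynamics with demographic noise
$\sqrt{N_i(\mu_i + N_{tot}/K)}\,\eta_i$ and correlated multiplicative
noise $N_i \xi_i$ (covariances $c_{1A}, c_{1B}$, correlation
$\rho_{AB}$) by Euler–Maruyama with step $\Delta t = 0.1$; halving
$\Delta t$ moves fixation estimates by less than their Monte-Carlo
confidence intervals (asserted in the test suite).  Abundances are
clamped at zero and extinction is absorbing, since the multiplicative
noise is undefined for negative abundance.  The standing simulation
conditions are $K/2 = 10^3$, $\mu_A = 1$, $\rho_{AB} = 0.5$, initial
abundances $10^{-3}K$ and $K$; trajectories for fixation estimates run
until the minor genotype drops below 0.1 individuals, with an explicit
non-termination error at a configurable horizon (default $10^7$
steps) instead of an unbounded loop.

**The coupled logistic maps.** The chaotic two-genotype model iterates

$$N_A \leftarrow r\,N_A\!\left(1 - \frac{N_A}{K_A} -
c\,\frac{N_B}{K_B}\right),$$

and symmetrically for $B$; at $c=0$ the genotypes are independent
standard logistic maps, and $r = 3.9$ puts them in the chaotic
regime.  The cross-competition term is normalized by the competitor's
carrying capacity.  This choice makes the normalized dynamics
$(u, v) = (N_A/K_A,\, N_B/K_B)$ independent of the carrying
capacities, which is what produces exact Taylor exponents of two for
both abundance and frequency across any sweep of $K$ — the property
the model exists to demonstrate — and keeps the map well behaved when
the capacities differ by orders of magnitude.  Normalizing the cross
term by $K_A$ instead drives the minor genotype negative whenever
$K_A \ll K_B$, which defeats the capacity sweep.  The map is reliable
for $c \lesssim 0.15$ at $r = 3.9$; stronger coupling can push
abundances negative, which the simulator reports as a divergence
error, so the coupling-insensitivity checks in the test suite cover
$c \in \{0.01, 0.05, 0.1\}$.  The default exponent sweep holds
$K_B = 10^6$ and varies $K_A$ over three decades chosen to keep the
mean frequency below $10^{-2}$: at higher frequencies the $(1-f)^2$
saturation factor visibly bends the log–log relation and the fitted
exponent drops below two for reasons unrelated to the dynamics.

## Diffusion theory

In the diffusion limit the frequency process has variance
$v(f) = f(1-f)/N_e + \delta f^2(1-f)^2$ and drift
$a(f) = f(1-f)\,[s_e + \delta(1/2 - f)]$ with effective fitness
$s_e = s + (c_{1B}-c_{1A})/2$, obtained by Itô reduction of the
abundance Langevin equations and verified against short-time ensemble
moments of the simulator before anything downstream relies on it (a
dedicated test).  The frequency-dependent part of the drift gives an
otherwise neutral mutant an effective advantage when rare and a
handicap when common.

Fixation probabilities use the standard scale-function construction
$p_{fix}(f_0) = S(f_0)/S(1)$ with
$\psi = \exp(-2\!\int\! a/v)$ and $S(x)=\int_0^x \psi$.  The inner
integrand $2a/v = (2s_e + \delta(1-2u))/(1/N_e + \delta u(1-u))$ is a
rational function whose antiderivative is evaluated in closed form
(partial fractions), so only the outer integrals are computed by
adaptive quadrature, on a common log-scale offset so that widely
different magnitudes of $\psi$ cannot overflow.  The site frequency
spectrum uses the sojourn-time construction
$p_{SFS}(f) = \theta\,(S(1)-S(f)) / (N_e\,v(f)\,\psi(f)\,S(1))$, with
the mutational-influx constant calibrated so the neutral drift-only
limit is $\theta/f$; the Monte-Carlo estimator `estimate_sfs` divides
binned sojourn densities by $2 f_0 N_e$, the same convention, so
theory and simulation are directly comparable (the simulation
estimate is valid above the injection frequency $f_0$, and the
comparison starts mutants at $f_0 = 10^{-2}$ so that enough
trajectories traverse the spectrum).

Known limits reproduced by the quadrature and asserted in tests:
neutral $p_{fix} = f_0$ and $p_{SFS} = \theta/f$; the classical
constant-selection formulas as $\delta \to 0$; midpoint diversity
$4\theta$ under strong selection without decoupling, falling
continuously to $2\theta$ under strong decoupling; the high-frequency
plateaus $2 s_e N_e \theta$ (selection) and
$\theta\,\delta N_e/(2\log\delta N_e)$ (decoupling); and a $1/f$
low-frequency decay in all regimes.

The decoupling-drift barrier is implemented as
$s_e^* = \delta/(2\log\delta N_e)$.  This grouping is fixed by an
exact anchor: in the neutral strong-decoupling limit the quadrature
(and a two-line closed form, since $\psi = D(0)/D(x)$ with
$D(x) = 1/N_e + \delta x(1-x)$) gives
$p_{fix} = f_0\,\delta N_e/(2\log\delta N_e)$, which equals the flat
branch $f_0 N_e s_e^*$ of the piecewise approximation only under this
reading; it also makes the barrier shrink with growing $N_e$, as
selection efficiency demands.  The piecewise approximation switches
to the classical branch at $s_e^*$ and agrees with the quadrature to
better than 15% away from the crossover at $\delta N_e \in \{10,
100\}$.

The first-order Langevin reduction degrades at large $\delta N_e$;
`fixation_probability` emits a regime warning above a configurable
threshold (default $\delta N_e > 100$) rather than guessing
higher-order corrections.

## Scaling statistics

`robust_variance` is $2.1981 \cdot \mathrm{MAD}^2$ (the constant is
$1/\Phi^{-1}(0.75)^2$, Gaussian-consistent).  `fit_power_law` is OLS
of $\log$ variance on $\log$ mean with bootstrap confidence intervals
that resample replicate trajectories, not points, wherever replicate
structure exists; nonpositive pairs are excluded with a count rather
than pseudocounted, because pseudocounts bias the exponent.
`moving_average_multiplicative` averages within
$[x_0(1-w), x_0(1+w)]$ (default $w = 0.3$), i.e. a constant-width
window on $\log x$, for extracting mean–variance curves from
per-lineage scatter.  `drift_variance_recursion` gives the
bottleneck-drift null expectation
$\mathrm{var} f_{t+1} = \mathrm{var} f_t + f_t(1-f_t)/N_e$.

## Chaos diagnostics

Exponentially growing between-replicate variance is the fingerprint
of chaotic divergence from nearly identical initial conditions.
`fit_variance_growth_models` compares exponential, linear,
generalized-power and quadratic growth curves on the log-variance
scale by $AIC = n\log(\mathrm{MSE}) + 2p$, with one-sided paired
bootstrap p-values obtained by resampling replicate trajectories.
`lyapunov_from_variance` reads $\lambda = b/2$ off the exponential
fit (since $\mathrm{var} \propto e^{2\lambda t}$);
`lyapunov_nnd` is a Rosenstein-style estimator adapted to many short
replicates: delay-embed, pair each trajectory with its nearest
neighbour at the initial time, and fit
$\log d_{i,j}(t) = \lambda t + b$ pooled over pairs with equal
weighting (the source method does not state a weighting; equal weights
are the neutral choice).  Distances default to logit-transformed
frequencies, since genotype frequencies live on $(0,1)$; a raw-scale
option covers general data, and exact ties (duplicate trajectories)
are excluded rather than propagating $\log 0$.  Embedding
hyperparameters are chosen by shuffle-split cross-validation (1000
splits, 30 in-sample points by default).  Both estimators recover
$\lambda = \ln 2$ on the $r = 4$ logistic map, agree with each other
at $r = 3.9$, and stay consistent with $\lambda \le 0$ on diffusive
or noisy non-chaotic ensembles (test suite).  The analysis window
(the paper-like "after 7 hours" choice for real timecourses) is a
required user decision, not auto-detected.

## Partitioning intrinsic and extrinsic decoupling noise

Multi-day split designs make the noise sources separable: intrinsic
decoupling noise decorrelates replicate cultures, environmental
(extrinsic) noise moves all same-day cultures together, and
memory-like effects correlate cultures sharing a mother at a split.
The hierarchical model for logit-frequency displacements is

$$\Delta\mathrm{logit} f_{t,g,i} \sim \mathcal{N}\!\left(\alpha +
\beta f_{t,g,i} + E_t + M_{g,t},\; \delta_I + \mu_{t,i}\right),
\quad E_t \sim \mathcal{N}(0, \delta_E),
\quad M_{g,t} \sim \mathcal{N}(0, v_M),$$

with mother effects active only on displacements leaving a split day.
The frequency-dependent fitness covariate is the measured natural-scale
frequency, kept as stated in the source model even though a
logit-scale covariate would be a defensible alternative.  Measurement
variance uses the delta-method binomial form on the transformed
scale, $\mu = 1/(f_{t+1}(1-f_{t+1})n_{t+1}) + 1/(f_t(1-f_t)n_t)$ for
logit displacements and $(1-f)/(fn)$ per endpoint for log
displacements; the generator moment check (sample displacement
variance $\approx \delta_I + \bar\mu$) pins this form down.

Variance components carry the $p(x) \propto x^{-2}$ prior,
implemented exactly as a uniform prior on $1/x$ truncated at $10^7$
(variance floor $10^{-7}$): the prior is improper at zero, so the
truncation is what makes the posterior proper, and a consequence
worth understanding is that when the data only weakly demand a
positive shared-effect variance, the posterior for that component
concentrates at the truncation floor.  That is the expected behaviour
for the mother-effect variance in realistic designs (a handful of
split events cannot overcome the prior's preference for zero unless
the effects are large) and mirrors the near-zero mother effects seen
in such experiments.  Sampling uses JAGS (four chains by default,
seeded, non-centred latent effects, uniform priors on $\alpha,
\beta$).  Non-convergence is an error, not a return value: the gate
applies the split-chain diagnostic to $\alpha$, $\beta$ and
$\delta_I$, which every record informs, on the sampled $1/x$ scale
for the variance; $\delta_E$ and $v_M$ are reported with their
diagnostics but not gated, because floor/bump mode alternation of a
boundary-concentrated component inflates the statistic regardless of
parameterization.

Three caveats, quantified in the package's calibration tests.  The
model treats displacement records as independent although consecutive
records of one culture share the middle measurement; the frequency
covariate is measured with error; and the $x^{-2}$ prior acts like
two phantom zero-observations on each variance component, which
matters for $\delta_E$ with only a dozen latent day effects.
Together these depress $\delta_I$ slightly (about $-7\%$ at $10^4$
counted events) and leave the 95% intervals of $\delta_I$ and
$\delta_E$ covering their generative values a few points below the
nominal rate on full synthetic trajectories — hovering around nine in
ten — while coverage is nominal on records generated exactly under
the model's independence assumptions.  All three features are
inherited from the published model form rather than the
implementation.

For barcoded-lineage data at low frequency the log scale replaces the
logit and the model gains per-barcode fitness intercepts and loses
mother terms, with measurement-noise scales $\hat\zeta_t$ supplied by
the MSD machinery: `estimate_kappa` computes robust
(MAD-based) variances of replicate-centred log displacements — the
centring removes per-barcode fitness and batch-shared environmental
displacement, and the $(1-1/R)$ variance deflation from centring
across $R$ replicates is corrected by $R/(R-1)$ — and
`deconvolve_msd` separates the time-accumulating component
$\delta\Delta t$ from the time-local measurement components $\zeta_t$
by weighted least squares over timepoint pairs (nonnegativity
enforced; at least two distinct $\Delta t$ values are required for
identifiability, and rank deficiency is an error).  Deconvolved MSD
values may be negative by noise and are reported as such, with a
clamped column for plotting only; confidence intervals use a
parametric bootstrap on $\hat\kappa$ because the function's contract
receives only the table of estimates and standard errors.  The
$\zeta_t$ are treated as constant over the analysis frequency
window.

## Synthetic data generators

All generators return the latent truth next to the observations, and
all recovery tests consume only the observations.  Fixed seeds give
bitwise-identical output.

* `generate_split_experiment` — serial-split design: 4 cultures at
  day 0, 3-fold splits at day 3 and 2-fold at day 7 (so 24 cultures
  from day 7 on), 12 days, logit-displacement dynamics with
  frequency-dependent fitness defaulting to an equilibrium near
  $f = 0.05$, intrinsic/extrinsic variances $\delta_I = 0.01$,
  $\delta_E = 0.02$, no mother effects by default, and binomial
  measurement at $10^4$ events.  Daughter cultures are measured
  independently from the split day onward; the displacement interval
  entering a split day belongs to the parent and is not duplicated.
* `generate_barcode_batches` — batches of barcode trajectories with
  one pre-split sample and three replicates thereafter, log-uniform
  initial frequencies over three decades ($5\times10^{-6}$ to
  $5\times10^{-3}$), per-barcode fitness effects, shared per-timepoint
  environmental displacements, intrinsic decoupling noise, classical
  drift at $1/N_e$ (log-normal approximation, valid for $f \gg 1/N_e$;
  the per-step drift variance is capped at 1 to keep the
  approximation's tails physical), and multinomial read sampling.
  With the default $N_e = 10^6$ and $\delta_I = 5\times10^{-3}$ the
  mean–variance cloud crosses from drift-like slope 1 to
  decoupling-like slope 2 near $f^* = 1/(N_e\delta_I) = 2\times
  10^{-4}$.
* `generate_flow_cytometry_replicates` — the single-cycle design: a
  grid of mother frequencies over two decades, 16 daughters each, one
  offspring-model transition, binomial measurement.  The default
  covariance structure has drift strength 1, $c_1 = 0.05$ and
  $\rho_{AB} = 0.9$, i.e. strongly but not perfectly coupled
  genotypes with $\delta = 0.01$.

What the generators deliberately do not emulate: within-cycle growth
phases (lag/exponential/stationary), environmental autocorrelation
across days, read-count overdispersion beyond multinomial, barcode
extraction artefacts, and real flow-cytometry gating.  Passing
recovery tests therefore demonstrate that the estimators invert the
stated generative models at realistic sizes and noise levels — not
that real cultures obey those models.

## Problem sizes used by the test suite

Simulation sizes are chosen so the full suite exercises every
pipeline at meaningful precision: $10^5$-draw oracle sweeps, $10^4$
Langevin replicates for fixation concordance, $10^5$-iteration map
sweeps with three replicate trajectories per capacity, 50-repetition
hierarchical recovery at slightly reduced MCMC length (4 chains,
1500 burn-in, 2000 kept), and 500-barcode batches for the MSD
round-trip.
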