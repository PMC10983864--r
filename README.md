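# decoupnoise

Genotype frequencies in replicate microbial cultures can fluctuate
orders of magnitude more than classical genetic drift allows.
`decoupnoise` implements an effective model in which this excess —
*decoupling noise* — arises from offspring numbers that are correlated
more strongly within genotypes than between them, together with the
simulators, diffusion theory, scaling statistics, chaos diagnostics
and Bayesian variance partitioning needed to detect it, quantify it,
and work out its evolutionary consequences.  It is aimed at people
analysing replicate frequency timecourses from serial-dilution
evolution experiments or barcoded-lineage tracking.

## The model

Each individual of genotype $\mu \in \{A, B\}$ leaves a random number
of net offspring with variance $c_{0\mu}$, within-genotype covariance
$c_{1\mu}$ and between-genotype covariance $c_{AB}$.  The abundance
moments are exact,

$$\mathrm{var}\,N'_\mu = (c_{0\mu}-c_{1\mu})\,N_\mu + c_{1\mu} N_\mu^2,
\qquad \mathrm{cov}(N'_A,N'_B) = c_{AB}\,N_A N_B,$$

so correlated reproduction produces Taylor's-law scaling
$\mathrm{var}\,N \propto N^2$.  The genotype-frequency variance is

$$\mathrm{var}\,f' \approx \frac{f(1-f)}{N_e} + \delta\,f^2(1-f)^2,
\qquad \delta = c_{1A} + c_{1B} - 2c_{AB},$$

classical drift plus a quadratically scaling decoupling term that
vanishes only when the genotypes fluctuate in perfect sync.  In the
diffusion limit, decoupling reshapes evolutionary outcomes: a neutral
mutant fixes with probability above its initial frequency, selection
weaker than the decoupling-drift barrier
$s_e^* = \delta/(2\log\delta N_e)$ cannot sort genotypes, and the site
frequency spectrum is depressed at intermediate frequencies (from
$4\theta$ toward $2\theta$ at $f = 1/2$) while gaining a
high-frequency uptick.

## Worked example

Partition the frequency-displacement variance of a serial-split
experiment into intrinsic decoupling noise, shared environmental
noise and mother-culture effects:

```r
library(decoupnoise)

# synthetic serial-split design: 4 cultures split 3-fold at day 3 and
# 2-fold at day 7, 12 days, truth deltaI = 0.01, deltaE = 0.02
g <- generate_split_experiment(seed = 11)
recs <- compute_displacements(g$observed, mode = "logit")
fit <- fit_hierarchical_model(recs, seed = 5)
fit
#> Posterior partition of frequency-displacement variance
#>              q2.5     median     q97.5
#> alpha    0.389992   0.537914  0.680953
#> beta   -13.973726 -11.495405 -8.987097
#> deltaI   0.005399   0.007783  0.010998
#> deltaE   0.004763   0.010689  0.030004
#> vM       0.000000   0.000000  0.000002
#> max split-chain Rhat, gated parameters: 1.020
#>   (boundary-variance components reach Rhat 2.32; see docs)
```

The intrinsic and extrinsic components bracket their generative
values (0.01 and 0.02), the frequency-dependent fitness slope is
recovered (truth $\beta = -10$), and the mother-effect variance
collapses to zero (truth 0).

Diffusion-theory predictions come from the same parameter objects:

```r
p <- diffusion_params(Ne = 1e3, s = 0, delta = 0.01)   # deltaNe = 10
fixation_probability(1e-3, p)
#> [1] 0.002375698        # > f0: neutral mutants fix more often
sfs(0.5, diffusion_params(Ne = 1e3, s = 0.05, delta = 0))
#> [1] 4                  # classical strong-selection midpoint, 4*theta
```

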