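# mranoise

Noise propagation in Modular Response Analysis (MRA) network
reconstruction.

## The problem

MRA infers the *direct* pairwise interactions of a signalling network from
steady-state responses to node-specific perturbations. For an N-node
network described by an ODE system $\dot x = f(x, p)$, where each
parameter $p_j$ perturbs only node $j$ (e.g. a knockdown of its total
protein), the method proceeds in two transformations:

- **T1** — from measured fold changes to *global response coefficients*
  (GRCs): $\tilde R_{ij} = 2\,(\bar z_i^{\,j} - \bar z_i^{\,0}) /
  (\bar z_i^{\,0} + \bar z_i^{\,j})$, a symmetric finite-difference
  estimate of $\mathrm{d}\ln \bar x_i / \mathrm{d}p_j$ that is invariant
  to blot-proportionality factors.
- **T2** — from GRCs to *local response coefficients* (LRCs), the signed
  edge weights $r_{ij}$ of the network, by solving the MRA relations
  $\sum_{j \ne i} r_{ij} \tilde R_{jk} = \tilde R_{ik}$ ($k \ne i$), one
  independent $(N\!-\!1)\times(N\!-\!1)$ linear block per node, with
  $r_{ii} = -1$ by convention. Replicates can be handled by averaging
  GRCs ("mean"), by stacking into an overdetermined ordinary
  least-squares system ("ols"), or by total least squares ("tls", an
  error-in-variables solve via the SVD of $[A\,|\,y]$).

Real perturbation data (quantified Western blots) carry measurement error,
modelled here as $\bar z = \bar x \cdot \eta + \varepsilon$ with
$\eta \sim \log\mathcal N(0, \sigma_\eta^2)$ multiplicative and
$\varepsilon \sim \mathcal N(0, \sigma_\varepsilon^2)$ additive noise.
Both transformations are non-linear in the measurements, so the noise
distribution is reshaped on its way to the inferred network — notably, T2
produces *heavy-tailed* LRC distributions whose moments are unreliable.
The package quantifies this with robust tail statistics (the medcouple and
its one-sided variants LMC/RMC, ≈ 0.2 for Gaussian and ≈ 0.5 for Cauchy
tails), the bias of the median, the IQR, and a sign-aware AUC score of
network recovery (1 for perfect recovery, 0.25 expected for random
estimates).

Two built-in three-node test-bed models span the relevant non-linearity
range: a MAPK cascade (Michaelis–Menten kinetics, mildly non-linear
steady-state responses) and a p53–MDM2–ATM feedback circuit
(ultra-sensitive Hill kinetics, strongly sigmoidal responses).

## Worked example

```r
library(mranoise)

## one simulated experiment: 80% knockdowns, realistic blot noise
prof <- perturbation_response(mapk_model(), rep(0.2, 3))
ms   <- sample_measurements(prof, noise_spec(0.1, 0.2, seed = 7),
                            replicates = 3, strategy = "cs1")
fit  <- mra(ms, estimator = "mean")
fit
#> MRA fit (mean estimator, 3 replicate GRC matrices)
#> Local response coefficients (diagonal fixed at -1):
#>         [,1]    [,2]    [,3]
#> [1,] -1.0000  0.0337 -0.1697
#> [2,]  1.2650 -1.0000 -0.1448
#> [3,] -0.2372  1.4970 -1.0000
```

The three true edges (MEK activated by Raf, `r21 = 1.36`; ERK by MEK,
`r32 = 1.48`; the negative ERK→Raf feedback, `r13 = -0.51`) are recovered
with the right signs and dominant magnitudes; the small nonzero entries on
non-edges reflect noise plus the finite-perturbation approximation.

```r
## noise propagation at scale
mc <- mra_montecarlo(mra_scenario("mapk", "kd80", sigma_eta = 0.1,
                                  sigma_eps = 0.2, replicates = 1,
                                  control_strategy = "cs1",
                                  estimator = "mean",
                                  runs = 2000, seed = 1))
summary(mc)[, c("coefficient", "true", "noise_free", "median", "iqr", "lmc", "rmc")]
#>   coefficient   true noise_free  median   iqr   lmc   rmc
#> 1         r12  0.000     0.0347  0.0304 0.177 0.152 0.277
#> 2         r13 -0.511    -0.2787 -0.2747 0.178 0.225 0.206
#> 3         r21  1.363     1.1971  1.1872 0.318 0.196 0.291
#> 4         r23  0.000     0.0117  0.0224 0.241 0.208 0.215
#> 5         r31  0.000    -0.0656 -0.0609 0.445 0.307 0.256
#> 6         r32  1.478     1.1699  1.1729 0.318 0.212 0.256
sign_correct_rate(mc)
#> [1] 0.993
```

The Monte Carlo medians sit on the *noise-free* finite-perturbation values
(column `noise_free`), not on the Jacobian truth — the bias of the median
is dominated by the intrinsic finite-difference bias. Several LRC tail
weights (`lmc`/`rmc`) exceed the Gaussian reference 0.2 even though the
underlying measurement noise is Gaussian/lognormal: the T2 solve amplifies
tails. `grc_tail_summary(mc)` shows the GRC-level statistics for
comparison, and `plot(mc)` draws the estimate boxplots.

A thin command-line wrapper over the same pipeline is installed at
`inst/scripts/mra-noiselab.R`.

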