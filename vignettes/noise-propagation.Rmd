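---
title: "Noise propagation through MRA network reconstruction: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise propagation through MRA network reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mranoise)
```

# The estimation problem

Modular Response Analysis (MRA) treats a signalling network of $N$
modules (here: single proteins, "nodes") at steady state. The direct
influence of node $j$ on node $i$ is the local response coefficient (LRC)

$$ r_{ij} = \left.\frac{\partial \ln \bar x_i}{\partial \ln \bar x_j}
\right|_{\bar x_k\ \mathrm{const},\,k \ne i,j}, $$

which is not directly measurable. What experiments deliver are global
responses: after perturbing a parameter $p_j$ that acts on node $j$
alone, every node settles to a new steady state, and the fold change of
node $i$ defines the global response coefficient (GRC). MRA's central
identity, $\sum_{j\ne i} r_{ij} R_{jk} = R_{ik}$ for $k \ne i$, converts
measured GRCs into the LRCs that constitute the network's signed, weighted
edges.

The package implements the full simulated-experiment workflow:

1. **Test-bed truth.** An ODE model $\dot x = f(x, p)$ supplies exact
   steady states and, via the normalized Jacobian at steady state,
   ground-truth LRCs: $r_{ij}^{true} = -(J_{ij}/J_{ii})(\bar x_j/\bar
   x_i)$ with the convention $r_{ii} = -1$.
2. **T1.** Finite-difference GRCs from control/perturbed measurement
   pairs: $\tilde R_{ij} = 2(\bar z_i^j - \bar z_i^0)/(\bar z_i^0 + \bar
   z_i^j)$. The symmetrized denominator bounds the statistic in $(-2,2)$
   for positive data and cancels blot-proportionality factors; the
   perturbation increment $\Delta p_j$ cancels from the MRA relations, so
   its magnitude never needs to be known.
3. **T2.** Per target node $i$, an $(N-1)\times(N-1)$ linear block in the
   unknowns $r_{ij}$, $j \ne i$. Replicate GRC matrices are handled by
   one of three estimators: `mean` (average GRCs, one solve), `ols`
   (stack replicate blocks, QR least squares) or `tls` (stacked total
   least squares through the SVD of the augmented block).

Because T1 is a ratio of noisy quantities and T2 effectively divides by
noisy GRCs again, measurement noise is transformed non-linearly twice.
The package's purpose is to characterize the resulting LRC distributions
and their consequences for network recovery.

# Test-bed models

Both built-in models have three nodes, two activating edges and one
negative feedback, but deliberately different non-linearity:

* `mapk_model()` — a Raf→MEK→ERK cascade of
  phosphorylation/dephosphorylation cycles with Michaelis–Menten
  kinetics and a negative ERK→Raf feedback. Steady-state responses over
  the studied perturbation range $p_j \in [0.2, 1.5]$ are close to
  linear.
* `p53_model()` — ATM→p53→MDM2 with an MDM2⊣p53 feedback, using three
  ultra-sensitive Hill terms (coefficient 4). Responses are strongly
  sigmoidal over the same range.

Each $p_j$ multiplies the total-protein or production term of node $j$,
so $p_j = 0.2$ emulates an 80% knockdown and $p_j = 1.5$ a 150%
overexpression. The kinetic constants are the package's own documented
parameterizations, chosen (once) to satisfy the structural and
qualitative constraints: correct signed edges, strictly positive and
asymptotically stable steady states at every studied $p_j$ with no
bifurcation, the stated non-linearity contrast, and — for the p53 model —
an intrinsic finite-difference bias at strong knockdowns that clearly
exceeds the MAPK model's. All acceptance properties are therefore
property-based rather than tied to one parameter set.

**Concentration units.** States are expressed in units in which control
steady states lie at a few signal units (MAPK ≈ 2–4, p53 ≈ 3–5). This
pins the *meaning* of the additive-noise grid: with
$\sigma_\varepsilon \in \{0.1, 0.2, 0.5\}$ the additive error spans
roughly 2–20% of a control signal — a realistic background level for
normalized densitometry, and the regime in which measurement and GRC
distributions remain near-Gaussian while the LRC tails do not. If the
additive error were instead comparable to the signal itself, every
statistic would be dominated by sign flips of the measurements and the
noise *grid* would lose its graded interpretation.

# The noise model and experimental designs

`sample_measurements()` applies
$\bar z = \bar x\,\eta + \varepsilon$, $\eta \sim \log\mathcal N(0,
\sigma_\eta^2)$, $\varepsilon \sim \mathcal N(0, \sigma_\varepsilon^2)$,
independently across nodes, perturbations and replicates. Two control
strategies are supported: CS1 re-uses one control realization per
(node, replicate) across all perturbations — the economical design —
while CS2 draws an independent control per perturbation. CS1's sharing
induces block-wise positive correlations among the GRCs of one node;
whether this matters downstream is one of the questions the Monte Carlo
layer answers (it does not, to within the intrinsic bias).

Negative or zero noisy realizations, possible when
$\sigma_\varepsilon$ is large relative to a small steady state, are kept
untruncated: the error model places no truncation, and censoring would
bias every distributional summary. T1 guards its own domain (an exactly
zero denominator raises a domain error; the Monte Carlo driver counts and
drops such runs instead of imputing).

Blot-specific proportionality factors are not simulated; T1 is exactly
invariant to them as long as control and perturbed samples share a blot.

**Randomness.** Each `sample_measurements()` call seeds its own stream
and draws in a fixed, documented order (control block, then perturbed
block), so a (configuration, seed) pair is bit-reproducible. The Monte
Carlo driver derives one sub-seed per run (and per knockdown strength in
the mixture design) from the scenario's root seed; scenario grids derive
independent sub-seeds per scenario. This order-fixed scheme achieves the
same reproducibility as per-draw stream splitting with far less
machinery.

# Robust tail statistics

Heavy-tailed LRC distributions make moments (mean, variance, skewness,
kurtosis) unstable, so the package summarizes Monte Carlo samples with
quantile-based statistics: the median, its absolute bias from the true
LRC, the IQR, and the left/right medcouples. The medcouple of a sample
with median $m_n$ is the median of the kernel
$h(x_i, x_j) = ((x_j - m_n) - (m_n - x_i))/(x_j - x_i)$ over pairs
$x_i \le m_n \le x_j$; applied to the strict half-samples it yields
$\mathrm{LMC} = -\mathrm{MC}(x < m_n)$ and
$\mathrm{RMC} = \mathrm{MC}(x > m_n)$, monotone measures of tail weight
with reference values ≈ 0.2 (Gaussian) and ≈ 0.5 (Cauchy).

Implementation choices, made for fidelity to the printed kernel
definition:

* pairs with $x_i = x_j$ are excluded (the kernel is 0/0 there); values
  tied with the median enter both half-sets when admissible. No
  sign-kernel special-casing of median ties is applied — for continuous
  data exact ties have probability zero, and the tie behaviour is pinned
  by an exact brute-force oracle test instead.
* evaluation is the exact $O(n^2)$ enumeration. Samples beyond the `cap`
  (default 10,000 — the half-samples of a 10,000-run Monte Carlo are
  evaluated exactly) are first thinned to `cap` evenly spaced order
  statistics, a deterministic quantile-preserving reduction that avoids
  injecting RNG state into a summary statistic.
* even-length medians are the mean of the two central order statistics.

# Sign-aware network evaluation

To judge recovered *structures* rather than individual coefficients, the
package scores an estimated LRC matrix against the reference sign matrix
with a ROC-like sweep in which a detected interaction only counts as
correct when its sign matches. Sign-aware ROC scoring has no single
canonical algorithm, so this module fixes one precise rule and isolates
it behind its own interface:

* at threshold $t$, an off-diagonal entry is "present" iff
  $|\hat r_{ij}| > t$ (strict, for deterministic tie handling);
* sensitivity $=$ sign-correct detected edges / number of true edges;
  false-positive rate $=$ detected non-edges / number of non-edges (a
  detected edge with the wrong sign is a false positive in the confusion
  counts, and never contributes to sensitivity);
* $t$ sweeps all distinct magnitudes plus $0$ and $\infty$; the curve is
  completed at false-positive rate 1 and integrated by the trapezoidal
  rule (exact for step curves).

This interpretation reproduces both calibration anchors exactly: a
perfectly signed, perfectly ranked estimate scores 1, and random
estimates with continuous symmetric magnitudes and independent signs
score 0.25 in expectation — random signs halve the 0.5 expected area of a
sign-blind random ranking. The score is invariant to positive rescaling
of the estimate, and the all-signs-flipped estimate scores 0.

# Monte Carlo orchestration

`mra_scenario()` fixes a study configuration (model, design, noise,
replicates, control strategy, estimator, runs, seed);
`mra_montecarlo()` executes it, storing per-run LRC estimates,
replicate-mean GRCs and per-run fit quality, plus per-coefficient robust
summaries against the Jacobian truth and the design's intrinsic bias
$\Delta r_{ij} = |\tilde r_{ij}(p) - r_{ij}^{true}|$. Failed runs are
dropped and counted by reason. `run_scenario_grid()` executes a list of
scenarios with independent derived sub-seeds and returns one tidy table.

**The mixture design.** Taking "replicates" from three different
knockdown strengths (80/50/25%) admits two readings: average the three
strength-specific GRC matrices, or stack them before T2. The implemented
reading treats them as a replicate stack — stacked for `ols`/`tls`,
averaged by `mean` — so both paths are exposed through the estimator
argument.

**Problem sizes.** The package's Monte Carlo default is 1,000 runs;
10,000 reproduces the full-scale study. The shipped test suite exercises
the qualitative findings at 800–5,000 runs per scenario — amply
sufficient, since each result is a strict ordering (e.g. 80% vs 25%
knockdown sign-recovery rates differ by 0.2–0.6) rather than a marginal
effect. The medcouple reference anchors use $10^5$ draws.

# Numerical choices

* **Steady states**: `deSolve::lsoda` integration in chunks until
  $\|f\|_\infty < 10^{-9}$ (robust for the stiff Hill kinetics), then
  damped Newton polishing to $10^{-12}$; non-convergence raises an error
  carrying the residual. Jacobians by central differences with relative
  step $10^{-6}$ scaled to the state magnitude.
* **OLS** via QR (`qr.coef`), mathematically the normal-equation solution
  $(A^TA)^{-1}A^Ty$ but better conditioned; rank deficiency raises an
  error naming the block.
* **TLS** per block from the right singular vector of the smallest
  singular value of $[A\,|\,y]$; a (near-)multiple smallest singular
  value or a vanishing last component raises a degeneracy error rather
  than returning an arbitrary solution.
* **Diagonal convention**: $r_{ii} = -1$ is imposed, never estimated;
  only the $N(N-1)$ off-diagonals are unknowns.

# What the synthetic path does and does not emulate

The generator reproduces: steady-state fold-change measurements, combined
multiplicative-lognormal/additive-Gaussian error, replicate structure,
shared vs independent controls, and single-parameter perturbation
designs including mixtures of strengths. It does not emulate blot-level
normalization artifacts, loading-control error, non-Gaussian additive
error families, proportionality factors between blots, perturbation
off-target effects, or systems with bifurcations/multistability (the MRA
formalism itself assumes a continuous parameter–steady-state map).
Passing tests therefore validate the workflow's statistical behaviour
under the stated error model, not the fidelity of any particular
laboratory protocol.

# Known limitations

* The two test-bed parameterizations are representative, not fitted to
  data; quantitative figures (e.g. specific LRC magnitudes) are
  model-specific, and only order/sign/contrast properties are treated as
  conclusions.
* Estimators beyond mean/OLS/TLS (feasible GLS, maximum likelihood,
  Bayesian variants) and underdetermined/sparse MRA are out of scope.
* The optional import of deposited SBML models is not provided in this
  build; the model registry (`mra_model("mapk")`, `mra_model("p53")`)
  covers the supported systems.
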