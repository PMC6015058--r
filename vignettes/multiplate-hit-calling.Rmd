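---
title: "Multi-plate Bayesian hit calling: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-plate Bayesian hit calling: model, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(platehit)
```

## The problem

Primary high-throughput screens read out the activity of $10^4$–$10^6$
compounds arrayed on microtiter plates (96-well plates keep 80 compound
wells once the two outer control columns are removed; 384-well plates keep
352). Hit calling must contend with three facts: compound activity
distributions are rarely Gaussian (log-normal shapes with heavy right
tails are typical), systematic row/column artifacts differ from plate to
plate, and true hits are rare — sometimes a few per hundred thousand
wells. Classical per-plate scores (Z, B, R) normalize each plate in
isolation and then require an arbitrary score cutoff; they cannot borrow
strength across plates.

## The model

`platehit` models all plates jointly with two hierarchical Dirichlet
process (HDP) Gaussian mixtures, one per activity channel. For well $i$
on plate $m$ with readout $z_{mi}$:

$$
z_{mi} \sim \pi \sum_{h=1}^{H} \lambda^{(1)}_{mh}\,
  \mathcal{N}(z_{mi};\theta^{(1)}_{h})
 + (1-\pi) \sum_{h=1}^{H} \lambda^{(0)}_{mh}\,
  \mathcal{N}(z_{mi};\theta^{(0)}_{h}),
$$

where superscript (1) marks the active (hit) channel and (0) the inactive
one. Each plate carries its own local mixture weights
$\lambda^{(c)}_{m\cdot}$ (a finite stick-breaking DP with concentration
$\alpha_c$ and truncation $H$), and every local cluster points to one of
$K$ global Gaussian atoms per channel, themselves weighted by a global
stick-breaking DP (concentration $\tau_c$, truncation $K$). Atoms are
therefore shared across plates: two plates affected by the same artifact
can reuse the same atom, while an idiosyncratic plate can load on atoms
other plates ignore. Controls are not used.

Priors: $\pi \sim \mathrm{Beta}(a_\pi, b_\pi)$ (uniform by default),
$\alpha_c, \tau_c \sim \mathrm{Ga}(1, 1)$, and Normal–inverse-gamma atom
priors $\mu_c \sim \mathcal{N}(\mu_{c0}, \sigma_c^2)$,
$\sigma_c^2 \sim \mathrm{Inv\text{-}Ga}(a, b)$. The anchors $\mu_{10}$
(active) and $\mu_{00}$ (inactive) are the only asymmetry between the two
channels and are what identifies "active" as the upper mode.

### Automatic hyperparameters

`auto_hyperparameters()` sets, with $\mu$ and $v$ the pooled compound
mean and sample variance:
$\mu_{00} = \mu/2$, $\mu_{10} = 3\mu_{00}$,
$a = v^2/10^{-4} + 2$, $b = v^3/10^{-4} + v$ — an inverse-gamma prior
with mean $v$ and variance $10^{-4}$ ($v = 0.01$ gives exactly $a = 3$,
$b = 0.02$). These rules assume positive-scale readouts; for data already
standardized per plate (`standardize_plates()`, mean 0 / variance 1 per
plate), set the anchors manually.

### Gibbs sampler

One sweep updates, in fixed order: (1) activity indicators $b_{mi}$ from
the two channel mixture likelihoods weighted by $\pi$; (2) local cluster
labels; (3) local-to-global atom maps; (4) local and global sticks from
their Beta conditionals; (5) atoms from the Normal–inverse-gamma
conjugate update (empty atoms are refreshed from the prior); (6) $\pi$
from its Beta conditional; (7) $\alpha_c, \tau_c$ from their Gamma
conditionals. The sweep is implemented in C++ and consumes R's RNG
stream, so runs are bit-reproducible from a seed. The joint correctness
of the conditionals is tested with a Geweke-style comparison between
prior draws and successive-conditional simulation.

The per-well posterior hit probability is estimated by Rao-Blackwellization:
`hit_prob` averages the conditional probabilities
$P(b_{mi}=1 \mid \text{rest})$ over kept sweeps rather than the binary
draws themselves (kept as `hit_prob_draw`). Both estimate the same
posterior quantity; the averaged conditional has far lower Monte Carlo
variance, which matters when thousands of borderline wells must be
*ranked* — with 400–2000 kept sweeps the binary-draw estimate visibly
scrambles the ranking while the Rao-Blackwell estimate is stable across
chains.

### Initialization and label switching

The two channels are distinguished only by their anchors, so the posterior
has a mirror mode in which the active channel absorbs the inactive bulk
($\pi \to 1-\pi$); single-site Gibbs cannot tunnel between modes. Two
initialization choices keep the chain in the anchored basin:

* atoms start near their anchors with dispersion tied to the anchor
  separation, not as unconstrained prior draws (the prior atom variance is
  centered on the pooled data variance, which would leave the first sweep
  blind to the anchors);
* the top 1% of readouts start active and $\pi$ starts at that fraction.
  A small start is self-correcting — genuinely active wells flip up within
  a few hundred sweeps because the active mixture concentrates where they
  live — whereas a large start (e.g. everything above the pooled mean)
  seeds the absorbing mode, which at realistic hit rates never drains.

No post-hoc relabeling is applied; identification is monitored by the
fraction of kept sweeps in which the active-channel mean exceeds the
inactive one (tested to be ≥ 95% on anchored data).

### FDR control

With $\hat\pi(z_{mi})$ the posterior hit probability, the Bayesian FDR of
calling every well above a threshold $r$ is estimated by
$$
\overline{\mathrm{FDR}}(r) =
\frac{\sum_{m,i} 1(\hat\pi(z_{mi}) > r)\,(1-\hat\pi(z_{mi}))}
     {\sum_{m,i} 1(\hat\pi(z_{mi}) > r)},
$$
with the strict inequality as written (wells exactly at $r$ are not
called). `select_threshold()` searches only the observed unique
probabilities — the estimator is a step function, so a continuous search
adds nothing — and returns the smallest admissible threshold (the most
calls). Multiplicity is handled entirely by the hierarchical shrinkage of
the posteriors; no additional p-value correction layer exists.

## The synthetic-screen generator

`synthetic_spec()`/`simulate_screen()` emulate an activation-type screen:
hits from a four-component log-normal mixture with component means
{0.20, 0.24, 0.28, 0.32}, non-hits from components with means
{0.10, 0.12, 0.14, 0.16}; compounds are permuted uniformly at random over
`n_plates` complete 8 × 10 compound grids, and each plate receives an
independent matrix-normal noise draw $A G B^\top$ with configurable row
and column scale matrices.

Design notes, in decreasing order of consequence:

* **Component variance convention.** The component variances
  ({0.0020, …} for hits, {0.010, …} for non-hits) are interpreted as
  log-scale variances ($\mathrm{sdlog}^2$), with the listed means as
  means of the variate (moment-matched via
  $\mathrm{meanlog} = \log m - v/2$). Read instead as variate-scale
  variances, the non-hit components would have coefficient of variation
  near 1, the pooled density would be unimodal, and hits would be
  unrecoverable even by the oracle likelihood ratio built from the
  generating densities. The log-variance reading produces the clearly
  bimodal pooled density (tested) and the near-perfect rankings this
  recipe is supposed to exhibit.
* **Hit counts are exact**: `floor(hit_fraction * n)` hits, so a rate of
  0.021% on $10^5$ compounds yields exactly 21 labeled hits, reproducibly.
* **Component weights** default to uniform (1/4 each); none are stated in
  the source recipe.
* **Noise scales.** The default row scale is compound-symmetric
  (variance $s^2$, correlation 0.5) and the column scale diagonal
  ($s^2/4$), giving row-dominant within-plate artifacts; $s^2 = 0.065$
  makes the per-well noise sd $s^2/2 \approx 0.0325$, about 25% of the
  mean non-hit level (0.13). Real screens calibrate these from data; both
  matrices and the `noise_multiplier` are configurable, and the
  generator's matrices are synthetic stand-ins, not estimates.

What a green test on this generator does **not** establish: robustness to
non-separable (non-matrix-normal) artifacts, edge effects concentrated in
control columns, readout distributions with a single heavy tail and no
bimodal structure, or missing wells (unsupported in this version).

## Numerical and scope choices

* Variance convention is the sample variance (n−1) everywhere (Z-score,
  standardization, automatic hyperparameters).
* MAD always includes the 1.4826 Gaussian-consistency factor.
* Median polish stops when the total absolute adjustment of a full sweep
  falls below `tol` × mean(|input|); the decomposition identity is exact
  to floating point at every iteration.
* R-score IRLS (Huber constant 1.345) declares convergence on the
  relative change of the residual vector at $10^{-4}$, the `rlm`
  convention; because the robust scale is re-estimated every iteration
  the fit approaches its fixed point only geometrically, so much tighter
  tolerances are unattainable in practical iteration counts. Default
  iteration cap 200.
* ROC ties collapse into single cutoffs, making the AUC equal to the
  Mann–Whitney U statistic with half-credit ties; the best-threshold AUC
  of a binarized score, $(\mathrm{TPR} + \mathrm{TNR})/2$ maximized over
  a 101-point grid, is the benchmark a fixed score cutoff could at best
  achieve.
* Default MCMC budget is 7000 sweeps, 2000 burn-in, thinning 5. The
  shipped `small_screen` preset (100 plates × 80 wells, 5% hits) uses
  3000 sweeps / 1000 burn-in; the `low_hit` preset (1250 plates, 0.021%
  hits) uses 2000 / 500, a budget chosen for single-CPU runtimes at
  $10^5$ wells before any accuracy results were inspected.
* Truncations default to H = 10 (local) and K = 20 (global); Beta/Gamma
  prior constants default to 1. All are exposed in the JSON config (the
  configuration format is JSON rather than YAML; no YAML parser is
  assumed on the target systems).

## Known limitations

* Complete grids only: missing wells and ragged compound sub-grids are
  rejected, not imputed.
* The automatic anchor rule needs positive-mean readouts; standardized
  data require manual anchors.
* At very low hit rates the posterior mass for $\pi$ can drift upward on
  long runs as the active channel slowly annexes the upper non-hit tail;
  rankings (AUC) remain stable over the shipped budgets, but extremely
  long chains on low-hit data should monitor the $\pi$ trace with
  `mcmc_diagnostics()`.
* One RNG stream: no parallel chains in this version.
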