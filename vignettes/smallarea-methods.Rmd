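---
title: "Small-area risk modeling with smallarea: model, sampler, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area risk modeling with smallarea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smallarea)
```

## The problem and the model

Small-area studies of rare events — disease cases, violent-crime records,
court-issued protection orders — aggregate counts to small administrative
units (here, census block groups of roughly 800–2,600 residents) and ask
two questions: which neighborhood covariates are associated with risk, and
where is the residual excess risk located. Raw rates at this scale are
dominated by Poisson noise (a block group with 650 women at risk and a
handful of events swings wildly), and neighboring areas are not
independent: unmeasured influences are spatially clustered. Both problems
are addressed by the Besag–York–Mollié (BYM) convolution model, the
workhorse of Bayesian disease mapping.

For areas $i = 1, \dots, n$:

$$O_i \sim \text{Poisson}(\lambda_i E_i), \qquad
\log \lambda_i = \alpha + x_i'\beta + S_i + H_i$$

* $E_i$ is the expected count under internal standardization,
  $E_i = \text{pop}_i \cdot \sum O / \sum \text{pop}$, so $\lambda_i$ is a
  *relative* risk against the district-wide incidence and
  $\sum E = \sum O$ by construction (`compute_expected()`).
* $S$ is an intrinsic CAR (ICAR) field: conditionally,
  $S_i \mid S_{-i} \sim N\!\big(\tfrac{1}{n_i}\sum_{j \sim i} S_j,\;
  \sigma_S^2 / n_i\big)$, where $j \sim i$ ranges over the $n_i$ graph
  neighbors of $i$. The equivalent joint density is the pairwise-difference
  form $\exp\{-\tfrac{1}{2\sigma_S^2}\sum_{i \sim j, i<j}(S_i - S_j)^2\}$
  (each edge once), an improper distribution of rank $n - c$ for $c$
  connected components.
* $H_i \sim N(0, \sigma_H^2)$ absorbs unstructured overdispersion.

Priors are deliberately vague: flat improper on $\alpha$,
$\beta_k \sim N(0, 10^5)$, and $\sigma_S, \sigma_H \sim U(0, 1)$ on the
standard-deviation scale. Two readings of "N(0, 100000)" circulate in the
WinBUGS tradition (variance vs precision); the package reads it as
**variance** $10^5$, which matches the vague intent, and exposes
`prior_beta_variance` so either convention can be set. Likewise the
$U(0,1)$ upper bound is informative if the truth exceeds 1, so
`sigma_upper` is configurable; the default is retained for fidelity to the
reference analysis.

## Identifiability and the sum-to-zero constraint

The ICAR prior is invariant to adding a constant to $S$ within a connected
component, and the model has a free intercept, so $\alpha$ and the level of
$S$ are jointly unidentified. The sampler therefore recentres $S$ to sum to
zero per connected component after every sweep and absorbs the removed
constant into $\alpha$ (exact for a connected graph, the default lattice
case). Degree-zero areas ("islands") have no CAR conditional at all; model
fitting rejects them by default, or pins $S_i = 0$ with a warning under
`islands = "pin"`, mirroring common CAR software behavior.

A related, subtler point: under internal standardization the offset is
recomputed from the observed total, so the intercept is identified only up
to $-\log(\sum O / \text{baseline total})$ relative to the generator's
truth. With the default calibration this is a shift of about $+0.12$ —
well inside the intercept's posterior spread, but visible if you compare
$\hat\alpha$ to the generating value exactly.

## The sampler

`run_mcmc()` is an adaptive single-site Metropolis-within-Gibbs sampler
written in C++ (the same architecture the established CAR-model packages
use, because $10^5$ sweeps over hundreds of sites is not feasible in
interpreted loops):

* random-walk Metropolis updates for $\alpha$, each $\beta_k$, each $S_i$
  (against its likelihood term plus the local pairwise-difference prior)
  and each $H_i$;
* **exact conditional draws** for $\sigma_S$ and $\sigma_H$: with a
  uniform-on-sd prior the full conditional of $\sigma^2$ is a truncated
  inverse gamma (shape $(\text{rank}-1)/2$, scale $q/2$ with $q$ the ICAR
  quadratic form, truncated by `sigma_upper`), sampled by inverse CDF.
  Random-walk updates of the sigmas mix an order of magnitude worse here;
* the $S_i$/$H_i$ proposal standard deviations are *multiplied by the
  current* $\sigma_S$/$\sigma_H$. The sigmas traverse a wide posterior
  (the reference analysis reports $\sigma_S$ intervals like
  $(0.01, 0.59)$), and a fixed proposal width cannot hold a stable
  acceptance rate across that range. The proposal remains symmetric in the
  updated coordinate, so the kernel is valid;
* covariates are mean-centred internally (the intercept is transformed
  back afterwards), removing the strong $\alpha$–$\beta$ posterior
  correlation that raw-scale covariates induce;
* step sizes adapt toward a 0.44 acceptance rate during burn-in only, in
  windows of `adapt_window = 50` iterations, so retained draws come from a
  fixed kernel;
* chain $c$ is seeded with `seed + c - 1`; chains beyond the first start
  from jittered (overdispersed) initial values so that the Gelman–Rubin
  diagnostic is honest. Defaults follow the reference analysis: 100,000
  iterations, 10,000 burn-in; thinning (default 10) is a storage choice.

Correctness is defined by the target posterior, not the kernel: the test
suite checks the sampler against a dense two-dimensional quadrature oracle
on a toy fixed-effects model, against the Poisson MLE in the
vague-prior/no-random-effects limit, and against the exact prior moments
when the likelihood is switched off (`likelihood = FALSE`), including
Kolmogorov–Smirnov uniformity of the $\sigma$ draws.

## Diagnostics and model comparison

`gelman_rubin()` implements the classic PSRF
$\hat R = \sqrt{\hat V / W}$ with $\hat V = \frac{n-1}{n} W + B/n$,
computed on retained draws; split-chain $\hat R$ is available via
`split = TRUE` but is not the default, since the reference methodology
predates it. The `converged` flag uses $\hat R \le 1.05$ — a conservative
numerical reading of "near 1.0", which is all the source tradition states.
Effective sample sizes use Geyer-style initial-positive-sequence
truncation of the autocorrelation sum.

`compute_dic()` reports $\bar D$, $D(\bar\theta)$, $p_D$ and DIC, with the
plug-in evaluated at the posterior means of the *log-scale* parameters
$(\alpha, \beta, S, H)$ — the WinBUGS convention. DIC is
parameterization-dependent, so this choice is stated rather than hidden.
The deviance includes the $\log O_i!$ term (the "full" Poisson deviance),
so absolute DIC values are comparable to WinBUGS output. On synthetic data
with no random effects, a seven-fixed-effect fit yields $p_D \approx 7$,
as the asymptotics predict.

## The covariate-screening workflow

`model_selection_workflow()` fits the non-spatial regression (Model 1),
the full convolution model (Model 2), screens covariates on Model 2, and
refits the convolution model on the survivors (Model 3), choosing the
smallest-DIC model. The screening rule needed a design decision: published
small-area analyses often drop covariates "without a clear association"
while keeping ones whose 95% interval narrowly includes zero, so the rule
cannot be "CI excludes 0". The package uses a sign-probability
(probability-of-direction) rule, relevant iff
$\max(P(\beta > 0), P(\beta < 0)) \ge 0.90$: applied to the six-covariate
posterior summaries of the calibration analysis it reproduces all six of
that analysis's keep/drop decisions (keep immigration, policing activity,
physical disorder; drop property value, social disorder, residential
mobility). The threshold is configurable; `relevance_from_interval()`
applies the same rule to published mean/interval summaries via a normal
approximation when draws are unavailable.

At the calibrated effect sizes, exact recovery of the active covariate
*set* is intrinsically hard: the physical-disorder effect (0.030, posterior
SD ≈ 0.023 at $n = 80$) sits almost exactly at the 0.90 boundary, so
roughly half of replicated datasets drop it, and each truly null covariate
crosses the threshold in roughly a fifth of replicates. This is a property
of the study conditions, not of the estimator: the acceptance suite
measures it directly.

## The synthetic-data generator

`simulate_dataset()` emulates the study design the model assumes: an
$8 \times 10$ rook-contiguity lattice of 80 areas; covariates drawn
independently as truncated normals matching published per-area summary
tables (mean, SD, min, max) for property value, % immigration, policing
activity, social disorder, physical disorder and residential mobility;
population at risk (women 16+) likewise (mean 651.3, SD 191.15, range
361–1,174, rounded with floor 1); true effects at the calibration
analysis's final model ($\alpha = -1.715$, immigration 0.046, policing
0.064, physical disorder 0.030, $\sigma_S = 0.232$, $\sigma_H = 0.190$);
and a district total of 368 events allocated proportionally to population
($E_i$), matching the source magnitude of ~4.6 events per area. The ICAR
field is drawn exactly on its proper subspace by per-component
eigendecomposition of $Q = D - W$ (coefficients $N(0, \sigma_S^2/\omega_k)$
on positive-eigenvalue eigenvectors), not by Gibbs passes.

What the generator does **not** emulate: real covariates are mutually
correlated (a Gaussian-copula `correlation` hook is provided but off by
default, since only marginals are published); real census-block contiguity
is irregular, not a lattice; and real populations cluster spatially.
Passing tests therefore demonstrate correctness of the machinery under the
assumed generative model, not robustness to the full messiness of
administrative data.

## Numerical choices and degenerate inputs

* Expected counts: all-zero observed totals are rejected (the district
  rate is undefined). `validate_area_table()` enforces
  $\sum E = \sum O$ to $10^{-9}$ relative whenever `expected` is present.
* Sum-to-zero: enforced to machine precision by recentring; tests assert
  $10^{-9}$.
* $Q$ rank: number of zero eigenvalues equals the number of connected
  components; checked by dense eigendecomposition on small graphs.
* Truncated-normal sampling is inverse-CDF; `sd = 0` yields a constant
  column (requiring $\min \le \text{mean} \le \max$), and
  $\min \ge \max$ with positive sd is rejected at configuration time.
* The $\sigma$ conditional falls back to a Metropolis step when the
  inverse-gamma shape is non-positive (ICAR rank $\le 1$, e.g. a single
  edge).
* `mcmc_config()` rejects `burn_in >= n_iter` and `thin < 1`;
  `n_chains = 1` is allowed but `convergence_report()` then refuses to
  produce $\hat R$.

## Problem sizes used in the shipped checks

The package's own test suite runs the pipeline at reduced, stated sizes
chosen to keep the suite fast while leaving Monte-Carlo error small
relative to the quantities asserted: the parameter-recovery experiment
uses 50 replicates of the 80-area generator refit with 2 chains × 20,000
iterations (burn-in 2,000); DIC-ordering and covariate-retention
experiments use 25 replicates at 2 × 8,000 and 2 × 6,000 iterations
respectively; the quadrature comparison uses a 3-area model at 2 × 50,000.
For production analyses the defaults (2 × 100,000, burn-in 10,000) are
recommended.

## Known limitations

* The BYM spatial/heterogeneity split ($S$ vs $H$) is weakly identified at
  $n = 80$ with ~5 events per area; $\sigma_S$ and $\sigma_H$ mix slowly
  relative to the fixed effects and their effective sample sizes are
  correspondingly smaller. The fixed effects and the composite
  $\lambda_i$ are well identified.
* No proper-CAR ($\rho$-parameterized) or Leroux alternative is provided,
  and no approximate (INLA-style) fitting path.
* GeoJSON output attaches user-supplied polygons; the package does not
  compute contiguity from geometry (use a GAL file or the lattice
  helpers).
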