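---
title: "Population structure as sparse matrix factorization: models and methods"
author: "PopSFA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population structure as sparse matrix factorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PopSFA)
```

# The unifying view

Let $X$ be an $n \times p$ genotype matrix: $n$ individuals, $p$
biallelic SNPs, entries counting copies of the reference allele (0, 1,
2). Three standard ways of summarizing population structure can all be
written as low-rank factorizations $X \approx \Lambda F$, with
$\Lambda$ ($n \times K$) the per-individual *loadings* and $F$
($K \times p$) the per-SNP *factors*:

* **Admixture models** constrain each row of $\Lambda$ to the simplex
  and each entry of $\tfrac12 F$ to $[0,1]$; entries of $X$ are
  Binomial$(2, \sum_k \lambda_{ik} p_{kj})$. Factors are ancestral
  allele frequencies and loadings are ancestry fractions.
* **PCA** of the column-standardized matrix constrains loading columns
  to be orthogonal and factor rows orthonormal; the truncated SVD is
  the maximum-likelihood solution. Undoing the standardization shows
  that PCA of the raw matrix implicitly carries an extra factor — the
  vector of column means with an all-ones loading.
* **Sparse factor analysis (SFA)** replaces hard constraints with a
  sparsity-inducing prior on the loadings, letting the data decide
  which individuals load on which factors.

The package implements all three on the same `GenotypeMatrix` input so
their representations can be compared like for like, plus generators
for the synthetic scenarios used to contrast them.

# The SFA model

For individual $i$,
$$x_i = \mu + \lambda_i F + e_i, \qquad
\lambda_i \sim N(0, \mathrm{diag}(\sigma^2_{i1},\dots,\sigma^2_{iK})),
\qquad e_i \sim N(0, \Psi),$$
with a Gamma$(a, b)$ prior on the inverse residual variances acting as
a regularizer. The per-coordinate prior variances $\sigma^2_{ik}$ form
the automatic relevance determination (ARD) prior: they are estimated
by maximizing the marginal likelihood (type-II maximum likelihood),
and the per-coordinate maximizer is *exactly zero* whenever the
"quality" statistic of the corresponding sparse-regression problem
satisfies $q^2 \le s$ — pruning loading $(i,k)$ and encoding sparsity.
With the mean term $\mu$ estimated the model is called **SFAm**; with
$\mu \equiv 0$ it is plain **SFA**. Discrete population structure is
recovered by SFA (factors become scaled population allele
frequencies, loadings become memberships); continuous structure is
better displayed by SFAm, whose mean factor plays the role of PCA's
first component.

## Fitting: ECME

`fitSfa()` alternates:

1. **E-step** — posterior moments of each $\lambda_i$ by Gaussian
   conditioning, in $K$-dimensional working space (never forming a
   $p \times p$ covariance). Coordinates with $\sigma^2_{ik} = 0$ are
   clamped to zero mean and variance.
2. **CM steps** for $\mu$, $F$, $\psi$ in that order, each maximizing
   the *expected complete-data* objective at the start-of-iteration
   moments (the moments are deliberately not refreshed between CM
   steps).
3. **CME step** for all $\sigma^2_{ik}$, maximizing the *marginal*
   likelihood coordinate-wise with the fast sparse-Bayesian-regression
   quantities $s$ and $q$; all coordinates are updated in one sweep
   from start-of-sweep covariances, so the update is
   order-independent.
4. **Rescaling** — each factor row is divided by its sample standard
   deviation and the loading representation compensated, imposing the
   unit-variance identifiability constraint without changing the
   likelihood.

Because moments are not refreshed between CM steps the traced
objective is not guaranteed monotone; decreases are counted in the fit
configuration rather than treated as errors, and in practice the trace
is monotone to numerical precision on all the scenarios exercised in
the test suite. Every step is verified in the tests against an
independent oracle: dense joint-Gaussian conditioning for the E-step,
a dense covariance evaluation for the likelihood, per-coordinate
numeric maximization for the CM steps, and 1-D numeric maximization of
the marginal likelihood for the ARD updates.

## Parameters that matter

* `K` — factor count. No automatic selection is attempted: different
  K answer different questions (two factors describe a cline, five
  describe five demes), so K is the analyst's lens, not a quantity to
  optimize.
* `meanTerm` — SFAm vs SFA, as above.
* `varianceMode` — `"column"` (default) gives SNP-specific residual
  variances $\psi_j$ shared across individuals; `"row"` gives
  individual-specific $\psi_i$. Row mode admits a degenerate
  high-likelihood attractor: a factor that reproduces one
  individual's residual exactly lets that individual's $\psi_i$
  collapse to the floor, gaining $\mathcal{O}(p)$ log-likelihood units
  while destroying the factor's interpretability. We observed ECME
  finding these solutions reliably on weak-signal designs (one
  individual per deme), which is why column mode is the default;
  row mode remains available and fully tested.
* `priorShape`, `priorRate` ($a$, $b$) — gamma prior on $1/\psi$;
  defaults $a = b = 1$, centering the prior on inverse variance 1,
  the right scale for genotype residuals. The update for $\psi$ is
  $(2b + S)/(m + 2(a-1))$ with $S$ the expected residual sum of
  squares and $m$ the number of summed cells.
* `psiFloor` — hard lower bound ($10^{-6}$) on residual variances; a
  last-resort guard against the same degeneracy. A minor-allele
  frequency filter (`filterMAF()`, suggested threshold 0.05) removes
  the low-information SNPs that make it more likely.
* `relTol` — convergence on the relative change of the traced
  objective, default $10^{-7}$. At genotype-matrix scale the
  objective is $\mathcal{O}(10^5)$, so looser values (e.g. $10^{-5}$)
  can stop the algorithm within a handful of iterations, before the
  ARD sweep has pruned anything.
* `init` — `"sample"` (default) starts each factor row at a randomly
  chosen individual's (centered) genotype row plus jitter; a random
  individual's genotypes are an unbiased draw of twice its
  population's allele frequencies, so factors start near
  interpretable frequency combinations. Standard-normal `"random"`
  initialization is retained, but on discrete-population data it
  converges to visibly worse optima (two of three populations
  resolved, the third mixed) from every seed we tried, whereas the
  sampled start reaches the sparse basin consistently. `nRestarts`
  runs several seeded starts and keeps the best final objective.

## Numerical choices

Per-individual working systems are solved by Cholesky factorization;
a singular $K \times K$ system in the factor update falls back to a
ridge-jittered solve ($10^{-10}$) with a warning. In the ARD sweep the
de-inflation denominator $1 - \sigma^2 S$ is treated as re-estimation
from the excluded state when it falls within $10^{-12}$ of zero. A
zero-variance factor row (possible only in pathological inputs) is
re-drawn from the RNG with a warning. Exactly-pruned coordinates stay
in the state so a factor can re-enter in a later sweep.

# PCA and the admixture baseline

`fitPca()` standardizes columns (sample sd, denominator $n-1$),
drops monomorphic SNPs with a warning (their ids are kept for audit),
and takes the truncated SVD; factor signs are fixed by making each
row's largest-magnitude entry positive. `impliedRawFactorization()`
re-expresses the result as a $(K{+}1)$-factor factorization of the raw
matrix whose first factor is the column means with an all-ones
loading. The binomial variance normalization used by some PCA variants
is intentionally not applied; the empirical sd was chosen because it
requires no model assumption.

`fitAdmixture()` fits the binomial admixture factorization by plain
EM: expected allele-count allocations in the E-step, closed-form
updates of P and Q in the M-step. EM was chosen over quasi-Newton
schemes because it is the simplest fitter whose likelihood is provably
non-decreasing and whose iterates satisfy the simplex and box
constraints exactly — the model, not the optimizer, is the point of
the baseline. Success probabilities are clamped to
$[10^{-9}, 1-10^{-9}]$ inside the likelihood; an emptied component is
re-seeded from perturbed overall frequencies with a warning.
`mapAdmixture2D()` maps K = 4 proportions to the unit square as the
barycentric combination of its corners; the component-to-corner
assignment is the caller's (resolve label switching with
`matchFactors()` first).

# Synthetic scenarios

The generators replace coalescent simulation with allele-frequency
models that reproduce the scenarios' statistical structure directly;
since all SNPs are independent in both constructions, the spatial
covariance of deme allele frequencies is the entire signal, and
modelling it explicitly removes an external-binary dependency.

* `simDiscrete()` — Balding–Nichols populations: ancestral frequency
  $p_j$ uniform with minor-allele frequency in `mafRange` (default
  0.1–0.5, mirrored to both alleles so frequencies span 0.1–0.9 and
  monomorphic SNPs are rare; sampled-monomorphic SNPs are redrawn),
  population frequencies
  $\mathrm{Beta}(p_j \tfrac{1-F_{ST}}{F_{ST}}, (1-p_j)\tfrac{1-F_{ST}}{F_{ST}})$.
* `simAdmixed()` — the same population frequencies combined by given
  admixture proportions (e.g. `admixtureGradient()`).
* `simLine1D()` / `simClustered1D()` — deme frequencies follow a
  logit-scale random walk along the line with increment sd `tau`
  (default 0.15); clustered sampling takes `nPerDeme` individuals
  from five evenly spaced demes.
* `simGrid2D()` / `simTwoGrids()` — a Gaussian field over the grid
  with exponential covariance in Manhattan distance, scaled so the
  adjacent-deme increment sd is `tau`. The correlation length is
  fixed at ten grid sides, which puts the field near its random-walk
  limit — increment variance growing linearly with distance — the
  2-D analog of the 1-D cumulative-walk construction. The two-habitat
  variant adds an independent per-habitat logit shift of sd `delta`
  (default 0.5) on top of independent fields, creating discrete
  between-habitat divergence.

What the generators deliberately do not emulate: linkage
disequilibrium (all SNPs independent, as in the scenarios they
mirror), genotyping error and missingness, and coalescent variance in
deme frequencies beyond the Gaussian field. Recovery results on these
scenarios therefore speak to the methods' behavior under clean
structure of known shape, not to robustness against real-data
artifacts.

# Comparison utilities

Factor models are identified only up to permutation and sign (and, for
SFA, scale): `matchFactors()` resolves label switching by exhaustive
optimal assignment on absolute Pearson correlations (ties broken
toward the lowest index; zero-variance rows correlate as 0), and
`procrustesAlign()` removes rotations between runs by orthogonal
Procrustes. Correlations are computed over SNPs for factors and over
individuals for loadings. `loadingsToAdmixture()` converts an
all-positive loading row to admixture proportions by normalizing to
unit sum — defined only under positivity, so rows violating it return
NA rather than a silently re-signed estimate.
`robustnessExperiment()` refits chosen methods after thinning one
group and reports matched loading correlations for the retained
individuals — the design in which sparse and admixture factorizations
are expected to be more stable than PCA, whose components are global
variance-maximizers and shift when a group's sample size changes.

# Problem sizes and what the tests show

The test suite exercises the oracle checks at tiny sizes (n ≤ 6,
p ≤ 12) where dense evaluations are exact, and the
scenario-reproduction experiments at desk scale: 60 individuals ×
2000 SNPs for three discrete populations, a 50-deme line and 10×10
grids at 2000 SNPs, 100 gradient individuals at 5000 SNPs. These
sizes were chosen so each experiment completes in seconds to a couple
of minutes while keeping the statistical signal comparable to the
scenarios they reproduce. Two caveats surfaced at these sizes are
worth knowing about. First, with one individual per deme at
`tau = 0.15` the geography-recovery ceiling is set by binomial
sampling noise, not by the methods: the noise-free frequency field
recovers coordinates at r ≈ 0.99, while genotype-based PCA and SFAm
plateau around r ≈ 0.87–0.93. Second, the admixture baseline's
corner components on a single grid are only weakly identified at this
divergence; its mapped configuration preserves adjacency imperfectly
(pairwise-distance rank correlations well below the discrete-scenario
levels), consistent with its known sensitivity to initialization on
continuous habitats.

# Known limitations

Missing genotypes are rejected by the model code (mean imputation is
offered as explicit preprocessing in `readGenotypes()`); the
simultaneous row-and-column variance mode is not implemented; K is
never chosen automatically; and no significance testing of components
(e.g. Tracy–Widom) is provided.
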