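# PopSFA: sparse factor analysis of population structure

Population structure inference — which individuals share ancestry, and
how ancestry varies across a habitat — can be viewed as one problem:
factorize the genotype matrix. PopSFA is for population geneticists
who want to compare the three standard factorizations on equal
footing, and in particular to use **sparse factor analysis (SFA)**,
which often combines the best properties of the other two.

Writing the n × p genotype matrix (allele counts 0/1/2) as
X ≈ Λ F with loadings Λ (n × K) and factors F (K × p):

* **Admixture model** — Λ rows on the simplex, ½F entries in [0, 1],
  X_ij ~ Binomial(2, Σ_k λ_ik p_kj). Fitted here by EM
  (`fitAdmixture()`).
* **PCA** — orthogonal loadings, orthonormal factors, fitted by SVD of
  the column-standardized matrix (`fitPca()`); the implied
  factorization of the raw matrix carries an extra mean factor with
  all-ones loading (`impliedRawFactorization()`).
* **SFA / SFAm** — a Gaussian factor model with an automatic relevance
  determination (ARD) prior λ_ik ~ N(0, σ²_ik), the per-coordinate
  variances estimated by type-II maximum likelihood inside an ECME
  algorithm (`fitSfa()`). Estimated σ²_ik of exactly zero prune
  loadings, so discrete populations come out as disjoint blocks;
  adding an explicit mean term (SFAm, `meanTerm = TRUE`) makes the
  model behave like PCA on continuous habitats. One method, both
  regimes.

The package also generates the synthetic scenarios used to contrast
the methods (`simDiscrete()`, `simAdmixed()`, `simLine1D()`,
`simGrid2D()`, `simTwoGrids()`, `simClustered1D()`), each carrying its
generating truth, and comparison tools that resolve the permutation /
sign / rotation invariances of factor models (`matchFactors()`,
`procrustesAlign()`, `loadingsToAdmixture()`,
`robustnessExperiment()`).

## Worked example

Three divergent populations (F_ST = 0.15), 20 individuals each, 2000
SNPs; SFA with three factors:

```r
library(PopSFA)
sim <- simDiscrete(nPerPop = 20, nSnps = 2000, nPops = 3,
                   fst = 0.15, seed = 11)
fit <- fitSfa(sim@genotypes, K = 3, meanTerm = FALSE, seed = 1,
              nRestarts = 3, relTol = 1e-7, maxIter = 400)
fit
#> SfaFit: SFA with 3 factor(s), 60 individuals x 2000 SNPs
#>   variance mode: column; 134 iteration(s); final objective -104087.615
#>   sparsity: 48.3% of prior loading variances exactly zero

round(loadings(fit)[c(1, 21, 41), ], 2)
#>         factor1 factor2 factor3
#> pop1_1     0.00    0.58    0.00
#> pop2_21    0.00    0.00    0.59
#> pop3_41    0.58    0.00    0.00

matchFactors(factorMatrix(fit), 2 * sim@trueFreqs)$correlations
#> [1] 0.9764061 0.9739806 0.9757964
```

Each individual loads on exactly one factor (its population) with the
off-population loadings pruned to exact zeros — nearly half of the
ARD prior variances are estimated as exactly zero — and each fitted
factor correlates at 0.97+ with twice the corresponding population's
true allele frequencies: the factorization recovers the generating
structure, not just a variance decomposition. PCA on the same data
spreads every population across all three components.

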