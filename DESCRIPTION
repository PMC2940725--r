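Package: PopSFA
Title: Sparse Factor Analysis of Population Structure
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models population structure in genotype matrices as low-rank
    matrix factorization. Implements a sparse factor analysis model (SFA,
    and SFAm with an explicit mean term) with an automatic relevance
    determination prior on the loadings, fitted by an ECME algorithm in
    which the per-loading prior variances are updated by direct
    maximization of the marginal likelihood; exact zeros of the estimated
    prior variances encode sparsity. Also provides, within the same
    factorization framework, standardized-genotype principal component
    analysis (including the implied factorization of the raw matrix with
    a mean factor) and a binomial admixture model fitted by EM, together
    with synthetic population-genetic scenario generators (discrete
    Balding-Nichols populations, admixture gradients, one- and
    two-dimensional stepping-stone habitats) carrying ground truth for
    parameter-recovery experiments, and utilities for matching, aligning
    and comparing factorizations across methods and runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
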