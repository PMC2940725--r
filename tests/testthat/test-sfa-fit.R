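test_that("initialization honors its contracts", {
    X <- matrix(rbinom(40, 2, 0.5), 5, 8) + 0
    m <- sfaInitModel(X, K = 2, seed = 1)
    expect_equal(apply(m$F, 1, var), c(1, 1), tolerance = 1e-8)
    expect_true(all(m$Sigma == 1))
    # determinism
    m2 <- sfaInitModel(X, K = 2, seed = 1)
    expect_identical(m, m2)
    # degenerate all-zero input, no mean term
    Z <- matrix(0, 5, 8)
    mz <- sfaInitModel(Z, K = 2, meanTerm = FALSE, seed = 3)
    expect_identical(mz$mu, numeric(8))
    expect_equal(mz$psi, rep(1e-6, 8))     # column mode: one per SNP
    mzr <- sfaInitModel(Z, K = 2, meanTerm = FALSE,
                        varianceMode = "row", seed = 3)
    expect_equal(mzr$psi, rep(1e-6, 5))
    # config errors
    expect_error(sfaInitModel(X, K = 5), "K must satisfy")
    Xbad <- X; Xbad[1, 1] <- NA
    expect_error(sfaInitModel(Xbad, K = 2), "missing or non-finite")
})

test_that("fitting is deterministic given the seed", {
    sim <- simDiscrete(nPerPop = 8, nSnps = 150, nPops = 2, fst = 0.2,
                       seed = 4)
    f1 <- fitSfa(sim@genotypes, K = 2, seed = 7, maxIter = 30)
    f2 <- fitSfa(sim@genotypes, K = 2, seed = 7, maxIter = 30)
    expect_identical(f1@Omega, f2@Omega)
    expect_identical(f1@logLikTrace, f2@logLikTrace)
})

test_that("self-consistency: data from the model is fitted sparsely", {
    # two discrete populations induce block-sparse true loadings
    sim <- simDiscrete(nPerPop = 25, nSnps = 500, nPops = 2, fst = 0.2,
                       seed = 6)
    fit <- fitSfa(sim@genotypes, K = 2, meanTerm = FALSE, seed = 1,
                  relTol = 1e-7, maxIter = 300)
    tr <- logLikTrace(fit)
    expect_gte(tr[length(tr)], tr[1])
    expect_gte(mean(priorVariances(fit) == 0), 0.25)
})

test_that("a single factor on one population loads with a common sign", {
    set.seed(8)
    p0 <- runif(300, 0.2, 0.8)
    X <- matrix(rbinom(20 * 300, 2, rep(p0, each = 20)), 20, 300) + 0
    fit <- fitSfa(GenotypeMatrix(X), K = 1, meanTerm = FALSE, seed = 1,
                  relTol = 1e-7, maxIter = 200)
    lam <- loadings(fit)[, 1]
    expect_true(all(lam > 0) || all(lam < 0))
})

test_that("the fitted state satisfies the model invariants", {
    sim <- simDiscrete(nPerPop = 10, nSnps = 200, nPops = 2, fst = 0.2,
                       seed = 10)
    for (mode in c("row", "column")) {
        fit <- fitSfa(sim@genotypes, K = 2, varianceMode = mode,
                      seed = 2, maxIter = 60)
        expect_true(all(priorVariances(fit) >= 0))
        expect_true(all(residualVariances(fit) >= fit@config$psiFloor))
        expect_equal(apply(fit@F, 1, var), c(1, 1), tolerance = 1e-8)
        expect_length(residualVariances(fit),
                      if (mode == "row") 20 else 200)
    }
})

test_that("SFAm estimates the mean; SFA pins it at zero", {
    sim <- simDiscrete(nPerPop = 10, nSnps = 150, nPops = 2, fst = 0.2,
                       seed = 12)
    fm <- fitSfa(sim@genotypes, K = 1, meanTerm = TRUE, seed = 1,
                 maxIter = 40)
    f0 <- fitSfa(sim@genotypes, K = 1, meanTerm = FALSE, seed = 1,
                 maxIter = 40)
    expect_identical(f0@mu, numeric(150))
    expect_gt(cor(fm@mu, colMeans(genotypes(sim))), 0.95)
})

test_that("accessors expose the fitted components with labels", {
    sim <- simDiscrete(nPerPop = 5, nSnps = 60, nPops = 2, fst = 0.3,
                       seed = 14)
    fit <- fitSfa(sim@genotypes, K = 2, seed = 1, maxIter = 20)
    expect_identical(rownames(loadings(fit)),
                     individualIds(sim@genotypes))
    expect_identical(colnames(factorMatrix(fit)),
                     snpIds(sim@genotypes))
    expect_identical(dim(loadings(fit)), c(10L, 2L))
    expect_identical(dim(factorMatrix(fit)), c(2L, 60L))
})
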