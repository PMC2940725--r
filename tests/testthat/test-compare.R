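test_that("matchFactors undoes permutation and sign flips exactly", {
    set.seed(1)
    A <- matrix(rnorm(4 * 50), 4, 50)
    perm <- c(3, 1, 4, 2)
    signs <- c(-1, 1, -1, 1)
    B <- A[order(perm), ] * signs[order(perm)]
    mt <- matchFactors(A, B)
    expect_identical(mt$permutation, as.integer(perm))
    expect_equal(mt$correlations, rep(1, 4), tolerance = 1e-12)
    # identity input maps to the identity permutation
    mtI <- matchFactors(A, A)
    expect_identical(mtI$permutation, 1:4)
    expect_identical(mtI$signs, rep(1, 4))
})

test_that("matchFactors against independent noise stays near zero", {
    set.seed(2)
    A <- matrix(rnorm(3 * 2000), 3, 2000)
    B <- matrix(rnorm(3 * 2000), 3, 2000)
    expect_lt(mean(matchFactors(A, B)$correlations), 0.2)
})

test_that("matchFactors handles zero-variance rows and is order-invariant", {
    set.seed(3)
    A <- matrix(rnorm(3 * 30), 3, 30)
    A[2, ] <- 5
    mt <- matchFactors(A, A)
    expect_identical(mt$correlations[2], 0)
    B <- A[c(2, 3, 1), ]
    mt2 <- matchFactors(B, A)
    expect_identical(mt2$permutation, c(2L, 3L, 1L))
})

test_that("Procrustes alignment recovers a planted rotation", {
    set.seed(4)
    L <- matrix(rnorm(30 * 3), 30, 3)
    th <- 0.7
    R0 <- diag(3)
    R0[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    out <- procrustesAlign(L, L %*% R0)
    expect_lt(max(abs(out$rotation - R0)), 1e-8)
    # rotation is orthogonal
    expect_lt(max(abs(crossprod(out$rotation) - diag(3))), 1e-10)
})

test_that("Procrustes alignment never increases the distance", {
    set.seed(5)
    for (rep in 1:5) {
        L <- matrix(rnorm(20 * 2), 20, 2)
        tgt <- matrix(rnorm(20 * 2), 20, 2)
        out <- procrustesAlign(L, tgt)
        expect_lte(sum((out$aligned - tgt)^2), sum((L - tgt)^2) + 1e-12)
    }
    # scalar case: the better sign
    L1 <- matrix(rnorm(10), 10, 1)
    out <- procrustesAlign(L1, -L1)
    expect_equal(out$rotation[1, 1], -1)
})

test_that("positive loadings normalize onto the simplex", {
    expect_equal(drop(loadingsToAdmixture(c(0.5, 0.5))), c(0.5, 0.5))
    expect_equal(drop(loadingsToAdmixture(c(3, 1))), c(0.75, 0.25))
    out <- loadingsToAdmixture(rbind(c(2, 2), c(-1, 3)))
    expect_equal(out[1, ], c(0.5, 0.5))
    expect_true(all(is.na(out[2, ])))
    # orientation flips a negative column before converting
    out2 <- loadingsToAdmixture(rbind(c(1, -3), c(2, -2)), orient = TRUE)
    expect_equal(out2[1, ], c(0.25, 0.75))
})

test_that("dropping nothing leaves deterministic loadings unchanged", {
    sim <- simDiscrete(nPerPop = 8, nSnps = 200, nPops = 2, fst = 0.2,
                       seed = 6)
    rb <- robustnessExperiment(sim@genotypes,
                               rep(c("a", "b"), each = 8), "a",
                               dropFraction = 0, K = 2,
                               methods = "pca", seed = 1)
    expect_equal(unname(rb$correlations["pca"]), 1, tolerance = 1e-10)
})

test_that("robustness experiment validates its inputs", {
    sim <- simDiscrete(nPerPop = 3, nSnps = 50, nPops = 2, fst = 0.2,
                       seed = 7)
    expect_error(robustnessExperiment(sim@genotypes, rep("a", 5), "a",
                                      0.5, K = 2),
                 "cover all individuals")
    expect_error(robustnessExperiment(sim@genotypes,
                                      rep(c("a", "b"), each = 3), "a",
                                      1, K = 2),
                 "too small")
})
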