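# Each ECME step is checked against an independent slow oracle: dense
# joint-Gaussian conditioning for the E-step, a dense p x p covariance
# evaluation for the marginal likelihood, per-coordinate numeric
# maximization of the expected complete-data objective for the CM
# steps, and 1-D numeric maximization of the true marginal likelihood
# for the ARD updates.

test_that("E-step moments equal explicit joint-Gaussian conditioning", {
    for (mode in c("row", "column")) {
        st <- randomSfaState(n = 4, p = 6, K = 2, varianceMode = mode,
                             seed = 7)
        mom <- sfaEStep(st$X, st$m)
        for (i in 1:4) {
            o <- densePosterior(st$X, st$m, i)
            expect_lt(max(abs(o$omega - mom$Omega[i, ])), 1e-8)
            expect_lt(max(abs(o$V - mom$Vpost[, , i])), 1e-8)
        }
    }
})

test_that("zero prior variance clamps the posterior to zero", {
    st <- randomSfaState(n = 3, p = 5, K = 2, seed = 2, zeroFrac = 0)
    st$m$Sigma[1, ] <- 0
    mom <- sfaEStep(st$X, st$m)
    expect_identical(mom$Omega[1, ], c(0, 0))
    expect_identical(mom$Vpost[, , 1], matrix(0, 2, 2))
})

test_that("scalar E-step case matches the hand computation", {
    # K=1, p=1, sigma2=1, psi=1, f=1, x-mu=2: posterior mean 1, var 1/2
    m <- list(F = matrix(1, 1, 1), mu = 0, psi = 1,
              Sigma = matrix(1, 1, 1), meanTerm = FALSE,
              varianceMode = "row", priorShape = 1, priorRate = 1,
              psiFloor = 1e-6)
    mom <- sfaEStep(matrix(2, 1, 1), m)
    expect_equal(mom$Omega[1, 1], 1)
    expect_equal(mom$Vpost[1, 1, 1], 0.5)
})

test_that("K-space marginal likelihood equals dense evaluation", {
    for (mode in c("row", "column")) {
        st <- randomSfaState(n = 3, p = 5, K = 2, varianceMode = mode,
                             seed = 5)
        expect_lt(abs(sfaLogMarginal(st$X, st$m) -
                      denseLogMarginal(st$X, st$m)), 1e-8)
    }
    # larger p to exercise the Woodbury route properly
    st <- randomSfaState(n = 6, p = 200, K = 3, seed = 9)
    expect_lt(abs(sfaLogMarginal(st$X, st$m) -
                  denseLogMarginal(st$X, st$m)), 1e-6)
})

test_that("likelihood with all-zero Sigma reduces to the diagonal model", {
    st <- randomSfaState(n = 3, p = 4, K = 2, seed = 3)
    st$m$Sigma[] <- 0
    ll <- sfaLogMarginal(st$X, st$m)
    R <- sweep(st$X, 2, st$m$mu)
    direct <- sum(dnorm(R, 0, sqrt(st$m$psi), log = TRUE)) +
        sum(dgamma(1 / st$m$psi, 1, rate = 1, log = TRUE))
    expect_equal(ll, direct, tolerance = 1e-10)
})

test_that("likelihood is invariant to the factor/loading rescaling", {
    st <- randomSfaState(n = 4, p = 8, K = 3, seed = 11)
    ll0 <- sfaLogMarginal(st$X, st$m)
    m2 <- st$m
    c0 <- 2.5
    m2$F[2, ] <- m2$F[2, ] * c0
    m2$Sigma[, 2] <- m2$Sigma[, 2] / c0^2
    expect_lt(abs(sfaLogMarginal(st$X, m2) - ll0), 1e-10 * abs(ll0))
})

test_that("CM updates maximize the expected objective per coordinate", {
    for (mode in c("row", "column")) {
        st <- randomSfaState(n = 5, p = 6, K = 2, varianceMode = mode,
                             seed = 13)
        m <- st$m
        m$priorShape <- 2; m$priorRate <- 1
        mom <- sfaEStep(st$X, m)
        muN <- sfaUpdateMu(st$X, m, mom)
        for (j in c(1, 4)) {
            o <- optimize(function(v) {
                mu2 <- muN; mu2[j] <- v
                expectedObjective(st$X, m, mom, mu = mu2)
            }, muN[j] + c(-2, 2), maximum = TRUE, tol = 1e-9)
            expect_lt(abs(o$maximum - muN[j]), 1e-6)
        }
        m$mu <- muN
        FN <- sfaUpdateF(st$X, m, mom)
        for (idx in list(c(1, 2), c(2, 5))) {
            o <- optimize(function(v) {
                F2 <- FN; F2[idx[1], idx[2]] <- v
                expectedObjective(st$X, m, mom, F = F2)
            }, FN[idx[1], idx[2]] + c(-2, 2), maximum = TRUE, tol = 1e-9)
            expect_lt(abs(o$maximum - FN[idx[1], idx[2]]), 1e-6)
        }
        m$F <- FN
        psiN <- sfaUpdatePsi(st$X, m, mom)
        for (j in c(1, length(psiN))) {
            o <- optimize(function(v) {
                ps <- psiN; ps[j] <- v
                expectedObjective(st$X, m, mom, psi = ps)
            }, c(1e-4, 6), maximum = TRUE, tol = 1e-10)
            expect_lt(abs(o$maximum - psiN[j]), 1e-5)
        }
    }
})

test_that("CM steps never decrease the expected objective", {
    st <- randomSfaState(n = 5, p = 7, K = 2, seed = 17)
    m <- st$m
    mom <- sfaEStep(st$X, m)
    q0 <- expectedObjective(st$X, m, mom)
    m$mu <- sfaUpdateMu(st$X, m, mom)
    q1 <- expectedObjective(st$X, m, mom)
    m$F <- sfaUpdateF(st$X, m, mom)
    q2 <- expectedObjective(st$X, m, mom)
    m$psi <- sfaUpdatePsi(st$X, m, mom)
    q3 <- expectedObjective(st$X, m, mom)
    expect_gte(q1, q0 - 1e-8)
    expect_gte(q2, q1 - 1e-8)
    expect_gte(q3, q2 - 1e-8)
})

test_that("mu update reduces to the (weighted) column mean when F = 0", {
    st <- randomSfaState(n = 4, p = 5, K = 2, seed = 19)
    m <- st$m
    m$F <- matrix(0, 2, 5)
    mom <- sfaEStep(st$X, m)
    muN <- sfaUpdateMu(st$X, m, mom)
    w <- 1 / m$psi
    expect_equal(muN, colSums(st$X * w) / sum(w), tolerance = 1e-12)
    # equal psi: weighted and unweighted means coincide
    m$psi <- rep(0.7, 4)
    expect_equal(sfaUpdateMu(st$X, m, sfaEStep(st$X, m)),
                 colMeans(st$X), tolerance = 1e-12)
})

test_that("psi update reduces to the variance MLE without the prior", {
    st <- randomSfaState(n = 4, p = 6, K = 2, seed = 23,
                         meanTerm = FALSE)
    m <- st$m
    m$priorShape <- 1; m$priorRate <- 0
    m$F <- matrix(0, 2, 6)
    m$mu <- numeric(6)
    mom <- sfaEStep(st$X, m)
    expect_equal(sfaUpdatePsi(st$X, m, mom), rowMeans(st$X^2),
                 tolerance = 1e-12)
})

test_that("psi floor engages when the residual sum vanishes", {
    X <- matrix(0, 3, 4)
    m <- list(F = matrix(rnorm(8), 2, 4), mu = numeric(4),
              psi = rep(1, 3), Sigma = matrix(0, 3, 2),
              meanTerm = FALSE, varianceMode = "row",
              priorShape = 1, priorRate = 0, psiFloor = 1e-6)
    mom <- sfaEStep(X, m)
    expect_equal(sfaUpdatePsi(X, m, mom), rep(1e-6, 3))
})

test_that("ARD update matches 1-D maximization of the marginal likelihood", {
    st <- randomSfaState(n = 4, p = 6, K = 2, seed = 29)
    m <- st$m
    SN <- sfaUpdateSigma(st$X, m)
    for (ik in list(c(1, 1), c(2, 2), c(3, 1), c(4, 2))) {
        i <- ik[1]; k <- ik[2]
        f <- function(v) {
            mm <- m; mm$Sigma[i, k] <- v
            sfaLogMarginal(st$X, mm)
        }
        o <- optimize(f, c(0, 60), maximum = TRUE, tol = 1e-9)
        best <- if (f(0) >= o$objective) 0 else o$maximum
        expect_lt(abs(SN[i, k] - best), 1e-4)
    }
})

test_that("ARD update zeroes coordinates with insufficient evidence", {
    # scalar case with a hand-checkable stationary point: K=1, p=1,
    # f=1, psi=1, x-mu=3, sigma2_old=0 -> s=1, q=3, sigma2=(9-1)/1=8
    m <- list(F = matrix(1, 1, 1), mu = 0, psi = 1,
              Sigma = matrix(0, 1, 1), meanTerm = FALSE,
              varianceMode = "row", priorShape = 1, priorRate = 1,
              psiFloor = 1e-6)
    expect_equal(sfaUpdateSigma(matrix(3, 1, 1), m)[1, 1], 8)
    # weak signal x-mu=0.5: q^2 = 0.25 < s = 1 -> exact zero
    expect_identical(sfaUpdateSigma(matrix(0.5, 1, 1), m)[1, 1], 0)
})

test_that("rescaling is exact, idempotent and likelihood-invariant", {
    st <- randomSfaState(n = 4, p = 8, K = 2, seed = 31)
    m <- st$m
    m$F[1, ] <- m$F[1, ] * 2   # variance 4 on row 1
    mom <- sfaEStep(st$X, m)
    ll0 <- sfaLogMarginal(st$X, m)
    rec0 <- mom$Omega %*% m$F
    rs <- sfaRescaleFactors(m, mom)
    expect_equal(apply(rs$model$F, 1, var), c(1, 1), tolerance = 1e-8)
    expect_lt(max(abs(rs$moments$Omega %*% rs$model$F - rec0)), 1e-10)
    expect_lt(abs(sfaLogMarginal(st$X, rs$model) - ll0),
              1e-8 * abs(ll0))
    # idempotence
    rs2 <- sfaRescaleFactors(rs$model, rs$moments)
    expect_lt(max(abs(rs2$model$F - rs$model$F)), 1e-12)
})
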