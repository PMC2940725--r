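# Independent oracles used across the suite. These deliberately take the
# slow, explicit route (dense covariances, per-coordinate numeric
# maximization, direct summation) so they share no code path with the
# package's K-space implementations.

# Small random SFA model state with a mix of active and pruned loadings.
randomSfaState <- function(n, p, K, varianceMode = "row", seed = 1,
                           zeroFrac = 0.2, meanTerm = TRUE) {
    set.seed(seed)
    X <- matrix(rbinom(n * p, 2, runif(n * p, 0.2, 0.8)), n, p) + 0
    m <- sfaInitModel(X, K, meanTerm = meanTerm,
                      varianceMode = varianceMode, seed = seed)
    m$Sigma <- matrix(runif(n * K, 0.2, 2), n, K)
    m$Sigma[sample(n * K, round(zeroFrac * n * K))] <- 0
    m$psi <- if (varianceMode == "row") runif(n, 0.3, 1.5) else
        runif(p, 0.3, 1.5)
    m$mu <- if (meanTerm) colMeans(X) + rnorm(p, sd = 0.1) else numeric(p)
    list(X = X, m = m)
}

# Per-individual residual covariance Psi_i as a dense p x p matrix.
densePsi <- function(m, i, p) {
    if (m$varianceMode == "row") diag(m$psi[i], p) else diag(m$psi, p)
}

# Posterior moments by explicit conditioning in the (K+p)-dimensional
# joint normal of (lambda_i, x_i).
densePosterior <- function(X, m, i) {
    K <- nrow(m$F); p <- ncol(X)
    S <- diag(m$Sigma[i, ], K)
    Psi <- densePsi(m, i, p)
    Clx <- S %*% m$F
    Cxx <- t(m$F) %*% S %*% m$F + Psi
    r <- X[i, ] - m$mu
    w <- drop(Clx %*% solve(Cxx, r))
    V <- S - Clx %*% solve(Cxx, t(Clx))
    list(omega = w, V = V)
}

# Log marginal likelihood via the dense p x p covariance.
denseLogMarginal <- function(X, m) {
    n <- nrow(X); p <- ncol(X); K <- nrow(m$F)
    ll <- 0
    for (i in seq_len(n)) {
        S <- diag(m$Sigma[i, ], K)
        C <- t(m$F) %*% S %*% m$F + densePsi(m, i, p)
        r <- X[i, ] - m$mu
        ll <- ll - 0.5 * (p * log(2 * pi) +
                          determinant(C)$modulus[1] +
                          sum(r * solve(C, r)))
    }
    ll + sum(dgamma(1 / m$psi, shape = m$priorShape,
                    rate = m$priorRate, log = TRUE))
}

# Expected complete-data objective (the quantity the mu/F/psi CM steps
# maximize), computed by direct summation from fixed moments.
expectedObjective <- function(X, m, mom, mu = m$mu, F = m$F,
                              psi = m$psi) {
    n <- nrow(X); p <- ncol(X); K <- nrow(F)
    tot <- sum(dgamma(1 / psi, shape = m$priorShape,
                      rate = m$priorRate, log = TRUE))
    for (i in seq_len(n)) {
        Mi <- mom$Vpost[, , i] + outer(mom$Omega[i, ], mom$Omega[i, ])
        r <- X[i, ] - mu
        psij <- if (m$varianceMode == "row") rep(psi[i], p) else psi
        Sij <- r^2 - 2 * r * drop(mom$Omega[i, ] %*% F) +
            colSums(F * (Mi %*% F))
        tot <- tot - 0.5 * sum(log(2 * pi * psij) + Sij / psij)
    }
    tot
}

# Hudson-style Fst between two populations from known allele
# frequencies (no sampling correction needed: frequencies are exact).
fstFromFreqs <- function(p1, p2) {
    num <- mean((p1 - p2)^2)
    den <- mean(p1 * (1 - p2) + p2 * (1 - p1))
    num / den
}

# Weir & Cockerham theta (ratio-of-averages) from genotype counts and
# population labels.
wcFst <- function(X, pop) {
    pops <- unique(pop)
    r <- length(pops)
    nk <- vapply(pops, function(g) sum(pop == g), 0)
    suma <- 0; sumabc <- 0
    for (j in seq_len(ncol(X))) {
        pk <- vapply(pops, function(g) mean(X[pop == g, j]) / 2, 0)
        hk <- vapply(pops, function(g) mean(X[pop == g, j] == 1), 0)
        nbar <- mean(nk)
        pbar <- sum(nk * pk) / (r * nbar)
        s2 <- sum(nk * (pk - pbar)^2) / ((r - 1) * nbar)
        hbar <- sum(nk * hk) / (r * nbar)
        nc <- (r * nbar - sum(nk^2) / (r * nbar)) / (r - 1)
        a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) -
            (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
        b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
            (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
        cc <- hbar / 2
        suma <- suma + a
        sumabc <- sumabc + a + b + cc
    }
    suma / sumabc
}

# Orthogonal-Procrustes-aligned mean per-axis Pearson correlation of a
# 2-column loading matrix with 2-D coordinates.
procrustesAxisCor <- function(L, coords) {
    Lc <- scale(L, scale = FALSE); Tc <- scale(coords, scale = FALSE)
    Lc <- Lc / sqrt(sum(Lc^2)); Tc <- Tc / sqrt(sum(Tc^2))
    al <- procrustesAlign(Lc, Tc)$aligned
    mean(c(cor(al[, 1], Tc[, 1]), cor(al[, 2], Tc[, 2])))
}
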