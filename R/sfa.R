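## Sparse factor analysis with an ARD prior, fitted by ECME.
##
## Model: x_i = mu + lambda_i F + e_i for individual i, with
##   lambda_i ~ N(0, diag(sigma2_i1..sigma2_iK))   (ARD prior, estimated)
##   e_i ~ N(0, Psi_i),  Psi_i = psi_i I_p ("row" variance mode) or
##                       diag(psi_1..psi_p) shared across i ("column" mode)
## and a Gamma(a, b) prior on the inverse residual variances. Integrating
## out lambda_i gives x_i ~ N(mu, F' Sigma_i F + Psi_i); the traced
## objective is that marginal log likelihood plus the log gamma prior.
##
## All per-individual computations stay in K-dimensional working space:
## with G_i = F Psi_i^-1 F' and h_i = F Psi_i^-1 (x_i - mu), restricted
## to the active set A_i = {k : sigma2_ik > 0},
##   B_i  = Sigma_iA^-1 + G_iAA
##   V_i  = B_i^-1 (posterior covariance; zero rows/cols off the set)
##   w_i  = V_i h_iA (posterior mean)
##   log|Cov_i| = log|Psi_i| + log|Sigma_iA| + log|B_i|
##   quadratic form = r_i' Psi_i^-1 r_i - h_iA' B_i^-1 h_iA.
## Exact zeros in Sigma clamp the corresponding loading to zero; they are
## the sparsity mechanism and are kept in the state so a factor can
## re-enter in a later ARD sweep.

.sfaCheckState <- function(model) {
    stopifnot(is.list(model),
              is.matrix(model$F), is.numeric(model$mu),
              is.numeric(model$psi), is.matrix(model$Sigma))
    if (any(model$Sigma < 0)) stop("negative ARD prior variance")
    if (any(model$psi <= 0)) stop("non-positive residual variance")
}

## Per-mode inverse-variance weights over SNPs for individual i are
## either 1/psi_i (row mode, scalar) or 1/psi_j (column mode, shared).
.sfaIsRow <- function(model) identical(model$varianceMode, "row")

#' Initialize a sparse factor analysis model state
#'
#' Draws a starting state for the ECME algorithm: factor rows are
#' standard normal rescaled to unit sample variance, the mean is set to
#' the column means (or zero without a mean term), residual variances to
#' the per-row (or per-column) variances of the column-centered data
#' floored at `psiFloor`, and all ARD prior variances to one (all
#' factors active). Deterministic given `seed`.
#'
#' @param X numeric n x p genotype matrix (complete, finite).
#' @param K number of factors, `1 <= K < min(n, p)`.
#' @param meanTerm logical; `TRUE` fits SFAm (explicit column means),
#'   `FALSE` plain SFA (means fixed at zero).
#' @param varianceMode `"column"` (default) for SNP-specific residual
#'   variances shared across individuals, `"row"` for
#'   individual-specific ones. Row mode admits a degenerate
#'   high-likelihood solution in which a factor exactly fits one
#'   individual's residual and that individual's variance collapses;
#'   column mode removes that attractor (see the methods vignette).
#' @param priorShape,priorRate gamma prior on the inverse residual
#'   variances (shape a, rate b); defaults 1 and 1.
#' @param psiFloor lower bound on residual variances, guarding against
#'   the degeneracy where a variance collapses toward zero.
#' @param init `"sample"` (default) starts each factor row at the
#'   (column-centered, for SFAm) genotype row of a randomly chosen
#'   individual plus a small jitter — an unbiased draw of twice that
#'   individual's population allele frequencies, which starts the
#'   factors near interpretable allele-frequency combinations;
#'   `"random"` uses independent standard-normal entries. Both are
#'   rescaled to unit row variance.
#' @param seed integer seed for the factor draw.
#' @return the model state: a list with elements `F` (K x p), `mu` (p),
#'   `psi` (n or p), `Sigma` (n x K), and the configuration fields.
#' @seealso [fitSfa()] for the full algorithm; the individual steps are
#'   [sfaEStep()], [sfaUpdateMu()], [sfaUpdateF()], [sfaUpdatePsi()],
#'   [sfaUpdateSigma()], [sfaRescaleFactors()].
#' @export
sfaInitModel <- function(X, K, meanTerm = TRUE,
                         varianceMode = c("column", "row"),
                         priorShape = 1, priorRate = 1,
                         psiFloor = 1e-6, init = c("sample", "random"),
                         seed = 1) {
    varianceMode <- match.arg(varianceMode)
    init <- match.arg(init)
    X <- as.matrix(X)
    if (anyNA(X) || any(!is.finite(X)))
        stop("X contains missing or non-finite entries")
    n <- nrow(X); p <- ncol(X)
    if (K < 1 || K >= min(n, p))
        stop("K must satisfy 1 <= K < min(n, p)")
    if (psiFloor <= 0) stop("psiFloor must be positive")
    set.seed(seed)
    if (init == "sample") {
        idx <- sample.int(n, K)
        F <- X[idx, , drop = FALSE]
        if (meanTerm) F <- sweep(F, 2, colMeans(X))
        F <- F + matrix(stats::rnorm(K * p, sd = 0.1), K, p)
    } else {
        F <- matrix(stats::rnorm(K * p), K, p)
    }
    sds <- apply(F, 1, stats::sd)
    degen <- sds < 1e-8
    if (any(degen)) {
        F[degen, ] <- stats::rnorm(sum(degen) * p)
        sds <- apply(F, 1, stats::sd)
    }
    F <- F / sds
    mu <- if (meanTerm) colMeans(X) else numeric(p)
    Xc <- sweep(X, 2, colMeans(X))
    psi <- if (varianceMode == "row") {
        pmax(rowSums(Xc^2) / max(p - 1, 1), psiFloor)
    } else {
        pmax(colSums(Xc^2) / max(n - 1, 1), psiFloor)
    }
    list(F = F, mu = mu, psi = psi,
         Sigma = matrix(1, n, K),
         meanTerm = meanTerm, varianceMode = varianceMode,
         priorShape = priorShape, priorRate = priorRate,
         psiFloor = psiFloor)
}

## K-space working quantities shared by the E-step, the likelihood and
## the ARD sweep. Returns, for each individual, G_i and h_i as described
## above (row mode: scaled copies of FF' and F R'; column mode: shared).
.sfaWork <- function(X, model) {
    F <- model$F
    R <- sweep(X, 2, model$mu)
    if (.sfaIsRow(model)) {
        G0 <- tcrossprod(F)
        H0 <- F %*% t(R)
        list(R = R, G0 = G0, H0 = H0, row = TRUE, psi = model$psi)
    } else {
        w <- 1 / model$psi
        Fw <- sweep(F, 2, w, "*")
        G <- tcrossprod(Fw, F)
        G <- (G + t(G)) / 2
        H <- Fw %*% t(R)
        list(R = R, G = G, H = H, row = FALSE, psi = model$psi)
    }
}

.sfaGi <- function(wk, i) {
    if (wk$row) wk$G0 / wk$psi[i] else wk$G
}
.sfaHi <- function(wk, i) {
    if (wk$row) wk$H0[, i] / wk$psi[i] else wk$H[, i]
}

#' E-step: posterior moments of the loadings
#'
#' Computes, for each individual, the posterior mean and covariance of
#' its loading vector given the current parameters, by Gaussian
#' conditioning in K-dimensional working space. Coordinates whose ARD
#' prior variance is exactly zero are clamped: posterior mean 0 and zero
#' variance.
#'
#' @param X numeric n x p data matrix.
#' @param model model state from [sfaInitModel()] (or a later update).
#' @return list with `Omega` (n x K posterior means) and `Vpost`
#'   (K x K x n posterior covariances).
#' @export
sfaEStep <- function(X, model) {
    .sfaCheckState(model)
    X <- as.matrix(X)
    n <- nrow(X); K <- nrow(model$F)
    wk <- .sfaWork(X, model)
    Omega <- matrix(0, n, K)
    Vpost <- array(0, c(K, K, n))
    for (i in seq_len(n)) {
        A <- which(model$Sigma[i, ] > 0)
        if (!length(A)) next
        G <- .sfaGi(wk, i)
        B <- G[A, A, drop = FALSE] + diag(1 / model$Sigma[i, A],
                                          length(A))
        ch <- tryCatch(chol(B), error = function(e)
            stop("singular posterior system for individual ", i, ": ",
                 conditionMessage(e)))
        Vi <- chol2inv(ch)
        h <- .sfaHi(wk, i)
        Omega[i, A] <- drop(Vi %*% h[A])
        Vpost[A, A, i] <- Vi
    }
    list(Omega = Omega, Vpost = Vpost)
}

#' Log marginal likelihood of an SFA model state
#'
#' Sum over individuals of the Gaussian log density of `x_i` under
#' `N(mu, F' Sigma_i F + Psi_i)`, evaluated with the matrix inversion and
#' determinant lemmas in K-dimensional working space (the p x p
#' covariance is never formed), plus the log gamma prior density on the
#' inverse residual variances. This is the objective the ECME algorithm
#' maximizes and traces.
#'
#' @inheritParams sfaEStep
#' @return a single numeric value.
#' @export
sfaLogMarginal <- function(X, model) {
    .sfaCheckState(model)
    X <- as.matrix(X)
    n <- nrow(X); p <- ncol(X)
    wk <- .sfaWork(X, model)
    logdetPsi <- if (.sfaIsRow(model)) p * log(model$psi) else
        rep(sum(log(model$psi)), n)
    ll <- 0
    for (i in seq_len(n)) {
        r <- wk$R[i, ]
        rPr <- if (.sfaIsRow(model)) sum(r^2) / model$psi[i] else
            sum(r^2 / model$psi)
        A <- which(model$Sigma[i, ] > 0)
        ld <- logdetPsi[i]
        quad <- rPr
        if (length(A)) {
            G <- .sfaGi(wk, i)
            B <- G[A, A, drop = FALSE] + diag(1 / model$Sigma[i, A],
                                              length(A))
            ch <- tryCatch(chol(B), error = function(e)
                stop("working matrix not positive definite for ",
                     "individual ", i))
            h <- .sfaHi(wk, i)[A]
            v <- backsolve(ch, h, transpose = TRUE)
            quad <- quad - sum(v^2)
            ld <- ld + 2 * sum(log(diag(ch))) +
                sum(log(model$Sigma[i, A]))
        }
        ll <- ll + (-0.5) * (p * log(2 * pi) + ld + quad)
    }
    ll + sum(stats::dgamma(1 / model$psi, shape = model$priorShape,
                           rate = model$priorRate, log = TRUE))
}

#' CM-step: update the column means
#'
#' Maximizes the expected complete-data objective over `mu` with the
#' moments held fixed: a precision-weighted mean of the residuals
#' `x_ij - omega_i f_j` in row variance mode (weights 1/psi_i), the
#' plain mean in column mode. Returns zeros when the model has no mean
#' term.
#'
#' @inheritParams sfaEStep
#' @param moments output of [sfaEStep()] under the current parameters;
#'   the moments are not refreshed between CM steps.
#' @return numeric p-vector.
#' @export
sfaUpdateMu <- function(X, model, moments) {
    X <- as.matrix(X)
    if (!model$meanTerm) return(numeric(ncol(X)))
    E <- moments$Omega %*% model$F
    if (.sfaIsRow(model)) {
        w <- 1 / model$psi
        colSums((X - E) * w) / sum(w)
    } else {
        colMeans(X - E)
    }
}

#' CM-step: update the factor matrix
#'
#' Maximizes the expected complete-data objective over F column by
#' column: each SNP's factor column solves a K x K normal system built
#' from the posterior loading moments. In row variance mode the system
#' matrix is shared across SNPs; in column mode the SNP-specific
#' residual variance cancels.
#'
#' @inheritParams sfaUpdateMu
#' @return numeric K x p matrix.
#' @export
sfaUpdateF <- function(X, model, moments) {
    X <- as.matrix(X)
    K <- nrow(model$F); n <- nrow(X)
    R <- sweep(X, 2, model$mu)
    Vflat <- matrix(moments$Vpost, K * K, n)
    if (.sfaIsRow(model)) {
        w <- 1 / model$psi
        A <- matrix(Vflat %*% w, K, K) + crossprod(moments$Omega,
                                                   moments$Omega * w)
        RHS <- crossprod(moments$Omega * w, R)
    } else {
        A <- matrix(rowSums(Vflat), K, K) + crossprod(moments$Omega)
        RHS <- crossprod(moments$Omega, R)
    }
    A <- (A + t(A)) / 2
    Fnew <- tryCatch(solve(A, RHS), error = function(e) {
        warning("singular K x K system in the factor update; ",
                "solving with ridge jitter 1e-10")
        solve(A + diag(1e-10, K), RHS)
    })
    matrix(Fnew, K, ncol(X))
}

#' CM-step: update the residual variances
#'
#' Maximizes the expected complete-data objective (including the gamma
#' prior on the inverse variances) over psi. With `S` the expected
#' residual sum of squares for a row (or column), the maximizer is
#' `(2b + S) / (p + 2(a - 1))` in row mode and `(2b + S) / (n + 2(a - 1))`
#' in column mode, floored at `psiFloor`.
#'
#' @inheritParams sfaUpdateMu
#' @return numeric vector of length n (row mode) or p (column mode).
#' @export
sfaUpdatePsi <- function(X, model, moments) {
    X <- as.matrix(X)
    n <- nrow(X); p <- ncol(X); K <- nrow(model$F)
    a <- model$priorShape; b <- model$priorRate
    R <- sweep(X, 2, model$mu)
    E <- moments$Omega %*% model$F
    Vflat <- matrix(moments$Vpost, K * K, n)
    if (.sfaIsRow(model)) {
        denom <- p + 2 * (a - 1)
        if (denom <= 0)
            stop("non-positive denominator in the psi update; ",
                 "priorShape too small for this p")
        G0 <- tcrossprod(model$F)
        quad <- colSums(Vflat * as.vector(G0)) +
            rowSums((moments$Omega %*% G0) * moments$Omega)
        S <- rowSums(R^2) - 2 * rowSums(R * E) + quad
        pmax((2 * b + S) / denom, model$psiFloor)
    } else {
        denom <- n + 2 * (a - 1)
        if (denom <= 0)
            stop("non-positive denominator in the psi update; ",
                 "priorShape too small for this n")
        M <- matrix(rowSums(Vflat), K, K) + crossprod(moments$Omega)
        quad <- colSums(model$F * (M %*% model$F))
        S <- colSums(R^2) - 2 * colSums(R * E) + quad
        pmax((2 * b + S) / denom, model$psiFloor)
    }
}

#' CME-step: ARD update of the prior loading variances
#'
#' Updates every prior variance `sigma2_ik` to the value maximizing the
#' marginal likelihood in that coordinate with everything else fixed,
#' using the fast type-II maximum likelihood quantities of sparse
#' Bayesian regression: with `C_i` the current marginal covariance of
#' `x_i`, `S = f_k C_i^-1 f_k'` and `Q = f_k C_i^-1 (x_i - mu)`, the
#' factor's own contribution is removed (`s = S/(1 - sigma2 S)`,
#' `q = Q/(1 - sigma2 S)`), and the maximizer is `(q^2 - s)/s^2` when
#' `q^2 > s` and exactly 0 otherwise — the mechanism that prunes
#' loadings. All (i, k) are updated in one sweep from start-of-sweep
#' covariances, so the update is order-independent.
#'
#' @inheritParams sfaEStep
#' @return numeric n x K matrix of updated prior variances.
#' @export
sfaUpdateSigma <- function(X, model) {
    .sfaCheckState(model)
    X <- as.matrix(X)
    n <- nrow(X); K <- nrow(model$F)
    wk <- .sfaWork(X, model)
    Snew <- matrix(0, n, K)
    for (i in seq_len(n)) {
        G <- .sfaGi(wk, i)
        h <- .sfaHi(wk, i)
        A <- which(model$Sigma[i, ] > 0)
        if (length(A)) {
            B <- G[A, A, drop = FALSE] + diag(1 / model$Sigma[i, A],
                                              length(A))
            Binv <- chol2inv(chol(B))
            T <- Binv %*% G[A, , drop = FALSE]
            Svec <- diag(G) - colSums(G[A, , drop = FALSE] * T)
            Qvec <- h - drop(crossprod(G[A, , drop = FALSE],
                                       Binv %*% h[A]))
        } else {
            Svec <- diag(G)
            Qvec <- h
        }
        for (k in seq_len(K)) {
            d <- 1 - model$Sigma[i, k] * Svec[k]
            if (abs(d) < 1e-12) {
                s <- Svec[k]; q <- Qvec[k]
            } else {
                s <- Svec[k] / d; q <- Qvec[k] / d
            }
            Snew[i, k] <- if (s > 0 && q^2 > s) (q^2 - s) / s^2 else 0
        }
    }
    Snew
}

#' Rescale factor rows to unit variance
#'
#' Applies the identifiability constraint: each factor row is divided by
#' its sample standard deviation, and the corresponding column of the
#' loading representation is scaled to compensate (posterior means by
#' s_k, prior and posterior variances by s_k^2), leaving the
#' reconstruction and the marginal likelihood unchanged. A zero-variance
#' factor row is re-drawn from the RNG with a warning.
#'
#' @param model model state.
#' @param moments optional moments to rescale alongside (e.g. for a
#'   final consistent state); refreshed moments are otherwise
#'   recomputed by the next E-step.
#' @return list with rescaled `model` (and `moments` if supplied).
#' @export
sfaRescaleFactors <- function(model, moments = NULL) {
    F <- model$F
    s <- apply(F, 1, stats::sd)
    bad <- which(s == 0 | !is.finite(s))
    if (length(bad)) {
        warning("re-drawing ", length(bad), " zero-variance factor row(s)")
        for (k in bad) {
            F[k, ] <- stats::rnorm(ncol(F))
        }
        s <- apply(F, 1, stats::sd)
    }
    model$F <- F / s
    model$Sigma <- sweep(model$Sigma, 2, s^2, "*")
    if (is.null(moments)) return(list(model = model))
    moments$Omega <- sweep(moments$Omega, 2, s, "*")
    K <- length(s)
    for (i in seq_len(dim(moments$Vpost)[3])) {
        moments$Vpost[, , i] <- moments$Vpost[, , i] * outer(s, s)
    }
    list(model = model, moments = moments)
}

#' Fit a sparse factor analysis model (SFA / SFAm)
#'
#' Fits the K-factor Gaussian factor model with an automatic relevance
#' determination prior on the loadings by an ECME algorithm. Each
#' iteration runs one E-step, then conditional maximization steps in the
#' order mu, F, psi (maximizing the expected complete-data objective at
#' fixed moments) followed by the ARD update of the prior variances
#' (maximizing the marginal likelihood directly), and finally the
#' unit-variance rescaling of the factor rows. Because the moments are
#' not refreshed between CM steps, the traced objective is not
#' guaranteed monotone; decreases are recorded, not fatal. With
#' `nRestarts > 1` the model is fitted from successive seeds and the
#' restart with the highest final objective is returned.
#'
#' @param X a [GenotypeMatrix] or numeric matrix (individuals x SNPs).
#' @inheritParams sfaInitModel
#' @param maxIter maximum ECME iterations.
#' @param relTol convergence threshold on the relative change of the
#'   log marginal likelihood.
#' @param nRestarts number of random restarts (seeds `seed, seed+1, ...`).
#' @param seed integer seed; the fit is deterministic given it.
#' @param verbose print the objective every 10 iterations.
#' @return an [SfaFit].
#' @examples
#' sim <- simDiscrete(nPerPop = 10, nSnps = 200, nPops = 2,
#'                    fst = 0.2, seed = 1)
#' fit <- fitSfa(sim@genotypes, K = 2, meanTerm = FALSE, seed = 1,
#'               maxIter = 50)
#' head(loadings(fit))
#' mean(priorVariances(fit) == 0)  # fraction of pruned loadings
#' @export
fitSfa <- function(X, K, meanTerm = TRUE,
                   varianceMode = c("column", "row"),
                   priorShape = 1, priorRate = 1,
                   maxIter = 200, relTol = 1e-5,
                   nRestarts = 1, init = c("sample", "random"),
                   seed = 1, psiFloor = 1e-6,
                   verbose = FALSE) {
    varianceMode <- match.arg(varianceMode)
    init <- match.arg(init)
    indIds <- NULL; sIds <- NULL
    if (is(X, "GenotypeMatrix")) {
        indIds <- X@individualIds; sIds <- X@snpIds
        X <- X@values
    }
    X <- as.matrix(X)
    if (is.null(indIds)) indIds <- paste0("ind", seq_len(nrow(X)))
    if (is.null(sIds)) sIds <- paste0("snp", seq_len(ncol(X)))
    best <- NULL
    for (r in seq_len(nRestarts)) {
        res <- tryCatch(
            .sfaRunOnce(X, K, meanTerm, varianceMode, priorShape,
                        priorRate, maxIter, relTol, init,
                        seed + r - 1L, psiFloor, verbose),
            error = function(e) e)
        if (inherits(res, "error")) {
            warning("restart ", r, " failed: ", conditionMessage(res))
            next
        }
        if (is.null(best) ||
            res$ll > best$ll) best <- res
    }
    if (is.null(best))
        stop("all ", nRestarts, " restart(s) failed numerically")
    new("SfaFit",
        F = best$model$F, mu = best$model$mu, psi = best$model$psi,
        Sigma = best$model$Sigma, Omega = best$moments$Omega,
        Vpost = best$moments$Vpost, logLikTrace = best$trace,
        config = list(K = K, meanTerm = meanTerm,
                      varianceMode = varianceMode,
                      priorShape = priorShape, priorRate = priorRate,
                      maxIter = maxIter, relTol = relTol,
                      nRestarts = nRestarts, init = init, seed = seed,
                      psiFloor = psiFloor, restartSeed = best$seed,
                      nIter = length(best$trace),
                      nDecreases = best$nDecreases),
        individualIds = indIds, snpIds = sIds)
}

.sfaRunOnce <- function(X, K, meanTerm, varianceMode, priorShape,
                        priorRate, maxIter, relTol, init, seed,
                        psiFloor, verbose) {
    model <- sfaInitModel(X, K, meanTerm, varianceMode, priorShape,
                          priorRate, psiFloor, init, seed)
    trace <- numeric(0)
    llPrev <- -Inf
    nDecreases <- 0L
    moments <- NULL
    for (it in seq_len(maxIter)) {
        moments <- sfaEStep(X, model)
        model$mu <- sfaUpdateMu(X, model, moments)
        model$F <- sfaUpdateF(X, model, moments)
        model$psi <- sfaUpdatePsi(X, model, moments)
        model$Sigma <- sfaUpdateSigma(X, model)
        model <- sfaRescaleFactors(model)$model
        ll <- sfaLogMarginal(X, model)
        trace <- c(trace, ll)
        if (verbose && it %% 10 == 0)
            message(sprintf("iter %d: log marginal = %.4f", it, ll))
        if (is.finite(llPrev)) {
            if (ll < llPrev - 1e-10) nDecreases <- nDecreases + 1L
            if (abs(ll - llPrev) < relTol * abs(llPrev)) break
        }
        llPrev <- ll
    }
    moments <- sfaEStep(X, model)
    list(model = model, moments = moments, trace = trace,
         ll = trace[length(trace)], seed = seed,
         nDecreases = nDecreases)
}

## ---- accessors & show ----

#' @rdname loadings
#' @export
setMethod("loadings", "SfaFit", function(x) {
    m <- x@Omega
    dimnames(m) <- list(x@individualIds,
                        paste0("factor", seq_len(ncol(m))))
    m
})

#' @rdname factorMatrix
#' @export
setMethod("factorMatrix", "SfaFit", function(x) {
    m <- x@F
    dimnames(m) <- list(paste0("factor", seq_len(nrow(m))), x@snpIds)
    m
})

#' @rdname logLikTrace
#' @export
setMethod("logLikTrace", "SfaFit", function(x) x@logLikTrace)

#' @rdname priorVariances
#' @export
setMethod("priorVariances", "SfaFit", function(x) x@Sigma)

#' @rdname residualVariances
#' @export
setMethod("residualVariances", "SfaFit", function(x) x@psi)

#' @rdname individualIds
#' @export
setMethod("individualIds", "SfaFit", function(x) x@individualIds)

#' @rdname snpIds
#' @export
setMethod("snpIds", "SfaFit", function(x) x@snpIds)

setMethod("show", "SfaFit", function(object) {
    cfg <- object@config
    cat("SfaFit:", if (cfg$meanTerm) "SFAm" else "SFA",
        "with", cfg$K, "factor(s),",
        length(object@individualIds), "individuals x",
        length(object@snpIds), "SNPs\n")
    cat(sprintf("  variance mode: %s; %d iteration(s); final objective %.3f\n",
                cfg$varianceMode, cfg$nIter,
                object@logLikTrace[length(object@logLikTrace)]))
    cat(sprintf("  sparsity: %.1f%% of prior loading variances exactly zero\n",
                100 * mean(object@Sigma == 0)))
})
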