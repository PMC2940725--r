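#' Binomial admixture model log likelihood
#'
#' Log likelihood of genotype counts under the admixture factorization:
#' each entry is Binomial(2, sum_k q_ik p_kj). Success probabilities are
#' clamped to [1e-9, 1 - 1e-9] before taking logs.
#'
#' @param X a [GenotypeMatrix] or integer 0/1/2 matrix.
#' @param Q numeric n x K admixture proportions, rows on the simplex.
#' @param P numeric K x p allele frequencies in [0, 1].
#' @return a single numeric value.
#' @export
admixLogLik <- function(X, Q, P) {
    if (is(X, "GenotypeMatrix")) X <- X@values
    X <- as.matrix(X)
    pm <- Q %*% P
    pm <- pmin(pmax(pm, 1e-9), 1 - 1e-9)
    sum(X * log(pm) + (2 - X) * log1p(-pm)) +
        sum(lchoose(2, X))
}

#' Fit the binomial admixture model by EM
#'
#' Fits admixture proportions Q (rows on the simplex) and population
#' allele frequencies P (entries in [0, 1]) by expectation-maximization:
#' the E-step allocates each individual's reference and non-reference
#' allele counts to ancestral populations in proportion to the current
#' parameters, and the M-step re-estimates P and Q from the expected
#' counts in closed form. The constraints hold exactly after every
#' M-step and the log likelihood is non-decreasing. P is initialized
#' from logit-perturbed overall allele frequencies and Q from a
#' symmetric Dirichlet(1); with `nRestarts > 1` the best of several
#' seeded starts is returned.
#'
#' @param X a [GenotypeMatrix] or integer 0/1/2 matrix.
#' @param K number of ancestral populations.
#' @param seed integer seed; the fit is deterministic given it.
#' @param maxIter,relTol stopping rule on the relative log likelihood
#'   change.
#' @param nRestarts number of random restarts.
#' @return an [AdmixFit].
#' @examples
#' sim <- simDiscrete(nPerPop = 15, nSnps = 400, nPops = 2,
#'                    fst = 0.2, seed = 2)
#' fit <- fitAdmixture(sim@genotypes, K = 2, seed = 1)
#' round(head(admixtureProportions(fit)), 3)
#' @export
fitAdmixture <- function(X, K, seed = 1, maxIter = 2000, relTol = 1e-6,
                         nRestarts = 1) {
    indIds <- NULL; sIds <- NULL
    if (is(X, "GenotypeMatrix")) {
        indIds <- X@individualIds; sIds <- X@snpIds; X <- X@values
    }
    X <- as.matrix(X)
    if (!all(X %in% c(0, 1, 2)))
        stop("the admixture model requires integer 0/1/2 genotypes")
    if (is.null(indIds)) indIds <- paste0("ind", seq_len(nrow(X)))
    if (is.null(sIds)) sIds <- paste0("snp", seq_len(ncol(X)))
    best <- NULL
    for (r in seq_len(nRestarts)) {
        res <- .admixRunOnce(X, K, seed + r - 1L, maxIter, relTol)
        if (is.null(best) || res$ll > best$ll) best <- res
    }
    new("AdmixFit", Q = best$Q, P = best$P,
        logLikTrace = best$trace,
        config = list(K = K, seed = seed, maxIter = maxIter,
                      relTol = relTol, nRestarts = nRestarts,
                      restartSeed = best$seed,
                      nIter = length(best$trace)),
        individualIds = indIds, snpIds = sIds)
}

.admixRunOnce <- function(X, K, seed, maxIter, relTol) {
    set.seed(seed)
    n <- nrow(X); p <- ncol(X)
    pbar <- pmin(pmax(colMeans(X) / 2, 1e-3), 1 - 1e-3)
    P <- matrix(stats::plogis(stats::qlogis(rep(pbar, each = K)) +
                              stats::rnorm(K * p, sd = 0.5)), K, p)
    Qraw <- matrix(stats::rexp(n * K), n, K)
    Q <- Qraw / rowSums(Qraw)
    eps <- 1e-9
    trace <- numeric(0)
    llPrev <- -Inf
    for (it in seq_len(maxIter)) {
        QP <- Q %*% P
        QP <- pmin(pmax(QP, eps), 1 - eps)
        U <- X / QP          # reference-allele responsibility scale
        W <- (2 - X) / (1 - QP)
        # expected allele counts per component, all k at once:
        #   colA[j,k] = p_kj sum_i q_ik U_ij, colB analogous for the
        #   non-reference allele; rowA/rowB are the per-individual sums
        colA <- t(P) * crossprod(U, Q)      # p x K
        colB <- (1 - t(P)) * crossprod(W, Q)
        rowA <- Q * (U %*% t(P))            # n x K
        rowB <- Q * (W %*% (1 - t(P)))
        tot <- colA + colB
        newP <- t(ifelse(tot > 0, colA / pmax(tot, eps), t(P)))
        newQ <- (rowA + rowB) / (2 * p)
        empty <- colSums(tot) < 1e-12
        if (any(empty)) {
            warning("component(s) ", paste(which(empty), collapse = ","),
                    " emptied; re-seeding their frequency rows")
            for (k in which(empty)) {
                newP[k, ] <- stats::plogis(stats::qlogis(pbar) +
                                           stats::rnorm(p, sd = 0.5))
                newQ[, k] <- 1 / K
            }
        }
        newQ <- newQ / rowSums(newQ)
        P <- newP; Q <- newQ
        ll <- admixLogLik(X, Q, P)
        trace <- c(trace, ll)
        if (is.finite(llPrev) &&
            abs(ll - llPrev) < relTol * abs(llPrev)) break
        llPrev <- ll
    }
    list(Q = Q, P = P, trace = trace, ll = trace[length(trace)],
         seed = seed)
}

#' Map four-way admixture proportions to the plane
#'
#' Projects each individual's 4-dimensional admixture proportions to a
#' point in the unit square as the convex combination of the square's
#' corners (0,0), (1,0), (0,1), (1,1) weighted by the proportions —
#' used to visualize a two-dimensional habitat fitted with K = 4.
#' The component-to-corner assignment is the column order of `Q`;
#' resolve label switching first (see [matchFactors()]).
#'
#' @param Q numeric n x 4 matrix, rows on the simplex.
#' @return numeric n x 2 matrix of coordinates in the unit square.
#' @examples
#' mapAdmixture2D(rbind(c(1, 0, 0, 0), c(0.25, 0.25, 0.25, 0.25)))
#' @export
mapAdmixture2D <- function(Q) {
    Q <- as.matrix(Q)
    if (ncol(Q) != 4)
        stop("Q must have exactly 4 columns")
    if (any(Q < -1e-9) || any(abs(rowSums(Q) - 1) > 1e-6))
        stop("Q rows must lie on the simplex")
    corners <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
    Q %*% corners
}

#' @rdname admixtureProportions
#' @export
setMethod("admixtureProportions", "AdmixFit", function(x) {
    m <- x@Q
    dimnames(m) <- list(x@individualIds,
                        paste0("pop", seq_len(ncol(m))))
    m
})

#' @rdname alleleFrequencies
#' @export
setMethod("alleleFrequencies", "AdmixFit", function(x) {
    m <- x@P
    dimnames(m) <- list(paste0("pop", seq_len(nrow(m))), x@snpIds)
    m
})

#' @rdname loadings
#' @export
setMethod("loadings", "AdmixFit", function(x) admixtureProportions(x))

#' @rdname factorMatrix
#' @export
setMethod("factorMatrix", "AdmixFit", function(x) 2 * alleleFrequencies(x))

#' @rdname logLikTrace
#' @export
setMethod("logLikTrace", "AdmixFit", function(x) x@logLikTrace)

#' @rdname individualIds
#' @export
setMethod("individualIds", "AdmixFit", function(x) x@individualIds)

#' @rdname snpIds
#' @export
setMethod("snpIds", "AdmixFit", function(x) x@snpIds)

setMethod("show", "AdmixFit", function(object) {
    cat("AdmixFit:", ncol(object@Q), "ancestral populations,",
        nrow(object@Q), "individuals x", ncol(object@P), "SNPs\n")
    cat(sprintf("  %d EM iteration(s); final log likelihood %.3f\n",
                object@config$nIter,
                object@logLikTrace[length(object@logLikTrace)]))
})
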