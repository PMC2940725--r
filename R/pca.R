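#' Standardize the columns of a genotype matrix
#'
#' Mean-centers each SNP column and divides by its sample standard
#' deviation (denominator n - 1). Monomorphic (zero-variance) columns
#' cannot be standardized and are dropped, with their ids reported.
#'
#' @param X a [GenotypeMatrix] or numeric matrix.
#' @return list with `Z` (standardized matrix over retained columns),
#'   `columnMeans`, `columnSds` (full length; sd 0 marks a dropped
#'   column), `retained` (logical), and `droppedSnpIds`.
#' @export
standardizeGenotypes <- function(X) {
    sIds <- NULL
    if (is(X, "GenotypeMatrix")) {
        sIds <- X@snpIds; X <- X@values
    }
    X <- as.matrix(X)
    if (is.null(sIds)) sIds <- paste0("snp", seq_len(ncol(X)))
    mu <- colMeans(X)
    sds <- apply(X, 2, stats::sd)
    keep <- sds > 0
    if (!any(keep))
        stop("all SNP columns are monomorphic; nothing to standardize")
    if (any(!keep))
        warning(sum(!keep), " monomorphic SNP(s) dropped before PCA")
    Z <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2,
               sds[keep], "/")
    sdsOut <- sds
    sdsOut[!keep] <- 0
    list(Z = Z, columnMeans = mu, columnSds = sdsOut, retained = keep,
         droppedSnpIds = sIds[!keep])
}

#' Principal component factorization of a genotype matrix
#'
#' Standardizes the columns and computes the truncated SVD
#' `Z ~ U_K D_K V_K'`. Loadings are `U_K D_K` (orthogonal columns,
#' the individuals' principal components), factors `V_K'` (orthonormal
#' rows); the K-term product is the best rank-K approximation of Z in
#' squared error. Sign convention: each factor row's largest-magnitude
#' entry is made positive, so output is deterministic.
#'
#' @param X a [GenotypeMatrix] or numeric matrix (individuals x SNPs).
#' @param K number of components, at most `min(n, p_retained)`.
#' @return a [PcaFit].
#' @examples
#' sim <- simDiscrete(nPerPop = 10, nSnps = 300, nPops = 2,
#'                    fst = 0.2, seed = 1)
#' fit <- fitPca(sim@genotypes, K = 2)
#' fit@singularValues
#' @export
fitPca <- function(X, K) {
    indIds <- NULL; sIds <- NULL
    if (is(X, "GenotypeMatrix")) {
        indIds <- X@individualIds; sIds <- X@snpIds; X <- X@values
    }
    X <- as.matrix(X)
    if (is.null(indIds)) indIds <- paste0("ind", seq_len(nrow(X)))
    if (is.null(sIds)) sIds <- paste0("snp", seq_len(ncol(X)))
    std <- standardizeGenotypes(X)
    Z <- std$Z
    if (K > min(dim(Z)))
        stop("K exceeds min(n, number of polymorphic SNPs)")
    sv <- svd(Z, nu = K, nv = K)
    d <- sv$d[seq_len(K)]
    U <- sv$u; V <- sv$v
    for (k in seq_len(K)) {
        jmax <- which.max(abs(V[, k]))
        if (V[jmax, k] < 0) {
            V[, k] <- -V[, k]
            U[, k] <- -U[, k]
        }
    }
    new("PcaFit",
        loadings = U %*% diag(d, K),
        factors = t(V),
        singularValues = d,
        columnMeans = std$columnMeans,
        columnSds = std$columnSds,
        retained = std$retained,
        droppedSnpIds = std$droppedSnpIds,
        individualIds = indIds, snpIds = sIds)
}

#' Implied factorization of the raw genotype matrix
#'
#' Re-expresses a PCA of the standardized matrix as a (K + 1)-factor
#' factorization of the raw matrix: the extra factor is the vector of
#' genotype column means with an all-ones loading for every individual,
#' and each PCA factor is rescaled by the column standard deviations.
#' The product approximates the raw matrix with the same error as the
#' rank-K approximation of the standardized matrix (up to the sd
#' reweighting); dropped monomorphic columns are reconstructed exactly
#' by the mean factor.
#'
#' @param fit a [PcaFit].
#' @param K number of PCA factors to include (default: all fitted).
#' @return list with `LambdaAug` (n x (K + 1); column 1 all ones) and
#'   `FAug` ((K + 1) x p over all input SNPs; row 1 the column means).
#' @export
impliedRawFactorization <- function(fit, K = length(fit@singularValues)) {
    stopifnot(is(fit, "PcaFit"),
              K >= 0, K <= length(fit@singularValues))
    n <- nrow(fit@loadings)
    p <- length(fit@columnMeans)
    LambdaAug <- cbind(rep(1, n),
                       fit@loadings[, seq_len(K), drop = FALSE])
    FAug <- matrix(0, K + 1, p)
    FAug[1, ] <- fit@columnMeans
    if (K > 0) {
        Fr <- fit@factors[seq_len(K), , drop = FALSE]
        FAug[-1, fit@retained] <-
            sweep(Fr, 2, fit@columnSds[fit@retained], "*")
    }
    list(LambdaAug = LambdaAug, FAug = FAug)
}

#' @rdname loadings
#' @export
setMethod("loadings", "PcaFit", function(x) {
    m <- x@loadings
    dimnames(m) <- list(x@individualIds,
                        paste0("PC", seq_len(ncol(m))))
    m
})

#' @rdname factorMatrix
#' @export
setMethod("factorMatrix", "PcaFit", function(x) {
    m <- x@factors
    dimnames(m) <- list(paste0("PC", seq_len(nrow(m))),
                        x@snpIds[x@retained])
    m
})

#' @rdname individualIds
#' @export
setMethod("individualIds", "PcaFit", function(x) x@individualIds)

#' @rdname snpIds
#' @export
setMethod("snpIds", "PcaFit", function(x) x@snpIds)

setMethod("show", "PcaFit", function(object) {
    cat("PcaFit:", length(object@singularValues), "components,",
        nrow(object@loadings), "individuals x",
        sum(object@retained), "retained SNPs",
        sprintf("(%d monomorphic dropped)\n",
                length(object@droppedSnpIds)))
    cat("  singular values:",
        paste(signif(object@singularValues, 4), collapse = ", "), "\n")
})
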