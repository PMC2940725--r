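## Cross-method and cross-run comparison utilities. Factor models are
## identified only up to permutation, sign and (for SFA) scale of the
## components, and loadings from different runs may further be rotated
## versions of one another; these helpers resolve those invariances
## before any correlation is computed.

.permutations <- function(k) {
    if (k == 1) return(matrix(1, 1, 1))
    sub <- .permutations(k - 1)
    out <- matrix(0L, 0, k)
    for (pos in seq_len(k)) {
        block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                       if (pos <= k - 1)
                           sub[, pos:(k - 1), drop = FALSE])
        out <- rbind(out, block)
    }
    out
}

#' Match factors across two factorizations
#'
#' Finds the bijection between the rows of `A` and the rows of `B`
#' maximizing the total absolute Pearson correlation (optimal
#' assignment, exhaustive over permutations; ties broken toward the
#' lowest-index assignment), and the signs making every matched
#' correlation nonnegative. Zero-variance rows correlate as 0. Use it to
#' resolve label switching before comparing fits: rows are factors and
#' columns SNPs (transpose loadings first to compare those, with
#' columns = individuals).
#'
#' @param A,B numeric k x p matrices with equal dimensions.
#' @return list with `permutation` (integer k-vector: row i of `A`
#'   matches row `permutation[i]` of `B`), `signs` (+/-1 per row of
#'   `A`), and `correlations` (matched absolute correlations, in `A`
#'   row order).
#' @examples
#' A <- matrix(rnorm(30), 3)
#' matchFactors(A, A[c(2, 3, 1), ] * c(-1, 1, -1))$permutation
#' @export
matchFactors <- function(A, B) {
    A <- as.matrix(A); B <- as.matrix(B)
    if (!all(dim(A) == dim(B)))
        stop("A and B must have identical dimensions")
    k <- nrow(A)
    if (k > 8)
        stop("exhaustive matching supports at most 8 factors")
    C <- suppressWarnings(stats::cor(t(A), t(B)))
    C[!is.finite(C)] <- 0
    perms <- .permutations(k)
    best <- -Inf; bestPerm <- seq_len(k)
    for (r in seq_len(nrow(perms))) {
        sc <- sum(abs(C[cbind(seq_len(k), perms[r, ])]))
        if (sc > best + 1e-12) {
            best <- sc; bestPerm <- perms[r, ]
        }
    }
    matched <- C[cbind(seq_len(k), bestPerm)]
    list(permutation = as.integer(bestPerm),
         signs = ifelse(matched >= 0, 1, -1),
         correlations = abs(matched))
}

#' Orthogonal Procrustes alignment of loadings
#'
#' Finds the orthogonal matrix R (rotation, possibly with reflection)
#' minimizing `||L R - target||^2` and returns it together with the
#' aligned loadings. Loadings from separate runs of the factor model
#' may differ by such a rotation; aligning removes it before
#' correlation with a reference or with geography.
#'
#' @param L numeric n x k matrix to align.
#' @param target numeric n x k reference.
#' @return list with `rotation` (k x k orthogonal) and `aligned`
#'   (`L %*% rotation`).
#' @export
procrustesAlign <- function(L, target) {
    L <- as.matrix(L); target <- as.matrix(target)
    if (!all(dim(L) == dim(target)))
        stop("L and target must have identical dimensions")
    M <- crossprod(L, target)
    sv <- svd(M)
    if (min(sv$d) < 1e-12 * max(sv$d, 1))
        warning("rank-deficient crossproduct in Procrustes alignment; ",
                "rotation fixed by the SVD convention")
    R <- sv$u %*% t(sv$v)
    list(rotation = R, aligned = L %*% R)
}

#' Convert positive loadings to admixture proportions
#'
#' When an individual's loadings on all factors are strictly positive,
#' their normalized values (each divided by the row sum) are a natural
#' estimate of its admixture proportions. Rows with any non-positive
#' entry are returned as NA: the estimate is only defined under
#' positivity. Factor signs are arbitrary, so columns may need
#' orientation first (`orient = TRUE` flips any column whose sum is
#' negative).
#'
#' @param Lambda numeric n x k loading matrix (or a single k-vector).
#' @param orient flip negative-sum columns before converting.
#' @return numeric n x k matrix; defined rows lie on the simplex.
#' @examples
#' loadingsToAdmixture(c(3, 1))
#' @export
loadingsToAdmixture <- function(Lambda, orient = FALSE) {
    Lambda <- if (is.null(dim(Lambda))) matrix(Lambda, 1) else
        as.matrix(Lambda)
    if (orient) {
        flip <- colSums(Lambda) < 0
        Lambda[, flip] <- -Lambda[, flip, drop = FALSE]
    }
    out <- Lambda / rowSums(Lambda)
    bad <- apply(Lambda <= 0, 1, any)
    out[bad, ] <- NA_real_
    out
}

#' Sampling-robustness experiment
#'
#' Quantifies how much each method's loadings for the individuals kept
#' in the sample move when part of one group is removed: fits each
#' method on the full data and on the data with a fraction of
#' `dropGroup` deleted, resolves label switching with [matchFactors()]
#' on the retained individuals' loadings, and reports the mean matched
#' absolute Pearson correlation per method. Sparse factor analysis and
#' the admixture model are expected to be more stable under this
#' perturbation than PCA.
#'
#' @param X a [GenotypeMatrix].
#' @param groupLabels vector of group memberships, one per individual.
#' @param dropGroup the group to thin.
#' @param dropFraction fraction of that group to remove (seeded draw).
#' @param K factor count used for every method.
#' @param methods subset of `c("sfa", "pca", "admixture")`.
#' @param seed integer seed controlling the dropped subset and the fits.
#' @param ... further arguments passed to [fitSfa()] (e.g. `maxIter`).
#' @return list with `correlations` (named mean per method) and
#'   `perFactor` (matched per-factor correlations per method).
#' @export
robustnessExperiment <- function(X, groupLabels, dropGroup,
                                 dropFraction = 0.5, K,
                                 methods = c("sfa", "pca", "admixture"),
                                 seed = 1, ...) {
    stopifnot(is(X, "GenotypeMatrix"))
    methods <- match.arg(methods, several.ok = TRUE)
    groupLabels <- as.character(groupLabels)
    if (length(groupLabels) != nrow(X@values))
        stop("groupLabels must cover all individuals")
    inGroup <- which(groupLabels == dropGroup)
    nDrop <- round(dropFraction * length(inGroup))
    if (length(inGroup) - nDrop < 1 && dropFraction > 0)
        stop("group '", dropGroup, "' too small to drop from")
    set.seed(seed)
    dropped <- if (nDrop > 0) sort(sample(inGroup, nDrop)) else integer(0)
    keep <- setdiff(seq_along(groupLabels), dropped)
    Xred <- X[keep, ]
    loadOf <- function(method, data) {
        switch(method,
               sfa = loadings(fitSfa(data, K = K, seed = seed, ...)),
               pca = loadings(fitPca(data, K = K)),
               admixture = admixtureProportions(
                   fitAdmixture(data, K = K, seed = seed)))
    }
    cors <- numeric(0); perFactor <- list()
    for (m in methods) {
        Lfull <- loadOf(m, X)[keep, , drop = FALSE]
        Lred <- loadOf(m, Xred)
        mt <- matchFactors(t(Lfull), t(Lred))
        perFactor[[m]] <- mt$correlations
        cors[m] <- mean(mt$correlations)
    }
    list(correlations = cors, perFactor = perFactor,
         droppedIndividuals = X@individualIds[dropped])
}
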