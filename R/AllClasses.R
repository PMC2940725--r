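#' @import methods
NULL

#' Genotype matrix container
#'
#' Holds an n x p matrix of allele counts (individuals in rows, SNPs in
#' columns) together with individual and SNP identifiers. Entries are
#' counts of a reference allele: 0, 1 or 2 for diploid genotypes, though
#' real values are permitted after preprocessing (e.g. mean imputation).
#' Fitting functions require a complete matrix; missing values are
#' rejected at construction.
#'
#' @slot values numeric matrix, individuals x SNPs.
#' @slot individualIds character vector of row labels.
#' @slot snpIds character vector of column labels.
#'
#' @seealso [GenotypeMatrix()], [readGenotypes()], [filterMAF()]
#' @export
setClass("GenotypeMatrix",
    representation(
        values = "matrix",
        individualIds = "character",
        snpIds = "character"
    )
)

setValidity("GenotypeMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v))
        msg <- c(msg, "'values' must be a numeric matrix")
    if (anyNA(v) || any(!is.finite(v)))
        msg <- c(msg, "genotype matrix contains missing or non-finite entries")
    if (length(object@individualIds) != nrow(v))
        msg <- c(msg, "individualIds length must equal nrow(values)")
    if (length(object@snpIds) != ncol(v))
        msg <- c(msg, "snpIds length must equal ncol(values)")
    if (length(msg)) msg else TRUE
})

#' Fitted sparse factor analysis model
#'
#' The state returned by [fitSfa()]: a K-factor Gaussian factor model of
#' the genotype matrix with an automatic relevance determination (ARD)
#' prior on the loadings. `Sigma` holds the estimated per-individual,
#' per-factor prior variances; exact zeros there force the corresponding
#' posterior loading to zero and are the model's sparsity mechanism.
#'
#' @slot F numeric K x p factor matrix (rows rescaled to unit sample
#'   variance).
#' @slot mu numeric p-vector of column means (all zero when the mean term
#'   is off, i.e. plain SFA rather than SFAm).
#' @slot psi numeric vector of residual variances: length n in "row"
#'   (individual-specific) variance mode, length p in "column"
#'   (SNP-specific) mode.
#' @slot Sigma numeric n x K matrix of ARD prior variances, entries >= 0.
#' @slot Omega numeric n x K matrix of posterior mean loadings.
#' @slot Vpost numeric K x K x n array of per-individual posterior
#'   loading covariances.
#' @slot logLikTrace numeric vector, log marginal likelihood (including
#'   the gamma prior on the inverse residual variances) per iteration.
#' @slot config list echoing the fitting configuration and seed.
#' @slot individualIds,snpIds identifiers carried over from the input.
#'
#' @seealso [fitSfa()], [loadings()], [factorMatrix()]
#' @export
setClass("SfaFit",
    representation(
        F = "matrix",
        mu = "numeric",
        psi = "numeric",
        Sigma = "matrix",
        Omega = "matrix",
        Vpost = "array",
        logLikTrace = "numeric",
        config = "list",
        individualIds = "character",
        snpIds = "character"
    )
)

setValidity("SfaFit", function(object) {
    msg <- character()
    if (any(object@Sigma < 0))
        msg <- c(msg, "ARD prior variances must be >= 0")
    floor <- object@config$psiFloor
    if (!is.null(floor) && any(object@psi < floor - 1e-12))
        msg <- c(msg, "residual variances fall below psiFloor")
    if (nrow(object@F) > 0) {
        rv <- apply(object@F, 1, stats::var)
        if (any(abs(rv - 1) > 1e-6))
            msg <- c(msg, "factor rows must have unit sample variance")
    }
    if (length(msg)) msg else TRUE
})

#' Principal component factorization of a genotype matrix
#'
#' PCA of the column-standardized genotype matrix, stored in
#' factorization form: `loadings` (left singular vectors scaled by
#' singular values) times `factors` (orthonormal right singular vectors)
#' is the best rank-K approximation of the standardized matrix. Column
#' means/sds and the identities of dropped monomorphic SNPs are retained
#' so the implied factorization of the raw matrix (with an all-ones mean
#' factor) can be reconstructed via [impliedRawFactorization()].
#'
#' @slot loadings numeric n x K matrix, mutually orthogonal columns.
#' @slot factors numeric K x p_retained matrix, orthonormal rows.
#' @slot singularValues numeric K-vector, non-increasing.
#' @slot columnMeans,columnSds numeric p-vectors over all input SNPs
#'   (sd reported for dropped SNPs is 0).
#' @slot retained logical p-vector: which SNPs survived standardization.
#' @slot droppedSnpIds ids of monomorphic SNPs dropped before the SVD.
#' @slot individualIds,snpIds identifiers from the input matrix.
#' @seealso [fitPca()]
#' @export
setClass("PcaFit",
    representation(
        loadings = "matrix",
        factors = "matrix",
        singularValues = "numeric",
        columnMeans = "numeric",
        columnSds = "numeric",
        retained = "logical",
        droppedSnpIds = "character",
        individualIds = "character",
        snpIds = "character"
    )
)

setValidity("PcaFit", function(object) {
    msg <- character()
    d <- object@singularValues
    if (is.unsorted(rev(d), strictly = FALSE))
        msg <- c(msg, "singular values must be non-increasing")
    if (length(msg)) msg else TRUE
})

#' Fitted binomial admixture model
#'
#' Constrained matrix factorization of the genotype matrix in which each
#' entry is Binomial(2, sum_k q_ik p_kj): `Q` rows are admixture
#' proportions on the simplex and `P` holds population allele
#' frequencies in [0, 1]. Fitted by EM, so `logLikTrace` is
#' non-decreasing.
#'
#' @slot Q numeric n x K admixture proportions, rows summing to one.
#' @slot P numeric K x p population allele frequencies.
#' @slot logLikTrace numeric binomial log likelihood per iteration.
#' @slot config list echoing the fitting configuration and seed.
#' @slot individualIds,snpIds identifiers from the input matrix.
#' @seealso [fitAdmixture()], [admixLogLik()]
#' @export
setClass("AdmixFit",
    representation(
        Q = "matrix",
        P = "matrix",
        logLikTrace = "numeric",
        config = "list",
        individualIds = "character",
        snpIds = "character"
    )
)

setValidity("AdmixFit", function(object) {
    msg <- character()
    if (any(object@Q < -1e-12) ||
        any(abs(rowSums(object@Q) - 1) > 1e-8))
        msg <- c(msg, "Q rows must lie on the simplex")
    if (any(object@P < -1e-12) || any(object@P > 1 + 1e-12))
        msg <- c(msg, "P entries must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Synthetic scenario with ground truth
#'
#' Output of the scenario generators: a simulated [GenotypeMatrix] plus
#' the generating quantities needed for parameter-recovery experiments —
#' deme coordinates, true admixture proportions, and true population (or
#' per-deme) allele frequencies. Slots that do not apply to a scenario
#' hold zero-extent objects.
#'
#' @slot genotypes a [GenotypeMatrix].
#' @slot demeCoords numeric n x 1 or n x 2 matrix of sampling
#'   coordinates (0 x 0 for discrete scenarios).
#' @slot trueQ numeric n x K true admixture proportions (one-hot for
#'   discrete populations; 0 x 0 when undefined).
#' @slot trueFreqs numeric (populations or demes) x p matrix of true
#'   allele frequencies.
#' @slot habitatLabels integer n-vector (two-habitat scenario only).
#' @slot scenario character scalar naming the generator.
#' @slot seed integer seed the scenario was generated from.
#' @export
setClass("SimTruth",
    representation(
        genotypes = "GenotypeMatrix",
        demeCoords = "matrix",
        trueQ = "matrix",
        trueFreqs = "matrix",
        habitatLabels = "integer",
        scenario = "character",
        seed = "integer"
    )
)

setValidity("SimTruth", function(object) {
    msg <- character()
    if (length(object@trueQ) && (any(object@trueQ < -1e-12) ||
        any(abs(rowSums(object@trueQ) - 1) > 1e-8)))
        msg <- c(msg, "trueQ rows must lie on the simplex")
    if (length(object@trueFreqs) &&
        (any(object@trueFreqs <= 0) || any(object@trueFreqs >= 1)))
        msg <- c(msg, "true allele frequencies must lie in (0, 1)")
    if (length(msg)) msg else TRUE
})
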