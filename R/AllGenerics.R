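#' Extract genotype values
#'
#' @param x a [GenotypeMatrix] or [SimTruth].
#' @return numeric matrix of allele counts, individuals x SNPs.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' Individual identifiers
#' @param x an object carrying individual labels.
#' @return character vector.
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' SNP identifiers
#' @param x an object carrying SNP labels.
#' @return character vector.
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' Per-individual loadings of a factorization
#'
#' For SFA fits these are posterior mean loadings; for PCA, left singular
#' vectors scaled by singular values; for the admixture model, the
#' admixture proportions Q.
#'
#' @param x a fitted model object.
#' @return numeric n x K matrix.
#' @export
setGeneric("loadings", function(x) standardGeneric("loadings"))

#' Per-SNP factors of a factorization
#'
#' @param x a fitted model object.
#' @return numeric K x p matrix.
#' @export
setGeneric("factorMatrix", function(x) standardGeneric("factorMatrix"))

#' Log likelihood trace of an iterative fit
#' @param x a fitted model object.
#' @return numeric vector, one entry per iteration.
#' @export
setGeneric("logLikTrace", function(x) standardGeneric("logLikTrace"))

#' ARD prior variances of an SFA fit
#' @param x an [SfaFit].
#' @return numeric n x K matrix; exact zeros encode pruned loadings.
#' @export
setGeneric("priorVariances", function(x) standardGeneric("priorVariances"))

#' Residual variances of an SFA fit
#' @param x an [SfaFit].
#' @return numeric vector (per individual or per SNP, by variance mode).
#' @export
setGeneric("residualVariances",
    function(x) standardGeneric("residualVariances"))

#' Admixture proportions of an admixture fit
#' @param x an [AdmixFit].
#' @return numeric n x K matrix, rows on the simplex.
#' @export
setGeneric("admixtureProportions",
    function(x) standardGeneric("admixtureProportions"))

#' Population allele frequencies of an admixture fit
#' @param x an [AdmixFit].
#' @return numeric K x p matrix with entries in [0, 1].
#' @export
setGeneric("alleleFrequencies",
    function(x) standardGeneric("alleleFrequencies"))
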