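#' Construct a GenotypeMatrix
#'
#' @param values numeric matrix of allele counts, individuals in rows.
#' @param individualIds optional row labels (defaults to `ind1..indn` or
#'   existing rownames).
#' @param snpIds optional column labels (defaults to `snp1..snpp` or
#'   existing colnames).
#' @param checkCounts if `TRUE`, require every entry to be 0, 1 or 2
#'   (integer coding); set to `FALSE` for real-valued matrices produced
#'   by preprocessing such as imputation.
#' @return a [GenotypeMatrix].
#' @examples
#' gm <- GenotypeMatrix(matrix(c(0, 1, 2, 1, 0, 2), nrow = 2))
#' dim(gm)
#' @export
GenotypeMatrix <- function(values, individualIds = NULL, snpIds = NULL,
                           checkCounts = TRUE) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (anyNA(values) || any(!is.finite(values)))
        stop("genotype matrix contains missing or non-finite entries; ",
             "impute or filter first (see readGenotypes missingPolicy)")
    if (checkCounts && !all(values %in% c(0, 1, 2)))
        stop("integer-coded genotypes must be 0, 1 or 2; ",
             "use checkCounts = FALSE for real-valued matrices")
    if (is.null(individualIds))
        individualIds <- rownames(values)
    if (is.null(individualIds))
        individualIds <- paste0("ind", seq_len(nrow(values)))
    if (is.null(snpIds))
        snpIds <- colnames(values)
    if (is.null(snpIds))
        snpIds <- paste0("snp", seq_len(ncol(values)))
    dimnames(values) <- NULL
    new("GenotypeMatrix", values = values,
        individualIds = as.character(individualIds),
        snpIds = as.character(snpIds))
}

#' @rdname genotypes
#' @export
setMethod("genotypes", "GenotypeMatrix", function(x) {
    v <- x@values
    dimnames(v) <- list(x@individualIds, x@snpIds)
    v
})

#' @rdname individualIds
#' @export
setMethod("individualIds", "GenotypeMatrix", function(x) x@individualIds)

#' @rdname snpIds
#' @export
setMethod("snpIds", "GenotypeMatrix", function(x) x@snpIds)

#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@values))

setMethod("show", "GenotypeMatrix", function(object) {
    d <- dim(object@values)
    cat("GenotypeMatrix:", d[1], "individuals x", d[2], "SNPs\n")
    cat("  allele-count range:", paste(range(object@values), collapse = ".."),
        "\n")
})

#' Subset a GenotypeMatrix
#'
#' @param x a [GenotypeMatrix].
#' @param i,j individual and SNP indices (any standard matrix index).
#' @param ... ignored.
#' @param drop ignored; the result is always a GenotypeMatrix.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@values))
    if (missing(j)) j <- seq_len(ncol(x@values))
    ii <- seq_len(nrow(x@values))[i]
    jj <- seq_len(ncol(x@values))[j]
    new("GenotypeMatrix",
        values = x@values[ii, jj, drop = FALSE],
        individualIds = x@individualIds[ii],
        snpIds = x@snpIds[jj])
})

#' Filter SNPs on minor allele frequency
#'
#' Removes SNPs whose sample minor allele frequency is below `minMaf`.
#' Low-frequency SNPs carry little information about structure and are
#' the documented cause of residual-variance degeneracy in the sparse
#' factor model, so a modest filter (e.g. 0.05) is recommended before
#' fitting.
#'
#' @param x a [GenotypeMatrix] with integer-coded entries.
#' @param minMaf minimum minor allele frequency in [0, 0.5); SNPs with
#'   MAF strictly below it are dropped. `0` keeps everything.
#' @return list with `genotypes` (filtered [GenotypeMatrix]) and
#'   `removedIds` (character vector of dropped SNP ids).
#' @examples
#' gm <- GenotypeMatrix(cbind(c(0, 0, 0, 1), c(1, 1, 2, 0)))
#' filterMAF(gm, 0.2)$removedIds
#' @export
filterMAF <- function(x, minMaf) {
    stopifnot(is(x, "GenotypeMatrix"))
    if (minMaf < 0 || minMaf >= 0.5)
        stop("minMaf must lie in [0, 0.5)")
    freq <- colMeans(x@values) / 2
    maf <- pmin(freq, 1 - freq)
    keep <- maf >= minMaf
    if (!any(keep))
        stop("all SNPs fall below the MAF threshold")
    list(genotypes = x[, keep], removedIds = x@snpIds[!keep])
}

.parseGenotypeTable <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines))
        stop("empty genotype file: ", path)
    toks <- strsplit(trimws(lines), "[ \t]+")
    suppressWarnings(first <- as.numeric(toks[[1]]))
    hasHeader <- anyNA(first)
    body <- if (hasHeader) toks[-1] else toks
    if (!length(body))
        stop("genotype file has a header but no data rows: ", path)
    widths <- lengths(body)
    if (length(unique(widths)) != 1)
        stop("ragged genotype file: line ",
             which(widths != widths[1])[1] + hasHeader,
             " has ", widths[widths != widths[1]][1],
             " fields, expected ", widths[1])
    suppressWarnings(firstCol <- as.numeric(vapply(body, `[`, "", 1)))
    hasIds <- anyNA(firstCol)
    indIds <- if (hasIds) vapply(body, `[`, "", 1) else NULL
    dataToks <- if (hasIds) lapply(body, `[`, -1) else body
    snpIds <- NULL
    if (hasHeader) {
        hdr <- toks[[1]]
        if (length(hdr) == length(dataToks[[1]]) + 1)
            hdr <- hdr[-1]
        if (length(hdr) != length(dataToks[[1]]))
            stop("header width does not match data width in ", path)
        snpIds <- hdr
    }
    vals <- matrix(NA_real_, length(dataToks), length(dataToks[[1]]))
    for (r in seq_along(dataToks)) {
        suppressWarnings(row <- as.numeric(dataToks[[r]]))
        bad <- is.na(row) & !(toupper(dataToks[[r]]) %in% c("NA", "-9"))
        if (any(bad))
            stop("unparseable genotype at line ", r + hasHeader,
                 ", field ", which(bad)[1] + hasIds, ": '",
                 dataToks[[r]][which(bad)[1]], "'")
        row[toupper(dataToks[[r]]) == "-9"] <- NA_real_
        vals[r, ] <- row
    }
    list(values = vals, individualIds = indIds, snpIds = snpIds)
}

#' Read a genotype matrix from delimited text
#'
#' Reads whitespace/tab-delimited allele-count matrices (individuals x
#' SNPs), with an optional header row of SNP ids and an optional leading
#' column of individual ids, both auto-detected. Also reads
#' plink-`.raw`-style dosage tables (`format = "raw"`: header
#' `FID IID PAT MAT SEX PHENOTYPE SNP...`, one individual per row).
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"raw"`.
#' @param transpose set `TRUE` for SNP-major files (SNPs in rows); the
#'   matrix is transposed after reading. Ignored for `"raw"`.
#' @param missingPolicy `"error"` (default: the factor models require a
#'   complete matrix) or `"imputeMean"` (replace NA by the SNP's mean
#'   count; the result is real-valued).
#' @return a [GenotypeMatrix].
#' @seealso [writeGenotypes()]
#' @export
readGenotypes <- function(path, format = c("tsv", "raw"), transpose = FALSE,
                          missingPolicy = c("error", "imputeMean")) {
    format <- match.arg(format)
    missingPolicy <- match.arg(missingPolicy)
    if (!file.exists(path))
        stop("no such file: ", path)
    if (format == "raw") {
        tab <- utils::read.table(path, header = TRUE,
                                 stringsAsFactors = FALSE,
                                 check.names = FALSE)
        fixed <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                           names(tab))
        indIds <- if ("IID" %in% names(tab)) as.character(tab$IID) else NULL
        vals <- as.matrix(tab[, setdiff(names(tab), fixed), drop = FALSE])
        snpIds <- colnames(vals)
        storage.mode(vals) <- "double"
        parsed <- list(values = vals, individualIds = indIds, snpIds = snpIds)
    } else {
        parsed <- .parseGenotypeTable(path)
        if (transpose) {
            parsed <- list(values = t(parsed$values),
                           individualIds = parsed$snpIds,
                           snpIds = parsed$individualIds)
        }
    }
    vals <- parsed$values
    if (anyNA(vals)) {
        if (missingPolicy == "error") {
            idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
            stop("missing genotype at individual ", idx[1], ", SNP ", idx[2],
                 "; the model requires complete data ",
                 "(use missingPolicy = 'imputeMean' to impute)")
        }
        for (j in which(colSums(is.na(vals)) > 0)) {
            m <- mean(vals[, j], na.rm = TRUE)
            if (is.nan(m)) m <- 0
            vals[is.na(vals[, j]), j] <- m
        }
    }
    intCoded <- all(vals %in% c(0, 1, 2))
    if (!intCoded && missingPolicy == "error" && format == "tsv" &&
        !all(vals >= 0 & vals <= 2))
        stop("genotype entries outside [0, 2]; expected allele counts")
    GenotypeMatrix(vals, parsed$individualIds, parsed$snpIds,
                   checkCounts = FALSE)
}

#' Write a genotype matrix as tab-delimited text
#'
#' Writes the individuals x SNPs matrix with a header row of SNP ids and
#' a leading `id` column, the format [readGenotypes()] round-trips.
#'
#' @param x a [GenotypeMatrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(x, path) {
    stopifnot(is(x, "GenotypeMatrix"))
    df <- data.frame(id = x@individualIds, x@values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("id", x@snpIds)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
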