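.writeTsv <- function(x, path, rowIds = NULL, idName = "id") {
    df <- as.data.frame(x, check.names = FALSE)
    if (!is.null(rowIds)) {
        df <- cbind(stats::setNames(data.frame(rowIds,
                                               stringsAsFactors = FALSE),
                                    idName), df)
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a run manifest
#'
#' Records, in a small key-value text file, everything needed to
#' reproduce a run: command, configuration, seed(s), md5 digests of the
#' input files, package version, and the final log likelihood(s).
#'
#' @param dir output directory (one manifest per directory).
#' @param command character scalar describing the invocation.
#' @param config named list of configuration values.
#' @param inputFiles character vector of input paths to digest.
#' @param finalLogLik optional named numeric of final objectives.
#' @return the manifest path, invisibly.
#' @export
writeRunManifest <- function(dir, command, config = list(),
                             inputFiles = character(0),
                             finalLogLik = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(dir, "manifest.txt")
    lines <- c(
        paste0("command\t", command),
        paste0("package_version\t",
               as.character(utils::packageVersion("PopSFA"))),
        paste0("timestamp\t", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
        vapply(names(config), function(k)
            paste0("config.", k, "\t",
                   paste(format(config[[k]]), collapse = ",")), ""),
        if (length(inputFiles))
            paste0("input.", basename(inputFiles), ".md5\t",
                   unname(tools::md5sum(inputFiles))),
        if (!is.null(finalLogLik))
            paste0("loglik.", names(finalLogLik), "\t",
                   format(finalLogLik, digits = 12))
    )
    writeLines(lines, path)
    invisible(path)
}

#' Write an SFA fit to tab-delimited files
#'
#' Writes `loadings.tsv` (posterior-mean loadings with individual ids;
#' correlations over individuals are the relevant comparison for these),
#' `factors.tsv` (factors with SNP ids; compare over SNPs),
#' `mu.tsv`, `psi.tsv`, `sigma.tsv` and `loglik_trace.tsv`, plus a run
#' manifest.
#'
#' @param fit an [SfaFit].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeSfaFit <- function(fit, dir) {
    stopifnot(is(fit, "SfaFit"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    K <- ncol(fit@Omega)
    fcol <- paste0("factor", seq_len(K))
    .writeTsv(stats::setNames(as.data.frame(fit@Omega), fcol),
              file.path(dir, "loadings.tsv"), fit@individualIds)
    Fdf <- as.data.frame(t(fit@F))
    colnames(Fdf) <- fcol
    .writeTsv(Fdf, file.path(dir, "factors.tsv"), fit@snpIds, "snp")
    .writeTsv(data.frame(mu = fit@mu), file.path(dir, "mu.tsv"),
              fit@snpIds, "snp")
    .writeTsv(data.frame(psi = fit@psi), file.path(dir, "psi.tsv"),
              if (fit@config$varianceMode == "row") fit@individualIds
              else fit@snpIds,
              if (fit@config$varianceMode == "row") "id" else "snp")
    .writeTsv(stats::setNames(as.data.frame(fit@Sigma), fcol),
              file.path(dir, "sigma.tsv"), fit@individualIds)
    .writeTsv(data.frame(iteration = seq_along(fit@logLikTrace),
                         logLik = fit@logLikTrace),
              file.path(dir, "loglik_trace.tsv"))
    writeRunManifest(dir, "fit-sfa", fit@config,
                     finalLogLik = c(final = fit@logLikTrace[
                         length(fit@logLikTrace)]))
    invisible(dir)
}

#' Write a PCA fit to tab-delimited files
#'
#' Writes `pca_loadings.tsv`, `pca_factors.tsv` and `eigenvalues.tsv`
#' (squared singular values), plus a run manifest.
#'
#' @param fit a [PcaFit].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writePcaFit <- function(fit, dir) {
    stopifnot(is(fit, "PcaFit"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    K <- length(fit@singularValues)
    pcol <- paste0("PC", seq_len(K))
    .writeTsv(stats::setNames(as.data.frame(fit@loadings), pcol),
              file.path(dir, "pca_loadings.tsv"), fit@individualIds)
    Fdf <- as.data.frame(t(fit@factors))
    colnames(Fdf) <- pcol
    .writeTsv(Fdf, file.path(dir, "pca_factors.tsv"),
              fit@snpIds[fit@retained], "snp")
    .writeTsv(data.frame(component = seq_len(K),
                         eigenvalue = fit@singularValues^2),
              file.path(dir, "eigenvalues.tsv"))
    writeRunManifest(dir, "fit-pca", list(K = K))
    invisible(dir)
}

#' Write an admixture fit to tab-delimited files
#'
#' Writes `Q.tsv`, `P.tsv` and `admix_loglik.tsv`, plus a run manifest.
#'
#' @param fit an [AdmixFit].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeAdmixFit <- function(fit, dir) {
    stopifnot(is(fit, "AdmixFit"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    K <- ncol(fit@Q)
    pcol <- paste0("pop", seq_len(K))
    .writeTsv(stats::setNames(as.data.frame(fit@Q), pcol),
              file.path(dir, "Q.tsv"), fit@individualIds)
    Pdf <- as.data.frame(t(fit@P))
    colnames(Pdf) <- pcol
    .writeTsv(Pdf, file.path(dir, "P.tsv"), fit@snpIds, "snp")
    .writeTsv(data.frame(iteration = seq_along(fit@logLikTrace),
                         logLik = fit@logLikTrace),
              file.path(dir, "admix_loglik.tsv"))
    writeRunManifest(dir, "fit-admix", fit@config,
                     finalLogLik = c(final = fit@logLikTrace[
                         length(fit@logLikTrace)]))
    invisible(dir)
}
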