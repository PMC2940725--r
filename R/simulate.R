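## Synthetic population-genetic scenarios with ground truth.
##
## All generators share the same building blocks: ancestral allele
## frequencies drawn uniformly away from the boundaries, population- or
## deme-level frequencies derived from them (Balding-Nichols beta draws
## for discrete populations; logit-scale Gaussian fields for spatial
## scenarios), and binomial(2, .) genotype draws. SNPs are independent.
## Every generator is deterministic given its seed, and SNP columns that
## come out monomorphic in the sample are redrawn so downstream
## standardization never hits zero-variance columns.

.drawAncestral <- function(nSnps, mafRange) {
    if (length(mafRange) != 2 || mafRange[1] <= 0 || mafRange[2] > 0.5 ||
        mafRange[1] >= mafRange[2])
        stop("mafRange must be an interval within (0, 0.5]")
    p <- stats::runif(nSnps, mafRange[1], mafRange[2])
    flip <- stats::runif(nSnps) < 0.5
    p[flip] <- 1 - p[flip]
    p
}

.baldingNichols <- function(ancestral, fst) {
    if (fst <= 0 || fst >= 1)
        stop("fst must lie in (0, 1)")
    c0 <- (1 - fst) / fst
    x <- stats::rbeta(length(ancestral), ancestral * c0,
                      (1 - ancestral) * c0)
    pmin(pmax(x, 1e-9), 1 - 1e-9)
}

.drawGenotypes <- function(probRows) {
    # probRows: n x p per-individual success probabilities
    matrix(stats::rbinom(length(probRows), 2, probRows),
           nrow(probRows), ncol(probRows))
}

## Redraw columns of a SimTruth-in-progress that are monomorphic in the
## sample. `redraw(j)` must regenerate ancestral/deme frequencies and
## genotypes for SNP indices j and return the updated pieces.
.resampleMonomorphic <- function(G, redraw, maxTries = 50) {
    for (t in seq_len(maxTries)) {
        mono <- which(apply(G, 2, function(col) length(unique(col)) == 1))
        if (!length(mono)) break
        G <- redraw(mono, G)
    }
    G
}

.finishSim <- function(values, scenario, seed, demeCoords = NULL,
                       trueQ = NULL, trueFreqs = NULL,
                       habitatLabels = NULL, indIds = NULL) {
    gm <- GenotypeMatrix(values, individualIds = indIds)
    new("SimTruth", genotypes = gm,
        demeCoords = if (is.null(demeCoords)) matrix(0, 0, 0) else
            as.matrix(demeCoords),
        trueQ = if (is.null(trueQ)) matrix(0, 0, 0) else as.matrix(trueQ),
        trueFreqs = if (is.null(trueFreqs)) matrix(0, 0, 0) else
            as.matrix(trueFreqs),
        habitatLabels = if (is.null(habitatLabels)) integer(0) else
            as.integer(habitatLabels),
        scenario = scenario, seed = as.integer(seed))
}

#' Simulate discrete populations (Balding-Nichols model)
#'
#' Draws ancestral allele frequencies uniformly (minor-allele frequency
#' within `mafRange`, mirrored to both alleles), population frequencies
#' from the Balding-Nichols beta distribution with divergence `fst`, and
#' genotypes Binomial(2, p_kj). Ground truth holds the one-hot
#' population memberships and the population allele frequencies.
#'
#' @param nPerPop individuals per population.
#' @param nSnps number of independent SNPs.
#' @param nPops number of populations (>= 2).
#' @param fst divergence of population frequencies from the ancestral
#'   frequency, in (0, 1).
#' @param mafRange ancestral minor-allele-frequency interval within
#'   (0, 0.5]; frequencies are bounded away from 0/1 so monomorphic
#'   SNPs stay rare.
#' @param seed integer seed; generation is deterministic given it.
#' @return a [SimTruth] with `trueQ` one-hot and `trueFreqs` the
#'   nPops x nSnps population frequencies.
#' @export
simDiscrete <- function(nPerPop, nSnps, nPops, fst,
                        mafRange = c(0.1, 0.5), seed = 1) {
    if (nPops < 2) stop("nPops must be at least 2")
    set.seed(seed)
    pop <- rep(seq_len(nPops), each = nPerPop)
    n <- length(pop)
    gen <- function(j) {
        anc <- .drawAncestral(length(j), mafRange)
        Pk <- vapply(seq_len(nPops),
                     function(k) .baldingNichols(anc, fst),
                     numeric(length(j)))
        Pk <- matrix(Pk, length(j), nPops)  # snps x pops
        list(P = t(Pk), G = .drawGenotypes(t(Pk)[pop, , drop = FALSE]))
    }
    first <- gen(seq_len(nSnps))
    P <- first$P; G <- first$G
    G <- .resampleMonomorphic(G, function(j, Gcur) {
        nw <- gen(j)
        P[, j] <<- nw$P
        Gcur[, j] <- nw$G
        Gcur
    })
    trueQ <- diag(nPops)[pop, , drop = FALSE]
    .finishSim(G, "discrete", seed, trueQ = trueQ, trueFreqs = P,
               indIds = paste0("pop", pop, "_", seq_len(n)))
}

#' Convenience admixture design: a linear gradient
#'
#' Rows run from fully population 1 to fully population K along equally
#' spaced mixing proportions (for K = 2, `(1, 0)` to `(0, 1)`); for
#' K > 2 the gradient interpolates between consecutive populations.
#'
#' @param n number of individuals.
#' @param K number of ancestral populations.
#' @return numeric n x K matrix with rows on the simplex.
#' @export
admixtureGradient <- function(n, K = 2) {
    t <- seq(0, 1, length.out = n)
    pos <- t * (K - 1)
    Q <- matrix(0, n, K)
    lo <- pmin(floor(pos), K - 2)
    frac <- pos - lo
    for (i in seq_len(n)) {
        Q[i, lo[i] + 1] <- 1 - frac[i]
        Q[i, lo[i] + 2] <- frac[i]
    }
    Q
}

#' Simulate admixed individuals
#'
#' Population frequencies arise as in [simDiscrete()]; each individual's
#' genotype at a SNP is Binomial(2, sum_k q_ik p_kj) with its given
#' admixture proportions.
#'
#' @param Q numeric n x K matrix of admixture proportions, rows on the
#'   simplex (e.g. [admixtureGradient()]).
#' @inheritParams simDiscrete
#' @return a [SimTruth] with `trueQ = Q` and population `trueFreqs`.
#' @export
simAdmixed <- function(Q, nSnps, fst, mafRange = c(0.1, 0.5), seed = 1) {
    Q <- as.matrix(Q)
    if (any(Q < -1e-12) || any(abs(rowSums(Q) - 1) > 1e-8))
        stop("Q rows must lie on the simplex")
    set.seed(seed)
    K <- ncol(Q); n <- nrow(Q)
    gen <- function(j) {
        anc <- .drawAncestral(length(j), mafRange)
        Pk <- vapply(seq_len(K), function(k) .baldingNichols(anc, fst),
                     numeric(length(j)))
        Pk <- matrix(Pk, length(j), K)
        probs <- Q %*% t(Pk)     # n x |j|
        list(P = t(Pk), G = .drawGenotypes(probs))
    }
    first <- gen(seq_len(nSnps))
    P <- first$P; G <- first$G
    G <- .resampleMonomorphic(G, function(j, Gcur) {
        nw <- gen(j)
        P[, j] <<- nw$P
        Gcur[, j] <- nw$G
        Gcur
    })
    .finishSim(G, "admixed", seed, trueQ = Q, trueFreqs = P)
}

## Deme frequencies for spatial scenarios: inverse-logit of the
## ancestral logit plus a Gaussian field z over demes. For a 1-D line, z
## is a random walk with increment sd tau (deme 1 at 0). For a 2-D
## grid, z has covariance sigma_f^2 exp(-d1 / ell) in grid Manhattan
## distance d1, with ell = gridSide and sigma_f chosen so the increment
## sd between adjacent demes equals tau.
.lineField <- function(nDemes, nSnps, tau) {
    inc <- matrix(stats::rnorm((nDemes - 1) * nSnps, sd = tau),
                  nDemes - 1, nSnps)
    rbind(0, apply(inc, 2, cumsum))
}

## Correlation length ell = 10 * gridSide puts the field near its
## random-walk limit, where the variance of the difference between two
## demes grows linearly with their Manhattan distance — the 2-D analog
## of the 1-D cumulative-walk construction (which has exactly that
## property), keeping the two spatial generators consistent.
.gridFieldChol <- function(gridSide, tau) {
    coords <- expand.grid(x = seq_len(gridSide), y = seq_len(gridSide))
    d1 <- as.matrix(stats::dist(coords, method = "manhattan"))
    ell <- 10 * gridSide
    sigf2 <- tau^2 / (2 * (1 - exp(-1 / ell)))
    C <- sigf2 * exp(-d1 / ell)
    list(L = chol(C + diag(1e-10, nrow(C))), coords = as.matrix(coords))
}

.gridField <- function(cholInfo, nSnps) {
    m <- nrow(cholInfo$L)
    crossprod(cholInfo$L, matrix(stats::rnorm(m * nSnps), m, nSnps))
}

.spatialSim <- function(zGen, demeOf, coordsOf, nSnps, mafRange, tau,
                        scenario, seed, habitatLabels = NULL,
                        shiftGen = NULL) {
    n <- length(demeOf)
    gen <- function(j) {
        anc <- .drawAncestral(length(j), mafRange)
        z <- zGen(length(j))
        lg <- sweep(z, 2, stats::qlogis(anc), "+")
        if (!is.null(shiftGen)) lg <- lg + shiftGen(length(j))
        freqs <- stats::plogis(lg)          # demes x |j|
        list(freqs = freqs,
             G = .drawGenotypes(freqs[demeOf, , drop = FALSE]))
    }
    first <- gen(seq_len(nSnps))
    freqs <- first$freqs; G <- first$G
    G <- .resampleMonomorphic(G, function(j, Gcur) {
        nw <- gen(j)
        freqs[, j] <<- nw$freqs
        Gcur[, j] <- nw$G
        Gcur
    })
    .finishSim(G, scenario, seed, demeCoords = coordsOf,
               trueFreqs = freqs, habitatLabels = habitatLabels)
}

#' Simulate a one-dimensional stepping-stone habitat
#'
#' Demes lie along a line; per SNP, deme allele frequencies follow a
#' logit-scale random walk with increment standard deviation `tau`
#' between adjacent demes, so frequency similarity decays with distance
#' (isolation by distance). One diploid individual is sampled per deme.
#'
#' @param nDemes number of demes along the line.
#' @param nSnps number of independent SNPs.
#' @param tau logit-scale drift between adjacent demes (> 0).
#' @inheritParams simDiscrete
#' @return a [SimTruth] with 1-D `demeCoords` and per-deme `trueFreqs`.
#' @export
simLine1D <- function(nDemes = 50, nSnps = 2000, tau = 0.15,
                      mafRange = c(0.1, 0.5), seed = 1) {
    if (tau <= 0) stop("tau must be positive")
    set.seed(seed)
    demeOf <- seq_len(nDemes)
    .spatialSim(function(m) .lineField(nDemes, m, tau),
                demeOf, matrix(demeOf, ncol = 1), nSnps, mafRange, tau,
                "line_1d", seed)
}

#' Simulate clustered sampling from a one-dimensional habitat
#'
#' Same habitat as [simLine1D()], but individuals are sampled only from
#' `nSampled` evenly spaced demes, `nPerDeme` each — a design in which
#' continuous spatial structure masquerades as discrete clusters.
#'
#' @inheritParams simLine1D
#' @param nSampled number of evenly spaced sampled demes.
#' @param nPerDeme individuals per sampled deme.
#' @return a [SimTruth].
#' @export
simClustered1D <- function(nDemes = 50, nSampled = 5, nPerDeme = 20,
                           nSnps = 2000, tau = 0.15,
                           mafRange = c(0.1, 0.5), seed = 1) {
    if (tau <= 0) stop("tau must be positive")
    set.seed(seed)
    sampled <- round(seq(1, nDemes, length.out = nSampled))
    demeOf <- rep(sampled, each = nPerDeme)
    .spatialSim(function(m) .lineField(nDemes, m, tau),
                demeOf, matrix(demeOf, ncol = 1), nSnps, mafRange, tau,
                "clustered_1d", seed)
}

#' Simulate a two-dimensional stepping-stone habitat
#'
#' Demes form a square grid; per SNP, deme frequencies are the
#' inverse-logit of the ancestral logit plus a Gaussian field with
#' exponential covariance in grid Manhattan distance, scaled so the
#' increment sd between adjacent demes is `tau` (correlation length:
#' one grid side). One individual per deme.
#'
#' @param gridSide demes per side of the square grid.
#' @inheritParams simLine1D
#' @return a [SimTruth] with 2-D `demeCoords`.
#' @export
simGrid2D <- function(gridSide = 10, nSnps = 2000, tau = 0.15,
                      mafRange = c(0.1, 0.5), seed = 1) {
    if (tau <= 0) stop("tau must be positive")
    set.seed(seed)
    ch <- .gridFieldChol(gridSide, tau)
    demeOf <- seq_len(gridSide^2)
    .spatialSim(function(m) .gridField(ch, m),
                demeOf, ch$coords, nSnps, mafRange, tau, "grid_2d", seed)
}

#' Simulate two independent gridded habitats
#'
#' Two square-grid habitats share ancestral frequencies but receive
#' independent spatial fields plus independent habitat-level logit
#' shifts of standard deviation `delta`, creating discrete
#' between-habitat divergence on top of within-habitat isolation by
#' distance. One individual per deme; `habitatLabels` records the
#' habitat of each individual.
#'
#' @inheritParams simGrid2D
#' @param delta standard deviation of the per-SNP habitat-level logit
#'   shift (> 0).
#' @return a [SimTruth] with stacked coordinates and habitat labels.
#' @export
simTwoGrids <- function(gridSide = 10, nSnps = 2000, tau = 0.15,
                        delta = 0.5, mafRange = c(0.1, 0.5), seed = 1) {
    if (tau <= 0) stop("tau must be positive")
    if (delta <= 0) stop("delta must be positive")
    set.seed(seed)
    ch <- .gridFieldChol(gridSide, tau)
    m <- gridSide^2
    demeOf <- seq_len(2 * m)
    coords <- rbind(ch$coords, ch$coords)
    labels <- rep(1:2, each = m)
    zGen <- function(nj) {
        rbind(.gridField(ch, nj), .gridField(ch, nj))
    }
    shiftGen <- function(nj) {
        u <- rbind(matrix(stats::rnorm(nj, sd = delta), 1, nj),
                   matrix(stats::rnorm(nj, sd = delta), 1, nj))
        u[labels, , drop = FALSE]
    }
    .spatialSim(zGen, demeOf, coords, nSnps, mafRange, tau,
                "two_grids", seed, habitatLabels = labels,
                shiftGen = shiftGen)
}

#' Dispatch a scenario by name
#'
#' Thin front-end over the scenario generators, mainly for the command
#' line: passes `...` through to the named generator.
#'
#' @param scenario one of `"discrete"`, `"admixed"`, `"line_1d"`,
#'   `"grid_2d"`, `"two_grids"`, `"clustered_1d"`.
#' @param ... arguments of the corresponding generator.
#' @return a [SimTruth].
#' @export
simulateScenario <- function(scenario = c("discrete", "admixed",
                                          "line_1d", "grid_2d",
                                          "two_grids", "clustered_1d"),
                             ...) {
    scenario <- match.arg(scenario)
    switch(scenario,
           discrete = simDiscrete(...),
           admixed = simAdmixed(...),
           line_1d = simLine1D(...),
           grid_2d = simGrid2D(...),
           two_grids = simTwoGrids(...),
           clustered_1d = simClustered1D(...))
}

#' @rdname genotypes
#' @export
setMethod("genotypes", "SimTruth", function(x) genotypes(x@genotypes))

setMethod("show", "SimTruth", function(object) {
    d <- dim(object@genotypes@values)
    cat("SimTruth: scenario '", object@scenario, "', ", d[1],
        " individuals x ", d[2], " SNPs (seed ", object@seed, ")\n",
        sep = "")
})

#' Write a simulated scenario to tab-delimited files
#'
#' Writes `genotypes.tsv` plus whichever ground-truth files apply:
#' `truth_coords.tsv`, `truth_Q.tsv`, `truth_freqs.tsv`,
#' `truth_labels.tsv`.
#'
#' @param sim a [SimTruth].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSimTruth <- function(sim, dir) {
    stopifnot(is(sim, "SimTruth"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeGenotypes(sim@genotypes, file.path(dir, "genotypes.tsv"))
    wt <- function(x, name, rowIds = NULL) {
        df <- as.data.frame(x)
        if (!is.null(rowIds)) df <- cbind(id = rowIds, df)
        utils::write.table(df, file.path(dir, name), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    ids <- sim@genotypes@individualIds
    if (length(sim@demeCoords))
        wt(sim@demeCoords, "truth_coords.tsv", ids)
    if (length(sim@trueQ))
        wt(sim@trueQ, "truth_Q.tsv", ids)
    if (length(sim@trueFreqs))
        wt(sim@trueFreqs, "truth_freqs.tsv")
    if (length(sim@habitatLabels))
        wt(data.frame(habitat = sim@habitatLabels),
           "truth_labels.tsv", ids)
    invisible(dir)
}
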