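test_that("generators are deterministic and produce valid genotypes", {
    s1 <- simDiscrete(nPerPop = 5, nSnps = 100, nPops = 3, fst = 0.1,
                      seed = 42)
    s2 <- simDiscrete(nPerPop = 5, nSnps = 100, nPops = 3, fst = 0.1,
                      seed = 42)
    expect_identical(genotypes(s1), genotypes(s2))
    expect_true(all(genotypes(s1) %in% 0:2))
    expect_true(all(s1@trueFreqs > 0 & s1@trueFreqs < 1))
    expect_true(all(rowSums(s1@trueQ) == 1))
    # no monomorphic columns after resampling
    expect_true(all(apply(genotypes(s1), 2, var) > 0))
})

test_that("Balding-Nichols frequencies have the ancestral mean and
           collapse in the fst -> 0 limit", {
    set.seed(1)
    anc <- runif(4000, 0.1, 0.9)
    drawn <- PopSFA:::.baldingNichols(anc, 0.2)
    # E[p_kj] = p_j: regression through the ancestral values
    expect_lt(abs(mean(drawn - anc)), 0.01)
    # theoretical correlation sqrt(V/(V + F E[p(1-p)])) ~ 0.76 here
    expect_gt(cor(drawn, anc), 0.7)
    tight <- PopSFA:::.baldingNichols(anc, 1e-6)
    expect_lt(max(abs(tight - anc)), 0.01)
    expect_error(PopSFA:::.baldingNichols(anc, 1.5), "fst")
})

test_that("realized divergence matches the nominal Fst", {
    sim <- simDiscrete(nPerPop = 30, nSnps = 5000, nPops = 2, fst = 0.1,
                       seed = 3)
    est <- wcFst(genotypes(sim), rep(1:2, each = 30))
    expect_lt(abs(est - 0.1), 0.02)  # within 20% of nominal
})

test_that("admixed genotypes mix population frequencies", {
    Q <- admixtureGradient(40, 2)
    expect_equal(Q[1, ], c(1, 0))
    expect_equal(Q[40, ], c(0, 1))
    expect_true(all(abs(rowSums(Q) - 1) < 1e-12))
    sim <- simAdmixed(Q, nSnps = 150, fst = 0.2, seed = 4)
    expect_identical(sim@trueQ, Q)
    expect_identical(dim(genotypes(sim)), c(40L, 150L))
})

test_that("1-D frequency correlation decays with deme distance", {
    sim <- simLine1D(nDemes = 50, nSnps = 5000, tau = 0.15, seed = 5)
    fr <- sim@trueFreqs
    dists <- c(1, 5, 15, 30, 45)
    cors <- vapply(dists, function(d)
        cor(qlogis(fr[1, ]), qlogis(fr[1 + d, ])), 0)
    expect_true(all(diff(cors) < 0))
    # end-to-end divergence exceeds adjacent-deme divergence
    expect_gt(fstFromFreqs(fr[1, ], fr[50, ]),
              fstFromFreqs(fr[1, ], fr[2, ]))
})

test_that("clustered sampling hits five evenly spaced demes", {
    sim <- simClustered1D(nDemes = 50, nSampled = 5, nPerDeme = 20,
                          nSnps = 100, tau = 0.15, seed = 6)
    expect_identical(dim(genotypes(sim)), c(100L, 100L))
    expect_identical(sort(unique(sim@demeCoords[, 1])),
                     c(1, 13, 26, 38, 50))
    expect_identical(as.integer(table(sim@demeCoords[, 1])),
                     rep(20L, 5))
})

test_that("2-D field divergence grows with grid distance", {
    sim <- simGrid2D(gridSide = 10, nSnps = 4000, tau = 0.15, seed = 7)
    co <- sim@demeCoords
    fr <- sim@trueFreqs
    d1 <- as.matrix(dist(co, method = "manhattan"))
    pick <- function(d) {
        idx <- which(d1 == d, arr.ind = TRUE)[1, ]
        fstFromFreqs(fr[idx[1], ], fr[idx[2], ])
    }
    expect_lt(pick(1), pick(9))
    expect_lt(pick(2), pick(18))
})

test_that("two habitats diverge more between than within", {
    sim <- simTwoGrids(gridSide = 6, nSnps = 3000, tau = 0.15,
                       delta = 0.5, seed = 8)
    expect_identical(length(sim@habitatLabels), 72L)
    fr <- sim@trueFreqs
    between <- fstFromFreqs(fr[1, ], fr[37, ])  # same grid position
    within <- fstFromFreqs(fr[1, ], fr[2, ])    # adjacent demes
    expect_gt(between, within)
})

test_that("sample allele frequencies converge to the truth", {
    sim <- simDiscrete(nPerPop = 500, nSnps = 300, nPops = 2, fst = 0.1,
                       seed = 9)
    emp <- colMeans(genotypes(sim)[1:500, ]) / 2
    expect_lt(max(abs(emp - sim@trueFreqs[1, ])), 0.08)
    expect_lt(mean(abs(emp - sim@trueFreqs[1, ])), 0.02)
})

test_that("scenario truth files round-trip through the writers", {
    sim <- simClustered1D(nDemes = 20, nSampled = 3, nPerDeme = 4,
                          nSnps = 30, tau = 0.2, seed = 10)
    dir <- withr::local_tempdir()
    writeSimTruth(sim, dir)
    gm <- readGenotypes(file.path(dir, "genotypes.tsv"))
    expect_identical(genotypes(gm), genotypes(sim))
    coords <- read.table(file.path(dir, "truth_coords.tsv"),
                         header = TRUE, sep = "\t")
    expect_equal(as.numeric(coords[[2]]), as.numeric(sim@demeCoords[, 1]))
})

test_that("the scenario dispatcher routes by name", {
    s <- simulateScenario("discrete", nPerPop = 4, nSnps = 50,
                          nPops = 2, fst = 0.2, seed = 11)
    expect_identical(s@scenario, "discrete")
    expect_identical(s@genotypes@values,
                     simDiscrete(4, 50, 2, 0.2, seed = 11)@genotypes@values)
})
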