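test_that("covariate marginals converge to their targets", {
    p <- simParams(nSubjects = 10000)
    cv <- generateCovariates(p, seed = 101)
    # truncated normal [18, 65] around (34.04, 12.84): closed-form mean
    a <- (18 - 34.04) / 12.84; b <- (65 - 34.04) / 12.84
    truncMean <- 34.04 + 12.84 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
    expect_lt(abs(mean(cv$age) - truncMean), 0.5)
    expect_true(all(cv$age >= 18 & cv$age <= 65))
    expect_lt(abs(mean(cv$tiv) - 1526.51), 5)
    expect_lt(abs(sd(cv$tiv) - 144.61), 5)
    expect_lt(abs(mean(cv$sex) - 582 / 904), 0.02)
    expect_true(all(cv$motion > 0))
    expect_gt(mean(cv$motion) , median(cv$motion))  # right-skewed
    # determinism
    expect_identical(cv, generateCovariates(p, seed = 101))
})

test_that("phenotypes have the right marginals and latent coupling", {
    p <- simParams(nSubjects = 10000)
    ph <- generatePhenotypes(p, seed = 202)
    expect_lt(abs(mean(ph$ctq) - 32.60), 0.5)
    expect_lt(abs(sd(ph$ctq) - 8.73), 0.5)
    expect_true(all(ph$ctq >= 25 & ph$ctq <= 125))
    expect_lt(abs(mean(ph$fsozu) - 4.51), 0.05)
    expect_true(all(ph$fsozu >= 1 & ph$fsozu <= 5))
    # skew directions
    expect_gt(mean(ph$ctq), median(ph$ctq))
    expect_lt(mean(ph$fsozu), median(ph$fsozu))
    # realized correlation in the calibrated band
    r <- cor(ph$ctq, ph$fsozu)
    expect_gt(r, -0.42); expect_lt(r, -0.32)
    # independence case
    p0 <- simParams(nSubjects = 10000, phenotypeCorr = 0)
    ph0 <- generatePhenotypes(p0, seed = 203)
    expect_lt(abs(cor(ph0[[1]], ph0[[2]])), 0.05)
    expect_identical(ph, generatePhenotypes(p, seed = 202))
})

test_that("ground truth has disjoint signed sets and inverse-sign shared edges", {
    p <- simParams(nSubjects = 50, nNodes = 20, nPlantedPos = 8,
                   nPlantedNeg = 6, nSharedPosANegB = 3, nSharedNegAPosB = 2)
    gt <- makeGroundTruth(p, seed = 7)
    expect_length(intersect(gt$plantedPosA, gt$plantedNegA), 0)
    expect_length(intersect(gt$plantedPosB, gt$plantedNegB), 0)
    expect_length(gt$plantedPosA, 8)
    expect_length(gt$plantedNegA, 6)
    expect_true(all(gt$sharedPosANegB %in%
                    intersect(gt$plantedPosA, gt$plantedNegB)))
    expect_true(all(gt$sharedNegAPosB %in%
                    intersect(gt$plantedNegA, gt$plantedPosB)))
    planted <- c(gt$plantedPosA, gt$plantedNegA,
                 gt$plantedPosB, gt$plantedNegB)
    expect_true(all(planted %in% gt$support))
    expect_error(makeGroundTruth(
        simParams(nSubjects = 50, nNodes = 6, density = 0.5,
                  nPlantedPos = 8, nPlantedNeg = 6,
                  nSharedPosANegB = 0, nSharedNegAPosB = 0), seed = 1),
        "support")
})

test_that("generated connectomes satisfy matrix invariants and carry the planted signal", {
    p <- simParams(nSubjects = 400, nNodes = 40, effectSize = 0.3)
    ce <- simulateCohort(p, seed = 5)
    w <- streamlines(ce)
    expect_true(all(w >= 0))
    expect_identical(storage.mode(w), "integer")
    expect_identical(dim(w), c(edgeUniverseSize(40), 400L))
    # support-set edges carry counts; off-support edges are zero
    gt <- groundTruth(ce)
    off <- setdiff(seq_len(nrow(w)), gt$support)
    expect_true(all(w[off, ] == 0))

    # realized partial Spearman magnitude on planted edges targets 0.3
    y <- subjectData(ce)$ctq
    C <- covariateColumns(ce)
    planted <- c(gt$plantedPosA, gt$plantedNegA)
    rho <- vapply(planted,
                  function(e) oraclePartialSpearman(w[e, ], y, C)["rho"],
                  numeric(1))
    expect_gt(median(abs(rho)), 0.2)
    expect_lt(median(abs(rho)), 0.4)
    # signs follow the ledger
    expect_true(all(rho[seq_along(gt$plantedPosA)] > 0))
    expect_true(all(rho[-seq_along(gt$plantedPosA)] < 0))

    # without planted effects no edge beats the chance rate at p < 0.001
    p0 <- simParams(nSubjects = 400, nNodes = 40, effectSize = 0,
                    nPlantedPos = 0, nPlantedNeg = 0,
                    nSharedPosANegB = 0, nSharedNegAPosB = 0)
    ce0 <- simulateCohort(p0, seed = 6)
    w0 <- streamlines(ce0)
    y0 <- subjectData(ce0)$ctq
    C0 <- covariateColumns(ce0)
    gt0 <- groundTruth(ce0)
    pv <- vapply(gt0$support,
                 function(e) oraclePartialSpearman(w0[e, ], y0, C0)["p"],
                 numeric(1))
    expect_lt(mean(pv < 0.001), 0.01)
})

test_that("simulation is substream-reproducible and write/load round-trips", {
    ce1 <- smallCohort(nSubjects = 12, nNodes = 8, seed = 9)
    ce2 <- smallCohort(nSubjects = 12, nNodes = 8, seed = 9)
    expect_identical(streamlines(ce1), streamlines(ce2))
    expect_identical(subjectData(ce1), subjectData(ce2))
    ce3 <- smallCohort(nSubjects = 12, nNodes = 8, seed = 10)
    expect_false(identical(streamlines(ce1), streamlines(ce3)))

    d1 <- tempfile(); d2 <- tempfile()
    writeDataset(ce1, d1); writeDataset(ce2, d2)
    m1 <- readLines(file.path(d1, "manifest.tsv"))
    m2 <- readLines(file.path(d2, "manifest.tsv"))
    expect_identical(m1, m2)
    expect_error(writeDataset(ce1, d1), "not empty")

    gtFile <- jsonlite::read_json(file.path(d1, "ground_truth.json"),
                                  simplifyVector = TRUE)
    expect_equal(sort(gtFile$plantedPosA),
                 sort(groundTruth(ce1)$plantedPosA))
})
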