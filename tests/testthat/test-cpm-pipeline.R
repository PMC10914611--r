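test_that("consistency screen keeps reliably present edges and drops absent ones", {
    X <- rbind(rep(0, 5),          # all zero -> out
               c(5, 6, 7, 8, 9),   # strong positive -> in
               rep(4, 5),          # constant positive -> in by convention
               c(-1, 1, 0, 1, -1)) # mean ~0 -> out
    mask <- consistencyMask(X, alpha = 0.05)
    expect_identical(mask, c(FALSE, TRUE, TRUE, FALSE))
    # the retained edge matches the closed-form one-sample t
    v <- X[2, ]
    tt <- mean(v) / (sd(v) / sqrt(5))
    expect_equal(tt, 9.899, tolerance = 1e-4)
    expect_lt(pt(tt, df = 4, lower.tail = FALSE), 0.05)
    expect_error(consistencyMask(X[, 1:2]), "at least 3")
})

test_that("partial Spearman reduces to Spearman, handles perfect rank agreement, and matches the oracle", {
    set.seed(30)
    x <- rnorm(25); y <- rnorm(25)
    expect_equal(unname(partialSpearman(x, y)["rho"]),
                 cor(x, y, method = "spearman"))
    expect_equal(unname(partialSpearman(x, x)["rho"]), 1)
    expect_equal(unname(partialSpearman(x, x)["p"]), 0)
    for (s in 1:50) {
        set.seed(s)
        n <- 30
        x <- rnorm(n); y <- rnorm(n); C <- matrix(rnorm(n * 4), n, 4)
        got <- partialSpearman(x, y, C)
        want <- oraclePartialSpearman(x, y, C)
        expect_equal(unname(got["rho"]), unname(want["rho"]),
                     tolerance = 1e-10)
        expect_equal(unname(got["p"]), unname(want["p"]),
                     tolerance = 1e-10)
    }
    # integer (tied) data exercise the counting-rank path
    set.seed(99)
    xi <- rpois(40, 3); yi <- rnorm(40); Ci <- matrix(rnorm(80), 40, 2)
    expect_equal(unname(partialSpearman(xi, yi, Ci)["rho"]),
                 unname(oraclePartialSpearman(xi, yi, Ci)["rho"]),
                 tolerance = 1e-10)
})

test_that("edge selection splits by sign, respects the mask, and is calibrated under the null", {
    ce <- smallCohort(nSubjects = 80, nNodes = 12, seed = 2)
    X <- filterMinStreamlines(streamlines(ce), 3)
    C <- covariateColumns(ce)
    mask <- consistencyMask(X, 0.05)
    sel <- selectEdges(X, subjectData(ce)$ctq, C, mask, 0.05)
    expect_length(intersect(sel$pos, sel$neg), 0)
    expect_true(all(c(sel$pos, sel$neg) %in% which(mask)))
    expect_true(all(sel$rho[sel$pos] > 0))
    expect_true(all(sel$rho[sel$neg] < 0))
    expect_true(all(sel$p[c(sel$pos, sel$neg)] < 0.05))
    # all edges masked out -> empty selection
    none <- selectEdges(X, subjectData(ce)$ctq, C,
                        rep(FALSE, nrow(X)), 0.05)
    expect_length(none$pos, 0); expect_length(none$neg, 0)

    # null phenotype: selection rate over masked edges approximates alpha
    p0 <- simParams(nSubjects = 400, nNodes = 40, effectSize = 0,
                    nPlantedPos = 0, nPlantedNeg = 0,
                    nSharedPosANegB = 0, nSharedNegAPosB = 0)
    rates <- vapply(1:10, function(s) {
        ce0 <- simulateCohort(p0, seed = 100 + s)
        X0 <- filterMinStreamlines(streamlines(ce0), 3)
        m0 <- consistencyMask(X0, 0.05)
        s0 <- selectEdges(X0, subjectData(ce0)$ctq,
                          covariateColumns(ce0), m0, 0.05)
        (length(s0$pos) + length(s0$neg)) / sum(m0)
    }, numeric(1))
    expect_lt(abs(mean(rates) - 0.05), 0.01)
})

test_that("network strength sums filtered weights over the edge set", {
    set.seed(4)
    X <- matrix(rpois(30 * 8, 5), 30, 8)
    expect_identical(networkStrength(X, integer()), rep(0, 8))
    expect_identical(networkStrength(X, 7L), X[7, ] + 0)
    st <- sample.int(30, 12)
    expect_equal(networkStrength(X, st), oracleNos(X, st))
    expect_error(networkStrength(X, 31L), "universe")
})

test_that("the prediction model is exact OLS with a covariate-only fallback", {
    set.seed(8)
    nos <- rnorm(40, 100, 10)
    y <- 2 + 0.5 * nos
    m <- fitNosModel(nos, NULL, y)
    expect_equal(unname(m$coef), c(2, 0.5), tolerance = 1e-8)
    expect_true(m$usedNos)
    # oracle equivalence with covariates, over seeded designs
    for (s in 1:50) {
        set.seed(s)
        C <- matrix(rnorm(40 * 3), 40, 3,
                    dimnames = list(NULL, c("a", "b", "c")))
        nos <- rnorm(40); y <- rnorm(40)
        m <- fitNosModel(nos, C, y)
        expect_equal(unname(m$coef),
                     unname(drop(oracleOls(cbind(1, nos, C), y))),
                     tolerance = 1e-8)
        pred <- predictNos(m, nos, C)
        expect_equal(pred, drop(cbind(1, nos, C) %*%
                                unname(m$coef)), tolerance = 1e-10)
    }
    # constant NOS -> flagged fallback to covariates only
    C <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("a", "b")))
    y <- rnorm(40)
    m0 <- fitNosModel(rep(5, 40), C, y)
    expect_false(m0$usedNos)
    expect_equal(unname(m0$coef), unname(drop(oracleOls(cbind(1, C), y))),
                 tolerance = 1e-8)
    # prediction design must match the trained model
    expect_error(predictNos(m0, NULL, C[, 1, drop = FALSE]), "match")
})

test_that("evaluation computes Pearson r and MAE with the degenerate-r convention", {
    ev <- evaluatePrediction(c(1, 2, 3, 4), c(1, 2, 3, 4))
    expect_equal(ev$r, 1); expect_equal(ev$mae, 0)
    x <- c(1, 2, 3, 4)
    ev2 <- evaluatePrediction(x, -x)
    expect_equal(ev2$r, -1)
    truth <- c(1, 2, 3, 4); pred <- c(1.5, 2.5, 2.5, 4.5)
    ev3 <- evaluatePrediction(truth, pred)
    expect_equal(ev3$mae, 0.5)
    rHand <- sum((truth - mean(truth)) * (pred - mean(pred))) /
        sqrt(sum((truth - mean(truth))^2) * sum((pred - mean(pred))^2))
    expect_equal(ev3$r, rHand)
    evc <- evaluatePrediction(truth, rep(2, 4))
    expect_true(is.na(evc$r)); expect_equal(evc$mae, 1)  # (1+0+1+2)/4
})

test_that("a fold trains only on training subjects and guards against leakage", {
    ce <- smallCohort(nSubjects = 60, nNodes = 12, seed = 21,
                      effectSize = 0.5)
    X <- filterMinStreamlines(streamlines(ce), 3)
    y <- subjectData(ce)$ctq
    C <- covariateColumns(ce)
    expect_error(runFold(X, y, C, 1:40, 35:60), "leakage")

    fr <- runFold(X, y, C, 1:45, 46:60)
    expect_true(is.finite(fr$maePos) && fr$maePos >= 0)
    expect_length(intersect(fr$selection$pos, fr$selection$neg), 0)

    # perturbing a test subject's phenotype leaves training output identical
    y2 <- y
    y2[50] <- y2[50] + 100
    fr2 <- runFold(X, y2, C, 1:45, 46:60)
    expect_identical(fr$selection, fr2$selection)
    # an all-zero matrix gives empty selections and missing r via fallback
    Xz <- matrix(0, nrow(X), ncol(X))
    frz <- runFold(Xz, y, C, 1:45, 46:60)
    expect_true(is.na(frz$rPos) && is.na(frz$rNeg))
    expect_true(frz$degeneratePos && frz$degenerateNeg)
    expect_true(is.finite(frz$maePos))
})
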