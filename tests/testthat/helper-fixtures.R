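suppressPackageStartupMessages({
    library(SummarizedExperiment)
})

# Random symmetric nonnegative integer connectivity matrix
randomConnectome <- function(n, maxCount = 20) {
    m <- matrix(0L, n, n)
    v <- sample.int(maxCount + 1L, n * (n - 1) / 2, replace = TRUE) - 1L
    m[lower.tri(m)] <- v
    m <- m + t(m)
    m
}

# Small in-memory cohort for pipeline tests
smallCohort <- function(nSubjects = 60, nNodes = 12, seed = 1, ...) {
    p <- simParams(nSubjects = nSubjects, nNodes = nNodes,
                   nPlantedPos = 3, nPlantedNeg = 2,
                   nSharedPosANegB = 1, nSharedNegAPosB = 1, ...)
    simulateCohort(p, seed = seed)
}

covariateColumns <- function(ce)
    as.matrix(subjectData(ce)[, c("age", "sex", "tiv", "motion")])

# ---- independent oracles ---------------------------------------------------

# Partial Spearman by explicit rank residualization with direct matrix
# least squares (normal equations), independent of the package's path.
oraclePartialSpearman <- function(x, y, C = NULL) {
    rx <- rank(x); ry <- rank(y)
    n <- length(x)
    M <- if (is.null(C)) matrix(1, n, 1)
         else cbind(1, apply(as.matrix(C), 2, rank))
    proj <- function(v) v - M %*% (solve(t(M) %*% M) %*% (t(M) %*% v))
    ex <- proj(rx); ey <- proj(ry)
    rho <- sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
    nc <- ncol(M) - 1
    df <- n - 2 - nc
    tt <- rho * sqrt(df / (1 - rho^2))
    c(rho = rho, p = 2 * pt(-abs(tt), df))
}

# OLS coefficients via the normal equations
oracleOls <- function(X, y) solve(t(X) %*% X) %*% (t(X) %*% y)

# Network strength by brute-force loop
oracleNos <- function(X, edgeSet) {
    out <- numeric(ncol(X))
    for (s in seq_len(ncol(X)))
        for (e in edgeSet) out[s] <- out[s] + X[e, s]
    out
}

# Write a cohort to a temporary dataset directory, return the manifest path
writeTempDataset <- function(ce) {
    d <- file.path(tempfile("dataset"))
    writeDataset(ce, d)
}
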