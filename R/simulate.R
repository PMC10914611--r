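#' Simulation parameters
#'
#' Assembles the parameter list for the synthetic cohort generator.  The
#' defaults emulate the statistical structure of a two-site adult cohort of
#' 904 subjects with a 114-node cortical atlas: a right-skewed childhood
#' trauma sum score bounded below at its scale minimum (CTQ-like, mean 32.60,
#' SD 8.73 on [25, 125]), a left-skewed social-support mean score (FSozU-like,
#' mean 4.51, SD 0.54 on [1, 5]), a phenotype correlation of -0.370, age
#' truncated-normal on [18, 65] (34.04 / 12.84), sex with P(female) =
#' 582/904, TIV normal (1526.51 / 144.61 cm^3) and right-skewed log-normal
#' head motion.  Streamline counts are over-dispersed negative-binomial
#' draws on a density-controlled support set; planted edges couple to the
#' phenotypes additively on the count scale with signs recorded in the
#' ground-truth ledger, including inverse-sign edges shared between the two
#' phenotypes (7 coupled +A/-B and 4 coupled -A/+B by default).
#'
#' @param nSubjects cohort size
#' @param nNodes atlas size
#' @param density fraction of the edge universe with nonzero expected count
#' @param countMeanlog,countSdlog log-normal parameters of per-edge mean
#'   streamline counts on the support set
#' @param dispersion negative-binomial size parameter (smaller = more
#'   over-dispersed)
#' @param effectSize target per-edge partial Spearman magnitude of planted
#'   edge-phenotype couplings
#' @param phenotypeCorr target Pearson correlation between the two phenotypes
#' @param nPlantedPos,nPlantedNeg planted positively / negatively coupled
#'   edges for phenotype A
#' @param nPlantedPosB,nPlantedNegB planted set sizes for phenotype B
#'   (default: mirror phenotype A's)
#' @param nSharedPosANegB planted edges coupled positively to phenotype A and
#'   negatively to phenotype B
#' @param nSharedNegAPosB planted edges coupled negatively to A, positively
#'   to B
#' @param confoundCoupling latent correlation between phenotype A and a
#'   standardized age/sex mix (0 = covariates independent of phenotypes, the
#'   default; positive values exercise covariate adjustment)
#' @param phenotypeNames names of the two phenotype columns
#' @param ageMean,ageSd,ageRange,pFemale,tivMean,tivSd,motionMeanlog,
#'   motionSdlog,pSite1 covariate marginals
#' @param phenoAMean,phenoASd,phenoARange,phenoBMean,phenoBSd,phenoBRange
#'   phenotype marginals (A right-skewed above its minimum, B left-skewed
#'   below its maximum)
#' @return a named list of class \code{simParams}
#' @export
simParams <- function(nSubjects = 904, nNodes = 114, density = 0.35,
                      countMeanlog = log(20), countSdlog = 1,
                      dispersion = 5, effectSize = 0.3,
                      phenotypeCorr = -0.370,
                      nPlantedPos = 30, nPlantedNeg = 20,
                      nPlantedPosB = nPlantedPos, nPlantedNegB = nPlantedNeg,
                      nSharedPosANegB = 7, nSharedNegAPosB = 4,
                      confoundCoupling = 0,
                      phenotypeNames = c("ctq", "fsozu"),
                      ageMean = 34.04, ageSd = 12.84, ageRange = c(18, 65),
                      pFemale = 582 / 904, tivMean = 1526.51, tivSd = 144.61,
                      motionMeanlog = log(0.15), motionSdlog = 0.4,
                      pSite1 = 530 / 904,
                      phenoAMean = 32.60, phenoASd = 8.73,
                      phenoARange = c(25, 125),
                      phenoBMean = 4.51, phenoBSd = 0.54,
                      phenoBRange = c(1, 5)) {
    p <- as.list(environment())
    stopifnot(p$nSubjects >= 10, p$nNodes >= 3,
              p$density > 0, p$density <= 1,
              p$phenotypeCorr > -1, p$phenotypeCorr < 1,
              p$effectSize >= 0, p$effectSize < 1,
              p$dispersion > 0, p$ageSd > 0, p$tivSd > 0,
              p$nSharedPosANegB <= p$nPlantedPos,
              p$nSharedPosANegB <= p$nPlantedNegB,
              p$nSharedNegAPosB <= p$nPlantedNeg,
              p$nSharedNegAPosB <= p$nPlantedPosB)
    class(p) <- "simParams"
    p
}

# Gauss-Hermite nodes/weights recast for a standard-normal integrand
# (Golub-Welsch on the Hermite Jacobi matrix).
ghNorm <- function(n = 64) {
    off <- sqrt(seq_len(n - 1) / 2)
    J <- diag(0, n)
    J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
    J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
    eg <- eigen(J, symmetric = TRUE)
    z <- sqrt(2) * eg$values
    w <- eg$vectors[1, ]^2
    list(z = z, w = w / sum(w))
}

# Marginal quantile transforms: A = right-skewed (min + gamma excess),
# B = left-skewed (max - gamma excess), both clipped into their ranges.
phenoQuantileFuns <- function(params) {
    exA <- params$phenoAMean - params$phenoARange[1]
    scA <- params$phenoASd^2 / exA
    shA <- exA / scA
    exB <- params$phenoBRange[2] - params$phenoBMean
    scB <- params$phenoBSd^2 / exB
    shB <- exB / scB
    list(
        qA = function(u) pmin(params$phenoARange[1] +
                              qgamma(u, shape = shA, scale = scA),
                              params$phenoARange[2]),
        qB = function(u) pmax(params$phenoBRange[2] -
                              qgamma(u, shape = shB, scale = scB),
                              params$phenoBRange[1]))
}

# Pearson correlation of the two transformed phenotypes under a Gaussian
# copula with latent correlation rhoLat, by 2-D Gauss-Hermite quadrature.
copulaPearson <- function(rhoLat, qA, qB, nq = 48) {
    gh <- ghNorm(nq)
    a <- qA(pnorm(gh$z))
    muA <- sum(gh$w * a); vA <- sum(gh$w * (a - muA)^2)
    b0 <- qB(pnorm(gh$z))
    muB <- sum(gh$w * b0); vB <- sum(gh$w * (b0 - muB)^2)
    z2 <- outer(rhoLat * gh$z, sqrt(1 - rhoLat^2) * gh$z, "+")
    bCond <- matrix(qB(pnorm(z2)), nq, nq) %*% gh$w  # E[B | z1]
    eAB <- sum(gh$w * a * bCond)
    (eAB - muA * muB) / sqrt(vA * vB)
}

#' Calibrate the latent copula correlation
#'
#' Finds, by deterministic root search on the quadrature expression of the
#' transformed-variable correlation, the latent Gaussian correlation whose
#' induced Pearson correlation between the two skewed phenotype marginals
#' equals the target.  Done once per generator call; no randomness involved.
#'
#' @param target desired Pearson correlation between the phenotypes
#' @param params a \code{\link{simParams}} list (for the marginals)
#' @return latent correlation in (-1, 1)
#' @export
calibrateLatentRho <- function(target, params = simParams()) {
    if (target == 0) return(0)
    q <- phenoQuantileFuns(params)
    f <- function(r) copulaPearson(r, q$qA, q$qB) - target
    stats::uniroot(f, c(-0.995, 0.995), tol = 1e-5)$root
}

#' Generate subject covariates
#'
#' Age is truncated-normal on its range (inverse-CDF sampling), sex is
#' Bernoulli (1 = female), TIV normal, head motion log-normal
#' (right-skewed, strictly positive), site a two-level label.
#'
#' @param params a \code{\link{simParams}} list
#' @param seed integer seed for the covariate substream
#' @return data.frame with columns age, sex, tiv, motion, site
#' @export
generateCovariates <- function(params, seed) {
    withSeed(seed, {
        n <- params$nSubjects
        pr <- pnorm(params$ageRange, params$ageMean, params$ageSd)
        age <- qnorm(runif(n, pr[1], pr[2]), params$ageMean, params$ageSd)
        sex <- rbinom(n, 1, params$pFemale)
        tiv <- rnorm(n, params$tivMean, params$tivSd)
        motion <- rlnorm(n, params$motionMeanlog, params$motionSdlog)
        site <- ifelse(runif(n) < params$pSite1, "site1", "site2")
        data.frame(age = age, sex = sex, tiv = tiv, motion = motion,
                   site = site)
    })
}

#' Generate the two coupled skewed phenotypes
#'
#' A shared latent Gaussian factor (Gaussian copula, latent correlation
#' calibrated by \code{\link{calibrateLatentRho}}) couples the two
#' phenotypes so the realized Pearson correlation targets
#' \code{params$phenotypeCorr} while preserving the skewed bounded
#' marginals.  With \code{confoundCoupling > 0} phenotype A's latent factor
#' additionally loads on a standardized age/sex mix.
#'
#' @param params a \code{\link{simParams}} list
#' @param seed integer seed for the phenotype substream
#' @param covariates optional covariate data.frame (required when
#'   \code{confoundCoupling > 0})
#' @return data.frame with the two phenotype columns named
#'   \code{params$phenotypeNames}
#' @export
generatePhenotypes <- function(params, seed, covariates = NULL) {
    rhoLat <- calibrateLatentRho(params$phenotypeCorr, params)
    q <- phenoQuantileFuns(params)
    withSeed(seed, {
        n <- params$nSubjects
        z1 <- rnorm(n)
        cc <- params$confoundCoupling
        if (cc > 0) {
            if (is.null(covariates))
                stop("confoundCoupling > 0 requires covariates")
            mix <- scale(scale(covariates$age)[, 1] +
                         scale(covariates$sex)[, 1])[, 1]
            z1 <- cc * mix + sqrt(1 - cc^2) * z1
        }
        z2 <- rhoLat * z1 + sqrt(1 - rhoLat^2) * rnorm(n)
        a <- q$qA(pnorm(z1))
        b <- q$qB(pnorm(z2))
        if (n >= 1000) {
            realized <- cor(a, b)
            if (abs(realized - params$phenotypeCorr) > 0.1)
                warning(sprintf(
                    "realized phenotype correlation %.3f misses target %.3f",
                    realized, params$phenotypeCorr))
        }
        out <- data.frame(a, b)
        names(out) <- params$phenotypeNames
        out
    })
}

#' Draw the planted-edge ground truth
#'
#' Samples disjoint signed edge sets for each phenotype from the support
#' set, including the inverse-sign shared edges (+A/-B and -A/+B).  The
#' ledger also fixes the support set (edges with nonzero expected count).
#'
#' @param params a \code{\link{simParams}} list
#' @param seed integer seed for the ground-truth substream
#' @return list with elements \code{support}, \code{plantedPosA},
#'   \code{plantedNegA}, \code{plantedPosB}, \code{plantedNegB},
#'   \code{sharedPosANegB}, \code{sharedNegAPosB}, \code{effectSize}
#'   (edge indices are 1-based positions in the lexicographic universe)
#' @export
makeGroundTruth <- function(params, seed) {
    E <- edgeUniverseSize(params$nNodes)
    nSupport <- max(2L, round(params$density * E))
    nDistinct <- params$nPlantedPos + params$nPlantedNeg +
        params$nPlantedPosB + params$nPlantedNegB -
        params$nSharedPosANegB - params$nSharedNegAPosB
    if (nDistinct > nSupport)
        stop("planted sets (", nDistinct, " distinct edges) exceed the ",
             nSupport, "-edge support set")
    withSeed(seed, {
        support <- sort(sample.int(E, nSupport))
        pool <- sample(support)  # shuffled; take disjoint slices
        take <- function(k) {
            if (k == 0L) return(integer())
            out <- pool[seq_len(k)]
            pool <<- pool[-seq_len(k)]
            out
        }
        sharedPN <- take(params$nSharedPosANegB)
        sharedNP <- take(params$nSharedNegAPosB)
        posA <- sort(c(sharedPN, take(params$nPlantedPos -
                                      params$nSharedPosANegB)))
        negA <- sort(c(sharedNP, take(params$nPlantedNeg -
                                      params$nSharedNegAPosB)))
        posB <- sort(c(sharedNP, take(params$nPlantedPosB -
                                      params$nSharedNegAPosB)))
        negB <- sort(c(sharedPN, take(params$nPlantedNegB -
                                      params$nSharedPosANegB)))
        list(support = support,
             plantedPosA = posA, plantedNegA = negA,
             plantedPosB = posB, plantedNegB = negB,
             sharedPosANegB = sort(sharedPN),
             sharedNegAPosB = sort(sharedNP),
             effectSize = params$effectSize)
    })
}

#' Generate the connectome stack
#'
#' Baseline counts per edge and subject are negative-binomial with a fixed
#' per-edge mean (log-normal across support edges, zero elsewhere).  Planted
#' edges add a signed term proportional to the subject's standardized
#' phenotype, with the per-edge gain chosen so the induced correlation
#' magnitude targets \code{effectSize}: gain = sqrt(es^2/(1-es^2)) * sd of
#' the edge's baseline count.  Sums are rounded and floored at 0, so all
#' entries remain nonnegative integers.
#'
#' @param params a \code{\link{simParams}} list
#' @param truth ground-truth ledger from \code{\link{makeGroundTruth}}
#' @param phenotypes phenotype data.frame (two columns)
#' @param seed integer seed for the connectome substream
#' @return E x N integer matrix of edge weights
#' @export
generateConnectomes <- function(params, truth, phenotypes, seed) {
    stopifnot(nrow(phenotypes) == params$nSubjects)
    E <- edgeUniverseSize(params$nNodes)
    N <- params$nSubjects
    withSeed(seed, {
        mu <- numeric(E)
        mu[truth$support] <- rlnorm(length(truth$support),
                                    params$countMeanlog, params$countSdlog)
        planted <- unique(c(truth$plantedPosA, truth$plantedNegA,
                            truth$plantedPosB, truth$plantedNegB))
        # keep planted baselines off the sparse low tail so the additive
        # signal is not destroyed by the floor at zero
        mu[planted] <- pmax(mu[planted], exp(params$countMeanlog))
        w <- matrix(rnbinom(E * N, mu = rep(mu, N),
                            size = params$dispersion), E, N)
        if (params$effectSize > 0 && length(planted)) {
            es <- params$effectSize
            zA <- scale(phenotypes[[1]])[, 1]
            zB <- scale(phenotypes[[2]])[, 1]
            sA <- sB <- numeric(E)
            sA[truth$plantedPosA] <- 1; sA[truth$plantedNegA] <- -1
            sB[truth$plantedPosB] <- 1; sB[truth$plantedNegB] <- -1
            gain <- sqrt(es^2 / (1 - es^2)) *
                sqrt(mu[planted] + mu[planted]^2 / params$dispersion)
            signal <- gain * (sA[planted] %o% zA + sB[planted] %o% zB)
            w[planted, ] <- pmax(0L, w[planted, ] + round(signal))
        }
        storage.mode(w) <- "integer"
        w
    })
}

#' Simulate a full synthetic cohort
#'
#' Runs the covariate, phenotype, ground-truth and connectome generators on
#' independent named substreams of one master seed and assembles the result
#' into a \linkS4class{ConnectomeExperiment} whose metadata carries the
#' ground-truth ledger and the parameters.
#'
#' @param params a \code{\link{simParams}} list
#' @param seed master seed
#' @return a \linkS4class{ConnectomeExperiment}
#' @examples
#' ce <- simulateCohort(simParams(nSubjects = 20, nNodes = 10,
#'                                nPlantedPos = 2, nPlantedNeg = 2,
#'                                nSharedPosANegB = 1, nSharedNegAPosB = 1),
#'                      seed = 7)
#' ce
#' @export
simulateCohort <- function(params = simParams(), seed = 1L) {
    covs <- generateCovariates(params, substreamSeed(seed, "covariates"))
    phen <- generatePhenotypes(params, substreamSeed(seed, "phenotypes"),
                               covariates = covs)
    truth <- makeGroundTruth(params, substreamSeed(seed, "groundtruth"))
    w <- generateConnectomes(params, truth, phen,
                             substreamSeed(seed, "connectome"))
    ids <- sprintf("sub_%04d", seq_len(params$nSubjects))
    colnames(w) <- ids
    atlas <- sprintf("node_%03d", seq_len(params$nNodes) - 1L)
    idx <- edgeIndexTable(params$nNodes)
    rd <- S4Vectors::DataFrame(
        node1 = idx$node1, node2 = idx$node2,
        label1 = atlas[idx$node1], label2 = atlas[idx$node2])
    se <- SummarizedExperiment(
        assays = list(streamlines = w), rowData = rd,
        colData = S4Vectors::DataFrame(cbind(phen, covs), row.names = ids),
        metadata = list(atlas = atlas, minStreamlines = NULL,
                        groundTruth = truth,
                        simParams = unclass(params)[
                            !vapply(params, is.function, logical(1))],
                        seed = as.integer(seed)))
    new("ConnectomeExperiment", se)
}
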