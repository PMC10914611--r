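#' Consistency screen: which edges are reliably present in training data
#'
#' For each edge, a one-sample t-test of the training-subject weights
#' against zero, one-tailed in the positive direction; the edge is retained
#' when p < alpha.  Zero-variance edges are decided by convention: retained
#' when the common value is positive (the edge is always present), excluded
#' when all values are zero.
#'
#' @param trainX E x n matrix of edge weights (training subjects in columns)
#' @param alpha screening threshold
#' @return logical vector of length E
#' @export
consistencyMask <- function(trainX, alpha = 0.05) {
    n <- ncol(trainX)
    if (n < 3L) stop("consistency screen needs at least 3 training subjects")
    mo <- row_moments_subset(trainX, seq_len(n))
    maskFromMoments(mo[, 1L], mo[, 2L], n, alpha)
}

maskFromMoments <- function(m, v, n, alpha) {
    zeroVar <- v == 0
    tt <- m / sqrt(v / n)
    p <- pt(tt, df = n - 1, lower.tail = FALSE)
    mask <- !zeroVar & p < alpha
    mask[zeroVar] <- m[zeroVar] > 0
    mask
}

#' Partial Spearman correlation
#'
#' Rank-transforms all variables (average ranks for ties), residualizes the
#' two rank vectors on the rank-transformed covariates plus an intercept,
#' and correlates the residuals.  The p-value uses
#' t = rho * sqrt((n - 2 - c) / (1 - rho^2)) on n - 2 - c degrees of
#' freedom (c = number of covariates), two-tailed.  With no covariates this
#' reduces to the ordinary Spearman correlation.
#'
#' @param x,y numeric vectors of equal length
#' @param covariates optional numeric matrix / data.frame of covariates
#' @return named vector c(rho, p); rho is NA when either variable is
#'   constant after ranking
#' @export
partialSpearman <- function(x, y, covariates = NULL) {
    n <- length(x)
    stopifnot(length(y) == n)
    C <- if (is.null(covariates)) NULL else as.matrix(covariates)
    nc <- if (is.null(C)) 0L else ncol(C)
    if (n <= nc + 2L) stop("need n > number of covariates + 2")
    res <- partialSpearmanMat(matrix(rank(x), 1L), y, C)
    c(rho = res$rho[1L], p = res$p[1L])
}

# Vectorized partial Spearman of many pre-ranked edge rows against one
# phenotype, given shared covariates.  `rankX` must already hold within-row
# ranks (see row_ranks); y and C are ranked here.  Residualization uses the
# normal equations of the small rank-covariate design, which is
# well-conditioned (rank columns have fixed scale) and much cheaper than a
# per-fold QR at this size.
partialSpearmanMat <- function(rankX, y, C = NULL, oneTailed = FALSE) {
    n <- ncol(rankX)
    ry <- rank(y)
    nc <- if (is.null(C)) 0L else ncol(C)
    if (nc > 0L) {
        M <- cbind(1, t(row_ranks(t(C))))
        cf <- solve(crossprod(M), cbind(crossprod(M, ry),
                                        tcrossprod(t(M), rankX)))
        resY <- ry - M %*% cf[, 1L]
        resX <- rankX - crossprod(cf[, -1L, drop = FALSE], t(M))
    } else {
        resY <- ry - mean(ry)
        resX <- rankX - rowMeans(rankX)
    }
    ssY <- sum(resY^2)
    ssX <- rowSums(resX^2)
    num <- drop(resX %*% resY)
    den <- sqrt(ssX * ssY)
    rho <- ifelse(den > 0, num / den, NA_real_)
    rho <- pmin(1, pmax(-1, rho))
    df <- n - 2L - nc
    p <- ifelse(is.na(rho), NA_real_,
         ifelse(abs(rho) >= 1, 0,
                2 * pt(-abs(rho) * sqrt(df / (1 - rho^2)), df)))
    out <- list(rho = rho, p = p)
    if (oneTailed)
        out$pPosOneTailed <- ifelse(is.na(rho), NA_real_,
            pt(rho * sqrt(df / pmax(1e-300, 1 - rho^2)),
               df, lower.tail = FALSE))
    out
}

#' Signed edge selection by covariate-adjusted partial Spearman correlation
#'
#' For every edge retained by the consistency mask, computes the partial
#' Spearman correlation between the edge's training weights and the
#' phenotype, controlling for the covariates, and splits the edges passing
#' p < alpha by the sign of rho.  Edges with undefined rho (constant after
#' ranking) are never selected.
#'
#' @param trainX E x n training edge-weight matrix
#' @param y training phenotype values
#' @param covariates training covariate matrix (may be NULL)
#' @param mask logical consistency mask of length E
#' @param alpha selection threshold
#' @param tails "two" (two-tailed p split by sign of rho) or "one"
#'   (one-tailed per direction at alpha each)
#' @return list with integer edge sets \code{pos} and \code{neg} (indices
#'   into the edge universe) and length-E vectors \code{rho}, \code{p}
#'   (NA outside the mask)
#' @export
selectEdges <- function(trainX, y, covariates, mask, alpha = 0.05,
                        tails = c("two", "one")) {
    tails <- match.arg(tails)
    E <- nrow(trainX)
    rho <- p <- rep(NA_real_, E)
    idx <- which(mask)
    if (!length(idx))
        return(list(pos = integer(), neg = integer(), rho = rho, p = p))
    rankX <- row_ranks_subset(trainX, idx, seq_len(ncol(trainX)))
    st <- partialSpearmanMat(rankX, y,
                             if (is.null(covariates)) NULL
                             else as.matrix(covariates),
                             oneTailed = tails == "one")
    rho[idx] <- st$rho
    p[idx] <- st$p
    ok <- !is.na(st$rho)
    if (tails == "two") {
        pos <- idx[ok & st$p < alpha & st$rho > 0]
        neg <- idx[ok & st$p < alpha & st$rho < 0]
    } else {
        pos <- idx[ok & st$pPosOneTailed < alpha]
        neg <- idx[ok & (1 - st$pPosOneTailed) < alpha & st$rho < 0]
    }
    list(pos = pos, neg = neg, rho = rho, p = p)
}

# selectEdges on a column (subject) subset of the full matrix, without
# materialising the training submatrix; same contract otherwise.
selectEdgesIdx <- function(X, cols, y, C, mask, alpha, tails) {
    E <- nrow(X)
    rho <- p <- rep(NA_real_, E)
    idx <- which(mask)
    if (!length(idx))
        return(list(pos = integer(), neg = integer(), rho = rho, p = p))
    rankX <- row_ranks_subset(X, idx, cols)
    st <- partialSpearmanMat(rankX, y, C, oneTailed = tails == "one")
    rho[idx] <- st$rho
    p[idx] <- st$p
    ok <- !is.na(st$rho)
    if (tails == "two") {
        pos <- idx[ok & st$p < alpha & st$rho > 0]
        neg <- idx[ok & st$p < alpha & st$rho < 0]
    } else {
        pos <- idx[ok & st$pPosOneTailed < alpha]
        neg <- idx[ok & (1 - st$pPosOneTailed) < alpha & st$rho < 0]
    }
    list(pos = pos, neg = neg, rho = rho, p = p)
}

#' Network strength: total streamlines over an edge set
#'
#' @param X E x n edge-weight matrix (or a single edge vector)
#' @param edgeSet integer edge indices
#' @return per-subject sums (numeric vector; 0 for an empty set)
#' @export
networkStrength <- function(X, edgeSet) {
    if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
    if (length(edgeSet) && (min(edgeSet) < 1L || max(edgeSet) > nrow(X)))
        stop("edge set outside the edge universe")
    colSums(X[edgeSet, , drop = FALSE])
}

#' Fit the phenotype-prediction linear model
#'
#' Ordinary least squares of the phenotype on an intercept, the network
#' strength (NOS) and the covariates.  A constant NOS column (or an empty
#' edge selection upstream) makes the design rank-deficient; the NOS column
#' is then dropped and the model flagged, so prediction falls back to
#' covariates plus intercept.
#'
#' @param nos training network-strength values (NULL to fit the
#'   covariate-only fallback directly)
#' @param covariates training covariate matrix (may be NULL)
#' @param y training phenotype
#' @return list with \code{coef} (named), \code{usedNos} (logical flag)
#' @export
fitNosModel <- function(nos, covariates, y) {
    C <- if (is.null(covariates)) NULL else as.matrix(covariates)
    usedNos <- !is.null(nos) && length(unique(nos)) > 1L
    X <- cbind(`(Intercept)` = 1,
               if (usedNos) cbind(nos = nos),
               C)
    if (nrow(X) < ncol(X) + 2L) stop("too few training subjects")
    fit <- lm.fit(X, y)
    if (fit$rank < ncol(X) || anyNA(fit$coefficients)) {
        if (usedNos) {  # drop the collinear NOS column and refit
            return(fitNosModel(NULL, covariates, y))
        }
        stop("singular design even without NOS")
    }
    list(coef = fit$coefficients, usedNos = usedNos)
}

#' Predict phenotype values from a fitted NOS model
#'
#' @param model result of \code{\link{fitNosModel}}
#' @param nos test network-strength values
#' @param covariates test covariate matrix (columns matching training)
#' @return numeric predictions
#' @export
predictNos <- function(model, nos, covariates = NULL) {
    C <- if (is.null(covariates)) NULL else as.matrix(covariates)
    X <- cbind(`(Intercept)` = 1,
               if (model$usedNos) cbind(nos = nos),
               C)
    if (ncol(X) != length(model$coef) ||
        !identical(colnames(X), names(model$coef)))
        stop("test design columns do not match the trained model")
    drop(X %*% model$coef)
}

#' Evaluate predictions: Pearson correlation and mean absolute error
#'
#' r is recorded as NA (a missing fold) when either vector is constant;
#' the MAE is always defined.
#'
#' @param truth,predicted numeric vectors of equal length >= 3
#' @return list(r =, mae =)
#' @export
evaluatePrediction <- function(truth, predicted) {
    stopifnot(length(truth) == length(predicted), length(truth) >= 3L)
    r <- if (stats::sd(truth) == 0 || stats::sd(predicted) == 0) NA_real_
         else stats::cor(truth, predicted)
    list(r = r, mae = mean(abs(truth - predicted)))
}

#' Run one cross-validation fold of the CPM pipeline
#'
#' Executes the six steps — consistency screen, signed edge selection,
#' network-strength summarisation, model fit, prediction, evaluation — for
#' the positive and negative networks.  Every statistic (mask, selection,
#' coefficients) is computed on training subjects only and applied to the
#' held-out test subjects.
#'
#' @param X E x N edge-weight matrix for the full cohort
#' @param y phenotype vector (length N)
#' @param covariates covariate matrix (N rows) or NULL
#' @param trainIdx,testIdx disjoint subject index vectors
#' @param selectionAlpha,consistencyAlpha,tails see \code{\link{cpmConfig}}
#' @return list with \code{rPos}, \code{rNeg}, \code{maePos}, \code{maeNeg},
#'   \code{selection} (from \code{\link{selectEdges}}), and flags
#'   \code{degeneratePos}/\code{degenerateNeg} (covariate-only fallback)
#' @export
runFold <- function(X, y, covariates, trainIdx, testIdx,
                    selectionAlpha = 0.05, consistencyAlpha = 0.05,
                    tails = "two") {
    if (length(intersect(trainIdx, testIdx)))
        stop("training and test subjects overlap (leakage guard)")
    if (!is.null(covariates) && !is.matrix(covariates))
        covariates <- as.matrix(covariates)
    Ctr <- if (is.null(covariates)) NULL
           else covariates[trainIdx, , drop = FALSE]
    Cte <- if (is.null(covariates)) NULL
           else covariates[testIdx, , drop = FALSE]
    trainIdx <- as.integer(trainIdx)
    testIdx <- as.integer(testIdx)
    if (length(trainIdx) < 3L)
        stop("consistency screen needs at least 3 training subjects")
    ytr <- y[trainIdx]
    mo <- row_moments_subset(X, trainIdx)
    mask <- maskFromMoments(mo[, 1L], mo[, 2L], length(trainIdx),
                            consistencyAlpha)
    sel <- selectEdgesIdx(X, trainIdx, ytr, Ctr, mask,
                          selectionAlpha, tails)

    evalSign <- function(set) {
        degenerate <- length(set) == 0L
        nosTr <- if (degenerate) NULL
                 else col_sums_subset(X, set, trainIdx)
        model <- fitNosModel(nosTr, Ctr, ytr)
        degenerate <- degenerate || !model$usedNos
        nosTe <- if (model$usedNos)
            col_sums_subset(X, set, testIdx) else NULL
        pred <- predictNos(model, nosTe, Cte)
        ev <- evaluatePrediction(y[testIdx], pred)
        list(r = if (degenerate) NA_real_ else ev$r, mae = ev$mae,
             degenerate = degenerate)
    }
    pos <- evalSign(sel$pos)
    neg <- evalSign(sel$neg)
    list(rPos = pos$r, rNeg = neg$r, maePos = pos$mae, maeNeg = neg$mae,
         selection = sel,
         degeneratePos = pos$degenerate, degenerateNeg = neg$degenerate)
}
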