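#' Balanced random fold assignment
#'
#' Partitions subjects uniformly at random into k folds whose sizes differ
#' by at most one.
#'
#' @param n number of subjects
#' @param k number of folds
#' @return integer fold labels in 1..k
#' @export
assignFolds <- function(n, k) {
    if (k > n) stop("more folds than subjects")
    sample(rep_len(seq_len(k), n))
}

# Covariate design for a run: standard = age, sex, TIV, head motion;
# quadratic_age adds age^2; global_nos replaces TIV by the subject's total
# streamline count over all edges.
covariateDesign <- function(ce, covariateSet, X) {
    cd <- as.data.frame(colData(ce))
    need <- c("age", "sex", "tiv", "motion")
    if (!all(need %in% colnames(cd)))
        stop("subject table lacks covariate columns: ",
             paste(setdiff(need, colnames(cd)), collapse = ", "))
    C <- as.matrix(cd[, need])
    if (covariateSet == "quadratic_age")
        C <- cbind(C, age2 = cd$age^2)
    else if (covariateSet == "global_nos")
        C[, "tiv"] <- colSums(X)
    if (anyNA(C)) stop("missing values in covariates")
    C
}

cpmInputs <- function(ce, phenotype, config) {
    if (!phenotype %in% colnames(colData(ce)))
        stop("unknown phenotype column: ", phenotype)
    X <- streamlines(ce)
    ms <- metadata(ce)$minStreamlines
    if (is.null(ms) || ms != config@minStreamlines)
        X <- filterMinStreamlines(X, config@minStreamlines)
    y <- colData(ce)[[phenotype]]
    if (anyNA(y)) stop("missing values in phenotype ", phenotype)
    C <- covariateDesign(ce, config@covariateSet, X)
    list(X = X, y = y, C = C)
}

# One full CV scheme (R repetitions x k folds) over prepared inputs.
# Returns per-iteration metrics and per-sign selection counts per edge.
# Edges that are zero in every subject can never pass the consistency
# screen in any fold, so the fold loop runs on the active rows only and
# selection indices are mapped back to the full universe.
runScheme <- function(X, y, C, k, R, config, seedBase,
                      foldList = NULL) {
    E <- nrow(X)
    N <- length(y)
    active <- which(rowSums(X) > 0)
    X <- X[active, , drop = FALSE]
    countPos <- countNeg <- numeric(E)
    nIter <- if (is.null(foldList)) R * k else length(foldList)
    acc <- matrix(NA_real_, nIter, 8L)
    degPos <- degNeg <- logical(nIter)
    it <- 0L
    for (rep in seq_len(R)) {
        if (is.null(foldList)) {
            folds <- withSeed(substreamSeed(seedBase, "folds", rep),
                              assignFolds(N, k))
            splits <- lapply(seq_len(k), function(f)
                list(test = which(folds == f), train = which(folds != f)))
        } else splits <- foldList
        for (f in seq_along(splits)) {
            it <- it + 1L
            fr <- runFold(X, y, C, splits[[f]]$train, splits[[f]]$test,
                          config@selectionAlpha, config@consistencyAlpha,
                          config@selectionTails)
            posE <- active[fr$selection$pos]
            negE <- active[fr$selection$neg]
            countPos[posE] <- countPos[posE] + 1
            countNeg[negE] <- countNeg[negE] + 1
            acc[it, ] <- c(rep, f, fr$rPos, fr$rNeg, fr$maePos, fr$maeNeg,
                           length(fr$selection$pos),
                           length(fr$selection$neg))
            degPos[it] <- fr$degeneratePos
            degNeg[it] <- fr$degenerateNeg
        }
        if (!is.null(foldList)) break
    }
    foldResults <- data.frame(
        repetition = as.integer(acc[, 1]), fold = as.integer(acc[, 2]),
        r_pos = acc[, 3], r_neg = acc[, 4],
        mae_pos = acc[, 5], mae_neg = acc[, 6],
        n_pos_edges = as.integer(acc[, 7]),
        n_neg_edges = as.integer(acc[, 8]),
        degenerate_pos = degPos, degenerate_neg = degNeg)
    list(foldResults = foldResults,
         stabilityPos = countPos / it, stabilityNeg = countNeg / it)
}

summariseFoldResults <- function(fr, ciMethod) {
    ciOf <- function(v) {
        v <- v[!is.na(v)]
        if (!length(v)) return(c(NA_real_, NA_real_, NA_real_))
        c(mean(v), unname(quantile(v, c(0.025, 0.975))))
    }
    perRep <- function(col) {
        if (ciMethod == "iteration") return(fr[[col]])
        tapply(fr[[col]], fr$repetition,
               function(v) mean(v, na.rm = TRUE))
    }
    out <- list()
    for (col in c("r_pos", "r_neg", "mae_pos", "mae_neg")) {
        s <- ciOf(perRep(col))
        out[[paste0("mean_", col)]] <- s[1]
        out[[paste0("ci_", col)]] <- s[2:3]
    }
    out$n_missing_r_pos <- sum(is.na(fr$r_pos))
    out$n_missing_r_neg <- sum(is.na(fr$r_neg))
    out
}

#' Run the repeated cross-validated CPM analysis
#'
#' For each repetition the subjects are randomly reassigned to k folds and
#' every fold is run through the six-step pipeline; metrics are averaged
#' over all non-missing iterations with 95 percent percentile confidence
#' intervals, and per-edge selection stability (proportion of the k x R
#' iterations in which the edge entered the positive / negative network) is
#' tracked per sign.
#'
#' @param ce a \linkS4class{ConnectomeExperiment}
#' @param phenotype name of the phenotype column to predict
#' @param config a \linkS4class{CpmConfig}
#' @param seed optional seed overriding \code{config@masterSeed}
#' @return a \linkS4class{CvResult}
#' @export
runRepeatedCv <- function(ce, phenotype, config = cpmConfig(),
                          seed = NULL) {
    validObject(config)
    seed <- if (is.null(seed)) config@masterSeed else as.integer(seed)
    inp <- cpmInputs(ce, phenotype, config)
    sch <- runScheme(inp$X, inp$y, inp$C, config@kFolds,
                     config@nRepetitions, config,
                     substreamSeed(seed, "cv"))
    if (all(is.na(sch$foldResults$r_pos)) &&
        all(is.na(sch$foldResults$r_neg)))
        stop("fully degenerate run: no fold produced a defined r")
    new("CvResult",
        foldResults = sch$foldResults,
        summary = summariseFoldResults(sch$foldResults, config@ciMethod),
        stabilityPos = sch$stabilityPos, stabilityNeg = sch$stabilityNeg,
        edgeLabels = edgeLabels(ce), phenotype = phenotype,
        config = config, seed = seed)
}

#' Leave-group-out cross-validation
#'
#' One fold per level of the grouping column (e.g. scanning site): the
#' model is trained on the complement and tested on the group.  No
#' repetitions; stability denominators equal the number of groups.
#'
#' @param ce a \linkS4class{ConnectomeExperiment}
#' @param phenotype phenotype column name
#' @param group name of the grouping column in the subject table
#' @param config a \linkS4class{CpmConfig}
#' @param seed optional seed override (used only for substream bookkeeping)
#' @return a \linkS4class{CvResult} with one fold result per group
#' @export
runLeaveGroupOut <- function(ce, phenotype, group = "site",
                             config = cpmConfig(cvMode = "leave_group_out"),
                             seed = NULL) {
    validObject(config)
    seed <- if (is.null(seed)) config@masterSeed else as.integer(seed)
    g <- colData(ce)[[group]]
    if (is.null(g)) stop("unknown group column: ", group)
    lev <- unique(g)
    if (length(lev) < 2L) stop("need at least 2 groups, found ", length(lev))
    sizes <- table(g)
    if (any(sizes < 3L))
        stop("every group needs at least 3 subjects")
    inp <- cpmInputs(ce, phenotype, config)
    foldList <- lapply(lev, function(l)
        list(test = which(g == l), train = which(g != l)))
    sch <- runScheme(inp$X, inp$y, inp$C, length(lev), 1L, config,
                     substreamSeed(seed, "lgo"), foldList = foldList)
    sch$foldResults$fold <- as.character(lev)[sch$foldResults$fold]
    new("CvResult",
        foldResults = sch$foldResults,
        summary = summariseFoldResults(sch$foldResults, config@ciMethod),
        stabilityPos = sch$stabilityPos, stabilityNeg = sch$stabilityNeg,
        edgeLabels = edgeLabels(ce), phenotype = phenotype,
        config = config, seed = seed)
}

#' Node degrees of a thresholded stability map
#'
#' Counts, for every node, the retained edges (stability >= threshold)
#' incident to it.
#'
#' @param stability per-edge stability values (length E)
#' @param threshold retention threshold in [0, 1]
#' @param nNodes atlas size
#' @param labels optional node labels
#' @return data.frame (node, label, degree) sorted by decreasing degree
#' @export
degreeSummary <- function(stability, threshold, nNodes, labels = NULL) {
    stopifnot(threshold >= 0, threshold <= 1,
              length(stability) == edgeUniverseSize(nNodes))
    idx <- edgeIndexTable(nNodes)
    keep <- which(stability >= threshold & stability > 0)
    deg <- tabulate(c(idx$node1[keep], idx$node2[keep]), nbins = nNodes)
    if (is.null(labels)) labels <- sprintf("node_%03d", seq_len(nNodes) - 1L)
    out <- data.frame(node = seq_len(nNodes), label = labels, degree = deg)
    out[order(-out$degree, out$node), ]
}

setMethod("show", "CvResult", function(object) {
    s <- object@summary
    cat("CvResult for phenotype '", object@phenotype, "': ",
        nrow(object@foldResults), " CV iterations\n", sep = "")
    fmt <- function(m, ci) sprintf("%.3f [%.3f; %.3f]", m, ci[1], ci[2])
    cat("  positive network: r =", fmt(s$mean_r_pos, s$ci_r_pos),
        " MAE =", fmt(s$mean_mae_pos, s$ci_mae_pos), "\n")
    cat("  negative network: r =", fmt(s$mean_r_neg, s$ci_r_neg),
        " MAE =", fmt(s$mean_mae_neg, s$ci_mae_neg), "\n")
    cat("  edges with stability > 0.5:",
        sum(object@stabilityPos > 0.5), "positive,",
        sum(object@stabilityNeg > 0.5), "negative\n")
})

#' @describeIn runRepeatedCv accessor for the per-edge stability maps
#' @param x a CvResult
#' @param sign "pos" or "neg"
#' @export
stabilityMap <- function(x, sign = c("pos", "neg")) {
    sign <- match.arg(sign)
    if (sign == "pos") x@stabilityPos else x@stabilityNeg
}

#' Write a CvResult to disk (JSON summary + per-edge / per-iteration TSV)
#'
#' @param result a \linkS4class{CvResult}
#' @param outDir output directory
#' @return invisibly, the paths written
#' @export
writeCvResult <- function(result, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(outDir, c("cv_summary.json", "edge_stability.tsv",
                                 "fold_metrics.tsv"))
    jsonlite::write_json(
        list(phenotype = result@phenotype, summary = result@summary,
             config = configAsList(result@config), seed = result@seed),
        paths[1], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.table(
        data.frame(edge = result@edgeLabels,
                   stability_pos = result@stabilityPos,
                   stability_neg = result@stabilityNeg),
        paths[2], sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(result@foldResults, paths[3], sep = "\t",
                row.names = FALSE, quote = FALSE)
    invisible(paths)
}
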