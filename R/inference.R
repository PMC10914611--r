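#' Shuffle phenotype values across subjects
#'
#' A uniform random permutation of the phenotype vector; connectomes and
#' covariates are left untouched, so the covariate-connectome coupling is
#' preserved under the null.
#'
#' @param y phenotype values
#' @return permuted vector with the same multiset of values
#' @export
permutePhenotype <- function(y) sample(y)

#' Permutation test for model performance and edge stability
#'
#' Repeats the CV scheme \code{config@nPermutations} times with the
#' phenotype randomly shuffled across subjects (fold assignments are
#' re-randomized per permutation), each time with
#' \code{config@permRepetitions} repetitions.  Performance p-values are the
#' proportion of permutations whose average performance strictly exceeded
#' the observed model's (larger mean r; smaller mean MAE); ties never count
#' against the observed model.  Per-edge stability p-values are the
#' proportion of permutations in which the edge's stability within the
#' permuted scheme strictly exceeded its observed stability.  The
#' conservative (b+1)/(m+1) p-value estimates are reported alongside the
#' plain proportions.
#'
#' @param ce a \linkS4class{ConnectomeExperiment}
#' @param phenotype phenotype column name
#' @param observed the \linkS4class{CvResult} of the unpermuted run (same
#'   configuration up to the number of repetitions)
#' @param config a \linkS4class{CpmConfig}
#' @param seed optional seed overriding \code{config@masterSeed}
#' @return a \linkS4class{PermutationResult}
#' @export
runPermutationTest <- function(ce, phenotype, observed,
                               config = cpmConfig(), seed = NULL) {
    validObject(config)
    seed <- if (is.null(seed)) config@masterSeed else as.integer(seed)
    inp <- cpmInputs(ce, phenotype, config)
    E <- nrow(inp$X)
    if (length(observed@stabilityPos) != E)
        stop("observed result and dataset have different edge universes")
    m <- config@nPermutations
    nullR <- nullMae <- matrix(NA_real_, m, 2,
                               dimnames = list(NULL, c("pos", "neg")))
    exceedPos <- exceedNeg <- numeric(E)
    for (b in seq_len(m)) {
        permSeed <- substreamSeed(seed, "permutation", b)
        yPerm <- withSeed(substreamSeed(permSeed, "shuffle"),
                          permutePhenotype(inp$y))
        sch <- runScheme(inp$X, yPerm, inp$C, config@kFolds,
                         config@permRepetitions, config, permSeed)
        fr <- sch$foldResults
        nullR[b, ] <- c(mean(fr$r_pos, na.rm = TRUE),
                        mean(fr$r_neg, na.rm = TRUE))
        nullMae[b, ] <- c(mean(fr$mae_pos, na.rm = TRUE),
                          mean(fr$mae_neg, na.rm = TRUE))
        exceedPos <- exceedPos + (sch$stabilityPos > observed@stabilityPos)
        exceedNeg <- exceedNeg + (sch$stabilityNeg > observed@stabilityNeg)
    }
    obs <- observed@summary
    propAbove <- function(nullv, obsv)
        sum(!is.na(nullv) & nullv > obsv) / m
    propBelow <- function(nullv, obsv)
        sum(!is.na(nullv) & nullv < obsv) / m
    pR <- c(pos = propAbove(nullR[, 1], obs$mean_r_pos),
            neg = propAbove(nullR[, 2], obs$mean_r_neg))
    pMae <- c(pos = propBelow(nullMae[, 1], obs$mean_mae_pos),
              neg = propBelow(nullMae[, 2], obs$mean_mae_neg))
    new("PermutationResult",
        nullR = nullR, nullMae = nullMae, pR = pR, pMae = pMae,
        pRConservative = (pR * m + 1) / (m + 1),
        pMaeConservative = (pMae * m + 1) / (m + 1),
        edgePPos = exceedPos / m, edgePNeg = exceedNeg / m,
        nDegenerate = c(pos = sum(is.na(nullR[, 1])),
                        neg = sum(is.na(nullR[, 2]))),
        nPermutations = m, permRepetitions = config@permRepetitions,
        seed = seed)
}

#' Edges with permutation-significant stability
#'
#' Selects, per sign, the edges whose observed stability is higher than
#' expected for random data (stability p < alpha, uncorrected), and reports
#' the size of the per-phenotype union together with its percentage of the
#' edge universe (two decimal places).
#'
#' @param observed a \linkS4class{CvResult}
#' @param perm the matching \linkS4class{PermutationResult}
#' @param alpha uncorrected threshold (default 0.05)
#' @return list with integer edge sets \code{pos}, \code{neg}, their
#'   \code{union}, \code{nUnion} and \code{pctUniverse}
#' @export
significantStabilityEdges <- function(observed, perm, alpha = 0.05) {
    E <- length(observed@stabilityPos)
    if (length(perm@edgePPos) != E)
        stop("edge universes of the two results differ")
    pos <- which(perm@edgePPos < alpha & observed@stabilityPos > 0)
    neg <- which(perm@edgePNeg < alpha & observed@stabilityNeg > 0)
    un <- sort(union(pos, neg))
    list(pos = pos, neg = neg, union = un, nUnion = length(un),
         pctUniverse = round(100 * length(un) / E, 2))
}

setMethod("show", "PermutationResult", function(object) {
    cat("PermutationResult:", object@nPermutations, "permutations x",
        object@permRepetitions, "repetition(s)\n")
    cat(sprintf("  p(r): pos %.4g, neg %.4g | p(MAE): pos %.4g, neg %.4g\n",
                object@pR["pos"], object@pR["neg"],
                object@pMae["pos"], object@pMae["neg"]))
    cat("  degenerate permutations:", object@nDegenerate[1], "pos,",
        object@nDegenerate[2], "neg\n")
})

#' Write a PermutationResult (JSON scalars + per-edge p TSV)
#'
#' @param perm a \linkS4class{PermutationResult}
#' @param edgeLabels "label1--label2" strings for the edge universe
#' @param outDir output directory
#' @return invisibly, the paths written
#' @export
writePermutationResult <- function(perm, edgeLabels, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(outDir, c("permutation_summary.json",
                                 "edge_stability_p.tsv"))
    jsonlite::write_json(
        list(p_r = as.list(perm@pR), p_mae = as.list(perm@pMae),
             p_r_conservative = as.list(perm@pRConservative),
             p_mae_conservative = as.list(perm@pMaeConservative),
             n_permutations = perm@nPermutations,
             perm_repetitions = perm@permRepetitions,
             n_degenerate = as.list(perm@nDegenerate), seed = perm@seed),
        paths[1], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.table(
        data.frame(edge = edgeLabels, p_pos = perm@edgePPos,
                   p_neg = perm@edgePNeg),
        paths[2], sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(paths)
}
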