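#' Permutation test for the overlap of two edge sets
#'
#' Compares the observed intersection of two stable networks against the
#' overlap of size-matched random edge sets drawn uniformly without
#' replacement from the edge universe.  The p-value is the proportion of
#' permutations whose null overlap strictly exceeds the observed overlap.
#' Under this null the overlap is hypergeometric with expectation
#' |A| |B| / E.
#'
#' @param setA,setB integer edge-index sets (subsets of 1..universeSize)
#' @param universeSize size of the edge universe sampled from
#' @param nPermutations number of random draws (default 1000)
#' @param seed integer seed
#' @return an \linkS4class{OverlapResult} (sign patterns empty; see
#'   \code{\link{classifySignPatterns}})
#' @export
overlapTest <- function(setA, setB, universeSize, nPermutations = 1000,
                        seed = 1L) {
    universeSize <- as.integer(universeSize)
    if (length(setA) > universeSize || length(setB) > universeSize)
        stop("set size exceeds the edge universe")
    if (length(setA) && max(setA) > universeSize ||
        length(setB) && max(setB) > universeSize)
        stop("edge index outside the universe")
    observed <- length(intersect(setA, setB))
    degenerate <- length(setA) == universeSize &&
        length(setB) == universeSize
    if (degenerate)
        warning("both sets equal the whole universe; ",
                "the overlap test is degenerate (p = 0 by construction)")
    nullOv <- withSeed(substreamSeed(seed, "overlap"), {
        vapply(seq_len(nPermutations), function(b) {
            a <- sample.int(universeSize, length(setA))
            inB <- logical(universeSize)
            inB[sample.int(universeSize, length(setB))] <- TRUE
            sum(inB[a])
        }, integer(1))
    })
    new("OverlapResult",
        observedOverlap = as.integer(observed),
        nullOverlaps = as.integer(nullOv),
        pOverlap = sum(nullOv > observed) / nPermutations,
        signPattern = data.frame(),
        setSizes = c(length(setA), length(setB)),
        universeSize = universeSize,
        nPermutations = as.integer(nPermutations),
        seed = as.integer(seed))
}

#' Classify sign patterns of overlapping stable edges
#'
#' Each edge present in the stable networks of both phenotypes is labelled
#' by its signed-set membership per phenotype: \code{(+,-)}, \code{(-,+)},
#' \code{(+,+)} or \code{(-,-)}.  An edge significant in both signed maps
#' of one phenotype is labelled ambiguous and reported separately.
#'
#' @param sigA,sigB per-phenotype significant-stability sets, as returned
#'   by \code{\link{significantStabilityEdges}} (lists with \code{pos} and
#'   \code{neg} integer sets)
#' @param edgeLabels optional "label1--label2" strings for the universe
#' @return data.frame with columns edge (index), label, signA, signB,
#'   pattern; attribute \code{counts} tabulates the patterns
#' @export
classifySignPatterns <- function(sigA, sigB, edgeLabels = NULL) {
    unionA <- union(sigA$pos, sigA$neg)
    unionB <- union(sigB$pos, sigB$neg)
    ov <- sort(intersect(unionA, unionB))
    signOf <- function(e, sig) {
        inP <- e %in% sig$pos
        inN <- e %in% sig$neg
        ifelse(inP & inN, "ambiguous", ifelse(inP, "+", "-"))
    }
    sA <- signOf(ov, sigA)
    sB <- signOf(ov, sigB)
    pattern <- ifelse(sA == "ambiguous" | sB == "ambiguous", "ambiguous",
                      paste0("(", sA, ",", sB, ")"))
    out <- data.frame(
        edge = ov,
        label = if (is.null(edgeLabels)) as.character(ov)
                else edgeLabels[ov],
        signA = sA, signB = sB, pattern = pattern,
        stringsAsFactors = FALSE)
    lev <- c("(+,-)", "(-,+)", "(+,+)", "(-,-)", "ambiguous")
    attr(out, "counts") <- table(factor(out$pattern, levels = lev))
    out
}

#' Connectome-wide edge-wise correlation profile of two phenotypes
#'
#' For every edge passing the full-sample consistency screen, computes the
#' covariate-adjusted partial Spearman correlation of the edge weights with
#' each phenotype on the full sample, and returns the Pearson correlation
#' across edges between the two coefficient profiles.  A negative profile
#' correlation means edges positively related to one phenotype tend to be
#' negatively related to the other.
#'
#' @param ce a \linkS4class{ConnectomeExperiment}
#' @param phenotypeA,phenotypeB phenotype column names
#' @param config a \linkS4class{CpmConfig} (covariate set, consistency
#'   alpha, min-streamline threshold)
#' @return list with \code{profileR}, per-edge vectors \code{rhoA},
#'   \code{rhoB} (NA outside the mask) and the \code{mask}
#' @export
edgewiseCorrelationProfile <- function(ce, phenotypeA, phenotypeB,
                                       config = cpmConfig()) {
    inpA <- cpmInputs(ce, phenotypeA, config)
    yB <- colData(ce)[[phenotypeB]]
    if (is.null(yB)) stop("unknown phenotype column: ", phenotypeB)
    mask <- consistencyMask(inpA$X, config@consistencyAlpha)
    if (sum(mask) < 3L)
        stop("fewer than 3 edges pass the consistency screen")
    idx <- which(mask)
    rankX <- row_ranks(inpA$X[idx, , drop = FALSE])
    stA <- partialSpearmanMat(rankX, inpA$y, inpA$C)
    stB <- partialSpearmanMat(rankX, yB, inpA$C)
    ok <- !is.na(stA$rho) & !is.na(stB$rho)
    rhoA <- rhoB <- rep(NA_real_, nrow(inpA$X))
    rhoA[idx] <- stA$rho
    rhoB[idx] <- stB$rho
    list(profileR = cor(stA$rho[ok], stB$rho[ok]),
         rhoA = rhoA, rhoB = rhoB, mask = mask)
}

setMethod("show", "OverlapResult", function(object) {
    cat("OverlapResult: |A| =", object@setSizes[1],
        ", |B| =", object@setSizes[2],
        "in a universe of", object@universeSize, "edges\n")
    cat(sprintf("  observed overlap %d, p = %.4g (%d permutations)\n",
                object@observedOverlap, object@pOverlap,
                object@nPermutations))
    if (nrow(object@signPattern)) {
        cnt <- attr(object@signPattern, "counts")
        cat("  sign patterns:",
            paste(names(cnt), cnt, sep = " ", collapse = ", "), "\n")
    }
})

#' Write an OverlapResult (JSON + sign-pattern TSV)
#'
#' @param result an \linkS4class{OverlapResult}
#' @param outDir output directory
#' @return invisibly, the paths written
#' @export
writeOverlapResult <- function(result, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(outDir, c("overlap_summary.json",
                                 "sign_patterns.tsv"))
    counts <- if (nrow(result@signPattern))
        as.list(attr(result@signPattern, "counts")) else list()
    jsonlite::write_json(
        list(observed_overlap = result@observedOverlap,
             p_overlap = result@pOverlap,
             set_sizes = result@setSizes,
             universe_size = result@universeSize,
             n_permutations = result@nPermutations,
             null_mean = mean(result@nullOverlaps),
             sign_pattern_counts = counts, seed = result@seed),
        paths[1], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.table(result@signPattern, paths[2], sep = "\t",
                row.names = FALSE, quote = FALSE)
    invisible(paths)
}
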