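#' @import SummarizedExperiment
#' @import S4Vectors
NULL

#' ConnectomeExperiment: a stack of streamline-count connectomes
#'
#' Container for a cohort of structural connectomes together with the subject
#' table.  Extends \linkS4class{SummarizedExperiment}: the single assay
#' \code{"streamlines"} is an E x N matrix holding, for each of the E
#' undirected edges of the atlas (rows, in the package's fixed lexicographic
#' edge ordering) the streamline count of each of the N subjects (columns).
#' \code{rowData} carries the edge index (node indices and labels);
#' \code{colData} is the subject table (phenotypes and covariates);
#' \code{metadata} holds the atlas labels, the min-streamline threshold
#' already applied (if any) and, for simulated data, the ground-truth ledger.
#'
#' Validity requires nonnegative integral weights and a row count equal to
#' \code{n(n-1)/2} for the atlas size \code{n}; symmetry and the zero
#' diagonal are inherent to the edge-vector representation (each unordered
#' pair is stored once, self-connections are never stored).
#'
#' @export
setClass("ConnectomeExperiment", contains = "SummarizedExperiment")

setValidity("ConnectomeExperiment", function(object) {
    msg <- character()
    if (!"streamlines" %in% assayNames(object))
        msg <- c(msg, "assay 'streamlines' is required")
    else {
        w <- assay(object, "streamlines")
        if (anyNA(w)) msg <- c(msg, "streamline counts contain NA")
        else {
            if (min(w) < 0) msg <- c(msg, "negative streamline counts")
            if (max(abs(w - round(w))) > 0)
                msg <- c(msg, "streamline counts must be integers")
        }
    }
    atlas <- metadata(object)$atlas
    if (is.null(atlas)) msg <- c(msg, "metadata$atlas (node labels) missing")
    else {
        if (anyDuplicated(atlas)) msg <- c(msg, "atlas labels not unique")
        n <- length(atlas)
        if (nrow(object) != n * (n - 1) / 2)
            msg <- c(msg, sprintf(
                "row count %d does not match edge universe %d of a %d-node atlas",
                nrow(object), n * (n - 1) / 2, n))
    }
    if (!all(c("node1", "node2") %in% colnames(rowData(object))))
        msg <- c(msg, "rowData must carry node1/node2 edge index columns")
    if (length(msg)) msg else TRUE
})

#' Cross-validated CPM run configuration
#'
#' Bundle of tuning parameters for a CPM run.  Defaults follow the standard
#' protocol: 10-fold cross-validation repeated 100 times, 1000 permutations,
#' edge selection and consistency screening at alpha = 0.05, edges kept when
#' supported by at least 3 streamlines.
#'
#' @slot kFolds number of cross-validation folds (>= 2)
#' @slot nRepetitions repetitions of the k-fold scheme
#' @slot nPermutations permutations for significance testing
#' @slot permRepetitions repetitions of the CV scheme inside each permutation
#' @slot selectionAlpha per-edge selection threshold (partial Spearman p)
#' @slot consistencyAlpha consistency-screen threshold (one-sample t p)
#' @slot minStreamlines minimum streamline count for an edge to be retained
#' @slot covariateSet one of "standard", "quadratic_age", "global_nos"
#' @slot cvMode "repeated_kfold" or "leave_group_out"
#' @slot selectionTails "two" (two-tailed p, split by sign) or "one"
#'   (one-tailed per direction)
#' @slot ciMethod percentile CI over "iteration" values or "repetition" means
#' @slot masterSeed integer master seed for all substreams
#' @export
setClass("CpmConfig", representation(
    kFolds = "integer", nRepetitions = "integer", nPermutations = "integer",
    permRepetitions = "integer", selectionAlpha = "numeric",
    consistencyAlpha = "numeric", minStreamlines = "integer",
    covariateSet = "character", cvMode = "character",
    selectionTails = "character", ciMethod = "character",
    masterSeed = "integer"))

setValidity("CpmConfig", function(object) {
    msg <- character()
    if (object@kFolds < 2L) msg <- c(msg, "kFolds must be >= 2")
    if (object@nRepetitions < 1L) msg <- c(msg, "nRepetitions must be >= 1")
    if (object@nPermutations < 1L) msg <- c(msg, "nPermutations must be >= 1")
    for (a in c("selectionAlpha", "consistencyAlpha")) {
        v <- slot(object, a)
        if (!(v > 0 && v < 1)) msg <- c(msg, paste(a, "must be in (0, 1)"))
    }
    if (object@minStreamlines < 0L) msg <- c(msg, "minStreamlines must be >= 0")
    if (!object@covariateSet %in% c("standard", "quadratic_age", "global_nos"))
        msg <- c(msg, "unknown covariateSet")
    if (!object@cvMode %in% c("repeated_kfold", "leave_group_out"))
        msg <- c(msg, "unknown cvMode")
    if (!object@selectionTails %in% c("two", "one"))
        msg <- c(msg, "selectionTails must be 'two' or 'one'")
    if (!object@ciMethod %in% c("iteration", "repetition"))
        msg <- c(msg, "ciMethod must be 'iteration' or 'repetition'")
    if (length(msg)) msg else TRUE
})

#' Result of a repeated cross-validation CPM run
#'
#' @slot foldResults data.frame with one row per CV iteration (repetition,
#'   fold, test-set Pearson r and MAE for the positive- and negative-network
#'   models, selected edge counts, degeneracy flags)
#' @slot summary list of aggregate metrics: mean and 95 percent percentile CI
#'   for r and MAE per sign, and counts of missing (degenerate) iterations
#' @slot stabilityPos,stabilityNeg per-edge proportion of CV iterations in
#'   which the edge entered the positive / negative predictive network
#' @slot edgeLabels "label1--label2" strings aligned to the edge universe
#' @slot phenotype name of the predicted phenotype column
#' @slot config the \linkS4class{CpmConfig} used
#' @slot seed integer seed the run was started from
#' @export
setClass("CvResult", representation(
    foldResults = "data.frame", summary = "list",
    stabilityPos = "numeric", stabilityNeg = "numeric",
    edgeLabels = "character", phenotype = "character",
    config = "CpmConfig", seed = "integer"))

#' Permutation-test result for CPM performance and edge stability
#'
#' @slot nullR,nullMae matrices (nPermutations x 2, columns pos/neg) of
#'   per-permutation average performance
#' @slot pR,pMae named performance p-values per sign: the proportion of
#'   permutations whose average performance exceeded the observed model's
#'   (strictly better: larger r, smaller MAE)
#' @slot pRConservative,pMaeConservative the (b+1)/(m+1) variants
#' @slot edgePPos,edgePNeg per-edge stability p-values: proportion of
#'   permutations in which the permuted stability strictly exceeded the
#'   observed stability
#' @slot nDegenerate number of permutations with a missing performance value
#'   per sign
#' @slot nPermutations,permRepetitions,seed run parameters
#' @export
setClass("PermutationResult", representation(
    nullR = "matrix", nullMae = "matrix",
    pR = "numeric", pMae = "numeric",
    pRConservative = "numeric", pMaeConservative = "numeric",
    edgePPos = "numeric", edgePNeg = "numeric",
    nDegenerate = "integer", nPermutations = "integer",
    permRepetitions = "integer", seed = "integer"))

#' Overlap test between two stable networks
#'
#' @slot observedOverlap size of the intersection of the two edge sets
#' @slot nullOverlaps per-permutation overlap of size-matched random edge sets
#' @slot pOverlap proportion of permutations with null overlap strictly
#'   greater than observed
#' @slot signPattern data.frame of overlapping edges with their sign for each
#'   phenotype and the pattern label
#' @slot setSizes sizes of the two input sets
#' @slot universeSize size of the edge universe sampled from
#' @slot nPermutations,seed run parameters
#' @export
setClass("OverlapResult", representation(
    observedOverlap = "integer", nullOverlaps = "integer",
    pOverlap = "numeric", signPattern = "data.frame",
    setSizes = "integer", universeSize = "integer",
    nPermutations = "integer", seed = "integer"))
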