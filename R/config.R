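#' Create a CPM run configuration
#'
#' @param kFolds number of CV folds (default 10)
#' @param nRepetitions repetitions of the k-fold scheme (default 100)
#' @param nPermutations permutations for significance tests (default 1000)
#' @param permRepetitions CV repetitions inside each permutation (default 1;
#'   the full-protocol value equal to \code{nRepetitions} is configurable but
#'   computationally disproportionate)
#' @param selectionAlpha edge-selection threshold on the partial Spearman p
#'   (default 0.05)
#' @param consistencyAlpha consistency-screen threshold on the one-sample t p
#'   (default 0.05)
#' @param minStreamlines minimum streamline support per edge (default 3)
#' @param covariateSet "standard" (age, sex, TIV, head motion),
#'   "quadratic_age" (adds age squared) or "global_nos" (replaces TIV by the
#'   subject's total streamline count over all edges)
#' @param cvMode "repeated_kfold" or "leave_group_out"
#' @param selectionTails "two": two-tailed selection p split by the sign of
#'   rho (default); "one": one-tailed per direction
#' @param ciMethod percentile CI over "iteration"-level values (default) or
#'   over "repetition" means
#' @param masterSeed master seed for all random substreams
#' @return a validated \linkS4class{CpmConfig}
#' @examples
#' cpmConfig(kFolds = 10, nRepetitions = 100)
#' @export
cpmConfig <- function(kFolds = 10, nRepetitions = 100, nPermutations = 1000,
                      permRepetitions = 1, selectionAlpha = 0.05,
                      consistencyAlpha = 0.05, minStreamlines = 3,
                      covariateSet = "standard", cvMode = "repeated_kfold",
                      selectionTails = "two", ciMethod = "iteration",
                      masterSeed = 1L) {
    new("CpmConfig",
        kFolds = as.integer(kFolds),
        nRepetitions = as.integer(nRepetitions),
        nPermutations = as.integer(nPermutations),
        permRepetitions = as.integer(permRepetitions),
        selectionAlpha = as.numeric(selectionAlpha),
        consistencyAlpha = as.numeric(consistencyAlpha),
        minStreamlines = as.integer(minStreamlines),
        covariateSet = covariateSet, cvMode = cvMode,
        selectionTails = selectionTails, ciMethod = ciMethod,
        masterSeed = as.integer(masterSeed))
}

configAsList <- function(config) {
    sl <- slotNames("CpmConfig")
    stats::setNames(lapply(sl, function(s) slot(config, s)), sl)
}

setMethod("show", "CpmConfig", function(object) {
    cat("CpmConfig:", object@kFolds, "folds x", object@nRepetitions,
        "repetitions,", object@nPermutations, "permutations\n")
    cat("  selection alpha", object@selectionAlpha,
        "| consistency alpha", object@consistencyAlpha,
        "| min streamlines", object@minStreamlines, "\n")
    cat("  covariates:", object@covariateSet, "| cv:", object@cvMode,
        "| seed:", object@masterSeed, "\n")
})
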