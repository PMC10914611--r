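#' @useDynLib connCPM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats pt qt qnorm pnorm qgamma rbinom rnbinom rlnorm runif
#'   quantile rnorm setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

#' Number of edges in a full undirected graph without self-connections
#'
#' For an atlas of \code{n} nodes the edge universe contains every unordered
#' pair of distinct nodes, i.e. \eqn{E = n(n-1)/2}.
#'
#' @param nNodes positive integer number of atlas nodes
#' @return integer edge count
#' @examples
#' edgeUniverseSize(114)  # 6441
#' @export
edgeUniverseSize <- function(nNodes) {
    stopifnot(is.numeric(nNodes), length(nNodes) == 1L, nNodes >= 1)
    as.integer(nNodes * (nNodes - 1) / 2)
}

#' Edge index table for an atlas
#'
#' Enumerates the edge universe in the package's fixed ordering:
#' lexicographic over node pairs (i, j) with i < j.  This ordering is the
#' contract that makes per-edge reports comparable across runs.
#'
#' @param nNodes number of nodes
#' @return data.frame with integer columns \code{node1}, \code{node2}
#'   (1-based) of \code{edgeUniverseSize(nNodes)} rows
#' @examples
#' edgeIndexTable(3)
#' @export
edgeIndexTable <- function(nNodes) {
    stopifnot(nNodes >= 2)
    n <- as.integer(nNodes)
    i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
    j <- sequence((n - 1L):1L) + i
    data.frame(node1 = i, node2 = j)
}

#' Linear edge index of a node pair
#'
#' Maps an unordered node pair to its position in the lexicographic edge
#' ordering used throughout the package.
#'
#' @param i,j 1-based node indices (vectors allowed); order is irrelevant
#' @param nNodes number of nodes
#' @return integer linear index in \code{1..E}
#' @examples
#' edgeLinearIndex(1, 2, 5)   # 1
#' edgeLinearIndex(4, 5, 5)   # 10
#' @export
edgeLinearIndex <- function(i, j, nNodes) {
    lo <- pmin(i, j)
    hi <- pmax(i, j)
    if (any(lo == hi)) stop("self-connections have no edge index")
    if (any(hi > nNodes) || any(lo < 1)) stop("node index out of range")
    as.integer((lo - 1) * nNodes - lo * (lo - 1) / 2 + (hi - lo))
}

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one master seed through named
#' substreams (covariates, phenotypes, connectome, folds, permutation, ...)
#' so each component is independently reproducible.  The substream seed is a
#' deterministic hash of the master seed, the stream name and an optional
#' stream counter, kept below 2^31.
#'
#' @param master integer master seed
#' @param stream character stream name
#' @param index optional nonnegative integer (e.g. repetition number)
#' @return integer seed
#' @export
substreamSeed <- function(master, stream, index = 0L) {
    stopifnot(is.numeric(master), length(stream) == 1L)
    p <- 2147483629  # large prime < 2^31
    h <- as.numeric(master) %% p
    for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% p
    h <- (h * 131 + as.numeric(index) %% p) %% p
    as.integer(h + 1)
}

# Evaluate expr with a local RNG state seeded from `seed`, restoring the
# caller's RNG afterwards.
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}
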