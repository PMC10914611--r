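#' Construct a ConnectomeExperiment from square connectivity matrices
#'
#' Validates each subject's matrix (square, symmetric, zero diagonal,
#' nonnegative integer weights), vectorizes the upper triangle in the fixed
#' lexicographic edge order and stacks subjects into the E x N assay.
#'
#' @param matrices named list of n x n matrices (names = subject ids) or a
#'   single n x n x N array
#' @param subjects data.frame of phenotypes/covariates, one row per subject
#'   in the same order (may be NULL)
#' @param atlas character vector of node labels; defaults to
#'   \code{node_000...} if NULL
#' @param minStreamlines if non-NULL, \code{\link{filterMinStreamlines}} is
#'   applied with this threshold after validation
#' @return a \linkS4class{ConnectomeExperiment}
#' @examples
#' m <- matrix(0L, 5, 5); m[1, 2] <- m[2, 1] <- 7L
#' ce <- ConnectomeExperiment(list(s1 = m, s2 = m))
#' nEdges(ce)  # 10
#' @export
ConnectomeExperiment <- function(matrices, subjects = NULL, atlas = NULL,
                                 minStreamlines = NULL) {
    if (is.array(matrices) && length(dim(matrices)) == 3L)
        matrices <- lapply(seq_len(dim(matrices)[3]), function(i)
            matrices[, , i])
    stopifnot(is.list(matrices), length(matrices) >= 1L)
    ids <- names(matrices)
    if (is.null(ids)) ids <- sprintf("subject_%03d", seq_along(matrices))
    n <- nrow(matrices[[1L]])
    if (is.null(atlas)) atlas <- sprintf("node_%03d", seq_len(n) - 1L)
    if (length(atlas) != n)
        stop("atlas has ", length(atlas), " labels but matrices have ",
             n, " nodes")
    idx <- edgeIndexTable(n)
    flat <- vapply(seq_along(matrices), function(s) {
        validateConnectomeMatrix(matrices[[s]], ids[s], n)
        edgeVector(matrices[[s]])
    }, numeric(nrow(idx)))
    storage.mode(flat) <- "integer"  # counts, validated integral above
    dimnames(flat) <- list(NULL, ids)
    rd <- S4Vectors::DataFrame(
        node1 = idx$node1, node2 = idx$node2,
        label1 = atlas[idx$node1], label2 = atlas[idx$node2])
    cd <- if (is.null(subjects)) S4Vectors::DataFrame(row.names = ids)
          else {
              if (nrow(subjects) != length(ids))
                  stop("subject table has ", nrow(subjects),
                       " rows for ", length(ids), " matrices")
              S4Vectors::DataFrame(subjects, row.names = ids)
          }
    se <- SummarizedExperiment(
        assays = list(streamlines = flat), rowData = rd, colData = cd,
        metadata = list(atlas = atlas, minStreamlines = NULL))
    out <- new("ConnectomeExperiment", se)
    if (!is.null(minStreamlines))
        out <- filterMinStreamlines(out, minStreamlines)
    out
}

validateConnectomeMatrix <- function(m, id, n = nrow(m)) {
    if (!is.matrix(m) || nrow(m) != ncol(m))
        stop("subject ", id, ": matrix is not square")
    if (nrow(m) != n)
        stop("subject ", id, ": ", nrow(m), " nodes, expected ", n)
    if (anyNA(m)) stop("subject ", id, ": missing values")
    asym <- abs(m - t(m))
    if (max(asym) > 0) {
        w <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
        stop("subject ", id, ": asymmetric matrix, max |w[i,j]-w[j,i]| = ",
             max(asym), " at (", w[1L], ",", w[2L], ")")
    }
    if (any(diag(m) != 0))
        stop("subject ", id, ": nonzero diagonal (self-connections)")
    if (min(m) < 0) stop("subject ", id, ": negative streamline count")
    if (max(abs(m - round(m))) > 0)
        stop("subject ", id, ": non-integer streamline counts ",
             "(counts are not rounded silently)")
    invisible(TRUE)
}

#' Vectorize a connectivity matrix / rebuild it from an edge vector
#'
#' \code{edgeVector} flattens the upper triangle of a symmetric matrix into
#' the fixed lexicographic edge order; \code{edgeMatrix} is its inverse.
#' The two are exact round-trip companions:
#' \code{edgeMatrix(edgeVector(W), nrow(W)) == W}.
#'
#' @param m square symmetric matrix
#' @return \code{edgeVector}: numeric vector of length \code{n(n-1)/2}
#' @examples
#' m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 7; m[2, 3] <- m[3, 2] <- 2
#' edgeVector(m)            # 7 0 2
#' edgeMatrix(c(7, 0, 2), 3)
#' @export
edgeVector <- function(m) {
    stopifnot(is.matrix(m), nrow(m) == ncol(m))
    t(m)[lower.tri(m)]  # row-major upper triangle = lexicographic (i<j)
}

#' @rdname edgeVector
#' @param v edge vector in lexicographic order
#' @param nNodes number of nodes of the target matrix
#' @export
edgeMatrix <- function(v, nNodes) {
    E <- edgeUniverseSize(nNodes)
    if (length(v) != E)
        stop("edge vector length ", length(v), " does not match the ",
             E, "-edge universe of a ", nNodes, "-node atlas")
    m <- matrix(0, nNodes, nNodes)
    m[lower.tri(m)] <- v
    m <- t(m)
    m[lower.tri(m)] <- v
    m
}

# ---- accessors --------------------------------------------------------------

#' @describeIn ConnectomeExperiment-accessors number of atlas nodes
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @describeIn ConnectomeExperiment-accessors number of edges in the universe
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @describeIn ConnectomeExperiment-accessors atlas node labels
#' @export
setGeneric("atlasLabels", function(x) standardGeneric("atlasLabels"))

#' @describeIn ConnectomeExperiment-accessors E x N streamline-count matrix
#' @export
setGeneric("streamlines", function(x) standardGeneric("streamlines"))

#' @describeIn ConnectomeExperiment-accessors apply the minimum-streamline
#'   support rule: entries below \code{minCount} are set to 0, entries at or
#'   above it are kept unchanged (idempotent)
#' @param minCount minimum streamline count (>= 0)
#' @export
setGeneric("filterMinStreamlines",
           function(x, minCount) standardGeneric("filterMinStreamlines"))

#' @describeIn ConnectomeExperiment-accessors ground-truth ledger of a
#'   simulated dataset (NULL for real data)
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' Accessors for ConnectomeExperiment
#'
#' @param x a \linkS4class{ConnectomeExperiment}
#' @name ConnectomeExperiment-accessors
NULL

#' @export
setMethod("nNodes", "ConnectomeExperiment",
          function(x) length(metadata(x)$atlas))

#' @export
setMethod("nEdges", "ConnectomeExperiment", function(x) nrow(x))

#' @export
setMethod("atlasLabels", "ConnectomeExperiment",
          function(x) metadata(x)$atlas)

#' @export
setMethod("streamlines", "ConnectomeExperiment",
          function(x) assay(x, "streamlines"))

#' @export
setMethod("groundTruth", "ConnectomeExperiment",
          function(x) metadata(x)$groundTruth)

#' @export
setMethod("filterMinStreamlines", "ConnectomeExperiment",
          function(x, minCount) {
    w <- assay(x, "streamlines")
    assay(x, "streamlines") <- filterMinStreamlines(w, minCount)
    metadata(x)$minStreamlines <- as.integer(minCount)
    validObject(x)
    x
})

#' @export
setMethod("filterMinStreamlines", "matrix", function(x, minCount) {
    if (!is.numeric(minCount) || length(minCount) != 1L || minCount < 0)
        stop("minCount must be a single nonnegative number")
    x[x < minCount] <- 0
    x
})

#' Subject table as a plain data.frame
#' @param x a ConnectomeExperiment
#' @return data.frame of phenotypes and covariates, one row per subject
#' @export
subjectData <- function(x) as.data.frame(colData(x))

#' @importFrom SummarizedExperiment colData
#' @export
SummarizedExperiment::colData

#' @importFrom SummarizedExperiment rowData
#' @export
SummarizedExperiment::rowData

#' @importFrom S4Vectors metadata
#' @export
S4Vectors::metadata

#' "label1--label2" strings for every edge of the universe
#' @param x a ConnectomeExperiment
#' @return character vector of length \code{nEdges(x)}
#' @export
edgeLabels <- function(x) {
    rd <- rowData(x)
    paste0(rd$label1, "--", rd$label2)
}

setMethod("show", "ConnectomeExperiment", function(object) {
    cat("ConnectomeExperiment:", nNodes(object), "nodes,",
        nEdges(object), "edges,", ncol(object), "subjects\n")
    ms <- metadata(object)$minStreamlines
    cat("  min-streamline filter:",
        if (is.null(ms)) "not applied" else paste0(">= ", ms), "\n")
    if (!is.null(metadata(object)$groundTruth))
        cat("  simulated data with ground-truth ledger\n")
    if (ncol(colData(object)))
        cat("  subject columns:",
            paste(colnames(colData(object)), collapse = ", "), "\n")
})
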