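#' Load a connectome stack from a subject manifest
#'
#' The manifest is a tab-separated table with a header row and at least the
#' columns \code{subject_id} and \code{matrix_path} (relative paths are
#' resolved against the manifest's directory); any further columns are merged
#' into the subject table.  Matrix files are auto-detected as either dense
#' n x n TSV or 3-column edge lists (\code{node1 TAB node2 TAB count},
#' 1-based node indices, missing pairs meaning weight 0).  All matrices must
#' share one shape and pass validation (symmetry, zero diagonal, nonnegative
#' integer counts).
#'
#' @param manifestPath path to the manifest TSV
#' @param atlasPath optional plain-text file with one node label per line;
#'   generated \code{node_000...} labels are used if absent
#' @param minStreamlines optional threshold passed to
#'   \code{\link{filterMinStreamlines}} after loading
#' @return a \linkS4class{ConnectomeExperiment} in manifest order
#' @export
loadConnectomeStack <- function(manifestPath, atlasPath = NULL,
                                minStreamlines = NULL) {
    man <- read.delim(manifestPath, check.names = FALSE,
                      stringsAsFactors = FALSE)
    need <- c("subject_id", "matrix_path")
    if (!all(need %in% colnames(man)))
        stop("manifest must have columns: ", paste(need, collapse = ", "))
    base <- dirname(normalizePath(manifestPath))
    paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$matrix_path),
                    man$matrix_path, file.path(base, man$matrix_path))
    atlas <- NULL
    if (!is.null(atlasPath)) atlas <- readLines(atlasPath)

    mats <- vector("list", nrow(man))
    names(mats) <- man$subject_id
    nRef <- NA_integer_
    for (s in seq_len(nrow(man))) {
        m <- readConnectomeMatrix(paths[s], nNodes = nRef)
        if (is.na(nRef)) nRef <- nrow(m)
        if (nrow(m) != nRef)
            stop("subject ", man$subject_id[s], ": matrix has ", nrow(m),
                 " nodes but previous subjects have ", nRef)
        mats[[s]] <- m
    }
    extra <- setdiff(colnames(man), need)
    subjects <- if (length(extra)) man[, extra, drop = FALSE] else NULL
    ConnectomeExperiment(mats, subjects = subjects, atlas = atlas,
                         minStreamlines = minStreamlines)
}

#' Read one connectivity-matrix file
#'
#' Files with 3 columns are read as edge lists (\code{node1, node2, count},
#' 1-based indices, absent pairs = 0), anything else as a dense square
#' matrix.  The one ambiguous case — a 3-row, 3-column file — is resolved as
#' dense when it is a valid connectivity matrix (symmetric, zero diagonal)
#' and as an edge list otherwise.
#'
#' @param path matrix file path
#' @param nNodes node count, needed for edge lists whose highest node has no
#'   entries; optional otherwise
#' @return a square numeric matrix
#' @export
readConnectomeMatrix <- function(path, nNodes = NA) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE)
    isEdgeList <- ncol(tab) == 3L
    if (isEdgeList && nrow(tab) == 3L && (is.na(nNodes) || nNodes == 3L)) {
        m <- as.matrix(unname(tab))
        if (isSymmetric(m, check.attributes = FALSE) && all(diag(m) == 0))
            isEdgeList <- FALSE
    }
    if (isEdgeList) {
        n <- if (!is.na(nNodes)) nNodes else max(tab[[1L]], tab[[2L]])
        m <- matrix(0, n, n)
        ij <- cbind(tab[[1L]], tab[[2L]])
        m[ij] <- tab[[3L]]
        m[ij[, 2:1, drop = FALSE]] <- tab[[3L]]
        m
    } else {
        if (nrow(tab) != ncol(tab))
            stop(path, ": dense matrix file is not square (",
                 nrow(tab), " x ", ncol(tab), ")")
        as.matrix(unname(tab))
    }
}

#' Write a (typically simulated) dataset to disk
#'
#' Writes one dense TSV matrix per subject, the subject manifest, the atlas
#' labels and, when present, the ground-truth ledger and simulation
#' parameters as JSON, so a run is fully reconstructable from disk with
#' \code{\link{loadConnectomeStack}}.
#'
#' @param ce a \linkS4class{ConnectomeExperiment}
#' @param outDir output directory (created if needed)
#' @param overwrite allow writing into a non-empty directory
#' @return the manifest path, invisibly
#' @export
writeDataset <- function(ce, outDir, overwrite = FALSE) {
    if (dir.exists(outDir) && length(dir(outDir)) && !overwrite)
        stop("output directory ", outDir,
             " is not empty; use overwrite = TRUE")
    dir.create(file.path(outDir, "matrices"), recursive = TRUE,
               showWarnings = FALSE)
    n <- nNodes(ce)
    ids <- colnames(ce)
    w <- streamlines(ce)
    rel <- file.path("matrices", paste0(ids, ".tsv"))
    for (s in seq_along(ids)) {
        m <- edgeMatrix(w[, s], n)
        write.table(m, file.path(outDir, rel[s]), sep = "\t",
                    row.names = FALSE, col.names = FALSE)
    }
    man <- data.frame(subject_id = ids, matrix_path = rel,
                      as.data.frame(colData(ce)),
                      check.names = FALSE, row.names = NULL)
    manifestPath <- file.path(outDir, "manifest.tsv")
    write.table(man, manifestPath, sep = "\t", row.names = FALSE,
                quote = FALSE)
    writeLines(atlasLabels(ce), file.path(outDir, "atlas.txt"))
    gt <- groundTruth(ce)
    if (!is.null(gt))
        jsonlite::write_json(gt, file.path(outDir, "ground_truth.json"),
                             auto_unbox = TRUE, digits = NA)
    sp <- metadata(ce)$simParams
    if (!is.null(sp))
        jsonlite::write_json(sp, file.path(outDir, "sim_params.json"),
                             auto_unbox = TRUE, digits = NA)
    invisible(manifestPath)
}
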