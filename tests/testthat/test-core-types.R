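test_that("edge universe size follows n(n-1)/2 and the index is bijective", {
    for (n in c(3L, 10L, 114L)) {
        E <- edgeUniverseSize(n)
        expect_identical(E, as.integer(n * (n - 1) / 2))
        idx <- edgeIndexTable(n)
        expect_identical(nrow(idx), as.integer(E))
        expect_true(all(idx$node1 < idx$node2))
        expect_false(anyDuplicated(idx) > 0)
        # lookup agrees with the table row position, order-insensitive
        lin <- edgeLinearIndex(idx$node1, idx$node2, n)
        expect_identical(lin, seq_len(E))
        expect_identical(edgeLinearIndex(idx$node2, idx$node1, n), lin)
    }
    expect_identical(edgeUniverseSize(114), 6441L)
    expect_error(edgeLinearIndex(2, 2, 5), "self-connection")
})

test_that("vectorization is lexicographic and round-trips exactly", {
    m <- matrix(0, 3, 3)
    m[1, 2] <- m[2, 1] <- 7
    m[2, 3] <- m[3, 2] <- 2
    expect_identical(edgeVector(m), c(7, 0, 2))
    expect_identical(edgeVector(matrix(0, 4, 4)), rep(0, 6))
    set.seed(42)
    for (n in c(3, 7, 20)) {
        w <- randomConnectome(n)
        expect_identical(edgeMatrix(edgeVector(w), n),
                         matrix(as.numeric(w), n, n))
    }
    expect_error(edgeMatrix(1:5, 4), "universe")
})

test_that("connectome validation rejects malformed matrices", {
    ms <- replicate(3, randomConnectome(5), simplify = FALSE)
    names(ms) <- paste0("s", 1:3)
    ce <- ConnectomeExperiment(ms)
    expect_s4_class(ce, "ConnectomeExperiment")
    expect_identical(nEdges(ce), 10L)
    expect_identical(colnames(ce), names(ms))

    bad <- ms
    bad$s2[3, 4] <- 4L; bad$s2[4, 3] <- 5L
    expect_error(ConnectomeExperiment(bad), "s2.*asymmetric")
    bad <- ms
    bad$s1[2, 3] <- bad$s1[3, 2] <- -1L
    expect_error(ConnectomeExperiment(bad), "negative")
    bad <- ms
    bad$s3[1, 2] <- bad$s3[2, 1] <- 2.5
    expect_error(ConnectomeExperiment(bad), "non-integer")
    bad <- ms
    diag(bad$s1) <- 1L
    expect_error(ConnectomeExperiment(bad), "diagonal")
})

test_that("min-streamline filter zeroes sub-threshold entries, inclusively and idempotently", {
    m <- matrix(c(0, 2, 3, 5,
                  2, 0, 1, 4,
                  3, 1, 0, 0,
                  5, 4, 0, 0), 4, 4)
    f <- filterMinStreamlines(m, 3)
    expect_identical(f[1, 2], 0)   # 2 < 3 -> dropped
    expect_identical(f[1, 3], 3)   # boundary inclusive
    expect_identical(f[1, 4], 5)
    expect_true(isSymmetric(f))
    expect_identical(filterMinStreamlines(f, 3), f)  # idempotent
    expect_identical(filterMinStreamlines(matrix(0, 3, 3), 3),
                     matrix(0, 3, 3))
    expect_error(filterMinStreamlines(m, -1), "nonnegative")

    ce <- smallCohort(nSubjects = 15, nNodes = 10)
    ce3 <- filterMinStreamlines(ce, 3)
    w <- streamlines(ce3)
    expect_true(all(w[w != 0] >= 3))
    expect_identical(metadata(ce3)$minStreamlines, 3L)
})

test_that("manifest loading round-trips a written dataset and validates shapes", {
    ce <- smallCohort(nSubjects = 10, nNodes = 10, seed = 3)
    man <- writeTempDataset(ce)
    back <- loadConnectomeStack(man,
                                atlasPath = file.path(dirname(man),
                                                      "atlas.txt"))
    expect_identical(unname(streamlines(back)), unname(streamlines(ce)))
    expect_identical(colnames(back), colnames(ce))
    expect_identical(atlasLabels(back), atlasLabels(ce))
    expect_equal(subjectData(back)$ctq, subjectData(ce)$ctq)

    # shape mismatch across subjects is caught
    d <- dirname(man)
    write.table(randomConnectome(5),
                file.path(d, "matrices", paste0(colnames(ce)[2], ".tsv")),
                sep = "\t", row.names = FALSE, col.names = FALSE)
    expect_error(loadConnectomeStack(man), "nodes")
})

test_that("edge-list matrix dialect is read, with absent pairs meaning zero", {
    d <- tempfile("el"); dir.create(d)
    writeLines(c("1\t2\t7", "2\t4\t3"), file.path(d, "m.tsv"))
    m <- readConnectomeMatrix(file.path(d, "m.tsv"))
    expect_identical(dim(m), c(4L, 4L))
    expect_identical(m[1, 2], 7)
    expect_identical(m[2, 1], 7)
    expect_identical(m[2, 4], 3)
    expect_identical(m[1, 3], 0)
    # ambiguous 3x3 file that is a valid dense matrix reads as dense
    mm <- matrix(c(0, 5, 1, 5, 0, 2, 1, 2, 0), 3, 3)
    write.table(mm, file.path(d, "dense.tsv"), sep = "\t",
                row.names = FALSE, col.names = FALSE)
    expect_equal(readConnectomeMatrix(file.path(d, "dense.tsv")), mm,
                 ignore_attr = TRUE)
})
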