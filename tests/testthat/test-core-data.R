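test_that("CountTable construction enforces the count invariants", {
    y <- matrix(c(1, 3, 2, 4), 2, 2,
                dimnames = list(c("f1", "f2"), c("s1", "s2")))
    ct <- CountTable(y)
    expect_equal(unname(libSizes(ct)), c(4, 6))
    expect_equal(sampleData(ct)$group, c("absent", "absent"))
    expect_equal(featureData(ct)$metabolism, c("absent", "absent"))

    expect_error(CountTable(y * 0.5 + 0.25), "integer")
    expect_error(CountTable(-y), "integer")
    yDup <- y
    rownames(yDup) <- c("f1", "f1")
    expect_error(CountTable(yDup))
    expect_error(CountTable(y[, 1, drop = FALSE]))

    # orientation is explicit, never guessed
    ctT <- CountTable(t(y), transposed = TRUE)
    expect_equal(counts(ctT), counts(ct))
})

test_that("TSV round trip reproduces the table and rejects bad input", {
    ct <- makeCounts(5, 4, seed = 2)
    dir <- withr::local_tempdir()
    cp <- file.path(dir, "counts.tsv")
    sp <- file.path(dir, "samples.tsv")
    fp <- file.path(dir, "features.tsv")
    writeCountTable(ct, cp, sp, fp)
    ct2 <- readCountTable(cp, sampleMetaPath = sp, featureMetaPath = fp)
    expect_equal(counts(ct2), counts(ct))
    expect_equal(sampleData(ct2), sampleData(ct))
    expect_equal(featureData(ct2), featureData(ct))

    bad <- file.path(dir, "bad.tsv")
    writeLines(c("feature_id\ts1\ts2", "f1\t3.5\t1", "f2\t1\t2"), bad)
    expect_error(readCountTable(bad), "integer")
    writeLines(c("feature_id\ts1\ts1", "f1\t3\t1", "f2\t1\t2"), bad)
    expect_error(readCountTable(bad), "duplicated sample")
})

test_that("filterCounts applies the strict prevalence and depth rules", {
    y <- rbind(kept = c(11, 11, 0), dropped = c(11, 0, 0),
               tiny = c(1, 1, 1))
    colnames(y) <- paste0("s", 1:3)
    ct <- CountTable(y)
    # present with > 10 reads in more than 1 sample
    fc <- filterCounts(ct, minCount = 10, minSamples = 1)
    expect_equal(rownames(fc), "kept")
    expect_equal(unname(libSizes(fc)), c(11, 11, 0)[1:3])

    # library-size rule is strictly greater-than: lib == threshold drops
    y2 <- matrix(c(999, 1000, 1001, 1500), 1,
                 dimnames = list("a", paste0("s", 1:4)))
    ct2 <- CountTable(y2)
    fc2 <- filterCounts(ct2, minLibSize = 1000, minCount = 0,
                        minSamples = 0)
    expect_equal(colnames(fc2), c("s3", "s4"))

    # idempotence
    ct3 <- makeCounts(30, 8, seed = 5, lambda = 8)
    once <- filterCounts(ct3, minCount = 5, minSamples = 2)
    twice <- filterCounts(once, minCount = 5, minSamples = 2)
    expect_equal(counts(twice), counts(once))

    expect_error(filterCounts(ct, minCount = 1e6), "no features left")
})

test_that("rarefaction conserves depth and matches the hypergeometric mean", {
    ct <- makeCounts(10, 5, seed = 3, lambda = 50)
    rf <- rarefyCounts(ct, depth = 100, seed = 9)
    expect_true(all(libSizes(rf) == 100))
    expect_true(all(counts(rf) <= counts(ct)))
    # full-depth rarefaction is the identity
    dmin <- min(libSizes(ct))
    ctEq <- CountTable(matrix(c(7, 7, 7, 7), 2,
                              dimnames = list(c("a", "b"),
                                              c("s1", "s2"))))
    expect_equal(counts(rarefyCounts(ctEq, 14, seed = 1)), counts(ctEq))
    # single feature: conservation forces count = depth
    one <- CountTable(matrix(c(50, 60), 1,
                             dimnames = list("only", c("s1", "s2"))))
    expect_equal(unname(counts(rarefyCounts(one, 40, seed = 1))[1, ]),
                 c(40, 40))
    # mean of the without-replacement draw: E = depth * 900 / 1000
    y <- matrix(c(900, 100), 2, 1, dimnames = list(c("big", "small"), "s1"))
    y <- cbind(y, s2 = c(900, 100))
    ctH <- CountTable(y)
    draws <- vapply(seq_len(2000), function(i)
        counts(rarefyCounts(ctH, 100, seed = i))["big", 1L], numeric(1))
    expect_lt(abs(mean(draws) - 90), 0.5)
    # shallow samples are dropped with a warning
    yS <- matrix(c(10, 5, 200, 100, 300, 50), 2,
                 dimnames = list(c("a", "b"), paste0("s", 1:3)))
    expect_warning(rs <- rarefyCounts(CountTable(yS), depth = 100,
                                      seed = 2), "dropped")
    expect_equal(ncol(rs), 2L)
    expect_error(rarefyCounts(ct, depth = 0), "depth")
})

test_that("zero fractions count cells and average per feature", {
    y <- matrix(c(0, 3, 2, 0), 2, dimnames = list(c("a", "b"),
                                                  c("s1", "s2")))
    zf <- zeroFraction(CountTable(y))
    expect_equal(zf$overall, 0.5)
    allZero <- CountTable(matrix(0, 3, 4,
        dimnames = list(paste0("f", 1:3), paste0("s", 1:4))))
    zf0 <- zeroFraction(allZero)
    expect_equal(zf0$overall, 1)
    expect_equal(unname(zf0$perFeature), rep(1, 3))
    ct <- makeCounts(12, 6, seed = 4, lambda = 1)
    zf2 <- zeroFraction(ct)
    expect_equal(mean(zf2$perFeature), zf2$overall)
})
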