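simTwoGroup <- function(F = 60L, nPerGroup = 10L, foldEffect = 5,
                        seed = 5L, distribution = "ZINB", null = FALSE) {
    tpl <- if (distribution == "ZINB") template16S(F) else {
        t0 <- template16S(F)
        new("TemplateParams", distribution = "NB",
            relMeans = t0@relMeans, dispersion = t0@dispersion,
            zeroProb = setNames(rep(0, F), names(t0@relMeans)),
            libSizes = t0@libSizes)
    }
    des <- simulationDesign(distribution, nPerGroup = nPerGroup,
                            foldEffect = foldEffect, daProportion = 0.2,
                            seed = seed)
    simulateDataset(des, tpl, 1L, null = null)
}

test_that("every catalogue method returns a valid result on simulated data", {
    sim <- simTwoGroup(F = 40, nPerGroup = 8)
    ct <- simCounts(sim)
    grp <- sampleData(ct)$group
    zfit <- fitModel(ct, "ZINB")
    for (m in daMethods()$method) {
        da <- runDA(ct, grp, m, seed = 7, B = 16L, zinbFit = zfit)
        tab <- daTable(da)
        expect_equal(nrow(tab), 40L, label = m)
        expect_true(all(tab$raw_p >= 0 & tab$raw_p <= 1, na.rm = TRUE),
                    label = m)
        both <- !is.na(tab$raw_p)
        expect_true(all(tab$adj_p[both] >= tab$raw_p[both] - 1e-12),
                    label = m)
        expect_gt(mean(!is.na(tab$raw_p)), 0.5, label = m)
    }
})

test_that("runDA validates its design and never mutates the input", {
    sim <- simTwoGroup(F = 20, nPerGroup = 5)
    ct <- simCounts(sim)
    before <- counts(ct)
    grp <- sampleData(ct)$group
    expect_error(runDA(ct, rep("one", ncol(ct)), "wilcoxon_norm"),
                 "two groups")
    expect_error(runDA(ct, grp, "no_such_method"), "unknown DA method")
    runDA(ct, grp, "wilcoxon_norm")
    expect_identical(counts(ct), before)
})

test_that("rank-sum p-values are 1 when the groups are identical", {
    y <- cbind(a = c(5, 9, 1), b = c(2, 4, 8), a2 = c(5, 9, 1),
               b2 = c(2, 4, 8))
    rownames(y) <- paste0("f", 1:3)
    ct <- CountTable(y)
    da <- runDA(ct, c("g1", "g1", "g2", "g2"), "wilcoxon_norm")
    expect_true(all(daTable(da)$raw_p == 1))
})

test_that("wilcoxon prefilters mark features missing with a reason", {
    sim <- simTwoGroup(F = 50, nPerGroup = 10)
    ct <- simCounts(sim)
    grp <- sampleData(ct)$group
    da <- runDA(ct, grp, "wilcoxon_norm", prevalenceFilter = 0.4,
                lfcFilter = 0.25)
    tab <- daTable(da)
    expect_true(any(is.na(tab$raw_p)))
    expect_true(all(!is.na(tab$missing_reason[is.na(tab$raw_p)])))
    # missing features rank last
    rk <- rankedFeatures(da)
    nMiss <- sum(is.na(tab$raw_p))
    expect_true(all(tail(rk, nMiss) %in%
                        tab$feature_id[is.na(tab$raw_p)]))
})

test_that("the beta-binomial LRT statistic is non-negative everywhere", {
    sim <- simTwoGroup(F = 30, nPerGroup = 8)
    ct <- simCounts(sim)
    da <- runDA(ct, sampleData(ct)$group, "betabin_lrt")
    st <- daTable(da)$statistic
    expect_true(all(st >= 0, na.rm = TRUE))
})

test_that("the Dirichlet-CLR test is reproducible given the seed", {
    sim <- simTwoGroup(F = 25, nPerGroup = 6)
    ct <- simCounts(sim)
    grp <- sampleData(ct)$group
    da1 <- runDA(ct, grp, "dirichlet_clr_wilcoxon", seed = 11, B = 8L)
    da2 <- runDA(ct, grp, "dirichlet_clr_wilcoxon", seed = 11, B = 8L)
    da3 <- runDA(ct, grp, "dirichlet_clr_wilcoxon", seed = 12, B = 8L)
    expect_identical(daTable(da1), daTable(da2))
    expect_false(identical(daTable(da1)$raw_p, daTable(da3)$raw_p))
})

test_that("NB GLM separates injected from null features", {
    sim <- simTwoGroup(F = 100, nPerGroup = 20, foldEffect = 5,
                       distribution = "NB", seed = 19)
    ct <- simCounts(sim)
    da <- runDA(ct, sampleData(ct)$group, "nb_glm_lrt")
    tab <- daTable(da)
    truth <- simTruth(sim)
    pDA <- tab$raw_p[truth$is_da]
    pNull <- tab$raw_p[!truth$is_da]
    expect_lt(median(pDA, na.rm = TRUE), median(pNull, na.rm = TRUE))
    # signed coefficients agree with the injected directions for most
    # strongly significant features
    sig <- which(truth$is_da & !is.na(tab$adj_p) & tab$adj_p < 0.05)
    if (length(sig) >= 5) {
        agree <- (tab$coefficient[sig] > 0) ==
            (truth$direction[sig] == "up")
        expect_gt(mean(agree), 0.8)
    }
})

test_that("ZINB observational weights follow the posterior formula", {
    sim <- simTwoGroup(F = 30, nPerGroup = 8)
    ct <- simCounts(sim)
    fit <- fitModel(ct, "ZINB")
    w <- zinbWeights(ct, fit)
    expect_true(all(w >= 0 & w <= 1))
    expect_true(all(w[counts(ct) > 0] == 1))
    # hand check: pi = 0.5, NB0 = 0.5 -> weight at a zero = 1/3
    fit2 <- fit
    mu <- fit@params$mu
    phi <- fit@params$phi
    piHalf <- setNames(rep(0.5, nrow(ct)), rownames(ct))
    nb0 <- (1 + phi * mu)^(-1 / phi)
    fit2@params$pi <- piHalf
    w2 <- zinbWeights(ct, fit2)
    y <- counts(ct)
    for (f in which(rowSums(y == 0) > 0)[1:3]) {
        j <- which(y[f, ] == 0)[1L]
        expect_equal(w2[f, j],
                     unname(0.5 * nb0[f] / (0.5 + 0.5 * nb0[f])))
    }
    # degenerate mixing
    fit2@params$pi <- setNames(rep(0, nrow(ct)), rownames(ct))
    expect_true(all(zinbWeights(ct, fit2) == 1))
    fit2@params$pi <- setNames(rep(1, nrow(ct)), rownames(ct))
    expect_true(all(zinbWeights(ct, fit2)[y == 0] == 0))
})

test_that("variance moderation matches the shrinkage formula", {
    eb <- empiricalBayesModeration(c(1, 3), c(4, 4), d0 = 4, s02 = 2)
    expect_equal(unname(eb$var), c(1.5, 2.5))
    expect_equal(unname(eb$df), c(8, 8))
    # d0 = 0: no shrinkage
    eb0 <- empiricalBayesModeration(c(1, 3), c(4, 4), d0 = 0, s02 = 2)
    expect_equal(unname(eb0$var), c(1, 3))
    # fixed point: s2 equal to the prior stays put
    ebf <- empiricalBayesModeration(c(2, 2), c(4, 4), d0 = 4, s02 = 2)
    expect_equal(unname(ebf$var), c(2, 2))
    # equal variances: the estimated prior collapses them (d0 = Inf)
    ebe <- empiricalBayesModeration(c(2, 2, 2), c(4, 4, 4))
    expect_true(is.infinite(ebe$d0))
    expect_equal(unname(ebe$var), c(2, 2, 2))
})

test_that("BH adjustment handles missing values and edge cases", {
    expect_equal(adjustBH(c(0.01, 0.02, 0.03)), rep(0.03, 3))
    expect_equal(adjustBH(0.2), 0.2)
    expect_equal(adjustBH(c(0.05, NA)), c(0.05, NA))
    expect_error(adjustBH(c(0.5, 1.2)), "\\[0, 1\\]")
    p <- c(0.4, NA, 0.01, 0.9, NA, 0.2)
    a <- adjustBH(p)
    expect_equal(is.na(a), is.na(p))
    expect_true(all(a >= p, na.rm = TRUE))
})

test_that("plugins can be registered and share the result contract", {
    sim <- simTwoGroup(F = 15, nPerGroup = 5)
    ct <- simCounts(sim)
    grp <- sampleData(ct)$group
    registerDAMethod("test_random_rank", function(ct, group, seed, ...) {
        ids <- rownames(ct)
        withr::with_seed(seed,
            data.frame(feature_id = ids, coefficient = rnorm(length(ids)),
                       statistic = NA_real_, raw_p = NA_real_,
                       rank_score = runif(length(ids))))
    }, norm = "none")
    expect_true("test_random_rank" %in% daMethods()$method)
    da <- runDA(ct, grp, "test_random_rank", seed = 3)
    expect_s4_class(da, "DAResult")
    expect_equal(length(rankedFeatures(da)), 15L)
    expect_error(registerDAMethod("nb_glm_lrt", identity), "built-in")
    # TSV round trip of the plugin exchange format
    path <- withr::local_tempfile(fileext = ".tsv")
    writeDAResult(da, path)
    da2 <- readDAResult(path, method = "test_random_rank")
    expect_equal(rankedFeatures(da2), rankedFeatures(da))
})
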