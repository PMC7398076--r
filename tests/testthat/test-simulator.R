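test_that("templates satisfy their own contracts", {
    for (mk in list(template16S, templateWMS)) {
        tpl <- mk(200)
        expect_equal(sum(tpl@relMeans), 1, tolerance = 1e-12)
        expect_true(all(tpl@relMeans > 0))
        expect_true(all(tpl@zeroProb >= 0 & tpl@zeroProb <= 1))
    }
    # deterministic: same arguments, same template
    expect_identical(template16S(100)@relMeans, template16S(100)@relMeans)
})

test_that("template estimation recovers known relative means", {
    tpl <- template16S(60)
    des <- simulationDesign("NB", nPerGroup = 100L, seed = 31)
    tplNB <- new("TemplateParams", distribution = "NB",
                 relMeans = tpl@relMeans, dispersion = 0.4,
                 zeroProb = setNames(rep(0, 60), names(tpl@relMeans)),
                 libSizes = rep(5e4, 40))
    sim <- simulateDataset(des, tplNB, 1L, null = TRUE)
    est <- estimateTemplate(simCounts(sim), "NB")
    expect_equal(sum(est@relMeans), 1, tolerance = 1e-10)
    # abundant features (expected count > 10 per sample) recover within
    # ~10% relative error
    abund <- tplNB@relMeans > 10 / 5e4
    relErr <- abs(est@relMeans[abund] - tplNB@relMeans[abund]) /
        tplNB@relMeans[abund]
    expect_lt(median(relErr), 0.1)
    # ZINB template on (almost) zero-free data: negligible inflation
    estZ <- estimateTemplate(simCounts(sim), "ZINB")
    expect_lt(stats::quantile(estZ@zeroProb[abund], 0.9), 0.05)
})

test_that("DA injection follows the flag-count and fold rules", {
    tpl <- template16S(250)
    inj <- injectDA(tpl, proportion = 0.10, foldEffect = 2,
                    compensation = FALSE, seed = 5)
    expect_equal(sum(inj$isDA), 25L)       # round(0.10 * 250)
    up <- inj$direction == "up"
    down <- inj$direction == "down"
    # parameter-scale ratios before renormalization
    expect_equal(unname(inj$modifiedUnnormalized[up] / tpl@relMeans[up]),
                 rep(2, sum(up)))
    expect_equal(unname(inj$modifiedUnnormalized[down] /
                            tpl@relMeans[down]),
                 rep(0.5, sum(down)))
    expect_equal(sum(inj$relMeans2), 1, tolerance = 1e-12)
    expect_error(injectDA(tpl, proportion = 0.001, foldEffect = 2),
                 "at least 2")
})

test_that("compensation conserves flagged mass and fixes unflagged means", {
    tpl <- templateWMS(300)
    for (seed in c(1, 7, 19)) {
        inj <- injectDA(tpl, proportion = 0.5, foldEffect = 5,
                        compensation = TRUE, seed = seed)
        flag <- inj$isDA
        # a*FE + a*(1 - FE) + b = a + b: mass conserved pre-normalization
        expect_equal(sum(inj$modifiedUnnormalized[flag]),
                     sum(tpl@relMeans[flag]), tolerance = 1e-12)
        # hence unflagged features are untouched after renormalization
        expect_equal(inj$relMeans2[!flag], tpl@relMeans[!flag],
                     tolerance = 1e-12)
        expect_equal(sum(inj$relMeans2), 1, tolerance = 1e-12)
    }
})

test_that("sparsity effects shift and clamp the mixing probabilities", {
    tpl <- template16S(50)
    inj <- injectDA(tpl, 0.2, 2, seed = 3)
    same <- applySparsityEffect(tpl, inj$direction, 0)
    expect_equal(same$zeroProb2, tpl@zeroProb)
    eff <- applySparsityEffect(tpl, inj$direction, 0.15)
    up <- inj$direction == "up"
    down <- inj$direction == "down"
    none <- inj$direction == "none"
    expect_equal(eff$zeroProb2[none], tpl@zeroProb[none])
    expect_equal(eff$zeroProb2[up],
                 pmax(tpl@zeroProb[up] - 0.15, 0))
    expect_equal(eff$zeroProb2[down],
                 pmin(tpl@zeroProb[down] + 0.15, 1))
    # explicit clamp: 0.99 + 0.05 -> 1
    tpl2 <- tpl
    tpl2@zeroProb[down][1L] <- 0.99
    eff2 <- applySparsityEffect(tpl2, inj$direction, 0.05)
    expect_equal(unname(eff2$zeroProb2[down][1L]), 1)
})

test_that("simulation is reproducible and respects the null construction", {
    tpl <- template16S(80)
    des <- simulationDesign("ZINB", nPerGroup = 10, seed = 13)
    s1 <- simulateDataset(des, tpl, replicate = 2L)
    s2 <- simulateDataset(des, tpl, replicate = 2L)
    expect_identical(counts(simCounts(s1)), counts(simCounts(s2)))
    s3 <- simulateDataset(des, tpl, replicate = 3L)
    expect_false(identical(counts(simCounts(s1)), counts(simCounts(s3))))
    # null datasets carry no flags and equal group parameters
    sNull <- simulateDataset(des, tpl, 1L, null = TRUE)
    expect_true(all(!simTruth(sNull)$is_da))
    expect_equal(simParams(sNull)$relMeans1, simParams(sNull)$relMeans2)
    # truth flags match the design proportion
    expect_equal(sum(simTruth(s1)$is_da), round(0.1 * 80))
})

test_that("ZINB with pi = 0 matches the NB simulation sparsity", {
    base <- template16S(100)
    piZero <- setNames(rep(0, 100), names(base@relMeans))
    tplZ <- new("TemplateParams", distribution = "ZINB",
                relMeans = base@relMeans, dispersion = base@dispersion,
                zeroProb = piZero, libSizes = base@libSizes)
    tplN <- new("TemplateParams", distribution = "NB",
                relMeans = base@relMeans, dispersion = base@dispersion,
                zeroProb = piZero, libSizes = base@libSizes)
    desZ <- simulationDesign("ZINB", nPerGroup = 15, seed = 17)
    desN <- simulationDesign("NB", nPerGroup = 15, seed = 17)
    zfZ <- vapply(1:20, function(r)
        zeroFraction(simCounts(simulateDataset(desZ, tplZ, r,
                                               null = TRUE)))$overall,
        numeric(1))
    zfN <- vapply(1:20, function(r)
        zeroFraction(simCounts(simulateDataset(desN, tplN, r,
                                               null = TRUE)))$overall,
        numeric(1))
    se <- sqrt(var(zfZ) / 20 + var(zfN) / 20)
    expect_lt(abs(mean(zfZ) - mean(zfN)), 3 * se + 0.005)
})

test_that("the partial AUROC agrees with an independent ROC library", {
    skip_if_not_installed("pROC")
    withr::with_seed(31, {
        truth <- rep(c(TRUE, FALSE), times = c(30, 70))
        score <- ifelse(truth, rnorm(100, 1.2), rnorm(100))
        names(truth) <- sprintf("f%03d", 1:100)
        ranked <- names(truth)[order(-score)]
        mine <- sparseDA:::.partialAuroc(ranked, truth, maxFpr = 1)
        ref <- as.numeric(pROC::auc(pROC::roc(
            response = truth, predictor = score, quiet = TRUE,
            direction = "<")))
        expect_equal(mine, ref, tolerance = 1e-10)
        minePart <- sparseDA:::.partialAuroc(ranked, truth, maxFpr = 0.1)
        refPart <- as.numeric(pROC::auc(pROC::roc(
            response = truth, predictor = score, quiet = TRUE,
            direction = "<"), partial.auc = c(1, 0.9),
            partial.auc.focus = "specificity",
            partial.auc.correct = FALSE))
        expect_equal(minePart, refPart, tolerance = 1e-10)
    })
})

test_that("power metrics recognize oracle and chance rankings", {
    tpl <- template16S(100)
    des <- simulationDesign("ZINB", nPerGroup = 10, foldEffect = 5,
                            seed = 23)
    sim <- simulateDataset(des, tpl, 1L)
    truth <- simTruth(sim)
    ids <- truth$feature_id
    # oracle plugin: p = 0 on true DA, 1 elsewhere
    registerDAMethod("test_oracle", function(ct, group, seed, ...) {
        p <- ifelse(truth$is_da, 1e-12, 1)
        data.frame(feature_id = ids, coefficient = 1, statistic = 1,
                   raw_p = p)
    })
    pw <- powerEvaluation(list(sim), "test_oracle")
    expect_equal(pw$tpr, 1)
    expect_equal(pw$fpr, 0)
    expect_equal(pw$pauroc_raw, 0.1, tolerance = 1e-12)
    expect_equal(pw$pauroc_norm, 1, tolerance = 1e-12)
    # chance-level ranking: normalized pAUROC ~ 0.05 on average
    registerDAMethod("test_coinflip", function(ct, group, seed, ...) {
        withr::with_seed(seed, data.frame(
            feature_id = ids, coefficient = 0, statistic = 0,
            raw_p = runif(length(ids))))
    })
    sims <- lapply(1:40, function(r) simulateDataset(des, tpl, r))
    pwC <- powerEvaluation(sims, "test_coinflip", seed = 2)
    expect_lt(abs(pwC$pauroc_norm - 0.05), 0.02)
})
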