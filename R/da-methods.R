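## The built-in differential abundance methods, behind one contract:
## every method receives a CountTable and a two-level grouping and returns
## a DAResult with a signed coefficient (group2 vs group1, groups ordered
## lexicographically), a statistic, raw and BH-adjusted p-values and a
## missing-reason code for untested features.

.daResult <- function(method, norm, featureIds, coefficient, statistic,
                      rawP, rankScore = NULL, missingReason = NULL) {
    nf <- length(featureIds)
    fill <- function(x) {
        if (is.null(x))
            return(rep(NA_real_, nf))
        stopifnot(length(x) == nf)
        unname(x)
    }
    rawP <- fill(rawP)
    mr <- if (is.null(missingReason)) rep(NA_character_, nf)
          else unname(missingReason)
    mr[is.na(rawP) & is.na(mr)] <- "not_tested"
    tab <- DataFrame(feature_id = featureIds,
                     coefficient = fill(coefficient),
                     statistic = fill(statistic),
                     raw_p = rawP,
                     adj_p = adjustBH(rawP),
                     rank_score = fill(rankScore),
                     missing_reason = mr)
    new("DAResult", method = method, norm = norm, table = tab)
}

#' @describeIn runDA result table accessor (data.frame, one row per
#'   feature).
#' @param da a [DAResult-class].
#' @export
daTable <- function(da) {
    stopifnot(is(da, "DAResult"))
    as.data.frame(da@table)
}

#' @describeIn runDA method label accessor.
#' @export
daMethodName <- function(da) {
    stopifnot(is(da, "DAResult"))
    da@method
}

#' @describeIn runDA normalization label accessor.
#' @export
daNorm <- function(da) {
    stopifnot(is(da, "DAResult"))
    da@norm
}

setMethod("show", "DAResult", function(object) {
    tab <- object@table
    cat(sprintf("DAResult '%s' (normalization: %s): %d features, %d tested\n",
                object@method, object@norm, nrow(tab),
                sum(!is.na(tab$raw_p))))
    invisible(NULL)
})

.groupDesign <- function(ct, group) {
    group <- as.character(group)
    if (length(group) != ncol(ct))
        stop("group labels must match the number of samples")
    lev <- sort(unique(group))
    if (length(lev) != 2L)
        stop("exactly two groups are required")
    if (min(table(group)) < 2L)
        stop("each group needs at least two samples")
    g2 <- group == lev[2L]
    design <- cbind(`(Intercept)` = 1, group2 = as.numeric(g2))
    list(design = design, g2 = g2, levels = lev)
}

.edgerDGE <- function(ct, norm = c("TMM", "poscounts")) {
    norm <- match.arg(norm)
    nf <- normFactors(ct, norm)
    d <- edgeR::DGEList(counts = counts(ct))
    d$samples$lib.size <- exp(unname(normOffsets(nf)))
    d$samples$norm.factors <- rep(1, ncol(ct))
    d
}

.daNbGlm <- function(ct, group, norm = "TMM", test = c("lrt", "robust"),
                     weights = NULL, method) {
    test <- match.arg(test)
    gd <- .groupDesign(ct, group)
    d <- .edgerDGE(ct, norm)
    if (!is.null(weights))
        d$weights <- weights
    if (test == "robust") {
        d <- edgeR::estimateGLMRobustDisp(d, gd$design)
        fit <- edgeR::glmQLFit(d, gd$design)
        res <- edgeR::glmQLFTest(fit, coef = 2L)
    } else {
        d <- edgeR::estimateDisp(d, gd$design)
        fit <- edgeR::glmFit(d, gd$design,
                             dispersion = d$tagwise.dispersion)
        res <- edgeR::glmLRT(fit, coef = 2L)
    }
    tab <- res$table
    .daResult(method, norm, rownames(ct),
              coefficient = tab$logFC,
              statistic = if (test == "robust") tab$F else tab$LR,
              rawP = tab$PValue)
}

.daNbWald <- function(ct, group, method = "nb_glm_wald") {
    gd <- .groupDesign(ct, group)
    grp <- factor(ifelse(gd$g2, "grp2", "grp1"), levels = c("grp1", "grp2"))
    sf <- normFactorValues(normFactors(ct, "poscounts"))
    sf <- sf / exp(mean(log(sf)))
    dds <- DESeq2::DESeqDataSetFromMatrix(
        countData = counts(ct),
        colData = S4Vectors::DataFrame(group = grp),
        design = ~group)
    DESeq2::sizeFactors(dds) <- unname(sf)
    dds <- DESeq2::estimateDispersions(dds, fitType = "local", quiet = TRUE)
    dds <- DESeq2::nbinomWaldTest(dds)
    res <- DESeq2::results(dds, name = "group_grp2_vs_grp1")
    mr <- ifelse(is.na(res$pvalue), "outlier_or_filtered", NA_character_)
    .daResult(method, "poscounts", rownames(ct),
              coefficient = res$log2FoldChange,
              statistic = res$stat,
              rawP = res$pvalue,
              missingReason = mr)
}

.daModeratedT <- function(ct, group, norm = "TMM", zinbW = NULL,
                          method = "moderated_t_logcpm") {
    gd <- .groupDesign(ct, group)
    d <- .edgerDGE(ct, norm)
    v <- limma::voom(d, gd$design)
    if (!is.null(zinbW)) {
        v$weights <- v$weights * zinbW
        fit <- limma::lmFit(v, gd$design)
        ## residual df adjusted for downweighted observations before the
        ## empirical-Bayes shrinkage (sum of weights minus rank)
        fit$df.residual <- pmax(rowSums(zinbW) - ncol(gd$design), 1)
    } else {
        fit <- limma::lmFit(v, gd$design)
    }
    fit <- limma::eBayes(fit)
    .daResult(method, norm, rownames(ct),
              coefficient = fit$coefficients[, 2L],
              statistic = fit$t[, 2L],
              rawP = fit$p.value[, 2L])
}

.daWilcoxon <- function(ct, group, prevalenceFilter = 0, lfcFilter = 0,
                        method = "wilcoxon_norm") {
    gd <- .groupDesign(ct, group)
    y <- counts(ct)
    lib <- libSizes(ct)
    dat <- log1p(sweep(y, 2L, 1e4 / lib, "*"))   # log-normalized counts
    coef <- rowMeans(dat[, gd$g2, drop = FALSE]) -
        rowMeans(dat[, !gd$g2, drop = FALSE])
    tested <- rep(TRUE, nrow(y))
    reason <- rep(NA_character_, nrow(y))
    if (prevalenceFilter > 0) {
        prev <- pmax(rowMeans(y[, gd$g2, drop = FALSE] > 0),
                     rowMeans(y[, !gd$g2, drop = FALSE] > 0))
        drop <- prev < prevalenceFilter
        tested[drop] <- FALSE
        reason[drop] <- "low_prevalence"
    }
    if (lfcFilter > 0) {
        drop <- tested & abs(coef) < lfcFilter
        tested[drop] <- FALSE
        reason[drop] <- "small_effect"
    }
    p <- rep(NA_real_, nrow(y))
    stat <- rep(NA_real_, nrow(y))
    if (any(tested)) {
        wt <- .rowWilcoxon(dat[tested, , drop = FALSE], gd$g2, ties = TRUE)
        p[tested] <- wt$p
        stat[tested] <- wt$statistic
    }
    .daResult(method, "TSS", rownames(y),
              coefficient = coef, statistic = stat, rawP = p,
              missingReason = reason)
}

.daZigEmT <- function(ct, group, method = "zig_em_t") {
    gd <- .groupDesign(ct, group)
    tr <- transformCounts(ct, "css_log_median")
    t <- tr$matrix
    o <- tr$offsets
    x <- log(libSizes(ct))
    design <- gd$design
    nf <- nrow(t)
    coef <- stat <- p <- rep(NA_real_, nf)
    reason <- rep(NA_character_, nf)
    s2 <- df <- cinv <- rep(NA_real_, nf)
    betas <- rep(NA_real_, nf)
    for (f in seq_len(nf)) {
        em <- .zigEmFeature(t[f, ], o, x, design)
        if (!isTRUE(em$converged)) {
            reason[f] <- "em_not_converged"
            next
        }
        w <- em$weights
        XtWX <- crossprod(design * w, design)
        ci <- try(solve(XtWX), silent = TRUE)
        if (inherits(ci, "try-error")) {
            reason[f] <- "singular_design"
            next
        }
        resid <- t[f, ] - o - drop(design %*% em$beta)
        dfres <- sum(w) - ncol(design)
        if (dfres < 1) {
            reason[f] <- "insufficient_weight"
            next
        }
        s2[f] <- sum(w * resid^2) / dfres
        df[f] <- dfres
        cinv[f] <- ci[2L, 2L]
        betas[f] <- em$beta[2L]
    }
    ok <- is.finite(s2)
    if (sum(ok) >= 2L) {
        eb <- empiricalBayesModeration(s2[ok], pmax(df[ok], 1))
        tt <- betas[ok] / sqrt(eb$var * cinv[ok])
        pp <- 2 * stats::pt(-abs(tt), df = eb$df)
        coef[ok] <- betas[ok]
        stat[ok] <- tt
        p[ok] <- pp
    }
    .daResult(method, "CSS", rownames(t),
              coefficient = coef, statistic = stat, rawP = p,
              missingReason = reason)
}

.daDirichletClr <- function(ct, group, B = 128L, seed = 1L,
                            method = "dirichlet_clr_wilcoxon") {
    gd <- .groupDesign(ct, group)
    y <- counts(ct)
    nf <- nrow(y)
    n <- ncol(y)
    withr::with_seed(seed, {
        pSum <- numeric(nf)
        zSum <- numeric(nf)
        effSum <- numeric(nf)
        for (b in seq_len(B)) {
            ## per-sample Dirichlet draw on counts + 0.5 via gammas
            g <- matrix(stats::rgamma(nf * n, shape = y + 0.5), nf, n)
            lp <- log(sweep(g, 2L, colSums(g), "/"))
            ## iqlr denominator: features whose CLR variance lies between
            ## the first and third quartile
            clr0 <- sweep(lp, 2L, colMeans(lp))
            v <- matrixStats::rowVars(clr0)
            qs <- stats::quantile(v, c(0.25, 0.75))
            idx <- v >= qs[1L] & v <= qs[2L]
            if (!any(idx))
                idx <- rep(TRUE, nf)
            clr <- sweep(lp, 2L, colMeans(lp[idx, , drop = FALSE]))
            wt <- .rowWilcoxon(clr, gd$g2, ties = FALSE)
            pSum <- pSum + wt$p
            zSum <- zSum + wt$statistic
            effSum <- effSum +
                rowMeans(clr[, gd$g2, drop = FALSE]) -
                rowMeans(clr[, !gd$g2, drop = FALSE])
        }
    })
    .daResult(method, "CLR", rownames(y),
              coefficient = effSum / B, statistic = zSum / B,
              rawP = pmin(pSum / B, 1))
}

## Beta-binomial log-likelihood, (a, b) parametrization from mean p and
## intra-class correlation rho: a = p(1-rho)/rho, b = (1-p)(1-rho)/rho.
.bbNegLogLik <- function(par, y, n, x) {
    p <- stats::plogis(drop(x %*% par[seq_len(ncol(x))]))
    rho <- stats::plogis(par[length(par)])
    rho <- pmin(pmax(rho, 1e-8), 1 - 1e-8)
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    a <- p * (1 - rho) / rho
    b <- (1 - p) * (1 - rho) / rho
    -sum(lbeta(y + a, n - y + b) - lbeta(a, b))
}

.daBetaBinomial <- function(ct, group, test = c("wald", "lrt"),
                            method = paste0("betabin_", test[1L])) {
    test <- match.arg(test)
    gd <- .groupDesign(ct, group)
    y <- counts(ct)
    lib <- libSizes(ct)
    nf <- nrow(y)
    coef <- stat <- p <- rep(NA_real_, nf)
    reason <- rep(NA_character_, nf)
    x0 <- matrix(1, ncol(y), 1L)
    x1 <- gd$design
    for (f in seq_len(nf)) {
        yf <- y[f, ]
        p0hat <- min(max(sum(yf) / sum(lib), 1e-8), 1 - 1e-8)
        start0 <- c(stats::qlogis(p0hat), stats::qlogis(0.01))
        fit0 <- try(optim(start0, .bbNegLogLik, y = yf, n = lib, x = x0,
                          method = "BFGS",
                          control = list(maxit = 200)), silent = TRUE)
        if (inherits(fit0, "try-error")) {
            reason[f] <- "no_convergence"
            next
        }
        start1 <- c(fit0$par[1L], 0, fit0$par[2L])
        fit1 <- try(optim(start1, .bbNegLogLik, y = yf, n = lib, x = x1,
                          method = "BFGS", hessian = (test == "wald"),
                          control = list(maxit = 200)), silent = TRUE)
        if (inherits(fit1, "try-error")) {
            reason[f] <- "no_convergence"
            next
        }
        coef[f] <- fit1$par[2L]
        if (test == "lrt") {
            ## the full fit starts from the null optimum, so the deviance
            ## difference is non-negative by construction
            stat[f] <- max(2 * (fit0$value - fit1$value), 0)
            p[f] <- stats::pchisq(stat[f], df = 1L, lower.tail = FALSE)
        } else {
            vc <- try(solve(fit1$hessian), silent = TRUE)
            se <- if (inherits(vc, "try-error") || vc[2L, 2L] <= 0)
                NA_real_ else sqrt(vc[2L, 2L])
            if (is.na(se)) {
                reason[f] <- "singular_information"
                coef[f] <- NA_real_
                next
            }
            stat[f] <- fit1$par[2L] / se
            p[f] <- 2 * stats::pnorm(-abs(stat[f]))
        }
    }
    .daResult(method, "none", rownames(y),
              coefficient = coef, statistic = stat, rawP = p,
              missingReason = reason)
}

.daHurdle <- function(ct, group, method = "hurdle_chisq") {
    gd <- .groupDesign(ct, group)
    tr <- transformCounts(ct, "log2_median_libsize")
    t <- tr$matrix
    y <- counts(ct)
    cdr <- detectionRates(ct)
    nf <- nrow(y)
    xFull <- cbind(gd$design, cdr = cdr)
    xNull <- cbind(1, cdr = cdr)
    coef <- stat <- p <- rep(NA_real_, nf)
    reason <- rep(NA_character_, nf)
    for (f in seq_len(nf)) {
        pos <- y[f, ] > 0
        chisq <- 0
        df <- 0L
        cf <- NA_real_
        ## discrete part: logistic LRT on the detection indicator
        if (any(pos) && !all(pos)) {
            g1 <- try(suppressWarnings(stats::glm.fit(xFull,
                      as.numeric(pos), family = stats::binomial())),
                      silent = TRUE)
            g0 <- try(suppressWarnings(stats::glm.fit(xNull,
                      as.numeric(pos), family = stats::binomial())),
                      silent = TRUE)
            if (!inherits(g1, "try-error") && !inherits(g0, "try-error")) {
                chisq <- chisq + max(g0$deviance - g1$deviance, 0)
                df <- df + 1L
                cf <- g1$coefficients[2L]
            }
        }
        ## continuous part: Gaussian LRT on the positive log counts
        if (sum(pos) > ncol(xFull) &&
            length(unique(gd$g2[pos])) == 2L) {
            l1 <- stats::lm.fit(xFull[pos, , drop = FALSE], t[f, pos])
            l0 <- stats::lm.fit(xNull[pos, , drop = FALSE], t[f, pos])
            rss1 <- sum(l1$residuals^2)
            rss0 <- sum(l0$residuals^2)
            if (rss1 > 0) {
                chisq <- chisq + sum(pos) * log(rss0 / rss1)
                df <- df + 1L
                cf <- l1$coefficients[2L]   # log2-scale group effect
            }
        }
        if (df == 0L) {
            reason[f] <- "degenerate"
            next
        }
        coef[f] <- cf
        stat[f] <- chisq
        p[f] <- stats::pchisq(chisq, df = df, lower.tail = FALSE)
    }
    .daResult(method, "none", rownames(y),
              coefficient = coef, statistic = stat, rawP = p,
              missingReason = reason)
}

.builtinCatalog <- function() {
    list(
        nb_glm_lrt = list(
            norm = "TMM",
            fun = function(ct, group, seed, ...)
                .daNbGlm(ct, group, norm = "TMM", test = "lrt",
                         method = "nb_glm_lrt")),
        nb_glm_lrt_poscounts = list(
            norm = "poscounts",
            fun = function(ct, group, seed, ...)
                .daNbGlm(ct, group, norm = "poscounts", test = "lrt",
                         method = "nb_glm_lrt_poscounts")),
        nb_glm_wald = list(
            norm = "poscounts",
            fun = function(ct, group, seed, ...) .daNbWald(ct, group)),
        nb_glm_robust = list(
            norm = "TMM",
            fun = function(ct, group, seed, ...)
                .daNbGlm(ct, group, norm = "TMM", test = "robust",
                         method = "nb_glm_robust")),
        moderated_t_logcpm = list(
            norm = "TMM",
            fun = function(ct, group, seed, ...)
                .daModeratedT(ct, group, norm = "TMM")),
        wilcoxon_norm = list(
            norm = "TSS",
            fun = function(ct, group, seed, prevalenceFilter = 0,
                           lfcFilter = 0, ...)
                .daWilcoxon(ct, group, prevalenceFilter, lfcFilter)),
        zig_em_t = list(
            norm = "CSS",
            fun = function(ct, group, seed, ...) .daZigEmT(ct, group)),
        dirichlet_clr_wilcoxon = list(
            norm = "CLR",
            fun = function(ct, group, seed, B = 128L, ...)
                .daDirichletClr(ct, group, B = B, seed = seed)),
        betabin_wald = list(
            norm = "none",
            fun = function(ct, group, seed, ...)
                .daBetaBinomial(ct, group, test = "wald",
                                method = "betabin_wald")),
        betabin_lrt = list(
            norm = "none",
            fun = function(ct, group, seed, ...)
                .daBetaBinomial(ct, group, test = "lrt",
                                method = "betabin_lrt")),
        hurdle_chisq = list(
            norm = "none",
            fun = function(ct, group, seed, ...) .daHurdle(ct, group)),
        nb_glm_zinbweights = list(
            norm = "TMM",
            fun = function(ct, group, seed, zinbFit = NULL, ...) {
                w <- .zinbWeightsFor(ct, zinbFit)
                .daNbGlm(ct, group, norm = "TMM", test = "lrt",
                         weights = w, method = "nb_glm_zinbweights")
            }),
        moderated_t_zinbweights = list(
            norm = "TMM",
            fun = function(ct, group, seed, zinbFit = NULL, ...) {
                w <- .zinbWeightsFor(ct, zinbFit)
                .daModeratedT(ct, group, norm = "TMM", zinbW = w,
                              method = "moderated_t_zinbweights")
            })
    )
}

.zinbWeightsFor <- function(ct, zinbFit = NULL) {
    if (is.null(zinbFit))
        zinbFit <- fitModel(ct, "ZINB")
    zinbWeights(ct, zinbFit)
}

.daRegistry <- new.env(parent = emptyenv())

#' The DA method catalogue
#'
#' Lists the built-in differential abundance methods together with the
#' normalization scheme each declares (so results can be grouped by
#' normalization), plus any plugin registered with [registerDAMethod()].
#'
#' @return A data.frame with columns `method` and `norm`.
#' @export
daMethods <- function() {
    cat <- .builtinCatalog()
    extra <- ls(.daRegistry)
    data.frame(
        method = c(names(cat), extra),
        norm = c(vapply(cat, `[[`, character(1L), "norm"),
                 vapply(extra, function(n) .daRegistry[[n]]$norm,
                        character(1L))),
        row.names = NULL)
}

#' Register a plugin DA method
#'
#' A plugin is any function with signature `function(ct, group, seed, ...)`
#' returning either a [DAResult-class] or a data.frame with columns
#' `feature_id`, `coefficient`, `statistic`, `raw_p` (and optionally
#' `rank_score`); external tools can be wrapped by reading their TSV
#' output.
#'
#' @param name method name.
#' @param fun the plugin function.
#' @param norm normalization label the method declares (default `"none"`).
#' @return Invisibly, `name`.
#' @export
registerDAMethod <- function(name, fun, norm = "none") {
    stopifnot(is.character(name), length(name) == 1L, is.function(fun))
    if (name %in% names(.builtinCatalog()))
        stop("cannot overwrite built-in method '", name, "'")
    assign(name, list(fun = fun, norm = norm), envir = .daRegistry)
    invisible(name)
}

#' Run a differential abundance method
#'
#' Runs one catalogue method (or registered plugin) on a two-group count
#' table. Coefficients are signed group2 vs group1, with the groups ordered
#' lexicographically (the first level is the reference). Stochastic methods
#' are reproducible given `seed`. The input table is never modified.
#'
#' @param ct a [CountTable-class].
#' @param group two-level grouping vector, one label per sample.
#' @param method method name; see [daMethods()].
#' @param seed integer seed for stochastic methods.
#' @param ... method-specific options (e.g. `B` for
#'   `dirichlet_clr_wilcoxon`, `prevalenceFilter`/`lfcFilter` for
#'   `wilcoxon_norm`, `zinbFit` to reuse a ZINB fit for the weighted
#'   methods).
#' @return A [DAResult-class].
#' @examples
#' sim <- simulateDataset(simulationDesign(nPerGroup = 10), template16S(60))
#' da <- runDA(simCounts(sim), sampleData(simCounts(sim))$group,
#'             "wilcoxon_norm")
#' head(daTable(da))
#' @export
runDA <- function(ct, group, method, seed = 1L, ...) {
    stopifnot(is(ct, "CountTable"))
    cat <- .builtinCatalog()
    entry <- if (method %in% names(cat))
        cat[[method]]
    else if (exists(method, envir = .daRegistry))
        .daRegistry[[method]]
    else
        stop("unknown DA method '", method, "'; see daMethods()")
    res <- entry$fun(ct, group, seed, ...)
    if (is.data.frame(res)) {
        res <- .daResult(method, entry$norm, res$feature_id,
                         res$coefficient, res$statistic, res$raw_p,
                         rankScore = res$rank_score)
    }
    stopifnot(is(res, "DAResult"))
    res
}

#' Write / read a DAResult as TSV (the plugin exchange format)
#'
#' @param da a [DAResult-class].
#' @param path TSV path.
#' @return `writeDAResult` invisibly returns `path`; `readDAResult`
#'   returns a [DAResult-class].
#' @export
writeDAResult <- function(da, path) {
    utils::write.table(daTable(da), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeDAResult
#' @param method,norm labels for the result read from `path`.
#' @export
readDAResult <- function(path, method = "plugin", norm = "none") {
    tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    .daResult(method, norm, tab$feature_id, tab$coefficient,
              tab$statistic, tab$raw_p,
              rankScore = if ("rank_score" %in% colnames(tab))
                  tab$rank_score else NULL)
}
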