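## Partial area under the ROC curve of a ranking, restricted to
## FPR in [0, maxFpr]. `ranked` is the feature order (best first),
## `positive` a named logical of ground-truth flags.
.partialAuroc <- function(ranked, positive, maxFpr = 0.1) {
    lab <- positive[ranked]
    nP <- sum(positive)
    nN <- sum(!positive)
    if (nP == 0L || nN == 0L)
        return(NA_real_)
    tp <- 0
    fp <- 0
    area <- 0
    stepN <- 1 / nN
    for (l in lab) {
        if (l) {
            tp <- tp + 1
        } else {
            fprBefore <- fp / nN
            fp <- fp + 1
            fprAfter <- fp / nN
            if (fprBefore >= maxFpr)
                break
            width <- min(fprAfter, maxFpr) - fprBefore
            area <- area + width * (tp / nP)
        }
    }
    ## ranking exhausted before reaching maxFpr: remaining features are
    ## unranked; extend horizontally with the final TPR
    fprNow <- fp / nN
    if (fprNow < maxFpr)
        area <- area + (maxFpr - fprNow) * (tp / nP)
    area
}

#' Power evaluation of DA methods on simulated datasets
#'
#' Runs each method on each simulated dataset and scores it against the
#' ground truth: TPR and FPR of the `adj_p < alpha` calls, and the partial
#' area under the ROC curve of the raw-p ranking (missing p-values ranked
#' last) restricted to FPR in `[0, 0.1]` — reported both raw (maximum 0.1)
#' and normalized to `[0, 1]`. All metrics are averaged over replicates;
#' datasets on which a method fails are dropped for that method only, with
#' a count.
#'
#' @param sims list of [SimulatedDataset-class] objects (replicates of one
#'   design).
#' @param methods character vector of catalogue method names.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param maxFpr upper FPR bound of the partial AUROC (default 0.1).
#' @param seed integer seed passed to stochastic methods.
#' @param zinbWeightsCache precompute the ZINB fit once per dataset when
#'   any `*_zinbweights` method is requested (default `TRUE`).
#' @param ... passed to [runDA()].
#' @return A data.frame with one row per method: `tpr`, `fpr`,
#'   `pauroc_raw`, `pauroc_norm`, `n_replicates`, `failures`.
#' @export
powerEvaluation <- function(sims, methods, alpha = 0.05, maxFpr = 0.1,
                            seed = 1L, zinbWeightsCache = TRUE, ...) {
    stopifnot(length(sims) >= 1L)
    acc <- list()
    fail <- setNames(integer(length(methods)), methods)
    needZinb <- zinbWeightsCache && any(grepl("zinbweights", methods))
    for (i in seq_along(sims)) {
        sim <- sims[[i]]
        ct <- simCounts(sim)
        truth <- simTruth(sim)
        positive <- setNames(truth$is_da, truth$feature_id)
        grp <- sampleData(ct)$group
        zfit <- if (needZinb) fitModel(ct, "ZINB") else NULL
        for (m in methods) {
            da <- try(runDA(ct, grp, m, seed = .subSeed(seed, 4L, i),
                            zinbFit = zfit, ...), silent = TRUE)
            if (inherits(da, "try-error")) {
                fail[m] <- fail[m] + 1L
                next
            }
            tab <- daTable(da)
            called <- !is.na(tab$adj_p) & tab$adj_p < alpha
            pos <- positive[tab$feature_id]
            tpr <- if (sum(pos)) sum(called & pos) / sum(pos) else NA_real_
            fpr <- if (sum(!pos)) sum(called & !pos) / sum(!pos)
                   else NA_real_
            pauc <- .partialAuroc(rankedFeatures(da), positive, maxFpr)
            acc[[length(acc) + 1L]] <- data.frame(
                method = m, replicate = i, tpr = tpr, fpr = fpr,
                pauroc_raw = pauc, pauroc_norm = pauc / maxFpr)
        }
    }
    if (!length(acc))
        stop("all method runs failed")
    df <- do.call(rbind, acc)
    agg <- stats::aggregate(
        cbind(tpr, fpr, pauroc_raw, pauroc_norm) ~ method, data = df,
        FUN = function(x) mean(x, na.rm = TRUE), na.action = stats::na.pass)
    reps <- table(df$method)
    agg$n_replicates <- as.integer(reps[agg$method])
    agg$failures <- fail[agg$method]
    rownames(agg) <- NULL
    agg
}
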