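#' Directional enrichment of metabolism classes among DA features
#'
#' Features with `adj_p < alpha` (or, for methods that only return an
#' importance score, the top `topFraction` of the ranking) form the DA
#' set; the sign of the coefficient assigns each DA feature a direction
#' (UP = over-abundant in group 2's reference comparison). For each
#' metabolism class (aerobic, anaerobic, facultative) and direction, a
#' one-sided Fisher exact test (`alternative = "greater"`) on the 2x2
#' table (class membership x directional DA membership) scores the
#' enrichment, and the log odds-ratio is computed with the
#' Haldane-Anscombe correction (+0.5 per cell; +1 per cell for its
#' variance). Features annotated `"unassigned"` or `"absent"` are kept in
#' the contingency universe but form no class of their own.
#'
#' @param da a [DAResult-class].
#' @param annotations named character vector of metabolism labels
#'   (`aerobic`, `anaerobic`, `facultative`, `unassigned`, `absent`)
#'   covering the feature universe.
#' @param alpha adjusted-p threshold for the DA set (default 0.1).
#' @param topFraction fallback fraction for rank-score-only methods
#'   (default 0.10).
#' @return A data.frame with one row per class x direction: `class`,
#'   `direction`, `count` (DA features of that class and direction),
#'   `fisher_p`, `log_or`, `log_or_var`.
#' @export
enrichmentAnalysis <- function(da, annotations, alpha = 0.1,
                               topFraction = 0.10) {
    stopifnot(is(da, "DAResult"))
    tab <- daTable(da)
    ann <- annotations[tab$feature_id]
    if (anyNA(ann))
        stop("annotations must cover the feature universe")
    ## DA set: adjusted p, or top fraction for rank-score-only methods
    if (all(is.na(tab$adj_p)) && !all(is.na(tab$rank_score))) {
        k <- max(1L, round(topFraction * nrow(tab)))
        isDA <- tab$feature_id %in% rankedFeatures(da)[seq_len(k)]
    } else {
        isDA <- !is.na(tab$adj_p) & tab$adj_p < alpha
    }
    dir <- ifelse(tab$coefficient > 0, "UP",
                  ifelse(tab$coefficient < 0, "DOWN", NA_character_))
    if (any(isDA) && all(is.na(dir[isDA])))
        stop("no DA feature has a direction (all coefficients missing)")
    classes <- c("aerobic", "anaerobic", "facultative")
    out <- list()
    for (cl in classes)
        for (dd in c("UP", "DOWN")) {
            inSet <- isDA & !is.na(dir) & dir == dd
            a <- sum(inSet & ann == cl)
            b <- sum(inSet & ann != cl)
            c <- sum(!inSet & ann == cl)
            d <- sum(!inSet & ann != cl)
            fp <- if (sum(inSet) == 0L)
                1
            else
                stats::fisher.test(matrix(c(a, b, c, d), 2L, byrow = TRUE),
                                   alternative = "greater")$p.value
            out[[length(out) + 1L]] <- data.frame(
                class = cl, direction = dd, count = a,
                fisher_p = fp,
                log_or = haldaneLogOR(a, b, c, d),
                log_or_var = sum(1 / (c(a, b, c, d) + 1)))
        }
    do.call(rbind, out)
}

#' Haldane-Anscombe corrected log odds-ratio
#'
#' `log((a + 0.5)(d + 0.5) / ((b + 0.5)(c + 0.5)))`, defined even with
#' zero cells.
#'
#' @param a,b,c,d cells of a 2x2 contingency table (row 1 = in DA set,
#'   column 1 = in class).
#' @return The corrected natural-log odds ratio.
#' @examples
#' haldaneLogOR(10, 0, 5, 5)  # log(21)
#' @export
haldaneLogOR <- function(a, b, c, d) {
    log((a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5)))
}

#' Putative TP minus FP along the ranking
#'
#' At each threshold (a fraction of the ranked feature universe), putative
#' true positives are aerobic features called UP plus anaerobic features
#' called DOWN (in the reference-site comparison), and putative false
#' positives are the two opposite combinations; facultative and
#' unannotated features are ignored. The curve of `TP - FP` across
#' thresholds rewards methods that rank the expected taxa on top
#' regardless of their power.
#'
#' @param da a [DAResult-class].
#' @param annotations named metabolism labels covering the universe.
#' @param thresholds fractions of the universe (default 1..20\%).
#' @return A data.frame with `threshold`, `tp`, `fp`, `tp_minus_fp`.
#' @export
tpFpCurve <- function(da, annotations,
                      thresholds = seq(0.01, 0.20, by = 0.01)) {
    stopifnot(is(da, "DAResult"))
    tab <- daTable(da)
    ranked <- rankedFeatures(da)
    ann <- annotations[ranked]
    dir <- setNames(ifelse(tab$coefficient > 0, "UP",
                    ifelse(tab$coefficient < 0, "DOWN", NA_character_)),
                    tab$feature_id)[ranked]
    nU <- length(ranked)
    out <- lapply(thresholds, function(th) {
        k <- max(1L, round(th * nU))
        topAnn <- ann[seq_len(k)]
        topDir <- dir[seq_len(k)]
        tp <- sum(topAnn == "aerobic" & topDir == "UP", na.rm = TRUE) +
            sum(topAnn == "anaerobic" & topDir == "DOWN", na.rm = TRUE)
        fp <- sum(topAnn == "aerobic" & topDir == "DOWN", na.rm = TRUE) +
            sum(topAnn == "anaerobic" & topDir == "UP", na.rm = TRUE)
        data.frame(threshold = th, tp = tp, fp = fp, tp_minus_fp = tp - fp)
    })
    do.call(rbind, out)
}

#' Features found DA in one direction by several methods
#'
#' Thresholds each result as in [enrichmentAnalysis()] and returns the
#' features called DA in the given direction by at least `minMethods` of
#' the supplied results (callers restrict the input to one representative
#' method per normalization or weighting scheme).
#'
#' @param results list of [DAResult-class] objects.
#' @param direction `"UP"` or `"DOWN"`.
#' @param minMethods minimum number of supporting methods.
#' @param alpha,topFraction thresholds, as in [enrichmentAnalysis()].
#' @return A data.frame with `feature_id` and `n_methods`, sorted by
#'   support.
#' @export
mutualFindings <- function(results, direction = c("UP", "DOWN"),
                           minMethods = 2L, alpha = 0.1,
                           topFraction = 0.10) {
    direction <- match.arg(direction)
    sets <- lapply(results, function(da) {
        tab <- daTable(da)
        if (all(is.na(tab$adj_p)) && !all(is.na(tab$rank_score))) {
            k <- max(1L, round(topFraction * nrow(tab)))
            isDA <- tab$feature_id %in% rankedFeatures(da)[seq_len(k)]
        } else {
            isDA <- !is.na(tab$adj_p) & tab$adj_p < alpha
        }
        want <- if (direction == "UP") tab$coefficient > 0
                else tab$coefficient < 0
        tab$feature_id[isDA & !is.na(want) & want]
    })
    cnt <- table(unlist(sets))
    keep <- cnt[cnt >= minMethods]
    if (!length(keep))
        return(data.frame(feature_id = character(0L),
                          n_methods = integer(0L)))
    out <- data.frame(feature_id = names(keep),
                      n_methods = as.integer(keep))
    out[order(-out$n_methods, out$feature_id), , drop = FALSE]
}
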