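#' Aggregate method ranks across evaluation criteria
#'
#' Ranks methods within each criterion (mean ranks for ties; direction
#' per criterion: `"lower"` is better for e.g. a KS statistic or
#' `|FPR - alpha|`, `"higher"` for concordance, enrichment score or
#' pAUROC), averages the ranks over the criteria available for each
#' method, and normalizes to `[0, 1]` as `(avgRank - 1) / (K - 1)` for
#' `K` methods — lower is better. Methods missing a criterion (e.g. no
#' type-I column for importance-ranked methods) are ranked on their
#' available criteria and flagged as incomplete.
#'
#' @param scores a methods x criteria numeric matrix or data.frame
#'   (rownames = method names; `NA` = criterion not available).
#' @param directions named character vector over the criteria, each
#'   `"lower"` or `"higher"` (better).
#' @param criteria optional subset of criteria to use (default: all
#'   columns of `scores`).
#' @return A data.frame with `method`, `avgRank`, `normRank`,
#'   `nCriteria`, `complete`, sorted by normalized rank.
#' @examples
#' s <- matrix(c(0.1, 0.3, 0.9, 0.4), 2,
#'             dimnames = list(c("m1", "m2"), c("ks", "wmc")))
#' aggregateRanks(s, c(ks = "lower", wmc = "higher"))
#' @export
aggregateRanks <- function(scores, directions, criteria = NULL) {
    scores <- as.matrix(scores)
    if (is.null(criteria))
        criteria <- colnames(scores)
    if (!length(criteria))
        stop("the criteria set must not be empty")
    if (!all(criteria %in% colnames(scores)))
        stop("unknown criteria: ",
             paste(setdiff(criteria, colnames(scores)), collapse = ", "))
    if (!all(criteria %in% names(directions)))
        stop("every criterion needs a direction")
    if (nrow(scores) < 2L)
        stop("at least two methods are required")
    rankMat <- sapply(criteria, function(cr) {
        x <- scores[, cr]
        if (sum(!is.na(x)) < 2L)
            stop("criterion '", cr, "' is available for fewer than 2 methods")
        if (directions[[cr]] == "higher")
            x <- -x
        r <- rep(NA_real_, length(x))
        r[!is.na(x)] <- rank(x[!is.na(x)], ties.method = "average")
        r
    })
    rankMat <- matrix(rankMat, nrow = nrow(scores),
                      dimnames = list(rownames(scores), criteria))
    avg <- rowMeans(rankMat, na.rm = TRUE)
    K <- nrow(scores)
    out <- data.frame(method = rownames(scores), avgRank = avg,
                      normRank = (avg - 1) / (K - 1),
                      nCriteria = rowSums(!is.na(rankMat)),
                      complete = rowSums(is.na(rankMat)) == 0L)
    out[order(out$normRank, out$method), , drop = FALSE]
}

#' Assemble a per-method evaluation report
#'
#' Collects the metric bundles of the evaluation engines into one tidy
#' table keyed by method: type-I metrics (median KS, FPR at each nominal
#' level), within-method concordance, enrichment score (TP - FP at the
#' adjusted-p threshold) and power (normalized pAUROC) — the inputs of
#' [aggregateRanks()].
#'
#' @param typeOne optional result of [typeOneError()].
#' @param concordance optional result of [concordanceAnalysis()].
#' @param enrichScores optional named numeric of per-method TP - FP
#'   scores.
#' @param power optional result of [powerEvaluation()].
#' @return A data.frame, one row per method, with any of the columns
#'   `ks_median`, `fpr_0.01`, `fpr_0.05`, `fpr_0.1`, `wmc`,
#'   `enrich_score`, `pauroc_norm`.
#' @export
evaluationReport <- function(typeOne = NULL, concordance = NULL,
                             enrichScores = NULL, power = NULL) {
    pieces <- list()
    if (!is.null(typeOne)) {
        s <- typeOneSummary(typeOne)
        rownames(s) <- s$method
        pieces$typeOne <- s[, setdiff(colnames(s), "method"), drop = FALSE]
    }
    if (!is.null(concordance))
        pieces$wmc <- data.frame(wmc = concordance$wmc,
                                 row.names = names(concordance$wmc))
    if (!is.null(enrichScores))
        pieces$enrich <- data.frame(enrich_score = enrichScores,
                                    row.names = names(enrichScores))
    if (!is.null(power)) {
        rownames(power) <- power$method
        pieces$power <- power[, "pauroc_norm", drop = FALSE]
    }
    if (!length(pieces))
        stop("at least one evaluation result is required")
    methods <- sort(unique(unlist(lapply(pieces, rownames))))
    out <- data.frame(row.names = methods)
    for (p in pieces)
        for (cn in colnames(p))
            out[[cn]] <- p[methods, cn]
    out
}
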