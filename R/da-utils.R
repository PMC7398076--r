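#' Benjamini-Hochberg adjustment tolerating missing p-values
#'
#' Applies the BH step-up over the present p-values only (the number of
#' tests `m` is the number of non-missing entries); missing entries stay
#' missing.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`, possibly with `NA`.
#' @return Adjusted p-values, same length and names as `p`.
#' @examples
#' adjustBH(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
adjustBH <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    out <- rep(NA_real_, length(p))
    present <- !is.na(p)
    out[present] <- stats::p.adjust(p[present], method = "BH")
    names(out) <- names(p)
    out
}

#' Empirical-Bayes variance moderation
#'
#' Shrinks per-feature residual variances toward a common prior:
#' `s2tilde = (d0 * s02 + d * s2) / (d0 + d)`, with the moderated t using
#' `d0 + d` degrees of freedom. When the prior is not supplied it is
#' estimated by moment matching on the log variances (the scaled-F model of
#' the limma machinery); `d0 = Inf` collapses all variances to `s02`.
#'
#' @param s2 per-feature residual variances (>= 0).
#' @param df per-feature residual degrees of freedom (>= 1).
#' @param d0,s02 optional prior degrees of freedom and prior variance; both
#'   estimated when `NULL`.
#' @return A list with `var` (moderated variances), `df` (augmented df
#'   `d0 + df`), `d0` and `s02`.
#' @examples
#' empiricalBayesModeration(c(1, 3), c(4, 4), d0 = 4, s02 = 2)$var  # 1.5 2.5
#' @export
empiricalBayesModeration <- function(s2, df, d0 = NULL, s02 = NULL) {
    stopifnot(all(df >= 1), all(s2 >= 0))
    if (is.null(d0) || is.null(s02)) {
        if (length(unique(s2)) == 1L) {
            pd0 <- Inf
            ps02 <- s2[1L]
        } else {
            fd <- limma::fitFDist(s2, df1 = df)
            pd0 <- fd$df2
            ps02 <- fd$scale
        }
        if (is.null(d0)) d0 <- pd0
        if (is.null(s02)) s02 <- ps02
    }
    var <- if (is.infinite(d0))
        rep(s02, length(s2))
    else
        (d0 * s02 + df * s2) / (d0 + df)
    names(var) <- names(s2)
    list(var = var, df = d0 + df, d0 = d0, s02 = s02)
}

#' Observational weights from a ZINB fit
#'
#' Posterior probability that each count was generated by the negative
#' binomial (non-inflated) component: 1 for positive counts, and for zeros
#' `(1 - pi) * NB0 / (pi + (1 - pi) * NB0)` with
#' `NB0 = (1 + phi * mu)^(-1/phi)`. Supplying these as observation weights
#' lets standard NB GLM and moderated-t pipelines account for zero
#' inflation.
#'
#' @param ct the [CountTable-class] the fit was produced on.
#' @param fit a ZINB [FitResult-class] on the same features and samples.
#' @return A features x samples matrix of weights in `[0, 1]`.
#' @export
zinbWeights <- function(ct, fit) {
    stopifnot(is(ct, "CountTable"), is(fit, "FitResult"))
    if (fit@model != "ZINB")
        stop("observational weights require a ZINB fit")
    y <- counts(ct)
    if (!identical(rownames(y), names(fit@mean)))
        stop("fit and count table cover different feature sets")
    mu <- fit@params$mu
    pi <- fit@params$pi
    phi <- fit@params$phi
    nb0 <- .nbZeroProb(mu, phi)
    wZero <- (1 - pi) * nb0 / (pi + (1 - pi) * nb0)
    wZero[!is.finite(wZero)] <- 0
    w <- matrix(1, nrow(y), ncol(y), dimnames = dimnames(y))
    w[y == 0] <- matrix(wZero, nrow(y), ncol(y))[y == 0]
    pmin(pmax(w, 0), 1)
}

## Vectorized two-sample rank-sum test over the rows of a matrix
## (normal approximation with tie correction; exchangeable under the null).
.rowWilcoxon <- function(m, g2, ties = TRUE) {
    n <- ncol(m)
    n2 <- sum(g2)
    n1 <- n - n2
    r <- matrixStats::rowRanks(m, ties.method = "average")
    W <- rowSums(r[, g2, drop = FALSE]) - n2 * (n2 + 1) / 2
    mu <- n1 * n2 / 2
    ## tie correction per row (skippable for continuous data)
    tieSum <- if (ties)
        apply(m, 1L, function(x) {
            tt <- tabulate(match(x, unique(x)))
            sum(tt^3 - tt)
        })
    else
        numeric(nrow(m))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tieSum / (n * (n - 1)))
    sigma2 <- pmax(sigma2, 0)
    z <- ifelse(sigma2 > 0, (W - mu) / sqrt(sigma2), 0)
    ## plain normal approximation (no continuity correction): P(p < alpha)
    ## then tracks alpha closely, which the calibration analyses rely on
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    list(statistic = z, p = pmin(p, 1))
}

## Deterministic ranked feature list: raw p ascending, then |statistic|
## descending, then feature id; missing p-values last.
.rankFeatures <- function(tab) {
    p <- tab$raw_p
    s <- abs(tab$statistic)
    s[is.na(s)] <- -Inf
    ord <- order(is.na(p), p, -s, tab$feature_id)
    tab$feature_id[ord]
}

#' Ranked feature list of a DA result
#'
#' Features ordered by raw p-value (importance score for rank-based
#' methods), breaking ties by descending absolute statistic and then by
#' feature id, with missing entries last — a strict, reproducible order as
#' required by the concordance analysis.
#'
#' @param da a [DAResult-class].
#' @return Character vector of feature ids.
#' @export
rankedFeatures <- function(da) {
    stopifnot(is(da, "DAResult"))
    tab <- as.data.frame(da@table)
    if (all(is.na(tab$raw_p)) && !all(is.na(tab$rank_score))) {
        ord <- order(-abs(tab$rank_score), tab$feature_id)
        return(tab$feature_id[ord])
    }
    .rankFeatures(tab)
}
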