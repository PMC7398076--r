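#' Random mock two-group labelings
#'
#' Balanced random splits of `n` samples into two groups (the extra sample
#' goes to group 1 when `n` is odd, e.g. 41 samples split 21 / 20), used
#' for mock comparisons on data assumed free of true differential
#' abundance. Reproducible given `seed`; labelings are drawn without
#' repetition whenever combinatorially possible.
#'
#' @param nSamples number of samples (>= 4).
#' @param B number of labelings.
#' @param seed integer seed.
#' @return A `B x nSamples` character matrix of `"grp1"` / `"grp2"` labels.
#' @export
mockLabelings <- function(nSamples, B, seed = 1L) {
    stopifnot(nSamples >= 4L, B >= 1L)
    n1 <- ceiling(nSamples / 2)
    total <- choose(nSamples, n1)
    withr::with_seed(seed, {
        seen <- character(0L)
        out <- matrix("grp1", B, nSamples)
        b <- 1L
        tries <- 0L
        while (b <= B) {
            idx <- sort(sample.int(nSamples, n1))
            key <- paste(idx, collapse = ",")
            tries <- tries + 1L
            if (key %in% seen && length(seen) < total && tries < 1000L * B)
                next
            seen <- c(seen, key)
            lab <- rep("grp2", nSamples)
            lab[idx] <- "grp1"
            out[b, ] <- lab
            b <- b + 1L
        }
        out
    })
}

## sup distance of a p-value sample to the uniform on [0, 1]
.ksUniform <- function(p) {
    p <- sort(p)
    m <- length(p)
    if (!m)
        return(NA_real_)
    dPlus <- max(seq_len(m) / m - p)
    dMinus <- max(p - (seq_len(m) - 1L) / m)
    max(dPlus, dMinus)
}

#' Type I error evaluation on mock comparisons
#'
#' Runs each method on `B` random balanced two-group labelings of a table
#' assumed to carry no true signal, and summarizes the raw p-value
#' distributions: the Kolmogorov-Smirnov sup-distance to the uniform per
#' mock, the false positive rate (fraction of tested features with
#' `p < alpha`) per mock and nominal level, and the qq curve obtained by
#' averaging the observed p-value quantiles over mocks.
#'
#' @param ct a [CountTable-class] with no real group structure.
#' @param methods character vector of catalogue method names.
#' @param B number of mock datasets (the full-scale analysis uses 1000).
#' @param alphas nominal thresholds (default `c(0.01, 0.05, 0.1)`).
#' @param seed integer seed.
#' @param qqPoints number of theoretical quantiles for the averaged qq
#'   curve.
#' @param ... passed to [runDA()].
#' @return A list with `ks` (B x methods matrix), `fpr` (data.frame:
#'   method, alpha, mock, fpr), `qq` (data.frame: method, theoretical,
#'   observed), and `failures` (per-method count of failed mocks).
#' @export
typeOneError <- function(ct, methods, B = 100L,
                         alphas = c(0.01, 0.05, 0.1), seed = 1L,
                         qqPoints = 100L, ...) {
    stopifnot(is(ct, "CountTable"))
    labs <- mockLabelings(ncol(ct), B, seed = seed)
    ks <- matrix(NA_real_, B, length(methods),
                 dimnames = list(NULL, methods))
    fpr <- list()
    qsum <- matrix(0, qqPoints, length(methods),
                   dimnames = list(NULL, methods))
    qn <- setNames(integer(length(methods)), methods)
    fail <- setNames(integer(length(methods)), methods)
    theo <- (seq_len(qqPoints) - 0.5) / qqPoints
    for (b in seq_len(B)) {
        for (m in methods) {
            da <- try(runDA(ct, labs[b, ], m, seed = seed + b, ...),
                      silent = TRUE)
            if (inherits(da, "try-error")) {
                fail[m] <- fail[m] + 1L
                next
            }
            p <- daTable(da)$raw_p
            p <- p[!is.na(p)]
            if (!length(p)) {
                fail[m] <- fail[m] + 1L
                next
            }
            ks[b, m] <- .ksUniform(p)
            for (a in alphas)
                fpr[[length(fpr) + 1L]] <-
                    data.frame(method = m, alpha = a, mock = b,
                               fpr = mean(p < a))
            qsum[, m] <- qsum[, m] + stats::quantile(p, probs = theo,
                                                     names = FALSE)
            qn[m] <- qn[m] + 1L
        }
    }
    qq <- do.call(rbind, lapply(methods, function(m)
        data.frame(method = m, theoretical = theo,
                   observed = if (qn[m] > 0) qsum[, m] / qn[m]
                              else NA_real_)))
    list(ks = ks, fpr = do.call(rbind, fpr), qq = qq, failures = fail)
}

#' @describeIn typeOneError per-method summary table: median KS and mean
#'   FPR at each nominal level.
#' @param res a result of `typeOneError()`.
#' @export
typeOneSummary <- function(res) {
    ksMed <- apply(res$ks, 2L, stats::median, na.rm = TRUE)
    agg <- stats::aggregate(fpr ~ method + alpha, data = res$fpr,
                            FUN = mean)
    wide <- stats::reshape(agg, idvar = "method", timevar = "alpha",
                           direction = "wide")
    colnames(wide) <- sub("^fpr\\.", "fpr_", colnames(wide))
    wide$ks_median <- ksMed[wide$method]
    wide
}
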