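#' Compute per-sample normalization factors
#'
#' Supported schemes:
#' \describe{
#'   \item{TMM}{trimmed mean of M-values via [edgeR::calcNormFactors]
#'     (30\% trim on M-values, 5\% on A-values, precision-weighted,
#'     reference sample chosen by the upper-quartile rule); factors are
#'     rescaled to geometric mean 1 and the offsets are the log effective
#'     library sizes `log(lib * factor)`.}
#'   \item{poscounts}{median-of-ratios with the per-feature reference
#'     `g_f = (prod of positive counts)^(1/n)` (the geometric mean of the
#'     positive counts); the per-sample factor is the median of `y_fj / g_f`
#'     over features with `g_f > 0`. Zero ratios are included in the median
#'     by default, preserving the sparsity-aware intent; set
#'     `poscountsIncludeZeros = FALSE` for the classic positive-only
#'     median.}
#'   \item{CSS}{cumulative sum scaling: the factor is the sum of each
#'     sample's counts up to a data-driven quantile chosen by an
#'     instability criterion (first quantile where the relative change of
#'     the median absolute deviation of the quantile profiles exceeds
#'     `cssRelChange`); falls back to quantile 0.5 with a warning when the
#'     search fails. Pass `cssQuantile` to skip the search.}
#'   \item{TSS}{total sum scaling, the library size itself.}
#' }
#'
#' @param ct a [CountTable-class].
#' @param scheme one of `"TMM"`, `"poscounts"`, `"CSS"`, `"TSS"`.
#' @param cssQuantile optional fixed CSS quantile in (0, 1).
#' @param cssRelChange instability threshold for the CSS quantile search
#'   (default 0.1).
#' @param poscountsIncludeZeros include zero ratios in the poscounts median
#'   (default `TRUE`).
#' @return A [NormFactors-class].
#' @examples
#' y <- matrix(c(2, 8, 0, 4), 2, 2,
#'             dimnames = list(c("f1", "f2"), c("s1", "s2")))
#' normFactorValues(normFactors(CountTable(y), "poscounts"))  # 0.25, 2
#' @export
normFactors <- function(ct, scheme = c("TMM", "poscounts", "CSS", "TSS"),
                        cssQuantile = NULL, cssRelChange = 0.1,
                        poscountsIncludeZeros = TRUE) {
    stopifnot(is(ct, "CountTable"))
    scheme <- match.arg(scheme)
    y <- counts(ct)
    lib <- libSizes(ct)
    if (any(lib == 0))
        stop("all-zero sample(s): ",
             paste(names(lib)[lib == 0], collapse = ", "),
             " have undefined normalization factors")
    f <- switch(scheme,
        TMM = {
            fac <- edgeR::calcNormFactors(y, lib.size = lib, method = "TMM")
            names(fac) <- colnames(y)
            fac
        },
        poscounts = .poscountsFactors(y, includeZeros = poscountsIncludeZeros),
        CSS = .cssFactors(y, quantile = cssQuantile,
                          relChange = cssRelChange),
        TSS = lib)
    offsets <- switch(scheme,
        TMM = log(lib * f),
        poscounts = log(f),
        CSS = log(f),
        TSS = log(lib))
    new("NormFactors", scheme = scheme, factors = f, offsets = offsets)
}

.poscountsFactors <- function(y, includeZeros = TRUE) {
    n <- ncol(y)
    logg <- rowSums(ifelse(y > 0, log(y), 0)) / n
    g <- exp(logg)
    use <- g > 0 & rowSums(y > 0) > 0
    if (!any(use))
        stop("poscounts: no usable features (all geometric means zero)")
    ratios <- y[use, , drop = FALSE] / g[use]
    s <- apply(ratios, 2L, function(r) {
        if (!includeZeros) r <- r[r > 0]
        stats::median(r)
    })
    if (any(!is.finite(s) | s <= 0))
        stop("poscounts: undefined factor for sample(s) ",
             paste(colnames(y)[!is.finite(s) | s <= 0], collapse = ", "))
    names(s) <- colnames(y)
    s
}

.cssQuantileSearch <- function(y, relChange = 0.1) {
    probs <- seq(0.05, 0.95, by = 0.01)
    qmat <- apply(y, 2L, function(x) stats::quantile(x[x > 0], probs))
    ref <- rowMeans(qmat)
    meddev <- apply(abs(qmat - ref), 1L, stats::median)
    if (all(meddev == 0))
        return(NA_real_)
    rel <- abs(diff(meddev)) / meddev[-1L]
    rel[!is.finite(rel)] <- 0
    hit <- which(rel > relChange)
    if (!length(hit))
        return(NA_real_)
    probs[hit[1L] + 1L]
}

.cssFactors <- function(y, quantile = NULL, relChange = 0.1) {
    if (is.null(quantile)) {
        quantile <- .cssQuantileSearch(y, relChange)
        if (is.na(quantile)) {
            warning("CSS quantile search failed; falling back to 0.5")
            quantile <- 0.5
        }
    }
    s <- apply(y, 2L, function(x) {
        pos <- x[x > 0]
        if (!length(pos))
            return(NA_real_)
        sum(pos[pos <= stats::quantile(pos, quantile)])
    })
    if (any(!is.finite(s) | s <= 0))
        stop("CSS: undefined factor for sample(s) ",
             paste(colnames(y)[!is.finite(s) | s <= 0], collapse = ", "))
    names(s) <- colnames(y)
    s
}

#' @describeIn normFactors factor accessor.
#' @param nf a [NormFactors-class].
#' @export
normFactorValues <- function(nf) {
    stopifnot(is(nf, "NormFactors"))
    nf@factors
}

#' @describeIn normFactors log-offset accessor.
#' @export
normOffsets <- function(nf) {
    stopifnot(is(nf, "NormFactors"))
    nf@offsets
}

#' @describeIn normFactors scheme accessor.
#' @export
normScheme <- function(nf) {
    stopifnot(is(nf, "NormFactors"))
    nf@scheme
}

#' @describeIn normFactors write factors as a 2-column TSV
#'   (sample_id, factor).
#' @param path output path.
#' @export
writeNormFactors <- function(nf, path) {
    stopifnot(is(nf, "NormFactors"))
    utils::write.table(
        data.frame(sample_id = names(nf@factors), factor = nf@factors),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Transform counts to the scales used by the Gaussian models
#'
#' Schemes:
#' \describe{
#'   \item{log2_cpm}{`log2(y * 1e6 / lib + pseudocount)` (counts per
#'     million).}
#'   \item{log2_median_libsize}{`log2(y * median(lib) / lib + pseudocount)`;
#'     reduces to `log2(y + 1)` when all library sizes are equal.}
#'   \item{clr}{centered log-ratio of the pseudocounted relative
#'     abundances; every sample's CLR vector sums to zero.}
#'   \item{css_log_thousand}{response `log2(y + pseudocount)` with
#'     per-sample offsets `log2(css_j / 1000 + 1)` ("counts per thousand"
#'     interpretation).}
#'   \item{css_log_median}{response `log2(y + pseudocount)` with offsets
#'     `log2(css_j / median(css))`.}
#' }
#'
#' @param ct a [CountTable-class].
#' @param scheme transformation scheme.
#' @param pseudocount positive pseudocount (default 1).
#' @param cssQuantile optional fixed CSS quantile, passed to
#'   [normFactors()].
#' @return A list with `matrix` (features x samples), `offsets` (per-sample,
#'   on the log2 scale for the CSS variants, zero otherwise) and `scheme`.
#' @export
transformCounts <- function(ct,
                            scheme = c("log2_cpm", "log2_median_libsize",
                                       "clr", "css_log_thousand",
                                       "css_log_median"),
                            pseudocount = 1, cssQuantile = NULL) {
    stopifnot(is(ct, "CountTable"), pseudocount > 0)
    scheme <- match.arg(scheme)
    y <- counts(ct)
    lib <- libSizes(ct)
    if (scheme == "log2_cpm") {
        m <- log2(sweep(y, 2L, 1e6 / lib, "*") + pseudocount)
        off <- setNames(numeric(ncol(y)), colnames(y))
    } else if (scheme == "log2_median_libsize") {
        m <- log2(sweep(y, 2L, stats::median(lib) / lib, "*") + pseudocount)
        off <- setNames(numeric(ncol(y)), colnames(y))
    } else if (scheme == "clr") {
        rel <- sweep(y + pseudocount, 2L, colSums(y + pseudocount), "/")
        lrel <- log(rel)
        m <- sweep(lrel, 2L, colMeans(lrel), "-")
        off <- setNames(numeric(ncol(y)), colnames(y))
    } else {
        s <- normFactorValues(normFactors(ct, "CSS",
                                          cssQuantile = cssQuantile))
        m <- log2(y + pseudocount)
        off <- if (scheme == "css_log_thousand")
            log2(s / 1000 + 1)
        else
            log2(s / stats::median(s))
    }
    list(matrix = m, offsets = off, scheme = scheme)
}
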