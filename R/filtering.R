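#' Filter samples by depth and features by prevalence
#'
#' Keeps samples whose library size is strictly greater than `minLibSize`,
#' then keeps features observed with a count strictly greater than
#' `minCount` in strictly more than `minSamples` samples. The inequalities
#' are strict on purpose: an off-by-one here changes every downstream
#' feature count, so the rule is applied literally. Library sizes are
#' recomputed after filtering.
#'
#' @param ct a [CountTable-class].
#' @param minLibSize keep samples with `library_size > minLibSize`
#'   (default 0).
#' @param minCount,minSamples keep features with `count > minCount` in more
#'   than `minSamples` samples (defaults 10 and 1).
#' @return The filtered [CountTable-class].
#' @examples
#' y <- matrix(c(11, 11, 0, 11, 0, 0), 2, 3, byrow = TRUE,
#'             dimnames = list(c("kept", "dropped"), paste0("s", 1:3)))
#' ct <- filterCounts(CountTable(y), minCount = 10, minSamples = 1)
#' rownames(ct)   # only "kept": present in 2 (> 1) samples with > 10 reads
#' @export
filterCounts <- function(ct, minLibSize = 0, minCount = 10, minSamples = 1) {
    stopifnot(is(ct, "CountTable"),
              minLibSize >= 0, minCount >= 0, minSamples >= 0)
    keepS <- libSizes(ct) > minLibSize
    if (sum(keepS) == 0L)
        stop("no samples left after the library-size filter (> ",
             minLibSize, ")")
    ct2 <- ct[, keepS]
    y <- assay(ct2, "counts")
    keepF <- rowSums(y > minCount) > minSamples
    if (sum(keepF) == 0L)
        stop("no features left after the prevalence filter (> ", minCount,
             " reads in > ", minSamples, " samples)")
    if (sum(keepS) < 2L)
        stop("fewer than two samples left after the library-size filter")
    .refreshLibSizes(ct2[keepF, ])
}

#' Rarefy samples to a common depth
#'
#' Down-samples each sample's reads without replacement (multivariate
#' hypergeometric) so every retained sample has exactly `depth` reads,
#' modelling the subsampling of physical reads. Samples shallower than
#' `depth` are dropped with a warning. Reproducible given `seed`.
#'
#' @param ct a [CountTable-class].
#' @param depth target library size (>= 1).
#' @param seed integer seed.
#' @return A rarefied [CountTable-class].
#' @export
rarefyCounts <- function(ct, depth, seed = 1L) {
    stopifnot(is(ct, "CountTable"))
    if (depth <= 0)
        stop("depth must be >= 1")
    ls <- libSizes(ct)
    keep <- ls >= depth
    if (!all(keep))
        warning(sum(!keep), " sample(s) shallower than depth ", depth,
                " dropped: ", paste(names(ls)[!keep], collapse = ", "))
    if (sum(keep) < 2L)
        stop("fewer than two samples at depth >= ", depth)
    ct2 <- ct[, keep]
    y <- assay(ct2, "counts")
    new_y <- if (nrow(y) == 1L) {
        matrix(depth, 1L, ncol(y))       # conservation: single feature
    } else {
        ## multivariate hypergeometric subsample per sample (vegan warns
        ## heuristically about large minimum counts; not relevant here)
        withr::with_seed(seed,
            t(suppressWarnings(vegan::rrarefy(t(y), depth))))
    }
    dimnames(new_y) <- dimnames(y)
    storage.mode(new_y) <- "double"
    assays(ct2)[["counts"]] <- new_y
    .refreshLibSizes(ct2)
}

#' Fraction of zero cells
#'
#' @param ct a [CountTable-class].
#' @return A list with `overall` (zero cells / (F * n)) and `perFeature`
#'   (named per-feature zero frequencies).
#' @export
zeroFraction <- function(ct) {
    stopifnot(is(ct, "CountTable"))
    y <- counts(ct)
    list(overall = mean(y == 0), perFeature = rowMeans(y == 0))
}
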