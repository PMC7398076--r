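#' Concordance At the Top between two ranked lists
#'
#' `C_i` is the cardinality of the intersection of the top `i` entries of
#' each list, divided by `i`, computed for `i = 1..R`. Both lists must rank
#' the same feature universe without duplicates. When `R` exceeds the
#' comparable depth, trailing values are `NA` (reported as non-computable
#' rather than extrapolated).
#'
#' @param listA,listB character vectors of ranked feature ids (strict
#'   orders; break ties before calling, e.g. with [rankedFeatures()]).
#' @param R maximum rank (default 100).
#' @return A [CATCurve-class].
#' @examples
#' catValues(catCurve(c("a", "b", "c"), c("b", "a", "c"), R = 3))  # 0 1 1
#' @export
catCurve <- function(listA, listB, R = 100L) {
    if (anyDuplicated(listA) || anyDuplicated(listB))
        stop("ranked lists must not contain duplicated ids")
    depth <- min(length(listA), length(listB))
    R <- as.integer(R)
    if (R > depth)
        warning("R = ", R, " exceeds the comparable depth ", depth,
                "; trailing values are NA")
    vals <- rep(NA_real_, R)
    upto <- min(R, depth)
    ## membership ranks: C_i counts entries of A's top i that sit within
    ## B's top i
    posB <- match(listA, listB)
    cnt <- vapply(seq_len(upto), function(i)
        sum(posB[seq_len(i)] <= i, na.rm = TRUE), integer(1L))
    vals[seq_len(upto)] <- cnt / seq_len(upto)
    new("CATCurve", R = R, values = vals)
}

#' @describeIn catCurve curve values accessor.
#' @param curve a [CATCurve-class].
#' @export
catValues <- function(curve) {
    stopifnot(is(curve, "CATCurve"))
    curve@values
}

#' Area under a CAT curve
#'
#' The rectangle-rule average of the concordance values,
#' `AUC = mean(C_1..C_R)`; identical lists give 1. When some ranks are not
#' computable the average is taken over the available ranks and the result
#' carries the attribute `partial = TRUE`.
#'
#' @param curve a [CATCurve-class].
#' @return A value in `[0, 1]`.
#' @export
catAUC <- function(curve) {
    stopifnot(is(curve, "CATCurve"))
    v <- curve@values
    ok <- !is.na(v)
    if (!any(ok))
        return(NA_real_)
    out <- mean(v[ok])
    if (!all(ok))
        attr(out, "partial") <- TRUE
    out
}

## seeded stratified half split: returns a list of two index vectors with
## balanced groups in each half
.halfSplit <- function(group) {
    lev <- sort(unique(group))
    idx1 <- idx2 <- integer(0L)
    for (l in lev) {
        ii <- sample(which(group == l))
        h <- floor(length(ii) / 2)
        idx1 <- c(idx1, ii[seq_len(h)])
        idx2 <- c(idx2, ii[(h + 1L):(2L * h)])
    }
    list(sort(idx1), sort(idx2))
}

#' One sample per subject / sequencing center subsetting
#'
#' Keeps the first sample per `subject_id` after a seeded shuffle, and
#' optionally restricts to the most frequent sequencing center, increasing
#' sample homogeneity before the concordance split.
#'
#' @param ct a [CountTable-class].
#' @param bySubject keep one sample per subject (default `TRUE`).
#' @param byCenter restrict to the largest center (default `FALSE`).
#' @param seed integer seed for the shuffle.
#' @return A [CountTable-class].
#' @export
dedupSamples <- function(ct, bySubject = TRUE, byCenter = FALSE,
                         seed = 1L) {
    stopifnot(is(ct, "CountTable"))
    sm <- sampleData(ct)
    keep <- rep(TRUE, ncol(ct))
    if (byCenter && length(unique(sm$center)) > 1L) {
        topCenter <- names(sort(table(sm$center), decreasing = TRUE))[1L]
        keep <- sm$center == topCenter
    }
    if (bySubject && any(duplicated(sm$subject_id[keep]))) {
        idx <- which(keep)
        shuffled <- withr::with_seed(seed, sample(idx))
        first <- shuffled[!duplicated(sm$subject_id[shuffled])]
        keep <- seq_len(ncol(ct)) %in% first
    }
    .refreshLibSizes(ct[, keep])
}

#' Within- and between-method concordance over random half splits
#'
#' Repeatedly splits the samples in half (stratified by group, one sample
#' per subject when `dedup = TRUE`), runs every method on both halves, and
#' scores concordance at the top between ranked feature lists: WMC compares
#' a method on Subset1 against itself on Subset2; BMC compares two methods
#' within the same subset (averaged over the two subsets). Both are
#' averaged over `nSplits` splits, after the per-curve [catAUC()].
#'
#' @param ct a [CountTable-class].
#' @param group two-level grouping vector.
#' @param methods character vector of catalogue method names.
#' @param nSplits number of random splits (the full-scale analysis uses
#'   100).
#' @param R maximum CAT rank (default 100).
#' @param seed integer seed.
#' @param dedup apply [dedupSamples()] first (default `TRUE`).
#' @param ... passed to [runDA()].
#' @return A list with `wmc` (named per-method average), `bmc` (methods x
#'   methods matrix, WMC on the diagonal), and `failures` (per-method
#'   failed split count).
#' @export
concordanceAnalysis <- function(ct, group, methods, nSplits = 10L,
                                R = 100L, seed = 1L, dedup = TRUE, ...) {
    stopifnot(is(ct, "CountTable"))
    group <- as.character(group)
    if (dedup) {
        keepIds <- colnames(dedupSamples(ct, seed = seed))
        sel <- colnames(ct) %in% keepIds
        ct <- .refreshLibSizes(ct[, sel])
        group <- group[sel]
    }
    if (min(table(group)) < 4L)
        stop("each group needs at least 4 samples after deduplication")
    K <- length(methods)
    wmcSum <- setNames(numeric(K), methods)
    wmcN <- setNames(integer(K), methods)
    bmcSum <- matrix(0, K, K, dimnames = list(methods, methods))
    bmcN <- matrix(0L, K, K, dimnames = list(methods, methods))
    fail <- setNames(integer(K), methods)
    for (s in seq_len(nSplits)) {
        halves <- withr::with_seed(seed + s, .halfSplit(group))
        ranks <- vector("list", 2L)
        for (h in 1:2) {
            idx <- halves[[h]]
            cth <- .refreshLibSizes(ct[, idx])
            ranks[[h]] <- lapply(setNames(methods, methods), function(m) {
                da <- try(runDA(cth, group[idx], m, seed = seed + s, ...),
                          silent = TRUE)
                if (inherits(da, "try-error"))
                    return(NULL)
                rankedFeatures(da)
            })
        }
        for (m in methods) {
            la <- ranks[[1L]][[m]]
            lb <- ranks[[2L]][[m]]
            if (is.null(la) || is.null(lb)) {
                fail[m] <- fail[m] + 1L
                next
            }
            auc <- suppressWarnings(catAUC(catCurve(la, lb, R)))
            if (!is.na(auc)) {
                wmcSum[m] <- wmcSum[m] + auc
                wmcN[m] <- wmcN[m] + 1L
            }
        }
        for (h in 1:2)
            for (i in seq_len(K))
                for (j in seq_len(K)) {
                    if (i == j)
                        next
                    la <- ranks[[h]][[methods[i]]]
                    lb <- ranks[[h]][[methods[j]]]
                    if (is.null(la) || is.null(lb))
                        next
                    auc <- suppressWarnings(catAUC(catCurve(la, lb, R)))
                    if (!is.na(auc)) {
                        bmcSum[i, j] <- bmcSum[i, j] + auc
                        bmcN[i, j] <- bmcN[i, j] + 1L
                    }
                }
    }
    wmc <- ifelse(wmcN > 0, wmcSum / wmcN, NA_real_)
    bmc <- ifelse(bmcN > 0, bmcSum / bmcN, NA_real_)
    diag(bmc) <- wmc
    list(wmc = wmc, bmc = bmc, failures = fail)
}
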