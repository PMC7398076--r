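#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- colData rowData colData<- rowData<-
NULL

#' CountTable: a feature-by-sample table of sequencing counts
#'
#' `CountTable` extends [SummarizedExperiment::SummarizedExperiment] with the
#' invariants required by microbiome count data: a single `"counts"` assay of
#' non-negative integers with features in rows and samples in columns, unique
#' feature and sample identifiers, per-sample metadata (`subject_id`, `group`,
#' `center`, `library_size`) and per-feature metadata (`taxonomy`,
#' `metabolism`). Missing metadata fields are filled with the sentinel
#' `"absent"`. The stored `library_size` must always equal the column sums of
#' the counts.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#'
#' @seealso [CountTable()] for construction, [readCountTable()] for file
#'   input, [filterCounts()], [rarefyCounts()], [zeroFraction()].
#' @export
setClass("CountTable", contains = "SummarizedExperiment")

.validCountTable <- function(object) {
    msg <- character()
    if (!("counts" %in% names(assays(object))))
        return("assay 'counts' is missing")
    y <- assay(object, "counts")
    if (!is.numeric(y))
        return("counts must be numeric")
    if (anyNA(y) || any(y < 0) || any(y != round(y)))
        msg <- c(msg, "counts must be non-negative integers")
    if (nrow(y) < 1L)
        msg <- c(msg, "at least one feature is required")
    if (ncol(y) < 2L)
        msg <- c(msg, "at least two samples are required")
    if (is.null(rownames(y)) || anyDuplicated(rownames(y)))
        msg <- c(msg, "feature ids must be present and unique")
    if (is.null(colnames(y)) || anyDuplicated(colnames(y)))
        msg <- c(msg, "sample ids must be present and unique")
    cd <- colData(object)
    if (!all(c("subject_id", "group", "center", "library_size") %in%
             colnames(cd)))
        msg <- c(msg, "colData must carry subject_id, group, center, library_size")
    else if (!isTRUE(all.equal(unname(cd$library_size),
                               unname(colSums(y)), tolerance = 0)))
        msg <- c(msg, "stored library_size does not match column sums")
    rd <- rowData(object)
    if (!all(c("taxonomy", "metabolism") %in% colnames(rd)))
        msg <- c(msg, "rowData must carry taxonomy and metabolism")
    if (length(msg)) msg else TRUE
}

setValidity("CountTable", .validCountTable)

#' Per-sample normalization factors
#'
#' Holds the scaling factors of one normalization scheme together with the
#' log-scale offsets used by count-model fits. Factors are strictly positive;
#' TMM factors are rescaled to geometric mean 1.
#'
#' @slot scheme character, one of `"TMM"`, `"poscounts"`, `"CSS"`, `"TSS"`,
#'   `"none"`.
#' @slot factors named numeric, one positive factor per sample.
#' @slot offsets named numeric, per-sample natural-log offsets (the log
#'   effective library size for `TMM`/`TSS`, the log size factor for
#'   `poscounts`, the log CSS scaling sum for `CSS`).
#' @export
setClass("NormFactors",
    representation(scheme = "character", factors = "numeric",
                   offsets = "numeric"),
    validity = function(object) {
        if (length(object@scheme) != 1L)
            return("scheme must be a single string")
        if (any(!is.finite(object@factors)) || any(object@factors <= 0))
            return("factors must be positive and finite")
        if (length(object@offsets) != length(object@factors))
            return("offsets and factors lengths differ")
        TRUE
    })

#' Per-feature parametric model fit
#'
#' The result of fitting one of the five candidate models (NB, ZINB, ZIG,
#' HURDLE, DM) to every feature of a [CountTable], reduced to the two
#' quantities compared in the goodness-of-fit analysis: the estimated mean
#' count on the `log2(. + 1)` scale and the estimated probability of
#' observing a zero.
#'
#' @slot model character, one of `"NB"`, `"ZINB"`, `"ZIG"`, `"HURDLE"`, `"DM"`.
#' @slot mean named numeric, estimated mean per feature on the `log2(. + 1)`
#'   scale.
#' @slot zeroProb named numeric in `[0, 1]`, estimated zero probability per
#'   feature.
#' @slot params list of model-specific parameter estimates (e.g. `mu`, `phi`,
#'   `pi`, `alpha`).
#' @slot converged named logical, per-feature convergence flag.
#' @export
setClass("FitResult",
    representation(model = "character", mean = "numeric",
                   zeroProb = "numeric", params = "list",
                   converged = "logical"),
    validity = function(object) {
        ok <- is.finite(object@zeroProb)
        if (any(object@zeroProb[ok] < -1e-8 | object@zeroProb[ok] > 1 + 1e-8))
            return("zeroProb must lie in [0, 1]")
        if (length(object@mean) != length(object@zeroProb))
            return("mean and zeroProb lengths differ")
        TRUE
    })

#' Differential abundance result for one method run
#'
#' One row per feature with the signed effect (group2 vs group1), the test
#' statistic, raw and BH-adjusted p-values (possibly missing, with a reason
#' code) and an optional importance score for rank-based methods.
#'
#' @slot method character, catalogue name of the method.
#' @slot norm character, normalization scheme the method declares.
#' @slot table a `DataFrame` with columns `feature_id`, `coefficient`,
#'   `statistic`, `raw_p`, `adj_p`, `rank_score`, `missing_reason`.
#' @export
setClass("DAResult",
    representation(method = "character", norm = "character",
                   table = "DataFrame"),
    validity = function(object) {
        need <- c("feature_id", "coefficient", "statistic", "raw_p",
                  "adj_p", "rank_score", "missing_reason")
        if (!all(need %in% colnames(object@table)))
            return(paste("table must have columns:",
                         paste(need, collapse = ", ")))
        p <- object@table$raw_p
        if (any(p < 0 | p > 1, na.rm = TRUE))
            return("raw_p outside [0, 1]")
        both <- !is.na(p) & !is.na(object@table$adj_p)
        if (any(object@table$adj_p[both] < p[both] - 1e-12))
            return("adj_p must be >= raw_p")
        TRUE
    })

#' Simulation template estimated from a count table
#'
#' Per-feature relative means (summing to one), a common NB dispersion,
#' per-feature zero-inflation probabilities (ZINB only) and the empirical
#' library-size pool that [simulateDataset()] resamples from.
#'
#' @slot distribution character, `"NB"` or `"ZINB"`.
#' @slot relMeans named numeric, positive, summing to 1.
#' @slot dispersion numeric, common NB dispersion (size = 1/dispersion).
#' @slot zeroProb named numeric in `[0, 1]` (all zero for NB templates).
#' @slot libSizes numeric, empirical library sizes to resample from.
#' @export
setClass("TemplateParams",
    representation(distribution = "character", relMeans = "numeric",
                   dispersion = "numeric", zeroProb = "numeric",
                   libSizes = "numeric"),
    validity = function(object) {
        if (!object@distribution %in% c("NB", "ZINB"))
            return("distribution must be NB or ZINB")
        if (any(object@relMeans <= 0))
            return("relative means must be positive")
        if (abs(sum(object@relMeans) - 1) > 1e-8)
            return("relative means must sum to 1")
        if (object@dispersion < 0)
            return("dispersion must be >= 0")
        if (any(object@zeroProb < 0 | object@zeroProb > 1))
            return("zero probabilities must lie in [0, 1]")
        if (object@distribution == "NB" && any(object@zeroProb > 0))
            return("NB templates must have zero zero-inflation")
        TRUE
    })

#' One cell of the simulation grid
#'
#' @slot distribution character, `"NB"` or `"ZINB"`.
#' @slot nPerGroup integer, samples per condition.
#' @slot daProportion numeric in (0, 1), fraction of features injected as DA.
#' @slot foldEffect numeric > 1 applied to the relative means of DA features.
#' @slot compensation logical; when `TRUE` the flagged set's total relative
#'   mean is conserved so non-DA features are unaffected by renormalization.
#' @slot sparsityEffect numeric >= 0 added to / subtracted from the ZINB
#'   mixing probability of down-/up-regulated features (forced to 0 for NB).
#' @slot replicates integer, datasets per grid cell.
#' @slot seed integer, base seed of the cell.
#' @export
setClass("SimulationDesign",
    representation(distribution = "character", nPerGroup = "integer",
                   daProportion = "numeric", foldEffect = "numeric",
                   compensation = "logical", sparsityEffect = "numeric",
                   replicates = "integer", seed = "integer"),
    validity = function(object) {
        if (object@foldEffect <= 1) return("foldEffect must be > 1")
        if (object@sparsityEffect < 0) return("sparsityEffect must be >= 0")
        if (object@distribution == "NB" && object@sparsityEffect != 0)
            return("sparsityEffect must be 0 for NB designs")
        if (object@daProportion <= 0 || object@daProportion >= 1)
            return("daProportion must be in (0, 1)")
        if (object@nPerGroup < 2L) return("nPerGroup must be >= 2")
        TRUE
    })

#' A simulated dataset with ground truth
#'
#' @slot countTable the simulated [CountTable] (`group` column set to
#'   `"grp1"`/`"grp2"`).
#' @slot truth data.frame with `feature_id`, `is_da`, `direction`
#'   (`"up"`/`"down"` in group 2, `"none"` otherwise).
#' @slot params list with the realized per-group relative means and
#'   zero-inflation probabilities.
#' @export
setClass("SimulatedDataset",
    representation(countTable = "CountTable", truth = "data.frame",
                   params = "list"))

#' Concordance-at-the-top curve
#'
#' `values[i]` is the fraction of shared features among the top `i` entries
#' of two ranked lists, for `i = 1..R`; entries beyond the comparable depth
#' are `NA`.
#'
#' @slot R integer, maximum rank.
#' @slot values numeric in `[0, 1]` (or `NA`), length `R`.
#' @export
setClass("CATCurve",
    representation(R = "integer", values = "numeric"),
    validity = function(object) {
        if (length(object@values) != object@R)
            return("values must have length R")
        v <- object@values[!is.na(object@values)]
        if (any(v < -1e-12 | v > 1 + 1e-12))
            return("values must lie in [0, 1]")
        TRUE
    })
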