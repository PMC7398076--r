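#' Construct a CountTable
#'
#' Builds a validated [CountTable-class] from a matrix of non-negative
#' integer counts with features in rows and samples in columns. Metadata
#' fields that are not supplied are filled with the sentinel `"absent"`;
#' library sizes are always recomputed from the counts.
#'
#' @param counts integer matrix, features x samples, with row and column
#'   names (unique feature and sample ids).
#' @param sampleData optional data.frame with a `sample_id` column and any of
#'   `subject_id`, `group`, `center`; rows are matched to samples by id.
#' @param featureData optional data.frame with a `feature_id` column and any
#'   of `taxonomy`, `metabolism`; rows are matched to features by id.
#' @param transposed set to `TRUE` if `counts` is samples x features; the
#'   orientation is never guessed.
#'
#' @return A [CountTable-class].
#' @examples
#' y <- matrix(rpois(12, 5), 3, 4,
#'             dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
#' ct <- CountTable(y)
#' libSizes(ct)
#' @export
CountTable <- function(counts, sampleData = NULL, featureData = NULL,
                       transposed = FALSE) {
    counts <- as.matrix(counts)
    if (transposed)
        counts <- t(counts)
    if (is.null(rownames(counts)))
        stop("counts must have feature ids as row names")
    if (is.null(colnames(counts)))
        stop("counts must have sample ids as column names")
    if (anyNA(counts) || !is.numeric(counts))
        stop("counts must be numeric with no missing values")
    if (any(counts < 0) || any(counts != round(counts)))
        stop("counts must be non-negative integers")
    storage.mode(counts) <- "double"

    sid <- colnames(counts)
    cd <- DataFrame(sample_id = sid, subject_id = "absent",
                    group = "absent", center = "absent", row.names = sid)
    if (!is.null(sampleData)) {
        sampleData <- as.data.frame(sampleData)
        if (!"sample_id" %in% colnames(sampleData))
            stop("sampleData must have a sample_id column")
        idx <- match(sid, sampleData$sample_id)
        for (col in c("subject_id", "group", "center"))
            if (col %in% colnames(sampleData)) {
                v <- as.character(sampleData[[col]])[idx]
                v[is.na(v) | v == ""] <- "absent"
                cd[[col]] <- v
            }
    }
    cd$library_size <- unname(colSums(counts))

    fid <- rownames(counts)
    rd <- DataFrame(feature_id = fid, taxonomy = "absent",
                    metabolism = "absent", row.names = fid)
    if (!is.null(featureData)) {
        featureData <- as.data.frame(featureData)
        if (!"feature_id" %in% colnames(featureData))
            stop("featureData must have a feature_id column")
        idx <- match(fid, featureData$feature_id)
        for (col in c("taxonomy", "metabolism"))
            if (col %in% colnames(featureData)) {
                v <- as.character(featureData[[col]])[idx]
                v[is.na(v) | v == ""] <- "absent"
                rd[[col]] <- v
            }
    }

    se <- SummarizedExperiment(assays = SimpleList(counts = counts),
                               colData = cd, rowData = rd)
    new("CountTable", se)
}

.refreshLibSizes <- function(ct) {
    colData(ct)$library_size <- unname(colSums(assay(ct, "counts")))
    validObject(ct)
    ct
}

#' @describeIn CountTable counts accessor.
#' @param object,ct a `CountTable`.
#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "CountTable", function(object) assay(object, "counts"))

#' Library sizes of a CountTable
#'
#' @param ct a [CountTable-class].
#' @return Named numeric vector of per-sample total counts.
#' @export
libSizes <- function(ct) {
    stopifnot(is(ct, "CountTable"))
    ls <- colData(ct)$library_size
    names(ls) <- colnames(ct)
    ls
}

#' Sample metadata of a CountTable
#' @param ct a [CountTable-class].
#' @return data.frame with sample_id, subject_id, group, center, library_size.
#' @export
sampleData <- function(ct) {
    stopifnot(is(ct, "CountTable"))
    as.data.frame(colData(ct))
}

#' Feature metadata of a CountTable
#' @param ct a [CountTable-class].
#' @return data.frame with feature_id, taxonomy, metabolism.
#' @export
featureData <- function(ct) {
    stopifnot(is(ct, "CountTable"))
    as.data.frame(rowData(ct))
}

setMethod("show", "CountTable", function(object) {
    y <- assay(object, "counts")
    cat(sprintf("CountTable: %d features x %d samples\n",
                nrow(y), ncol(y)))
    cat(sprintf("  library sizes: %s .. %s (median %s)\n",
                format(min(colSums(y))), format(max(colSums(y))),
                format(stats::median(colSums(y)))))
    cat(sprintf("  zero fraction: %.3f\n", mean(y == 0)))
    grp <- table(colData(object)$group)
    cat("  groups:", paste(sprintf("%s (%d)", names(grp), grp),
                           collapse = ", "), "\n")
    invisible(NULL)
})

#' Read a count table (and optional metadata) from TSV files
#'
#' The count file is tab-separated with feature ids in the first column
#' (header `feature_id`) and sample ids in the header row. Sample metadata
#' columns: `sample_id`, `subject_id`, `group`, `center`; feature metadata
#' columns: `feature_id`, `taxonomy`, `metabolism`. Non-integer or negative
#' cells and duplicated ids are rejected.
#'
#' @param path path to the count TSV.
#' @param sampleMetaPath,featureMetaPath optional metadata TSV paths.
#' @return A [CountTable-class].
#' @seealso [writeCountTable()]
#' @export
readCountTable <- function(path, sampleMetaPath = NULL,
                           featureMetaPath = NULL) {
    if (!file.exists(path))
        stop("count file not found: ", path)
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 3L)
        stop("malformed count table header: need feature_id plus >= 2 samples")
    fid <- as.character(tab[[1L]])
    if (anyDuplicated(fid))
        stop("duplicated feature ids in count table")
    if (anyDuplicated(colnames(tab)[-1L]))
        stop("duplicated sample ids in count table")
    body <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(body))
        stop("non-numeric counts in count table")
    if (anyNA(body) || any(body < 0) || any(body != round(body)))
        stop("counts must be non-negative integers")
    rownames(body) <- fid
    sm <- if (!is.null(sampleMetaPath))
        utils::read.delim(sampleMetaPath, sep = "\t",
                          stringsAsFactors = FALSE) else NULL
    fm <- if (!is.null(featureMetaPath))
        utils::read.delim(featureMetaPath, sep = "\t",
                          stringsAsFactors = FALSE) else NULL
    CountTable(body, sampleData = sm, featureData = fm)
}

#' Write a CountTable to TSV files
#'
#' @param ct a [CountTable-class].
#' @param path output path for the count TSV.
#' @param sampleMetaPath,featureMetaPath optional output paths for the
#'   metadata TSVs.
#' @return Invisibly, `path`.
#' @export
writeCountTable <- function(ct, path, sampleMetaPath = NULL,
                            featureMetaPath = NULL) {
    stopifnot(is(ct, "CountTable"))
    y <- counts(ct)
    out <- data.frame(feature_id = rownames(y), y, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(sampleMetaPath))
        utils::write.table(sampleData(ct), sampleMetaPath, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    if (!is.null(featureMetaPath))
        utils::write.table(featureData(ct), featureMetaPath, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    invisible(path)
}
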