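#' Fit one of the five candidate models to every feature
#'
#' Fits an intercept-only model per feature (samples are assumed
#' homogeneous, with normalization entering through offsets or covariates)
#' and reduces it to the two quantities the goodness-of-fit analysis
#' compares: the estimated mean on the `log2(. + 1)` scale and the
#' estimated probability of a zero count.
#'
#' \describe{
#'   \item{NB}{per-feature negative binomial GLM (edgeR machinery: tagwise
#'     dispersions shrunk toward a trend), with `log` effective library
#'     size offsets; `P(0) = (1 + phi * mu)^(-1/phi)`.}
#'   \item{ZINB}{penalized maximum likelihood with a common dispersion
#'     (the simulation-template model); the estimated mean is
#'     `(1 - pi) * mu` and `P(0) = pi + (1 - pi) * (1 + phi * mu)^(-1/phi)`.}
#'   \item{ZIG}{zero-inflated Gaussian mixture EM on `log2(count + 1)` with
#'     CSS offsets; the mixing probability follows a logistic regression on
#'     log library size and is reported as `P(0)`; the mean is the mixture
#'     mean on the log2 scale (which reproduces the model's visible
#'     underestimation of observed means).}
#'   \item{HURDLE}{logistic detection model with the sample detection rate
#'     (CDR) as covariate plus a Gaussian model on the positive
#'     log-transformed counts; `P(0) = 1 -` fitted detection probability.}
#'   \item{DM}{Dirichlet-multinomial ML on the concentration vector; the
#'     mean is `lib_j * alpha_f / alpha_0` averaged over samples and `P(0)`
#'     is the average beta-binomial marginal.}
#' }
#'
#' @param ct a [CountTable-class] (n >= 3 samples).
#' @param model one of `"NB"`, `"ZINB"`, `"ZIG"`, `"HURDLE"`, `"DM"`.
#' @param norm optional [NormFactors-class] supplying offsets for the NB
#'   fit (default TMM).
#' @param epsilon ZINB penalty scale; parameter norms are penalized by
#'   `||par||^2 / (2 * epsilon)`, so the default `1e10` is a very weak
#'   ridge used for numerical stability (use `1e14` when estimating
#'   simulation templates).
#' @param commonDispersion ZINB: estimate a single dispersion for all
#'   features (default `TRUE`).
#' @param piFixed ZINB: optionally fix the zero-inflation probability
#'   (e.g. `0` reduces the fit to a plain NB maximum likelihood).
#' @param scaleScheme transformation for the Gaussian models
#'   (`"css_log_median"` or `"css_log_thousand"` for ZIG;
#'   `"log2_median_libsize"` or `"log2_cpm"` for HURDLE).
#' @return A [FitResult-class].
#' @seealso [gofSummary()], [rankModels()]
#' @export
fitModel <- function(ct, model = c("NB", "ZINB", "ZIG", "HURDLE", "DM"),
                     norm = NULL, epsilon = 1e10, commonDispersion = TRUE,
                     piFixed = NULL, scaleScheme = NULL) {
    stopifnot(is(ct, "CountTable"))
    model <- match.arg(model)
    if (ncol(ct) < 3L)
        stop("model fitting needs at least 3 samples")
    y <- counts(ct)
    res <- switch(model,
        NB = {
            off <- if (is.null(norm)) NULL else normOffsets(norm)
            r <- .fitNB(y, offsets = off)
            list(mean = r$mean, zeroProb = r$zeroProb,
                 params = list(mu = rowMeans(r$mu), phi = r$phi),
                 converged = r$converged)
        },
        ZINB = {
            r <- .fitZINB(y, epsilon = epsilon,
                          commonDispersion = commonDispersion,
                          piFixed = piFixed)
            list(mean = r$mean, zeroProb = r$zeroProb,
                 params = list(mu = r$mu, pi = r$pi, phi = r$phi),
                 converged = r$converged)
        },
        ZIG = {
            ss <- if (is.null(scaleScheme)) "css_log_median" else scaleScheme
            r <- .fitZIG(ct, scaleScheme = ss)
            list(mean = r$mean, zeroProb = r$zeroProb,
                 params = list(fits = r$fits, scaleScheme = ss),
                 converged = r$converged)
        },
        HURDLE = {
            ss <- if (is.null(scaleScheme)) "log2_median_libsize"
                  else scaleScheme
            r <- .fitHurdle(ct, scaleScheme = ss)
            list(mean = r$mean, zeroProb = r$zeroProb,
                 params = list(fits = r$fits, scaleScheme = ss),
                 converged = r$converged)
        },
        DM = {
            r <- .fitDM(y)
            list(mean = r$mean, zeroProb = r$zeroProb,
                 params = list(alpha = r$alpha, alpha0 = r$alpha0),
                 converged = r$converged)
        })
    zp <- pmin(pmax(res$zeroProb, 0), 1)
    new("FitResult", model = model, mean = res$mean, zeroProb = zp,
        params = res$params, converged = res$converged)
}

#' @describeIn fitModel model label accessor.
#' @param fit a [FitResult-class].
#' @export
fitModelName <- function(fit) {
    stopifnot(is(fit, "FitResult"))
    fit@model
}

#' @describeIn fitModel parameter list accessor.
#' @export
fitParams <- function(fit) {
    stopifnot(is(fit, "FitResult"))
    fit@params
}

setMethod("show", "FitResult", function(object) {
    cat(sprintf("FitResult (%s): %d features, %d converged\n",
                object@model, length(object@mean), sum(object@converged)))
    invisible(NULL)
})

#' Goodness-of-fit summary: mean difference and zero probability difference
#'
#' Compares the fitted model against the observations feature by feature:
#' `MD_f` is the estimated minus the observed mean, both on the
#' `log2(. + 1)` scale, and `ZPD_f` is the model zero probability minus the
#' observed zero frequency. Both are summarized by their root mean squared
#' error over converged features.
#'
#' The observed mean is `log2(mean(y) + 1)` by default (the mean computed
#' on the count scale, then log-transformed); set
#' `observedMean = "mean_log2"` for the mean of the log-transformed counts
#' instead.
#'
#' @param fit a [FitResult-class] produced on `ct`.
#' @param ct the [CountTable-class] the fit was produced on.
#' @param observedMean `"log2_mean"` (default) or `"mean_log2"`.
#' @return A list with `model`, `md`, `zpd` (named per-feature vectors over
#'   converged features), `rmseMean`, `rmseZpd` and `nExcluded`
#'   (non-converged features excluded from the RMSEs).
#' @export
gofSummary <- function(fit, ct, observedMean = c("log2_mean", "mean_log2")) {
    stopifnot(is(fit, "FitResult"), is(ct, "CountTable"))
    observedMean <- match.arg(observedMean)
    y <- counts(ct)
    if (!identical(rownames(y), names(fit@mean)))
        stop("fit and count table cover different feature sets")
    obsMean <- if (observedMean == "log2_mean")
        log2(rowMeans(y) + 1)
    else
        rowMeans(log2(y + 1))
    obsZero <- rowMeans(y == 0)
    ok <- fit@converged & is.finite(fit@mean) & is.finite(fit@zeroProb)
    md <- (fit@mean - obsMean)[ok]
    zpd <- (fit@zeroProb - obsZero)[ok]
    list(model = fit@model, md = md, zpd = zpd,
         rmseMean = sqrt(mean(md^2)), rmseZpd = sqrt(mean(zpd^2)),
         nExcluded = sum(!ok))
}

#' Average-rank table across models and datasets
#'
#' Within each dataset, models are ranked by their RMSE (1 = lowest, mean
#' ranks for ties), and ranks are averaged across datasets.
#'
#' @param summaries a data.frame with columns `model`, `dataset` and
#'   `rmse` (one row per model and dataset).
#' @return A data.frame with `model`, `avgRank` and `avgRmse`, sorted by
#'   average rank.
#' @export
rankModels <- function(summaries) {
    stopifnot(all(c("model", "dataset", "rmse") %in% colnames(summaries)))
    if (length(unique(summaries$model)) < 2L)
        stop("at least two models are needed for ranking")
    ranks <- do.call(rbind, lapply(split(summaries, summaries$dataset),
        function(d) {
            d$rank <- rank(d$rmse, ties.method = "average")
            d
        }))
    agg <- stats::aggregate(cbind(rank, rmse) ~ model, data = ranks, FUN = mean)
    out <- data.frame(model = agg$model, avgRank = agg$rank,
                      avgRmse = agg$rmse)
    out[order(out$avgRank), , drop = FALSE]
}
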