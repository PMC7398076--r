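## Zero-inflated Gaussian mixture and truncated Gaussian hurdle fits on
## log2-transformed counts. Both are two-part models: a discrete component
## for the zeros (logistic on log library size for ZIG, logistic on the
## sample detection rate for the hurdle) and a Gaussian component for the
## log-scale signal.

## One feature's ZIG EM. t: transformed values, o: per-sample log2 offsets,
## x: covariate of the zero model (log library size), design: model matrix
## of the Gaussian part. Returns coefficients, sigma2, per-sample mixing
## probabilities and posterior weights.
.zigEmFeature <- function(t, o, x, design, maxIter = 100L, tol = 1e-6) {
    n <- length(t)
    isZero <- t == 0
    z <- ifelse(isZero, 0.7, 0)          # initial zero-component posterior
    piHat <- rep(mean(isZero), n)
    ll <- -Inf
    beta <- NULL
    sigma2 <- stats::var(t)
    conv <- FALSE
    for (iter in seq_len(maxIter)) {
        ## M-step: weighted Gaussian regression with offset
        w <- 1 - z
        if (sum(w) < 2 || sum(w > 1e-8) < ncol(design) + 1L)
            break
        fit <- stats::lm.wfit(design, t - o, w)
        beta <- fit$coefficients
        resid <- t - o - drop(design %*% ifelse(is.na(beta), 0, beta))
        sigma2 <- max(sum(w * resid^2) / max(sum(w), 1e-8), 1e-6)
        ## zero-rate logistic on log library size
        zc <- pmin(pmax(z, 1e-6), 1 - 1e-6)
        lfit <- try(suppressWarnings(
            stats::glm.fit(cbind(1, x), zc,
                           family = stats::quasibinomial())), silent = TRUE)
        piHat <- if (inherits(lfit, "try-error") || !lfit$converged)
            rep(mean(z), n)
        else
            pmin(pmax(lfit$fitted.values, 1e-6), 1 - 1e-6)
        ## E-step
        dens <- stats::dnorm(t, mean = o + drop(design %*%
                             ifelse(is.na(beta), 0, beta)),
                             sd = sqrt(sigma2))
        num <- piHat * as.numeric(isZero)
        den <- num + (1 - piHat) * pmax(dens, 1e-12)
        z <- ifelse(isZero, num / den, 0)
        llNew <- sum(log(pmax(ifelse(isZero, den, (1 - piHat) * dens),
                              1e-300)))
        if (is.finite(ll) && abs(llNew - ll) < tol * (abs(llNew) + 1)) {
            conv <- TRUE
            ll <- llNew
            break
        }
        ll <- llNew
    }
    list(beta = beta, sigma2 = sigma2, pi = piHat, weights = 1 - z,
         fitted = if (is.null(beta)) rep(NA_real_, n)
                  else o + drop(design %*% ifelse(is.na(beta), 0, beta)),
         converged = conv && !is.null(beta) && !anyNA(beta))
}

.fitZIG <- function(ct, scaleScheme = c("css_log_median",
                                        "css_log_thousand"),
                    design = NULL) {
    scaleScheme <- match.arg(scaleScheme)
    tr <- transformCounts(ct, scaleScheme)
    t <- tr$matrix
    o <- tr$offsets
    x <- log(libSizes(ct))
    n <- ncol(t)
    if (is.null(design))
        design <- matrix(1, n, 1L)
    res <- lapply(seq_len(nrow(t)), function(f)
        .zigEmFeature(t[f, ], o, x, design))
    pi <- do.call(rbind, lapply(res, `[[`, "pi"))
    fitted <- do.call(rbind, lapply(res, `[[`, "fitted"))
    conv <- vapply(res, `[[`, logical(1L), "converged")
    ## estimated mean on the log2 scale: mixture mean with a point mass at 0
    mHat <- rowMeans((1 - pi) * fitted)
    names(mHat) <- rownames(t)
    list(fits = res,
         mean = mHat,
         zeroProb = setNames(rowMeans(pi), rownames(t)),
         converged = setNames(conv, rownames(t)),
         transform = tr)
}

#' Sample detection rates
#'
#' The detection rate of a sample is the fraction of features with a
#' positive count; it enters the hurdle model as a normalization covariate.
#'
#' @param ct a [CountTable-class].
#' @return Named numeric vector in `[0, 1]`.
#' @export
detectionRates <- function(ct) {
    stopifnot(is(ct, "CountTable"))
    colMeans(counts(ct) > 0)
}

.fitHurdle <- function(ct, scaleScheme = c("log2_median_libsize",
                                           "log2_cpm"),
                       design = NULL) {
    scaleScheme <- match.arg(scaleScheme)
    tr <- transformCounts(ct, scaleScheme)
    t <- tr$matrix
    y <- counts(ct)
    cdr <- detectionRates(ct)
    n <- ncol(y)
    base <- if (is.null(design)) matrix(1, n, 1L) else design
    X <- cbind(base, cdr = cdr)
    res <- lapply(seq_len(nrow(y)), function(f) {
        pos <- y[f, ] > 0
        det <- try(suppressWarnings(
            stats::glm.fit(X, as.numeric(pos),
                           family = stats::binomial())), silent = TRUE)
        if (inherits(det, "try-error"))
            return(list(converged = FALSE))
        pDet <- pmin(pmax(det$fitted.values, 1e-8), 1 - 1e-8)
        if (sum(pos) <= ncol(X))
            return(list(pDet = pDet, converged = FALSE))
        cf <- stats::lm.fit(X[pos, , drop = FALSE], t[f, pos])
        beta <- ifelse(is.na(cf$coefficients), 0, cf$coefficients)
        muPos <- drop(X %*% beta)
        list(pDet = pDet, muPos = muPos,
             sigma2 = sum(cf$residuals^2) / max(cf$df.residual, 1L),
             converged = !any(is.na(cf$coefficients)))
    })
    conv <- vapply(res, function(r) isTRUE(r$converged), logical(1L))
    mHat <- vapply(res, function(r)
        if (isTRUE(r$converged)) mean(r$pDet * r$muPos) else NA_real_,
        numeric(1L))
    p0 <- vapply(res, function(r)
        if (!is.null(r$pDet)) mean(1 - r$pDet) else NA_real_, numeric(1L))
    list(fits = res,
         mean = setNames(mHat, rownames(y)),
         zeroProb = setNames(p0, rownames(y)),
         converged = setNames(conv, rownames(y)),
         transform = tr)
}
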