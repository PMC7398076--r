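## NB and ZINB per-feature fits (intercept-only designs, as used by the
## goodness-of-fit analysis and the simulation templates).

#' @importFrom stats dnbinom optim optimize setNames
NULL

.nbZeroProb <- function(mu, phi) {
    ## P(Y = 0) for NB with mean mu, dispersion phi; Poisson limit at
    ## phi = 0. phi may be scalar or per-feature (recycled along the rows
    ## of a features x samples mu matrix).
    res <- exp(-log1p(phi * mu) / phi)
    sel <- phi < 1e-12
    if (any(sel)) {
        pois <- exp(-mu)
        if (is.matrix(mu) && length(sel) > 1L)
            sel <- matrix(sel, nrow(mu), ncol(mu))
        res[sel] <- pois[sel]
    }
    res
}

.fitNB <- function(y, offsets = NULL) {
    n <- ncol(y)
    if (is.null(offsets))
        offsets <- log(colSums(y))
    design <- matrix(1, n, 1L)
    d <- edgeR::DGEList(counts = y, lib.size = exp(offsets))
    d <- edgeR::estimateDisp(d, design)
    fit <- edgeR::glmFit(d, design, dispersion = d$tagwise.dispersion)
    mu <- fit$fitted.values
    phi <- d$tagwise.dispersion
    p0 <- rowMeans(.nbZeroProb(mu, phi))
    list(mu = mu, phi = phi,
         mean = log2(rowMeans(mu) + 1),
         zeroProb = p0,
         converged = setNames(rep(TRUE, nrow(y)), rownames(y)))
}

.zinbNegLogLik <- function(y, mu, pi, theta) {
    mu <- max(mu, 1e-12)
    pi <- min(max(pi, 0), 1 - 1e-12)
    p0 <- suppressWarnings(dnbinom(0, size = theta, mu = mu))
    ll <- suppressWarnings(ifelse(y == 0,
                 log(pi + (1 - pi) * p0),
                 log1p(-pi) + dnbinom(y, size = theta, mu = mu,
                                      log = TRUE)))
    out <- -sum(ll)
    if (!is.finite(out)) 1e12 else out
}

.zinbFitFeature <- function(y, theta, epsilon, piFixed = NULL) {
    ybar <- mean(y)
    zf <- mean(y == 0)
    if (!is.null(piFixed)) {
        ## pi held fixed: the ML mean of an intercept-only NB is the sample
        ## mean scaled by the non-inflated fraction
        mu <- if (piFixed < 1) ybar / (1 - piFixed) else 0
        return(c(mu = mu, pi = piFixed, converged = 1,
                 nll = .zinbNegLogLik(y, mu, piFixed, theta)))
    }
    start <- c(logmu = log(max(ybar, 1e-4)),
               lpi = stats::qlogis(min(max(zf * 0.5 + 1e-3, 1e-3), 1 - 1e-3)))
    fn <- function(par) {
        mu <- exp(par[1L])
        pi <- stats::plogis(par[2L])
        .zinbNegLogLik(y, mu, pi, theta) + sum(par^2) / (2 * epsilon)
    }
    opt <- try(optim(start, fn, method = "L-BFGS-B",
                     lower = c(-30, -15), upper = c(30, 15)), silent = TRUE)
    if (inherits(opt, "try-error"))
        return(c(mu = ybar, pi = zf, converged = 0,
                 nll = .zinbNegLogLik(y, max(ybar, 1e-8), zf, theta)))
    c(mu = exp(opt$par[1L]), pi = stats::plogis(opt$par[2L]),
      converged = as.numeric(opt$convergence == 0), nll = opt$value)
}

.fitZINB <- function(y, epsilon = 1e10, commonDispersion = TRUE,
                     piFixed = NULL, maxOuter = 4L, tol = 1e-6) {
    nF <- nrow(y)
    ## moment start for the common dispersion
    m <- rowMeans(y)
    v <- matrixStats::rowVars(y)
    phi0 <- stats::median(pmax((v - m) / pmax(m^2, 1e-8), 1e-3), na.rm = TRUE)
    theta <- 1 / phi0
    fits <- NULL
    lastNll <- Inf
    for (it in seq_len(maxOuter)) {
        fits <- t(vapply(seq_len(nF), function(f)
            .zinbFitFeature(y[f, ], theta, epsilon, piFixed),
            c(mu = 0, pi = 0, converged = 0, nll = 0)))
        nll <- sum(fits[, "nll"])
        ## common-dispersion update given (mu, pi)
        if (commonDispersion) {
            obj <- function(ltheta) {
                th <- exp(ltheta)
                sum(vapply(seq_len(nF), function(f)
                    .zinbNegLogLik(y[f, ], fits[f, "mu"], fits[f, "pi"], th),
                    numeric(1L)))
            }
            ltheta <- optimize(obj, c(-12, 12))$minimum
            theta <- exp(ltheta)
        }
        if (abs(lastNll - nll) < tol * (abs(nll) + 1))
            break
        lastNll <- nll
    }
    mu <- fits[, "mu"]
    pi <- fits[, "pi"]
    phi <- 1 / theta
    names(mu) <- names(pi) <- rownames(y)
    list(mu = mu, pi = pi, phi = phi,
         mean = log2((1 - pi) * mu + 1),
         zeroProb = pmin(pmax(pi + (1 - pi) * .nbZeroProb(mu, phi), 0), 1),
         converged = setNames(fits[, "converged"] > 0, rownames(y)))
}
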