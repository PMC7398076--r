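## Dirichlet-multinomial fit (intercept-only): maximum likelihood on the
## concentration vector alpha via the standard fixed-point iteration, with
## a method-of-moments start. The zero probability of a feature under the
## DM is the beta-binomial marginal P(Y = 0 | n_j, alpha_f, alpha_0 -
## alpha_f), averaged over samples, computed in log-gamma arithmetic.

.dmMomentStart <- function(y) {
    props <- sweep(y, 2L, colSums(y), "/")
    p <- rowMeans(props)
    v <- matrixStats::rowVars(props)
    p <- pmax(p, 1e-10)
    ## moment estimate of the precision alpha0 from the proportion variances
    ratio <- v / pmax(p * (1 - p), 1e-12)
    ratio <- ratio[is.finite(ratio) & ratio > 0 & ratio < 1]
    a0 <- if (length(ratio)) stats::median(1 / ratio - 1) else 1
    a0 <- min(max(a0, 1e-2), 1e6)
    p / sum(p) * a0
}

.dmLogLik <- function(y, alpha) {
    n <- colSums(y)
    a0 <- sum(alpha)
    sum(lgamma(a0) - lgamma(n + a0)) +
        sum(lgamma(y + alpha) - lgamma(alpha))
}

.fitDM <- function(y, maxIter = 200L, tol = 1e-8) {
    alpha <- .dmMomentStart(y)
    n <- colSums(y)
    ll <- .dmLogLik(y, alpha)
    conv <- FALSE
    for (it in seq_len(maxIter)) {
        a0 <- sum(alpha)
        denom <- sum(digamma(n + a0) - digamma(a0))
        num <- rowSums(digamma(y + alpha) - digamma(alpha))
        alphaNew <- alpha * num / denom
        alphaNew <- pmax(alphaNew, 1e-10)
        llNew <- .dmLogLik(y, alphaNew)
        alpha <- alphaNew
        if (abs(llNew - ll) < tol * (abs(llNew) + 1)) {
            conv <- TRUE
            break
        }
        ll <- llNew
    }
    a0 <- sum(alpha)
    ## per-feature expected counts and beta-binomial zero probabilities
    meanCounts <- rowMeans(outer(alpha / a0, n))
    p0 <- vapply(seq_len(nrow(y)), function(f) {
        b <- a0 - alpha[f]
        mean(exp(lgamma(b + n) + lgamma(a0) - lgamma(a0 + n) - lgamma(b)))
    }, numeric(1L))
    list(alpha = alpha, alpha0 = a0,
         mean = setNames(log2(meanCounts + 1), rownames(y)),
         zeroProb = setNames(pmin(pmax(p0, 0), 1), rownames(y)),
         converged = setNames(rep(conv, nrow(y)), rownames(y)))
}
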