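## Shared fixtures, all generated in code.

makeCounts <- function(F = 6L, n = 4L, seed = 1L, lambda = 20) {
    withr::with_seed(seed, {
        y <- matrix(rpois(F * n, lambda), F, n,
                    dimnames = list(sprintf("f%02d", seq_len(F)),
                                    sprintf("s%02d", seq_len(n))))
    })
    CountTable(y)
}

## NB table with known per-feature means and common dispersion; no group
## structure unless foldEffect is supplied for the second half of samples.
makeNBTable <- function(F = 50L, n = 20L, phi = 0.5, seed = 1L,
                        meanRange = c(2, 200)) {
    withr::with_seed(seed, {
        mu <- exp(runif(F, log(meanRange[1L]), log(meanRange[2L])))
        y <- matrix(rnbinom(F * n, size = 1 / phi, mu = mu), F, n,
                    dimnames = list(sprintf("f%02d", seq_len(F)),
                                    sprintf("s%02d", seq_len(n))))
    })
    list(ct = CountTable(y), mu = mu, phi = phi)
}

balancedGroups <- function(ct) {
    n <- ncol(ct)
    rep(c("grpA", "grpB"), each = ceiling(n / 2))[seq_len(n)]
}
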