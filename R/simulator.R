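#' Estimate a simulation template from a count table
#'
#' Fits the ZINB (or NB) model with a common dispersion and a strong
#' penalty relaxation (`epsilon = 1e14`) and reduces it to the template
#' parameters: per-feature relative means (normalized fitted means), the
#' common dispersion, per-feature zero-inflation probabilities (ZINB) and
#' the empirical library sizes, which [simulateDataset()] resamples with
#' replacement.
#'
#' @param ct a [CountTable-class], already filtered with [filterCounts()].
#' @param distribution `"NB"` or `"ZINB"`.
#' @param epsilon penalty scale of the ZINB fit (default 1e14).
#' @return A [TemplateParams-class].
#' @export
estimateTemplate <- function(ct, distribution = c("NB", "ZINB"),
                             epsilon = 1e14) {
    stopifnot(is(ct, "CountTable"))
    distribution <- match.arg(distribution)
    y <- counts(ct)
    lib <- libSizes(ct)
    if (distribution == "ZINB") {
        ## fit on depth-scaled counts so mu is proportional to the
        ## relative mean
        fit <- .fitZINB(y, epsilon = epsilon, commonDispersion = TRUE)
        mu <- fit$mu
        pi <- fit$pi
        phi <- fit$phi
        if (mean(fit$converged) < 0.5) {
            warning("majority of features did not converge; ",
                    "falling back to method-of-moments template")
            mu <- rowMeans(y)
            pi <- pmax(rowMeans(y == 0) - .nbZeroProb(mu, phi), 0)
        }
    } else {
        fit <- .fitZINB(y, epsilon = epsilon, commonDispersion = TRUE,
                        piFixed = 0)
        mu <- fit$mu
        pi <- setNames(rep(0, nrow(y)), rownames(y))
        phi <- fit$phi
    }
    mu <- pmax(mu, 1e-10)
    r <- mu / sum(mu)
    new("TemplateParams", distribution = distribution, relMeans = r,
        dispersion = phi, zeroProb = pi, libSizes = unname(lib))
}

#' Bundled synthetic templates
#'
#' Deterministically generated templates emulating the two sequencing
#' platforms: a 16S-like template (library sizes around 5e3, high
#' sparsity) and a WMS-like one (library sizes around 1e6, heavier tail of
#' abundant features, zero inflation concentrated in rare features). Both
#' use log-normally spread relative means over `F` features. No download
#' is needed: the templates are pure functions of their arguments.
#'
#' @param F number of features (default 900).
#' @param seed integer seed for the deterministic draws.
#' @return A [TemplateParams-class].
#' @export
template16S <- function(F = 900L, seed = 7L) {
    withr::with_seed(seed, {
        r <- stats::rlnorm(F, meanlog = 0, sdlog = 2.2)
        r <- sort(r, decreasing = TRUE) / sum(r)
        pi <- pmin(pmax(stats::rbeta(F, 1.2, 3) *
                        (1 - rank(r) / F) * 0.9, 0), 0.95)
        lib <- round(stats::rlnorm(60L, meanlog = log(5e3), sdlog = 0.35))
    })
    names(r) <- sprintf("taxon%03d", seq_len(F))
    names(pi) <- names(r)
    new("TemplateParams", distribution = "ZINB", relMeans = r,
        dispersion = 0.9, zeroProb = pi, libSizes = pmax(lib, 1000))
}

#' @rdname template16S
#' @export
templateWMS <- function(F = 900L, seed = 11L) {
    withr::with_seed(seed, {
        r <- stats::rlnorm(F, meanlog = 0, sdlog = 3.5)
        r <- sort(r, decreasing = TRUE) / sum(r)
        pi <- pmin(pmax(0.05 + stats::rbeta(F, 1.4, 2) *
                        (rank(-r) / F)^0.7 * 0.85, 0), 0.9)
        lib <- round(stats::rlnorm(60L, meanlog = log(1.2e6), sdlog = 0.3))
    })
    names(r) <- sprintf("taxon%03d", seq_len(F))
    names(pi) <- names(r)
    new("TemplateParams", distribution = "ZINB", relMeans = r,
        dispersion = 0.5, zeroProb = pi, libSizes = pmax(lib, 1e6))
}

#' Build a simulation design
#'
#' One cell of the simulation grid, with the defaults of the benchmarking
#' framework: sample sizes per group in `{10, 20, 40}`, DA proportion in
#' `{0.10, 0.50}`, fold effect in `{2, 5}`, optional compensation, and
#' for ZINB designs a sparsity effect in `{0, 0.05, 0.15}`.
#'
#' @param distribution `"NB"` or `"ZINB"`.
#' @param nPerGroup samples per condition.
#' @param daProportion fraction of features injected as DA.
#' @param foldEffect multiplicative effect (> 1) on the relative means.
#' @param compensation conserve the flagged set's total relative mean.
#' @param sparsityEffect additive shift of the ZINB mixing probability.
#' @param replicates datasets per cell (default 50).
#' @param seed base seed.
#' @return A [SimulationDesign-class].
#' @export
simulationDesign <- function(distribution = "NB", nPerGroup = 20L,
                             daProportion = 0.1, foldEffect = 2,
                             compensation = FALSE, sparsityEffect = 0,
                             replicates = 50L, seed = 1L) {
    if (distribution == "NB")
        sparsityEffect <- 0
    new("SimulationDesign", distribution = distribution,
        nPerGroup = as.integer(nPerGroup), daProportion = daProportion,
        foldEffect = foldEffect, compensation = compensation,
        sparsityEffect = sparsityEffect,
        replicates = as.integer(replicates), seed = as.integer(seed))
}

#' The full simulation grid
#'
#' Enumerates the factorial of the framework's simulation variables for
#' one distribution: `nPerGroup` in {10, 20, 40} x `daProportion` in
#' {0.10, 0.50} x `foldEffect` in {2, 5} x compensation {off, on} x
#' (for ZINB) `sparsityEffect` in {0, 0.05, 0.15}.
#'
#' @param distribution `"NB"` or `"ZINB"`.
#' @param replicates datasets per cell.
#' @param seed base seed.
#' @return A list of [SimulationDesign-class] objects.
#' @export
simulationGrid <- function(distribution = c("NB", "ZINB"),
                           replicates = 50L, seed = 1L) {
    distribution <- match.arg(distribution)
    sparsity <- if (distribution == "ZINB") c(0, 0.05, 0.15) else 0
    grid <- expand.grid(n = c(10L, 20L, 40L), p = c(0.10, 0.50),
                        fe = c(2, 5), comp = c(FALSE, TRUE),
                        sp = sparsity)
    lapply(seq_len(nrow(grid)), function(i)
        simulationDesign(distribution, grid$n[i], grid$p[i], grid$fe[i],
                         grid$comp[i], grid$sp[i], replicates,
                         seed = seed + i))
}

#' Inject differential abundance into a template
#'
#' Flags `round(proportion * F)` features uniformly at random and modifies
#' their relative means for group 2. Without compensation, half of the
#' flagged relative means (floor for the up set) are multiplied by
#' `foldEffect` and the rest divided by it; the whole vector is then
#' renormalized, so unflagged features shift slightly. With compensation,
#' a fraction `1 / (1 + foldEffect)` of the flagged features (floored) is
#' multiplied by `foldEffect` and the remaining flagged features are
#' multiplied by `(a/b) * (1 - foldEffect) + 1`, where `a` and `b` are
#' the total relative mean of the up and down sets; this conserves the
#' flagged set's total mass, so after renormalization the unflagged
#' relative means are untouched.
#'
#' @param template a [TemplateParams-class].
#' @param proportion fraction of features to flag (0 < p < 1, at least 2
#'   features).
#' @param foldEffect multiplicative effect, > 1.
#' @param compensation logical.
#' @param seed integer seed for the flag draw.
#' @return A list with `relMeans1` (group 1, the template means),
#'   `relMeans2` (group 2, renormalized), `modifiedUnnormalized` (group 2
#'   before renormalization), `isDA` (logical flags) and `direction`
#'   (`"up"`, `"down"`, `"none"`).
#' @export
injectDA <- function(template, proportion, foldEffect,
                     compensation = FALSE, seed = 1L) {
    stopifnot(is(template, "TemplateParams"),
              proportion > 0, proportion < 1, foldEffect > 1)
    r <- template@relMeans
    nF <- length(r)
    nDA <- round(proportion * nF)
    if (nDA < 2L)
        stop("round(proportion * F) must be at least 2")
    nUp <- max(if (compensation) floor(nDA / (1 + foldEffect))
               else floor(nDA / 2), 1L)
    for (attempt in seq_len(100L)) {
        ## keep the random draw order: up/down assignment must not depend
        ## on abundance, or the compensation factor can turn non-positive
        flags <- withr::with_seed(.subSeed(seed, 11L, attempt),
                                  sample.int(nF, nDA))
        up <- flags[seq_len(nUp)]
        down <- flags[(nUp + 1L):nDA]
        a <- sum(r[up])
        b <- sum(r[down])
        downFactor <- if (compensation)
            (a / b) * (1 - foldEffect) + 1
        else
            1 / foldEffect
        if (b > 0 && a > 0 && downFactor > 0)
            break
        if (attempt == 100L)
            stop("degenerate flag draw: no admissible up/down split found")
    }
    mod <- r
    mod[up] <- r[up] * foldEffect
    mod[down] <- r[down] * downFactor
    dirn <- rep("none", nF)
    dirn[up] <- "up"
    dirn[down] <- "down"
    isDA <- seq_len(nF) %in% flags
    list(relMeans1 = r,
         relMeans2 = setNames(mod / sum(mod), names(r)),
         modifiedUnnormalized = mod,
         isDA = setNames(isDA, names(r)),
         direction = setNames(dirn, names(r)))
}

#' Sparsity effect on the ZINB mixing probabilities
#'
#' Exacerbates the injected differential abundance through the zeros:
#' down-regulated features gain `sparsityEffect` zero-inflation in group
#' 2, up-regulated features lose it; values falling outside `[0, 1]` are
#' forced to the closer limit. Unflagged features are untouched.
#'
#' @param template a [TemplateParams-class].
#' @param direction per-feature `"up"` / `"down"` / `"none"` (from
#'   [injectDA()]).
#' @param sparsityEffect additive shift, >= 0.
#' @return A list with `zeroProb1` and `zeroProb2`.
#' @export
applySparsityEffect <- function(template, direction, sparsityEffect) {
    stopifnot(is(template, "TemplateParams"), sparsityEffect >= 0)
    if (sparsityEffect > 0 && template@distribution != "ZINB")
        stop("sparsity effects require a ZINB template")
    pi1 <- template@zeroProb
    pi2 <- pi1
    pi2[direction == "down"] <- pi2[direction == "down"] + sparsityEffect
    pi2[direction == "up"] <- pi2[direction == "up"] - sparsityEffect
    pi2 <- pmin(pmax(pi2, 0), 1)
    list(zeroProb1 = pi1, zeroProb2 = pi2)
}

#' Simulate one dataset from a design and template
#'
#' Resamples library sizes with replacement from the template's empirical
#' pool, injects differential abundance per the design, and draws each
#' cell from `NB(lib_j * r_f^(group), phi)`, adding structural zeros with
#' probability `pi_f^(group)` for ZINB. Three separate RNG streams (flag
#' draw, library sizes, counts) are derived from `(design seed,
#' replicate)`, so changing one grid axis does not reshuffle the others.
#' Fully reproducible from `(design, template, replicate)`.
#'
#' @param design a [SimulationDesign-class].
#' @param template a [TemplateParams-class] of matching distribution.
#' @param replicate replicate index (default 1).
#' @param null skip the DA injection entirely (a null dataset; default
#'   `FALSE`).
#' @return A [SimulatedDataset-class].
#' @export
simulateDataset <- function(design, template, replicate = 1L,
                            null = FALSE) {
    stopifnot(is(design, "SimulationDesign"), is(template, "TemplateParams"))
    if (design@distribution != template@distribution)
        stop("design and template distributions differ")
    nF <- length(template@relMeans)
    n <- design@nPerGroup
    seedFlags <- .subSeed(design@seed, 1L, replicate)
    seedLibs <- .subSeed(design@seed, 2L, replicate)
    seedCounts <- .subSeed(design@seed, 3L, replicate)
    if (null) {
        inj <- list(relMeans1 = template@relMeans,
                    relMeans2 = template@relMeans,
                    isDA = setNames(rep(FALSE, nF),
                                    names(template@relMeans)),
                    direction = setNames(rep("none", nF),
                                         names(template@relMeans)))
    } else {
        inj <- injectDA(template, design@daProportion, design@foldEffect,
                        design@compensation, seed = seedFlags)
    }
    pis <- applySparsityEffect(template, inj$direction,
                               if (null) 0 else design@sparsityEffect)
    lib <- withr::with_seed(seedLibs,
        sample(template@libSizes, 2L * n, replace = TRUE))
    grp <- rep(c("grp1", "grp2"), each = n)
    rMat <- cbind(inj$relMeans1, inj$relMeans2)
    piMat <- cbind(pis$zeroProb1, pis$zeroProb2)
    phi <- template@dispersion
    size <- if (phi > 0) 1 / phi else Inf
    y <- withr::with_seed(seedCounts, {
        out <- matrix(0, nF, 2L * n)
        for (j in seq_len(2L * n)) {
            gi <- if (grp[j] == "grp1") 1L else 2L
            mu <- lib[j] * rMat[, gi]
            cnts <- if (is.finite(size))
                stats::rnbinom(nF, size = size, mu = mu)
            else
                stats::rpois(nF, lambda = mu)
            pi <- piMat[, gi]
            if (any(pi > 0)) {
                zero <- stats::runif(nF) < pi
                cnts[zero] <- 0
            }
            out[, j] <- cnts
        }
        out
    })
    dimnames(y) <- list(names(template@relMeans),
                        sprintf("sample%03d", seq_len(2L * n)))
    sm <- data.frame(sample_id = colnames(y),
                     subject_id = colnames(y), group = grp,
                     center = "sim")
    ct <- CountTable(y, sampleData = sm)
    truth <- data.frame(feature_id = names(template@relMeans),
                        is_da = unname(inj$isDA),
                        direction = unname(inj$direction))
    new("SimulatedDataset", countTable = ct, truth = truth,
        params = list(relMeans1 = inj$relMeans1,
                      relMeans2 = inj$relMeans2,
                      zeroProb1 = pis$zeroProb1,
                      zeroProb2 = pis$zeroProb2,
                      dispersion = phi))
}

#' @describeIn simulateDataset count table accessor.
#' @param sim a [SimulatedDataset-class].
#' @export
simCounts <- function(sim) {
    stopifnot(is(sim, "SimulatedDataset"))
    sim@countTable
}

#' @describeIn simulateDataset ground-truth accessor.
#' @export
simTruth <- function(sim) {
    stopifnot(is(sim, "SimulatedDataset"))
    sim@truth
}

#' @describeIn simulateDataset realized parameter accessor.
#' @export
simParams <- function(sim) {
    stopifnot(is(sim, "SimulatedDataset"))
    sim@params
}

setMethod("show", "SimulatedDataset", function(object) {
    cat(sprintf("SimulatedDataset: %d features x %d samples, %d DA\n",
                nrow(object@countTable), ncol(object@countTable),
                sum(object@truth$is_da)))
    invisible(NULL)
})

#' Write a simulated dataset as count + truth TSVs
#'
#' @param sim a [SimulatedDataset-class].
#' @param countPath,truthPath output paths.
#' @return Invisibly, `countPath`.
#' @export
writeSimulatedDataset <- function(sim, countPath, truthPath) {
    writeCountTable(simCounts(sim), countPath)
    utils::write.table(simTruth(sim), truthPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(countPath)
}
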