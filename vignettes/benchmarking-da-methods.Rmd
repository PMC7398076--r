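---
title: "Benchmarking differential abundance methods on sparse counts"
author: "sparseDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking differential abundance methods on sparse counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparseDA)
```

# The problem

Microbiome profiling — 16S amplicon or whole metagenome shotgun (WMS)
sequencing — produces a taxa-per-sample count table that is large and
highly sparse: 16S tables typically carry 55–83% zero cells at library
sizes around a few thousand reads, WMS tables 35–89% at library sizes of a
million reads or more. Differential abundance (DA) analysis asks, feature
by feature, whether abundance differs between two groups of samples. Many
DA methods exist, ported from bulk RNA-seq, from single-cell RNA-seq, or
purpose-built for microbiome data, and they disagree: they assume
different count distributions, normalize differently, and control false
discoveries to very different degrees.

`sparseDA` implements a benchmarking framework that evaluates DA methods
on five complementary axes:

1. **Goodness of fit** of the candidate count models;
2. **Type I error** on mock two-group splits of null data;
3. **Concordance at the top** (CAT) within and between methods on random
   data halves;
4. **Directional enrichment** against external taxon annotations;
5. **Power and specificity** on parametric simulations with known truth.

A rank-aggregation step (`aggregateRanks`) condenses the axes into one
normalized ordering per method.

# Data model

`CountTable` extends `SummarizedExperiment`: a single integer `counts`
assay (features in rows, samples in columns — the orientation is fixed and
a transposed input must be declared, never guessed), per-sample metadata
(`subject_id`, `group`, `center`, and a `library_size` that is always
recomputed from the counts) and per-feature metadata (`taxonomy`,
`metabolism`). Missing metadata is coded with the sentinel `"absent"` and
excluded from enrichment class definitions.

Filtering follows strict inequalities — samples with `library_size >`
threshold, features with `count > 10` in `> 1` sample — because an
off-by-one in these rules changes every downstream feature count. The same
prevalence rule is applied before every analysis in this vignette, as a
fixed part of the pipeline.

# The five fitted models

`fitModel()` fits each model per feature with an intercept-only design
(samples are assumed homogeneous; normalization enters through offsets or
covariates) and reduces each fit to the two quantities the
goodness-of-fit comparison uses: the estimated mean on the
`log2(count + 1)` scale and the estimated probability of a zero.

* **NB** — negative binomial GLM (edgeR machinery: tagwise dispersions
  shrunk toward a trend, log effective-library-size offsets);
  `P(0) = (1 + phi*mu)^(-1/phi)`.
* **ZINB** — in-package penalized maximum likelihood with a common
  dispersion: alternating L-BFGS-B updates of per-feature
  `(log mu, logit pi)` and a one-dimensional common-dispersion update.
  The penalty `||par||^2 / (2*epsilon)` is a very weak ridge kept for
  numerical stability (`epsilon = 1e10` for goodness of fit, `1e14` when
  estimating simulation templates); with an intercept-only design it
  leaves the optimum essentially unpenalized. `piFixed = 0` reduces the
  fit to plain NB maximum likelihood, which for an intercept-only design
  has the closed-form solution `mu = mean(y)` — a property the test suite
  uses as an oracle.
* **ZIG** — zero-inflated Gaussian mixture EM on `log2(count + 1)` with
  cumulative-sum-scaling (CSS) offsets; the mixing probability follows a
  logistic regression on log library size. The reported mean is the
  mixture mean on the log2 scale, which deliberately reproduces the
  model's visible underestimation of observed means (the zero component
  pulls the mixture mean down — a Jensen-type gap).
* **HURDLE** — logistic detection model with the sample detection rate
  (CDR, the fraction of positive features per sample) as covariate, plus
  a Gaussian model on the positive `log2` counts (median-library-size
  rescaling by default).
* **DM** — Dirichlet-multinomial maximum likelihood on the concentration
  vector via the standard fixed-point iteration; the zero probability is
  the beta-binomial marginal `P(Y=0 | n_j, alpha_f, alpha_0 - alpha_f)`
  averaged over samples, computed in log-gamma arithmetic (the marginal
  is not part of the usual DM fitting literature, so the formula is
  spelled out in the code).

`gofSummary()` reports the per-feature mean difference (MD) and zero
probability difference (ZPD) and their RMSEs; `rankModels()` averages
within-dataset RMSE ranks across datasets. The observed mean is
`log2(mean(y) + 1)` by default — the mean on the count scale, then
transformed, matching how mean–difference plots are usually drawn; the
alternative (`mean of log2(y + 1)`) is available by flag because either
reading is defensible and the choice shifts every MD by a Jensen gap.
Non-converged features are excluded from RMSEs (with a reported count)
rather than imputed.

# Normalization

`normFactors()` implements TMM (via edgeR: 30% trim on M-values, 5% on
A-values, precision weights, upper-quartile reference rule — constants
from the method's standard description), `poscounts` (median of ratios to
the geometric mean of the *positive* counts, with zero ratios included in
the median by default — the sparsity-aware reading; a flag restores the
positive-only median), CSS (factor = sum of counts up to a data-driven
quantile chosen by an instability criterion with a 0.1 relative-change
threshold, falling back to the 0.5 quantile with a warning; the threshold
is a documented constant with an override, and a fixed quantile can be
supplied directly), and TSS (the library size). `transformCounts()`
provides the Gaussian-model scales: logCPM, median-library-size rescaling,
CLR on pseudocounted relative abundances (pseudocount 1), and the two CSS
offset conventions (dividing scaling factors by 1000, or by their median —
the latter without the `+1` inside the log, as the convention is usually
printed).

# The DA method catalogue

`runDA()` exposes every method behind one contract: a `DAResult` with a
signed coefficient (group 2 vs group 1, levels ordered lexicographically
so "UP" is reproducible), a statistic, raw and BH-adjusted p-values
(adjustment over present p-values only) and a missing-reason code.
Features with missing p rank last and are excluded from FPR numerators
and denominators. The built-ins:

| method | normalization | test |
|---|---|---|
| `nb_glm_lrt`, `nb_glm_lrt_poscounts` | TMM / poscounts | NB GLM likelihood ratio |
| `nb_glm_wald` | poscounts | NB GLM Wald |
| `nb_glm_robust` | TMM | robust dispersion + quasi-likelihood F |
| `moderated_t_logcpm` | TMM | voom weights + moderated t |
| `wilcoxon_norm` | TSS | rank-sum on log-normalized counts |
| `zig_em_t` | CSS | ZIG EM + moderated t |
| `dirichlet_clr_wilcoxon` | CLR | Monte-Carlo Dirichlet + rank-sum |
| `betabin_wald`, `betabin_lrt` | none | beta-binomial regression |
| `hurdle_chisq` | none | two-part chi-square (df summed) |
| `nb_glm_zinbweights`, `moderated_t_zinbweights` | TMM | ZINB observational weights |

Notable internals:

* The rank-sum test uses a vectorized normal approximation with tie
  correction and **no continuity correction**: the exact Wilcoxon null
  (computable from `dwilcox`) shows that the plain approximation tracks
  the exact rejection level, while the corrected one is conservative —
  `P(p < 0.05) = 0.046` at group sizes 21/20. Prevalence (`< 0.1`) and
  effect-size (`|logFC| < 0.25`) prefilters are available but **off by
  default**: the effect filter selects features with large observed
  differences and destroys null calibration, so it is opt-in.
* `dirichlet_clr_wilcoxon` uses `B = 128` Monte-Carlo Dirichlet draws on
  `counts + 0.5`, an interquartile-log-ratio (iqlr) CLR denominator, a
  rank-sum per draw and the arithmetic mean of per-draw p-values. `B` is
  a documented default, chosen as a power of two large enough that the
  averaged p stabilizes at the fixture sizes used in the tests.
* The beta-binomial regression uses logit links on the mean and a
  logit-scaled intercept for the overdispersion, BFGS from the null fit's
  optimum — starting the full fit at the null optimum guarantees a
  non-negative LRT statistic by construction. Wald uses the observed
  information.
* ZINB observational weights are the posterior probability that a zero
  came from the NB component; they are 1 at positive counts. Weighted
  moderated-t runs adjust the residual df to `sum(weights) - rank` before
  the empirical-Bayes shrinkage (an approximation; the exact adjustment
  is not fully specified in the weighted-F literature). Weighted NB runs
  pass the weights to the GLM fit and use the LRT.
* `empiricalBayesModeration()` shrinks residual variances toward a
  moment-matched prior (limma's scaled-F machinery when the prior is not
  supplied); `d0 = Inf` (all variances equal) collapses to the prior — a
  legal branch, not an error.

External tools enter through `registerDAMethod()` or the TSV exchange
format (`readDAResult`/`writeDAResult`); multivariate or Bayesian methods
(sPLS-DA, multinomial regression with reference frames, Bayesian NB
mixtures) are deliberately not re-implemented.

# Evaluation engines

**Type I error** (`typeOneError`): balanced mock labelings (odd sample
counts give the extra sample to group 1, e.g. 41 samples split 21/20),
per-mock Kolmogorov–Smirnov sup-distance of raw p to the uniform, FPR at
nominal 0.01/0.05/0.1, and a qq curve from quantile-wise means across
mocks.

**Concordance** (`concordanceAnalysis`): random stratified half-splits
(one sample per subject first — the dedup keeps the first sample per
subject after a seeded shuffle), each method run on both halves, ranked
lists compared by CAT. Ties in p are broken by descending |statistic| and
then feature id, so every list is a strict, reproducible order. WMC
compares a method with itself across halves; BMC compares methods within
a half, averaged over the two halves and then over splits (averaging over
subsets last; the reverse order is a documented alternative). When fewer
features than `R` are comparable, trailing CAT values are reported as
missing and `catAUC` averages the available ranks with a `partial` flag,
rather than extrapolating.

**Enrichment** (`enrichmentAnalysis`): the DA set is `adj_p < 0.1` (top
10% of the ranking for score-only methods); six one-sided Fisher tests
(aerobic/anaerobic/facultative × UP/DOWN), log odds-ratios with the
Haldane–Anscombe `+0.5` correction (`+1` for the variance), and the
TP − FP curve over the top 1–20% of the ranking, where putative TP are
aerobic-UP plus anaerobic-DOWN calls in the reference-site comparison.

# The simulator

`simulateDataset()` draws counts from `NB(lib_j * r_f, phi)` (adding
structural zeros with probability `pi_f` for ZINB), with:

* per-feature relative means `r_f` summing to 1, a common dispersion and
  per-feature `pi_f`, either estimated from data (`estimateTemplate`,
  epsilon `1e14`) or taken from the bundled deterministic templates
  (`template16S`: 900 features, library sizes around 5×10³, overall zero
  fraction ≈ 0.6; `templateWMS`: library sizes around 1.2×10⁶, zero
  fraction ≈ 0.43 — both inside the sparsity ranges observed for the two
  platforms, with log-normal abundance spread chosen to mimic the heavy
  tail of real profiles);
* library sizes resampled with replacement from the template's empirical
  pool (preserving the 16S/WMS depth contrast);
* DA injection (`injectDA`): `round(p * F)` features flagged uniformly;
  without compensation half are multiplied and half divided by the fold
  effect, then the vector is renormalized; with compensation a fraction
  `1/(1 + foldEffect)` (floored) is up-regulated and the rest multiplied
  by `(a/b)(1 - foldEffect) + 1`, which conserves the flagged set's total
  mass so unflagged features are bitwise-unchanged after renormalization.
  Up/down membership follows the random draw order — assigning by
  abundance can make the compensation factor non-positive; such a draw is
  treated as degenerate and redrawn from a seeded stream;
* a sparsity effect that adds/subtracts from `pi` for down-/up-regulated
  features, clamped to `[0, 1]` ("forced to the closer limit");
* three separate RNG streams (flags, library sizes, counts) derived from
  `(seed, replicate)`, so varying one grid axis never reshuffles the
  others.

The default grid matches the framework's study conditions: 10/20/40
samples per group, 10% or 50% DA, fold effect 2 or 5, compensation on or
off, sparsity effect 0/0.05/0.15 (ZINB only), 50 replicates per cell.
What the generator does **not** emulate: taxon–taxon correlation,
compositional closure beyond the multinomial-like sampling, batch and
subject effects, and real taxonomies — so passing tests demonstrate
correct behaviour under the stated parametric model, not on arbitrary
real data.

`powerEvaluation()` scores `adj_p < 0.05` calls against the truth and
integrates the partial AUROC of the raw-p ranking over FPR ∈ [0, 0.1]
(raw and normalized), extending the curve horizontally when a ranking is
exhausted (missing p-values rank last).

# Numerical choices and test scale

* ZIG EM stops at a relative log-likelihood change below `1e-6` or 100
  iterations; Gaussian variances are floored at `1e-6`.
* The DM fixed point runs to relative tolerance `1e-8` (cap 200
  iterations) from a method-of-moments start, with concentrations floored
  at `1e-10`.
* Dispersion estimation for the NB methods uses edgeR's trend + tagwise
  shrinkage defaults (prior df 10 equivalent).
* The calibration analysis in the test suite uses an NB null with 40
  samples per group and 200 mocks: at 40/40 the exact rank-sum rejection
  level at nominal 0.05 is 0.0498, whereas at the 21/20 mock size the
  exact level is 0.0482 — the test is run where the property it checks is
  mathematically true.
* The power analyses in the tests use a reduced grid (200 features, 10
  replicates, 10% DA) — sized so the full suite exercises every method on
  every grid cell while remaining a desk-scale computation; the full
  50-replicate grid is available through `simulationGrid()`.

# Known limitations

* The ZIG and hurdle implementations are intercept/group-level EM and
  two-part fits, not feature-regularized Bayesian fits; on very small
  samples their per-feature logistic components can fail to converge
  (reported via missing-reason codes, never silently).
* The DM model is intercept-only (no covariate regression).
* `nb_glm_wald` delegates to DESeq2, whose independent filtering and
  outlier handling can set p-values to missing; this mirrors how the
  method is used in practice and the missing-p policy accounts for it.
* CAT requires a shared feature universe; comparing methods that test
  different universes requires pre-aligning the tables.
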