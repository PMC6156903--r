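---
title: "The W-test for SNP-CpG epistasis: model, calibration, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The W-test for SNP-CpG epistasis: model, calibration, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wepistasis)
```

## The problem

DNA methylation modulates how genetic variants act on phenotypes, but most
interaction analyses either pre-select markers by main effects (losing pairs
whose effect is purely epistatic) or rely on parametric regression models
whose interaction term encodes one specific functional form. `wepistasis`
implements a distribution-comparison alternative for case-control designs:
for each SNP-CpG pair it asks whether the joint distribution of genotype and
methylation state differs between the two outcome groups, with a null
distribution calibrated to the dataset at hand.

The intended study design is a pharmacogenomic cohort: subjects measured on
a genotyping array and a methylation array, with a binary drug-response
outcome. The package derives that outcome from triglyceride (TG) levels at
four clinical visits — two pre-treatment, two post-treatment — as the
fractional decrease of the visit-averaged levels,
$\Delta TG\% = (TG_{pre} - TG_{post})/TG_{pre}$, calling a subject a
responder when the decrease strictly exceeds 30%, the common clinical
criterion for effective lipid control. The boundary case of exactly 30% is a
non-responder, reflecting the strict inequality in the criterion. Because
the definition is a ratio, responder status is invariant to any common
rescaling of TG units, which the test suite checks.

## The statistic

Each SNP is coded additively as the count of minor alleles $g \in \{0,1,2\}$,
polarized so that the counted allele has cohort frequency at most 0.5
(flipping $g \mapsto 2-g$ when needed; flipping twice is the identity). Each
CpG's beta values are split into low/high methylation states by
one-dimensional two-mean clustering. The pair then forms at most
$k = 3 \times 2 = 6$ joint categories; categories empty in both outcome
groups are dropped and $k$ reduced, so the statistic adapts to what the data
actually populate.

With $\hat p_{1i}$ and $\hat p_{0i}$ the proportions of cases and controls
falling in category $i$, the raw statistic is

$$S = \sum_{i=1}^{k} \left[ \frac{1}{SE_i}\,
  \log \frac{\hat p_{1i} / (1 - \hat p_{1i})}{\hat p_{0i} / (1 - \hat p_{0i})}
  \right]^2 ,$$

i.e. a sum of squared standardized log odds ratios, one per category, each
computed on the category-vs-rest $2\times 2$ collapse
$(n_{1i},\, n_1 - n_{1i};\, n_{0i},\, n_0 - n_{0i})$. $SE_i$ is the canonical
log-odds-ratio standard error, the square root of the sum of the four
reciprocal counts. When a collapse contains a zero, the Haldane-Anscombe 0.5
correction is added to its four entries, keeping $S$ finite while leaving
populated cells untouched. $S$ is invariant to swapping the case/control
labels and is zero exactly when every category has identical case and
control proportions.

Because the $k$ per-category terms are built from overlapping margins they
are not independent $\chi^2_1$ variables, so $S$ is referred to a *scaled*
chi-squared: $W = h S \sim \chi^2_f$, with $h$ and $f$ estimated from the
data (next section). The resulting test is omnibus over the joint
distribution: it responds to marginal genotype or methylation effects as
well as to pure interaction structure. This matters when interpreting
comparisons with interaction-specific regression tests (see *Benchmarks*).

### Numerical notes

- Degenerate tables ($k < 2$, e.g. a monomorphic SNP after complete-case
  filtering) are refused, and the scan skips such markers with a logged
  reason rather than emitting a p-value.
- Standardized squared log odds ratios are *not* monotone in $|\log OR|$
  near the margins: once a margin cell drops to 1 or 0 subjects, $SE_i$
  grows faster than the squared log odds ratio and the cell's contribution
  turns over (the continuity correction further shrinks it at the boundary).
  This is a property of odds-ratio standardization, not an implementation
  artifact; the property-based tests therefore assert monotonicity of $S$
  under concentrating case mass only in the interior regime (every margin
  cell $\ge 2$).
- P-values that underflow to exactly zero in a scan are floored at the
  smallest positive double and counted in the scan summary, so downstream
  Q-Q computations never take $\log(0)$.

## Calibrating h and f

Under the null, $h$ and $f$ are chosen by moment matching on bootstrap null
samples of $S$: each of $B$ replicates resamples subjects with replacement,
permutes the phenotype *within the draw* (which enforces the null while
preserving the outcome ratio), picks a random candidate SNP-CpG pair, and
records the raw statistic under the category count $k$ it realized. For each
$k$ with at least 50 samples (configurable floor), with $m$ and $v$ the
sample mean and variance,

$$h = 2m/v, \qquad f = 2m^2/v,$$

the unique two-parameter choice making $E(hS) = f$ and $\mathrm{Var}(hS) = 2f$
— the mean and variance of $\chi^2_f$. Groups below the floor fall back to
the pooled estimate over all samples, with a warning. The identities
$h\,m = f$ and $h^2 v = 2f$ hold exactly by construction and are asserted in
the tests. On balanced null cohorts with $k = 6$ the estimated $f$ lands
near $k - 1 \approx 5$ and $h$ slightly below 1, consistent with the
correlation structure of the per-category terms.

Defaults: $B = 400$ replicates, subsample size $\min(n, 1000)$, floor 50,
calibration computed **once per cohort** (not per permutation replicate),
mirroring real usage where one calibration serves a whole scan. All draws
are governed by one integer seed; every stochastic function takes an
explicit seed and is reproducible bit-for-bit.

**Monte-Carlo error of the calibration.** With $B = 400$, the moment
estimates carry appreciable sampling error (the variance of a sample
variance of a skewed statistic is large), and the empirical type-I error of
the calibrated test at nominal 0.05, measured over 2000 phenotype
permutations, is itself a random variable: across calibration seeds it
ranges roughly 2-6% around a mean slightly above 5%. Single-run empirical
rates below 5% — including markedly conservative ones near 3% — are
expected behavior of the procedure at this $B$, not evidence of a
conservative test per se. Users wanting tighter calibration should raise
`boot_reps`; the p-value uniformity check in the test suite uses
$B = 2000$ for exactly this reason.

## Two-mean binarization

In one dimension the optimal two-mean (k-means, $k=2$) partition is always a
threshold split of the sorted values. The package therefore solves the
clustering *exactly*: it scans all $n-1$ candidate splits with
cumulative-sum arithmetic ($O(n \log n)$ total) and takes the split with
minimal within-cluster sum of squares. This is deterministic, needs no
initialization, and is provably the global optimum — Lloyd iteration from
extreme-point initialization, by contrast, converges to a local optimum on a
noticeable fraction of small inputs, which is why it was rejected here. The
returned centers are the cluster means; labels follow the midpoint rule
(beta at or below the centers' midpoint is "low"), which the optimal split
satisfies. Binarization is computed per CpG across **all** retained
subjects, never within outcome groups, so the discretization cannot leak
phenotype information into the test. Constant CpGs are refused.

## Benchmarks

Two logistic-regression comparators accompany the W-test, both fitting
`Y ~ SNP + CpG + SNP:CpG` by maximum likelihood with the SNP as one numeric
additive term: LR-m1 uses the binary two-mean label, LR-m2 the original
continuous beta value. The interaction is tested by the 1-df
likelihood-ratio test of the full against the no-interaction model — chosen
over the Wald test because it behaves better under sparse cells; the choice
is recorded in the result object. Non-convergence and (quasi-)complete
separation are reported as `converged = FALSE` with a missing p-value.
LR-m1 and LR-m2 coincide exactly when the continuous values are already 0/1.

Because the W-test is omnibus while the LR tests are interaction-specific,
their p-values need not agree under a generative model whose uncentered
product term induces marginal effects: in the planted-signal check the
W-test and a 5-df omnibus regression agree in order of magnitude, while the
1-df interaction LRT is orders of magnitude larger. The benchmark's
correctness is therefore verified against an independently coded
Newton-scoring ML fit on identical draws (agreement to ~1e-9 in p), not
against the W-test.

## The synthetic cohort generator

No public individual-level SNP-methylation drug-response cohort is
available at this scale, so the package ships a generator whose defaults
emulate the intended study conditions and which is itself first-class,
tested code:

- **Cohort size** 680 subjects — the size of the motivating cohort.
- **Genotypes**: per SNP, MAF $q \sim U(0.05, 0.5)$, genotypes from
  Hardy-Weinberg proportions $((1-q)^2, 2q(1-q), q^2)$, independent across
  SNPs (no linkage disequilibrium — a stated non-goal).
- **Methylation**: a two-component beta mixture, Beta(2,8) low state and
  Beta(8,2) high state with proportion 0.5 each — the bimodal shape typical
  of array beta values; mixture mean 0.5.
- **Positions**: SNPs uniform on a 1-Mb chromosome; each CpG placed within
  ±10 kb of a random SNP with probability 0.8 (else uniform), so cis pairs
  always exist.
- **Phenotype**: logistic model
  $P(Y{=}1) = \mathrm{logit}^{-1}(\beta_0 + \beta_G G + \beta_M M + \beta_{GM} G M)$
  on one designated causal pair; $\beta_0 = 0$ gives a balanced outcome.
  Null, main-effect and interaction regimes set the corresponding
  coefficients.

What the generator does **not** emulate: family structure/kinship,
linkage disequilibrium, cell-type composition effects on methylation,
batch effects, covariates (age, sex, smoking, center), or longitudinal TG
trajectories. Passing simulation checks therefore demonstrate calibration
and power of the statistic under idealized sampling, not robustness to
those real-data features.

The type-I-error experiment follows the permutation design: one cohort is
generated, (h, f) calibrated once, and the phenotype permuted per replicate
(2000 by default) on one designated pair; permutation — not re-simulation —
enforces the null exactly. The power experiment redraws the phenotype from
the interaction model per replicate over a grid of $\beta_{GM}$ values. The
experiments default to a 50-SNP × 50-CpG marker panel: large enough to give
the calibration a diverse candidate-pair list, small enough that a full
2000-replicate study runs in seconds.

## The scan

`genome_scan()` aligns subjects by id (never row order), drops incomplete
records with per-reason counts, enumerates all same-chromosome SNP-CpG
pairs within the window (10 kb by default, boundary inclusive, matching the
convention that a pair "within 10 kb" includes exactly 10 kb; each marker
contributes its single mapped 1-based coordinate), calibrates once, tests
every pair, and ranks by p-value with lexicographic tie-breaks for
reproducible output files. Multiple testing uses Bonferroni at the
configured family-wise level — e.g. 140,501 tests at FWER 5% give a
per-test threshold of 3.56e-7 — with tested and enumerated pair counts both
reported, since monomorphic/constant markers are skipped between the two.
`qq_points()` emits Q-Q coordinates on the $-\log_{10}$ scale with the
genomic inflation factor $\lambda$ (median chi-squared quantile ratio);
on null scans $\lambda$ should sit near 1.

## Problem sizes used in the checks

The shipped verification suite runs, at fixed seeds: the 2000-replicate
type-I study (n = 680, with both LR benchmarks), a 2000-pair null
uniformity check (Kolmogorov-Smirnov against U(0,1) and $\lambda$), a
200-pair planted-interaction scan ($\beta_{GM} = 2$), an exhaustive
small-table comparison of the raw statistic against an independent
arithmetic oracle (1e-10 agreement), and closed-form chi-squared identities.
These sizes were chosen so the whole suite completes in well under a minute
while keeping Monte-Carlo standard errors around half a percentage point on
the rate estimates.

## Known limitations

- The chi-squared moment match fits mean and variance, not the extreme
  tail; at genome-wide thresholds (~1e-7) the approximation is less
  validated than at nominal levels, and the bootstrap cannot probe that far
  with desk-scale $B$.
- Calibration at the default $B = 400$ carries the Monte-Carlo variability
  described above.
- No covariate adjustment: the W-test has no regression adjustment path,
  and the LR benchmarks deliberately mirror its unadjusted design.
- Complete-case filtering only; no genotype imputation or methylation
  normalization (BMIQ-style) is provided.
- SNP-SNP epistasis and single-marker (main-effect) W-tests are out of
  scope.
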