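---
title: "Multi-kernel genomic prediction from SNPs, haplotype blocks and runs of homozygosity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-kernel genomic prediction from SNPs, haplotype blocks and runs of homozygosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(KernelPred)
```

## The model

KernelPred predicts quantitative traits of genotyped animals (the
motivating setting is first-lactation dairy cows) from three sources of
genomic information derived from one SNP panel:

* **SNPs** — additive codes 0/1/2 counting one allele;
* **haplotype blocks (HAP)** — sets of physically adjacent SNPs in strong
  LD, each block treated as a multi-allelic locus whose alleles are
  recoded as 0/1/2 "pseudo-SNP" copy counts;
* **runs of homozygosity (ROH)** — long homozygous tracts, pooled across
  animals into population-level loci and scored presence/absence per
  animal.

Each source yields an $n \times n$ genomic relationship kernel.  SNP and
HAP features enter a linear (VanRaden-style) kernel

$$K = \frac{Z Z^{\top}}{k},$$

where $Z$ holds column-centered, unit-variance features and $k$ is the
number of columns.  The ROH incidence enters a Gaussian kernel

$$K_{ij} = \exp\!\left(-h \,\frac{d^2_{ij}}{\overline{d^2}}\right),$$

with $d^2_{ij}$ the squared Euclidean distance between incidence rows and
$\overline{d^2}$ the mean squared distance, so the exponent is
scale-free; the bandwidth $h$ defaults to 1.5 and a grid-search utility
(`bandwidthGrid()`) scores alternatives by cross-validated prediction.
Because the printed form of the normalizer is ambiguous about which pairs
enter the mean, we take it over unordered *distinct* pairs: including the
zero self-distances would shrink the mean by a factor that depends on the
data size, which cannot be intended for a scale adjustment.

Phenotypes are modelled as

$$y = X\beta + \sum_j g_j + e,\qquad
  g_j \sim N(0, K_j\,\sigma^2_j),\quad e \sim N(0, I\sigma^2_e),$$

where $X$ holds an intercept, herd-year-season (HYS) one-hot columns with
a reference level, and age at calving as linear and quadratic terms (age
is centered before squaring purely for conditioning).  Fitting is by
Gibbs sampling: $\beta$ has a flat prior, each variance a scaled
inverse-$\chi^2$ prior, and each $g_j$ is parameterised in the eigenbasis
of its kernel, $g_j = V_j \alpha_j$ with
$\alpha_j \sim N(0, \mathrm{diag}(\lambda_j)\sigma^2_j)$.  Because $V_j$
is orthonormal, the full conditional of $\alpha_j$ factorises over
coordinates, so one iteration costs two matrix-vector products per kernel
and the eigendecomposition is computed once.  Eigenvalues below
$10^{-10}$ of the largest are truncated.

Heritability and the percentage of genetic variance per kernel are
computed per retained draw and then summarised — never from plugged-in
posterior means:

$$h^2 = \frac{\sum_j \sigma^2_j}{\sum_j \sigma^2_j + \sigma^2_e},\qquad
  \text{pct}_j = 100\,\frac{\sigma^2_j}{\sum_l \sigma^2_l}.$$

### Priors

The analysis this package re-implements names the Bayesian framework but
not its priors.  We default to weakly informative scaled
inverse-$\chi^2$ priors with 5 degrees of freedom, with scales chosen so
each variance's prior mode corresponds to an equal split of half the
phenotypic variance across the kernels (and half to the residual) — the
common default of Bayesian genomic-regression software.  `modelSpec()`
exposes both the degrees of freedom and the scales.

### MCMC settings

The published schedule is 100,000 iterations, 30,000 burn-in, thinning 5,
retaining exactly $\lfloor(100{,}000-30{,}000)/5\rfloor = 14{,}000$
draws.  That schedule is the `modelSpec()` default.  The package's own
tests and the pipeline default use scaled-down chains (a few thousand
iterations); with the one-time eigendecomposition the sampler mixes
quickly for these models, and every result produced under a reduced
schedule is a choice recorded in the configuration echoed by the report.

## Quality control

* **Markers** (SNPs and pseudo-SNPs alike): call rate $\ge 0.95$, minor
  allele frequency $\ge 0.05$, Hardy-Weinberg exact test $p \ge 0.15$.
  The HWE rule is read as *exclude when the exact-test p-value is below
  0.15*; the source text lists the threshold among exclusion criteria
  without naming the statistic, so the direction is this package's
  documented reading.  The test is the exact conditional test (summing
  probabilities of heterozygote counts no more likely than observed);
  a chi-square alternative would misbehave at the small fixture sizes the
  test suite uses.
* **Records**: age at first calving within 16–60 months (all traits);
  milk yield within mean $\pm 3$ SD, the window computed once on the
  age-filtered set rather than iterated; days open within the closed
  interval [30, 400]; and only animals with both genotypes and phenotypes
  are kept.  Closed intervals are used at both ends because the stated
  ranges read as inclusive.  Somatic cell counts transform to scores as
  $\mathrm{SCS} = \log_2(\mathrm{SCC}/10^6) + 3$.

One caveat on idempotence: filters with fixed bounds are exactly
idempotent; the milk $\pm 3$ SD window is recomputed from its input, so a
second application can in principle trim records that sat close to the
first window's edge.  Computing the window once (not iteratively) is the
documented behaviour.

## Haplotype blocks

Block construction is a greedy left-to-right extension within each
chromosome: a block grows while the next SNP in map order has
$r^2 \ge 0.80$ with *every* SNP already in the block; blocks need at
least 2 SNPs and never span chromosomes.  The original analysis used an
external program whose exact block algorithm is not described; the
greedy all-pairs rule is this package's definition, chosen because it
matches the stated criteria literally and is easy to verify
exhaustively.

Pairwise $r^2$ comes from two-locus haplotype frequencies estimated by EM
on the 3x3 genotype table (only the double heterozygote is
phase-ambiguous); a composite genotypic-correlation estimator is
available as an option.  Within-block haplotypes are inferred by a
multinomial EM over each animal's compatible phase configurations,
initialised at linkage-equilibrium frequencies, converged at a maximum
frequency change below $10^{-8}$ (at most 500 iterations); each animal
receives its most probable diplotype, ties broken toward the
lexicographically smaller haplotype pair.  Haplotype alleles with
population frequency $\ge 1\%$ become pseudo-SNP columns.  Animals with
any missing call inside a block get a missing diplotype (missing cells
are mean-imputed when the kernel is built); marginalising the EM over
missing alleles would cost exponential enumeration for little gain at
the missingness rates considered here.

## ROH scanning

The scanner mirrors the standard sliding-window procedure: 50-SNP
windows, at most 1 heterozygous and 1 missing call per homozygous
window; a SNP joins a run candidate when at least 5% of the windows
covering it are homozygous; candidate stretches are split where adjacent
member SNPs are more than 500 kb apart; segments must hold at least 100
SNPs, span at least 1,000 kb, and average at most 50 kb per SNP.  The
four last values are the published defaults of the cited scanner (the
analysis only lists its overridden flags); all are exposed in
`rohParams()`.  The X chromosome is excluded case-insensitively, and
markers/animals with more than 10% missingness are dropped before
scanning.  Coordinates are 1-based and inclusive at member SNP
positions; lengths always derive from bp, never from SNP counts.

Pooling into population loci is single-linkage clustering per
chromosome, linking segments with reciprocal overlap $\ge 0.95$ (a
convention of the cited scanner's group mode; configurable because the
original threshold is unpublished).  Each cluster's consensus region is
the intersection of member spans; in a chained cluster that intersection
can be empty, which the locus table flags by `start > end`.  Animals
with no segment are absent from the incidence matrix, and per-trait
incidence matrices are rebuilt after record filtering, which is why the
pooled locus count differs between traits.

## Cross-validation

Records are randomly split into $k = 10$ nonoverlapping folds whose
sizes differ by at most one (5,746 / 5,508 / 4,707 records give smallest
folds of 574 / 550 / 470).  Per fold the model is refitted on training
records only; test records are predicted as the fixed-effect prediction
plus the conditional-expectation kernel projection
$K_{\text{test,train}} K_{\text{train}}^{-1} \hat g_{\text{train}}$,
evaluated in the cached eigenbasis.  A test record whose HYS level never
occurs in training gets the grand fixed-effect mean (HYS is a nuisance
here; the case is counted in the result).  Per-fold Pearson correlations
are summarised two ways:

* a normal-approximation interval, mean $\pm 1.96\,\mathrm{SE}$ across
  folds — the reporting convention of the original analysis, kept as the
  default display;
* a percentile interval of the fold correlations.

The normal interval should be read descriptively: fold correlations
share training records, so the naive across-fold SE underestimates the
spread (no unbiased cross-validation variance estimator exists), and on
null simulations its coverage of zero falls short of nominal — the same
shortfall appears for a plain least-squares cross-validation.  The
package's null-coverage test therefore asserts calibration of the
percentile interval and unbiasedness of the mean correlation.

## The synthetic-data generator

No data accompany the analysis this package re-implements, so
`simulateGenotypes()` / `simulatePhenotypes()` generate populations with
the statistical structure the method assumes:

* founders draw each chromosome from a finite pool of haplotypes
  (default 8), which creates block-wise LD without a coalescent
  simulator and keeps the block structure controllable;
* later generations arise by gene dropping with Poisson-recombination
  gametes, with a configurable fraction of matings (default 0.3) between
  half or full sibs, so autozygous loops create long ROH;
* phenotypes follow the same decomposition the model fits: HYS effects,
  linear and quadratic age, additive SNP effects, haplotype-block
  effects, ROH-linked effects, and Gaussian residuals.  Each genetic
  component is rescaled so its *realized* population variance equals the
  configured target, and the truth record stores the realized variances
  and effect vectors for recovery tests.  ROH effects are directional
  (all the same, negative, sign) to mimic an inbreeding-depression-like
  nonadditive signal, which gives the ROH kernel a distinguishable
  variance share to recover.
* HYS levels are assigned round-robin and then shuffled, so every level
  keeps at least `min_per_hys` (default 20) animals.

The default genome is 10 chromosomes of 500 evenly spaced SNPs over
25 Mb (50 kb spacing).  At these settings the scanner finds about 3 ROH
per animal covering roughly 15–20% of the 250 Mb genome; per unit of
genome this matches the ROH burden reported for real Holstein data
(about 33 ROH and 240 Mb covered on a ~2.5 Gb genome), which is the
qualitative character the generator is meant to emulate.  One global
seed drives every operation through named substreams, so genotypes,
phenotypes and downstream results are bit-reproducible.

What the generator does **not** emulate: realistic cattle demography or
chip-specific missingness; allele-frequency spectra shaped by selection;
X chromosomes (the analysis excludes X anyway); genotyping error.
Passing tests on this simulator show the pipeline recovers structure it
is designed for — they do not certify performance on real populations.

## Numerical choices

* Kernel standardisation uses the population (divide-by-$n$) SD, so a
  single standardized column yields diagonal mean 1 and trace/$n
  \approx 1$; zero-variance columns are dropped with $k$ adjusted.
* A jitter of $10^{-8}$ is added to a kernel diagonal only inside the
  sampler when the eigendecomposition flags a non-PSD matrix; it is
  never stored.
* EM for $r^2$ converges at $10^{-12}$ on the haplotype frequency;
  block EM at $10^{-8}$ on frequencies; diplotype ties break toward the
  lexicographically smaller pair; monomorphic markers yield a flagged
  `NA` $r^2$ rather than a guess.
* Degenerate inputs fail loudly: fewer than 2 animals for a kernel, an
  all-identical ROH incidence (degenerate distance normalizer),
  rank-deficient fixed designs (the collinear columns are named),
  truncated or mislabeled PLINK files.

## Problem sizes used by the tests and report

The shipped tests and the acceptance script run at desk scale, chosen as
the package's own verification conditions: parameter recovery at
$n = 1{,}000$ with 4,000-iteration chains averaged over 5 seeds;
closed-form sampler checks at $n = 150$–200; the end-to-end pipeline at
$n = 400$ animals, 5,000 SNPs, 2,000-iteration chains, 10-fold CV of all
8 model variants.  The `modelSpec()` defaults remain the published
schedule.

## Known limitations

* The greedy block rule and the 0.95 reciprocal-overlap pooling are this
  package's concrete readings of procedures the source describes only by
  their thresholds.
* Genotype imputation, pedigree-based single-step methods and REML
  variance estimation are out of scope.
* Multi-kernel fits with strongly correlated kernels (e.g., SNP and HAP
  built from the same markers) split variance according to the prior and
  the data jointly; the partition is identified but posterior shares
  between near-collinear kernels have wide uncertainty — mirrored in the
  wide `pctSd` those fits report.
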