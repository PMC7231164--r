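---
title: "Detecting single-generation selection in SNP cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting single-generation selection in SNP cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgselect)
```

## The problem

When juveniles of a high-dispersal species settle at random into ecologically
contrasting nursery habitats, differential survival over a single season can
shift allele frequencies at loci affecting fitness-related traits — even
though all individuals come from one panmictic gene pool. `sgselect` detects
and interprets these within-generation shifts from three samples of one
cohort: a pre-selection baseline (e.g. newly settled larvae) and two
post-selection groups grown in different habitats (e.g. brackish and marine
lagoon juveniles). Because the comparison is within one generation of one
panmictic population, any consistent frequency difference between the two
post-selection groups beyond sampling noise points to viability selection,
not to population structure.

## The SGS test

For a biallelic locus with reference-allele counts $x_1$ of $n_1$ alleles
and $x_2$ of $n_2$ alleles in the two groups, the test statistic is the
absolute frequency difference $\Delta p = |x_1/n_1 - x_2/n_2|$. Its null
distribution under "one common gene pool, no selection" has two variance
sources: uncertainty about the pool frequency itself, and binomial sampling
noise in each group. `sgs_null_draws()` composes them as a beta-binomial
posterior predictive:

$$p^* \sim \mathrm{Beta}(x_{pool} + a,\; n_{pool} - x_{pool} + b), \qquad
  x_i^* \sim \mathrm{Bin}(n_i, p^*), \qquad
  \Delta p^* = |x_1^*/n_1 - x_2^*/n_2|,$$

with a flat prior $(a, b) = (1, 1)$ by default (configurable; the null is
isolated in one function so an alternative construction can be swapped in).
The Monte-Carlo P-value uses the add-one estimator
$P = (1 + \#\{\Delta p^* \ge \Delta p_{obs}\})/(n_{iter} + 1)$ with ties
counted as extreme, so reported P-values are never zero. The default
$n_{iter} = 10{,}000$ resolves the nominal thresholds swept downstream
($10^{-4}$ to $10^{-2}$). `sgs_scan()` derives one RNG substream per locus
from the master seed, so results do not depend on scan order.

The pool frequency is estimated from the two compared samples pooled — not
from the baseline — so the test is self-contained for the two-habitat
comparison; the baseline enters only through equal-tailed Beta credibility
intervals (`baseline_credibility_interval()`) and the descriptive
classification of outliers (`classify_outliers_vs_baseline()`).

### Calibration properties, exactly stated

The Monte-Carlo P-value matches exact enumeration of the beta-binomial null
(the test suite checks all two-sample count configurations up to 20 alleles
per group against closed-form enumeration, at 3 Monte-Carlo standard
errors). Because $\Delta p$ is a discrete statistic and ties count as
extreme, P-values are *conservatively valid* rather than exactly uniform:
at 100 + 100 diploids the null rejection rate at $\alpha = 0.05$ is about
0.042–0.043, and the far tail is essentially exact (rejection at
$10^{-3}$ of about $10^{-3}$). This is a property of every deterministic
P-value for a discrete test — the probability atoms near $\Delta p = 0$ are
several percent at these sample sizes — and it slightly favors specificity
over sensitivity at loose thresholds. Diploid sampling is approximated at
the allele level (binomial on $2N$ alleles), which is accurate once
Hardy-Weinberg filtering has been applied.

## Power against Fisher's exact test

`simulate_replicate()` advances one generation in a finite panmictic
population: one binomial draw of the standing frequency at population size
$N$ (drift), Hardy-Weinberg genotypes, a neutral sample of $n_1$
individuals, and a second sample of $n_2$ individuals taken after viability
selection with fitnesses $\omega_{AA} = 1+s$, $\omega_{Aa} = 1$,
$\omega_{aa} = 1-s$. Survival is independent Bernoulli with probability
$\omega_g / \max\omega$ by default; a weighted sampling-without-replacement
alternative is available (`survivor_scheme = "weighted"`), since the
mechanism matters only at extreme selection. `power_grid()` runs both the
SGS test and two-sided Fisher's exact test over a $(p, s)$ grid (defaults
$N = 10{,}000$, 100 replicates per cell) and reports rejection fractions
with binomial standard errors. Both tests are conservative at $s = 0$ (both
are discrete); the SGS test is consistently the less conservative of the
two and at least matches Fisher's power across selected cells.

## Phenotypes and the G-by-E ANCOVA

Two fitness proxies are computed exactly as standardly defined for fish:
the relative condition factor $K$ — observed weight over the weight
predicted by one log–log length–weight regression pooled over all
individuals, so the geometric mean of $K$ is 1 — and a standardized length
(z-score within each habitat-by-sampling-date stratum, removing
heterochronous-sampling effects; singleton strata give `NA` with a
warning). `ancova_interaction()` fits `trait ~ group * covariate` by OLS
and reports per-group slopes, total $R^2$, and the interaction F-test,
which is the significance of the slope difference between habitats.

## Polygenic scores and the threshold sweep

At each outlier locus the allele at higher frequency in group A than group
B is the "A-favored" (brackish) allele; the complementary allele is
B-favored, so with complete data the two per-individual scores sum to twice
the locus count (`polygenic_scores()` leaves missing calls uncorrected, and
the identity bends by 2 per missing call). `threshold_sweep()` recomputes
scores for the outlier sets at a ladder of nominal SGS thresholds and
records the ANCOVA $R^2$ of `trait ~ habitat * score`. The resulting curve
typically rises as true small-effect loci accumulate and falls once noise
loci dominate the score; the argmax threshold is reported. Note that the
$R^2$ profile is quite flat near its optimum at a couple of hundred
phenotyped juveniles, so the argmax can move by a threshold step or two
between replicate cohorts — the sweep locates a plateau, not a sharp peak.
`gwa_linear()` provides the per-SNP companion models (additive, with
environment covariate, with G-by-E interaction; the interaction model
reports the interaction term), Bonferroni-corrected by the number of
distinct RAD-tags so SNPs in within-tag linkage count as one test.
`independent_association()` regresses a trait on a score in individuals
disjoint from the discovery set and refuses overlapping ids, protecting the
replication argument.

## Survival surfaces over genotype space

`pca_coordinates()` places all individuals (baseline and both
post-selection groups fitted jointly) in the plane of the two leading PCs
of the outlier genotypes, with per-locus mean imputation of missing calls
and a deterministic sign convention (non-negative loading sums).
`survival_surface()` subtracts the baseline kernel density from a
post-selection group's density on a shared lattice: positive values mark
multilocus genotypes enriched among survivors. Both densities use one
bandwidth (normal reference rule on the pooled coordinates) — per-group
bandwidths would confound the difference with smoothing — and one lattice
spanning the pooled range padded by one bandwidth, 100 x 100 by default.
Each density integrates to 1 within 1% by the trapezoid rule, and each
difference surface to 0 within 2%. The surface value is kept as a raw,
signed density difference — a *relative* survival score, not a probability.
`project_survival_scores()` evaluates it at each individual's coordinates
by bilinear interpolation (points outside the lattice are clipped and
flagged). Under stronger selection, survivor density concentrates, so a
*smaller* fraction of baseline genotypes retains a positive score — the
habitat exerting softer selection keeps the larger positive fraction.

## The synthetic cohort generator

`generate_cohort()` produces the study design the analysis assumes, with
known truth for recovery testing: group sizes default to 44 baseline larvae
and 106 + 106 juveniles; baseline frequencies uniform on (0.05, 0.95);
one binomial drift draw at $N = 10{,}000$; juvenile genotypes drawn from
the post-viability-selection genotype distribution with habitat-specific
coefficients, antagonistic by default ($s_B = -s_A$, drawn from
$s \sim U(0.2, 0.5)$ per planted locus), with a conditional-neutrality mode
($s_B = 0$) also provided. Traits are environment-dependent linear
combinations of the planted genotypes (effect sizes proportional to $|s|$,
on the view that selection acts through the trait) plus Gaussian noise,
scaled so the habitat-by-score ANCOVA explains a target fraction of trait
variance *within* habitats — by default 4% for growth (via the
marine-favored score) and 9% for condition (via the brackish-favored
score), the regime of a few percent that motivates polygenic rather than
single-locus analysis. The scaling uses the within-habitat genetic spread,
since selection also separates the group means and that between-group
component is absorbed by the habitat term of the ANCOVA. Lengths and
weights are back-transformed (log-normal lengths around habitat- and
date-specific means, cube-law weights times the condition deviation) so
`condition_factor()` and `standardized_length()` recover the planted
structure; baseline individuals get a larval growth trait driven by the
same loci (target $R^2$ 0.2) for the independent replication.
`generate_read_depths()` adds Poisson total depths with binomial
heterozygote splits, optionally biased at chosen loci, to exercise the
allele-balance filter.

What the generator deliberately omits: linkage disequilibrium between loci
(each locus is drawn independently, so multilocus selection acts marginally),
genotyping error, haplotype structure within RAD-tags, and habitat choice.
Passing recovery tests on these cohorts therefore shows the statistical
machinery is sound under the model's own assumptions; it does not certify
behavior under strong LD or assembly artifacts.

## Filters

`filter_loci()` applies the standard RAD post-export rules: at most 10%
missing calls within *every* group, pooled minor allele frequency at least
1%, and an exact Hardy-Weinberg test P of at least $10^{-3}$ within every
group. The HWE test enumerates all heterozygote counts compatible with the
observed allele counts and sums the probabilities of configurations no more
probable than the observed one (two-sided). `allele_balance_filter()`
catches systematic read-count bias: per locus, the allele with the lowest
total read count defines a per-heterozygote depth ratio whose mean is
tested against 0.5 with a one-sided t-test ($\alpha = 0.05$); constant
ratios are handled as the degenerate t limit (retained at 0.5, removed
below), and loci with fewer than two usable heterozygotes pass with a
warning. `pairwise_fst()` (Weir-Cockerham 1984 theta, ratio of summed
variance components) and `pca_coordinates()` support the genetic
homogeneity checks that justify the common-pool null; note the theta
estimator is unbiased around zero, so a group compared with a copy of
itself gives a small negative value of order $-1/(2(n-1))$, not exactly
zero.

## A worked example

```{r example, eval = FALSE}
co <- generate_cohort(n_loci = 1000, n_selected = 20, seed = 1)
scan <- sgs_scan(co$genotypes, "brackish", "marine", baseline = "larvae",
                 n_iter = 10000, seed = 1)
hits <- outlier_loci(scan, 1e-3)

ph <- co$phenotypes
trait <- setNames(as.numeric(condition_factor(ph$length_mm, ph$weight_g)),
                  ph$id)
habitat <- setNames(ph$habitat, ph$id)
sw <- threshold_sweep(scan, co$genotypes, trait, habitat,
                      thresholds = c(1e-4, 1e-3, 7.5e-3, 1e-2), score = "A")
plot_sweep(sw)

pcs <- pca_coordinates(co$genotypes, locus_subset = hits)
grp <- co$genotypes$groups
surf <- survival_surface(pcs[grp == "brackish", ], pcs[grp == "larvae", ])
plot_surface(surf, points = pcs[grp == "larvae", ])
```

`run_pipeline()` chains the same stages from a single validated
configuration (`run_config()` or a YAML file) and writes TSV/JSON reports;
`scripts/acceptance.R` at the repository root recomputes the headline
quantities end to end from a fixed seed.

## Numerical choices and problem sizes

Monte-Carlo iterations default to 10,000 per locus; the bundled tests and
the acceptance script use 1,000–10,000 iterations and cohorts of 250–5,020
loci, sizes at which every property they assert is stable under reseeding.
Ties in the Monte-Carlo tail count as extreme and are compared with a
$10^{-12}$ floating-point guard. Mean imputation for PCA is the standard
deterministic choice for near-complete data (a few percent missing);
monomorphic loci are dropped before scaling. Orientation ties (identical
frequencies in both groups) resolve to the reference allele and are
flagged. All randomized functions take explicit integer seeds and derive
per-locus or per-cell substreams, so every result in this package is
reproducible bit-for-bit from (inputs, seed).

## Known limitations

The test is conservative at loose thresholds (discreteness, above); the
null reconstruction is a posterior-predictive composition rather than a
closed-form derivation, and is deliberately isolated behind
`sgs_null_draws()`; multiple-testing control across loci is left to the
threshold sweep by design (nominal thresholds are the object of interest
downstream); and the survival surface is a relative enrichment measure that
depends on the KDE bandwidth — comparisons should always use the shared
bandwidth the package computes.
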