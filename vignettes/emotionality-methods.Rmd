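---
title: "Composite emotionality, exact group tests and cluster profiling: methods and design"
author: "emoprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite emotionality, exact group tests and cluster profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emoprofiler)
```

## The problem

Behavioral phenotyping of a 2×3 factorial rodent cohort — prenatal exposure
(saline vs valproic acid, an environmental autism risk factor) crossed with
rearing environment (standard, unpredictably enriched, predictably
enriched) — produces many partially redundant readouts per animal: open-arm
exploration on the elevated-plus maze, freezing percentages across fear
conditioning sessions, social sniffing preference, hot-plate withdrawal
latency, a rare Y-maze perseveration flag, and optional biochemistry
(glutamatergic protein immunoreactivity per brain region, corticosterone).
Three questions recur: do the factors interact at the group level; can the
correlated fear/anxiety measures be condensed into one defensible composite;
and do *individuals* — rather than group means — fall into interpretable
subgroups? This package answers the three in one pipeline.

## The emotionality composite

All measures are z-transformed over the **pooled** cohort (both prenatal
groups, all environments), using the n−1 standard deviation, and
orientation-aligned afterwards: measures on which a higher raw value means
*lower* emotionality (open-arm time) are negated after standardization, so
z > 0 always reads "more emotional". Pooled (rather than within-group)
standardization is deliberate: composite scores and cluster profiles are
compared across prenatal groups on one axis, which requires one scale.

Internal consistency is quantified by the standardized Cronbach's alpha,
$\alpha = k\bar r/(1+(k-1)\bar r)$, computed from the mean pairwise Pearson
correlation $\bar r$ of the $k$ items. The standardized form (not the
covariance-based one) is the natural choice here because the inputs are
unit-variance z-scores, and because the canonical published value pair for
this design ($\bar r = 0.335$, $\alpha = 0.716$ at $k = 5$) satisfies this
formula exactly.

`selectItems()` enumerates every subset of the candidate measures of size
≥ 3 (the candidate list is a catalog property, bounded at 20 items so the
search stays exhaustive), chooses per subset an orientation making all
item-rest correlations positive when one exists (leading-eigenvector sign
followed by greedy flips), and returns the subset maximizing alpha; ties go
to the larger subset, then lexicographic names, for determinism. Two
details worth noting:

* Pairwise correlations use pairwise-complete observations; a pair with
  fewer than 3 complete cases is an error naming the pair.
* Because orientation is chosen to maximize coherence, the winning subset's
  $\bar r$ is nonnegative by construction even for pure noise; the null
  case therefore shows up as $\alpha \approx 0$, and a correlation below
  the 0.28 reporting floor raises a flag rather than an error.

The composite score is the per-animal mean of the oriented z-scores over
the selected items, defined only when at least ⌈k/2⌉ items are observed —
a majority rule that keeps scores comparable without imputation.

## Group statistics

* **Factorial ANOVA** uses type III sums of squares with sum-to-zero
  contrasts (`car::Anova` on an `lm` fit). The design is unbalanced by one
  animal (VPA-PE n = 17), and main effects are interpreted in the presence
  of an interaction; type III is the partitioning under which that is
  well-defined. The tests verify the implementation against an explicit
  least-squares model-comparison oracle.
* **Post-hoc comparisons** are independent two-sample SAL-vs-VPA t-tests
  within each environment — not pooled-error contrasts — because the
  per-comparison Welch correction that this design calls for is
  incompatible with a pooled error term. Welch's correction is triggered
  automatically when the two-sided variance F-test for that pair has
  p < 0.05. The Bonferroni multiplier is the number of comparisons
  performed (3 when all environments are testable).
* **Exact tests.** Perseveration is rare (about 2/54 control, 10/53
  exposed), so contingency tests must be exact. Fisher's test uses the
  two-sided minimum-likelihood rule (sum of same-margin tables with point
  probability ≤ observed), the dominant software convention. Barnard's
  unconditional test is implemented in the package (no installed package
  provides it): the statistic is the pooled-proportion Wald score, and the
  p-value is the supremum over the common success rate π on a uniform grid
  (default step 0.001) of the two-binomial probability of the region
  |T| ≥ |T~obs~|; the maximizing π is reported alongside T. The grid step
  is a bias-speed trade-off; tests compare the default grid against a
  10⁻⁴ grid and agree to 3 decimals on small tables.
* **Rank correlations** between the composite and protein levels use
  Spearman's rho (mean ranks for ties, two-sided p via the t
  approximation), computed within each prenatal group because the
  behavior–protein coupling is expected to differ in sign between groups.

## Individual differences

Clustering runs separately per prenatal group, on the pooled-cohort
oriented z-scores of the selected items (again: no within-group
re-standardization). Distances are **squared** Euclidean; Ward's linkage is
computed through the Lance–Williams recurrence (via `stats::hclust`,
`ward.D`, with heights rescaled so each merge height equals the
within-cluster SS increase itself, no square-root transform). That
convention makes heights additive — they sum to the total SS, and the SS at
any cut plus the heights above the cut reconstruct the total, which the
test suite asserts. Common toolkits differ on exactly this convention, so
it is recorded in the output metadata.

The cut at k clusters relabels clusters I..k by ascending mean composite
score (ties to the larger cluster). k defaults to 4, matching the
granularity typically reported for cohorts of ~54 animals per group, and
`homogeneityDiagnostics()` always emits the merge-height gaps for k ≤ 10;
a gap is flagged dominant when it exceeds the sum of all other positive
gaps, a deliberately conservative rule that stays quiet on unstructured
data. Animals missing any clustering measure are excluded with a warning
(imputation is out of scope). Cluster percents are reported with
nearest-integer rounding; note that published figures occasionally
floor-round (4/53 printed as 7 % rather than 8 %), so the rounding rule is
recorded in the profile table's attributes.

Profiles separate **core** variables (the clustering inputs and the
composite, on the z scale) from **predicted** variables (social preference,
hot-plate latency, proteins, corticosterone, and the rearing-environment
composition) that never entered the clustering — the predicted profiles
are where the scientific claims live, since they are not circular.

## The synthetic cohort generator

`simulateCohort()` is first-class, tested code, not a fixture. It emulates
the cohort structure the analysis assumes:

* **Design**: 18 animals per cell, 17 in VPA-PE (107 total).
* **Emotionality measures**: per cell, a 5-dimensional normal built from a
  shared latent emotionality factor, giving compound-symmetry correlation.
  The latent factor loads with each measure's orientation, so open-arm time
  anti-correlates with the freezing measures in raw units, as it must.
  Draws are clamped to valid ranges (freezing to [0, 100], times ≥ 0);
  means sit ≥ 2.5 sd from the bounds so clamping touches < 1 % of draws
  (the realized fraction is recorded in the cohort metadata). Clamping
  rather than resampling preserves determinism per seed.
* **Correlation calibration.** The configured `inter_measure_r` (default
  0.335) is the **pooled-cohort** mean pairwise correlation, because that
  is what the published summary describes (it was computed across all 107
  animals). Programmed cell-mean differences already induce between-cell
  correlation, so the generator solves analytically for the within-cell
  compound-symmetry correlation that delivers the configured pooled value
  given the cell means, sds and sizes (about 0.13 at the defaults). A
  target unreachable without a non-positive-definite within-cell
  covariance is a hard error before sampling.
* **Cell means/sds**: chosen once to reproduce the qualitative orderings
  and variance ratios such studies report, since raw-scale group means are
  not published: VPA-ST highest and VPA-PE lowest emotionality, SAL-UE/PE
  slightly above SAL-ST, and a variance ratio of 4 for VPA-PE vs SAL-PE on
  open-arm time and social preference (mirroring a variance F near 4 on
  those scales). Freezing baselines sit near 45 % (sd 10), open-arm time
  near 40 s of a 300 s session (sd 12).
* **Perseveration**: Bernoulli per prenatal group at 2/54 and 10/53.
* **Biochemistry**: protein immunoreactivity is generated on the raw scale
  with multiplicative assay-batch effects (3 batches, counterbalanced) and
  then normalized within batch as percent of the batch's SAL-ST mean by the
  same `normalizeIR()` the user-facing pipeline uses — never pooled across
  batches. Proteins and corticosterone couple linearly to the animal's
  latent emotionality deviation with opposite signs in SAL vs VPA
  (in VPA: lower S1 GluN2B and dHip CaMKII, higher vHip GluN1 and plasma
  corticosterone with higher emotionality).
* **Determinism**: one `set.seed(config$seed)` initializes a single stream
  consumed in a fixed cell-by-cell, block-by-block order, so a seed fully
  determines the cohort; the previous RNG state is restored on exit.

What the generator does **not** emulate: litter effects or within-litter
correlation (animals are drawn independently, as the target analyses treat
them), floor-compressed skewed distributions (open-arm times near 5 % of
session in most groups are plainly non-normal in real data; the generator
uses clamped normals), session-to-session learning dynamics within fear
conditioning, and any genuine biological coupling beyond a single latent
factor. Passing tests therefore demonstrate that the *statistical
machinery* behaves correctly under the assumed structure — not that real
cohorts satisfy that structure.

## Numerical choices and problem sizes

* z-scoring tolerance: columns reproduce mean 0 / sd 1 to 10⁻¹⁰; the
  pooled composite mean is 0 to 10⁻⁸ when nothing is missing.
* Alpha is undefined at $\bar r \le -1/(k-1)$ and errors there.
* Ward merge tie-breaks follow `hclust`'s deterministic pair ordering;
  with continuous data ties have probability zero, and the permutation
  tests fix labels across 20 input shuffles.
* Test-suite problem sizes were chosen to keep the default run around a
  minute while leaving Monte-Carlo margins comfortable: the ANOVA type-I
  calibration uses 2,000 null replicates at n = 18/cell (acceptance band
  0.03–0.07 at α = 0.05), sign-pattern recovery uses 500 replicates at the
  study size, and large-sample recovery checks use 5,000–10,000 animals
  per cell.

## Known limitations

* `selectItems()` is exhaustive and thus exponential in the candidate
  count; the hard cap of 20 candidates keeps the worst case ~10⁶ subsets.
* The orientation search within a subset is a heuristic (eigenvector sign
  + greedy flips); it can in principle miss an orientation making all
  item-rest correlations positive, though no such case has surfaced in
  testing.
* Barnard's supremum is a grid maximum; π values between grid points are
  not examined. The default step 0.001 matches the granularity at which
  such results are printed.
* Cluster solutions carry no stability or significance measures
  (bootstrap stability and between-cluster tests are out of scope; with
  strongly unequal cluster sizes, comparisons should stay qualitative).
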