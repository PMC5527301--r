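---
title: "Methods: couple matching from skin microbiome OTU tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: couple matching from skin microbiome OTU tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinmatch)
```

# The problem

Cohabiting partners exchange skin microbiota through shared surfaces and
direct contact. Given 16S rRNA OTU tables from many body sites of a cohort of
couples, the analytical questions are: how strongly do body site,
individuality, sex, cohabitation and lifestyle structure the communities; can
a sample's nearest community neighbor identify its donor or the donor's
partner better than chance; and can a supervised classifier pair partners
more reliably than arbitrary male-female regroupings?

skinmatch implements that entire analysis as a reusable pipeline: data model
and I/O for QIIME-classic OTU tables and mapping files, depth filtering and
rarefaction, alpha diversity with multiple-rarefaction sweeps and
nonparametric category tests, Bray-Curtis distances and PCoA,
nearest-neighbor self/partner/other matching with analytic chance baselines,
one-factor PERMANOVA, a shuffled-couple (derangement) permutation null for
both the PERMANOVA pseudo-F and a random-forest classification error,
Dufrene-Legendre indicator analysis, core-OTU detection and sex-enrichment
tables. A hierarchical community simulator reproduces the study design so
every stage is testable without external sequence data.

# Statistical machinery

## Rarefaction and diversity

Samples below the depth cutoff (default 5,293 reads) are removed; the rest
are subsampled without replacement to exactly that depth, so per-OTU rarefied
counts have hypergeometric marginals. All-zero OTU columns are kept by
default so indices stay aligned across replicate rarefactions.

Alpha diversity is the Shannon index (log base 2, the QIIME-1 convention) or
the observed OTU count. The multiple-rarefaction sweep evaluates the metric
on `reps` independent rarefactions at every depth of an arithmetic grid; the
grid always includes the maximum depth, so the canonical 100..5,290-by-100
sweep has 53 depths x 10 replicates = 530 tables. For category testing,
per-sample alpha is the mean over replicates at the largest depth (the
aggregation rule is otherwise unspecified in the source analysis; this is the
package's choice). Two-sample contrasts use the unequal-variance t statistic
with a label-permutation p-value and the +1-smoothed estimator
p = (1 + #{|t*| >= |t|}) / (1 + B), so p is never zero; multi-level
categories expand to all pairwise contrasts and the Bonferroni factor is the
number of tests actually executed, which the sweep reports.

## Distances, ordination, PERMANOVA

Bray-Curtis dissimilarity d(x, y) = sum|x_i - y_i| / sum(x_i + y_i) is
computed on rarefied counts; with equal row sums this equals the
proportion-based form, and the function warns when depths are unequal. PCoA
is classical metric scaling: double-center -D^2/2, eigendecompose, scale
eigenvectors by sqrt of positive eigenvalues. Negative eigenvalues (expected
for Bray-Curtis) are reported and their axes dropped; no Lingoes/Cailliez
correction is applied because downstream statistics use the distance matrix
directly.

One-factor PERMANOVA uses the sums-of-squared-distances decomposition:
SS_T = (1/N) sum_{i<j} d_ij^2, SS_W = sum_g (1/n_g) sum_{i<j in g} d_ij^2,
F = (SS_A/(a-1)) / (SS_W/(N-a)), with unrestricted label permutations and the
smoothed p estimator. Only single factors are fitted (the analysis this
reproduces reports per-category F values); multi-factor requests run factors
independently.

## Closest-match analysis

For each sample the minimum-distance candidate is classified as self (same
participant), partner (same couple) or other. Three scopes shrink the
candidate pool: `all` (exclude only the query), `nonself` (exclude the
query's participant) and `nonself_opposite_sex` (additionally exclude same-sex
participants). Candidates are restricted to the query's body location by
default; a pooled mode is also emitted because the published overall rates
may pool locations. Distance ties are broken by lexicographic sample id and
counted.

Chance baselines for the partner relation are participant-level uniform
choices: 1/(n-1) under `nonself` (19 eligible participants for 20
subjects, ~5.3%) and 1/(n/2) under `nonself_opposite_sex` (10%). A
sample-level empirical baseline (partner samples / eligible samples, averaged
over queries) is reported alongside for sensitivity; the two coincide for
balanced designs. Among nonself matches that are neither self nor partner,
the same-sex fraction is tested against the design null (n/2 - 1)/(n - 2)
(= 0.5 for 10 couples) with an exact binomial test.

## The couple-pairing (derangement) null

An "incorrect pairing" rematches every female with a male who is not her
partner: a derangement of the couple indices. Counts follow the recurrence
!n = (n-1)(!(n-1) + !(n-2)); !10 = 1,334,961, from which 1,000 distinct
pairings are drawn uniformly without replacement (enumeration and subsampling
below n = 8, rejection sampling of uniform permutations above). A stricter
reading than "any non-identity matching" is used deliberately: derangements
leave no couple intact, which is the cleanest null for "couples carry no
signal".

Two statistics are recomputed under every pairing with metadata otherwise
untouched: the PERMANOVA pseudo-F of the couple labels (large F for the true
pairing = partners share structure) and the stratified k-fold cross-validated
error of a random-forest classifier predicting couple labels from rarefied
counts (small error = couples are coherent classes). Empirical p-values are
(1 + #{F* >= F}) / (1 + m) and (1 + #{err* <= err}) / (1 + m).

The classifier is a from-scratch random forest (CART trees, Gini splitting,
bootstrap resampling, sqrt(p) features per node, majority vote) implemented
in C++, because no tree-ensemble package is available in the target
environment; full-scale defaults are 1,000 trees and 10-fold CV. Repeated CV
(`n_repeats`) refines the error granularity for permutation testing. Each
pairing's evaluation draws from an RNG substream derived from the pairing's
content, so null distributions are invariant to evaluation order.

A caveat documented here because the test suite measures it: the set
{true pairing} U {derangements} is not a group orbit, so even under a fully
exchangeable null the derangement-null p-value is only approximately uniform.
The true pairing shares zero assignments with every derangement while
derangements overlap each other, so the observed statistic is slightly less
correlated with the null set than null members are among themselves; the
distortion shrinks as the number of couples grows (random derangements of 10
couples share ~1 assignment on average). The acceptance suite therefore
checks uniformity at the 10-couple design scale and checks the exact
smoothed-p arithmetic separately.

## Indicators, cores, enrichment

IndVal follows Dufrene-Legendre on the 0-1 scale: specificity
A = group mean / sum of group means, fidelity B = occupancy fraction,
IndVal = A x B. Significance permutes group labels with the max-over-groups
IndVal per OTU as the statistic (999 permutations by default); the OTU-level
p is attached to each group record. The canonical indicator filter keeps
IndVal >= 0.7 AND group mean abundance >= 10 reads AND p < 0.05. "Minimum
mean abundance" is interpreted as the mean within the indicated group on the
rarefied table. Core OTUs of a category level are those with at least one
read in every sample of the level. The sex-enrichment table reports, for
OTUs present in at least 30% of the enriched sex's samples, the percent
increase (mean_high / mean_low - 1) x 100, top 10 per direction; OTUs absent
from the depleted sex are flagged infinite and excluded from ranking unless
requested. (The upstream analysis prints a 1,111.4% increase while its text
calls it "11.1-fold"; this package defines percent increase as
(ratio - 1) x 100, under which 1,111.4% corresponds to a 12.1-fold ratio.)

# The synthetic cohort

`sim_config()` defaults encode the study design: 10 couples x 2 participants
x 17 swabs (7 bilateral locations + 3 midline) = 340 samples; three moisture
classes assigned per location; log-normal sequencing depth (median ~12,000
reads, floor 6,000) plus 10 samples deliberately degraded below the 5,293
cutoff, so the filter retains 330.

Per-sample OTU log-weights are additive Gaussian effects —
baseline (sd 1.5) + site (sd 2.0) + participant (sd 1.0) + couple (sd 0.7) +
sex (sd 1.0, only on designated sites, default inner thigh and armpit) +
replicate noise (sd 0.5) — softmax-normalized, Dirichlet-overdispersed
(concentration 200), and multinomially sampled. The log-additive form was
chosen over a stratified Dirichlet-multinomial because it factorizes the
variance components for recovery tests.

Two calibration choices deserve justification:

* **Effect ordering and scale.** Site >> individual > couple ~ sex mirrors
  the established structure of skin communities. The couple and noise scales
  (0.7, 0.5) were fixed once so the full design reproduces the published
  closest-match magnitudes — overall nonself partner matching near 20% and
  self matching near 58-64% — since the source analysis never quantifies the
  cohabitation effect on an interpretable scale.
* **Sex evenness factor.** A symmetric compositional sex effect cannot move
  Shannon diversity systematically, yet female-higher-diversity is a robust
  observation (4.59 vs 3.98 in the motivating cohort). Male log-weights are
  therefore scaled by `sex_evenness_factor` (default 1.1), mildly sharpening
  male communities.

What the generator does **not** emulate: taxonomy-realistic lineages (labels
are arbitrary but collapsible), phylogenetic structure (no UniFrac),
covariance between lifestyle columns and composition (lifestyle labels are
random), and read-level artifacts (chimeras, contamination). A green test on
synthetic data therefore establishes correctness of the statistics and the
qualitative effect structure, not biological realism of any particular OTU.

# Numerical and design choices

* All randomness flows through explicit seeds; `with_seed()` restores the
  caller's RNG state, so library calls never perturb user streams.
* Permutation p-values use the +1-smoothed estimator everywhere, bounded
  below by 1/(B+1).
* The permutation t-test sorts each group's values first, making results
  exactly invariant to sample order.
* Distance ties in nearest-neighbor matching: lexicographic winner, tie
  counted and reported.
* Rarefaction uses index subsampling via `findInterval` on cumulative
  counts, O(depth log p) per sample.
* The two rarefaction config values (removal cutoff 5,293; sweep maximum
  5,290) are deliberately independent, preserving a 3-read discrepancy in
  the source protocol.
* Degenerate simulator configs (all effects zero, no overdispersion) are
  allowed and warn rather than fail.
* `scaled_down = TRUE` in `pipeline_config()` substitutes a declared cheap
  configuration (99/49/99 permutations, 50 trees, 3 folds, small alpha grid)
  and records it in the manifest; full-scale defaults are the published
  settings.

# Known limitations

* UniFrac and other phylogenetic metrics are out of scope; externally
  computed distance matrices in the square TSV dialect are accepted instead.
* PERMANOVA is single-factor with unrestricted permutations; no
  strata/nested designs, no dispersion (PERMDISP) test.
* The derangement-null p-value is approximately, not exactly, uniform under
  the null (see above); at 10 couples the deviation is within Monte-Carlo
  noise for practical purposes.
* The classifier reports no variable importance; the pipeline's purpose is
  the error statistic, not feature discovery.
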