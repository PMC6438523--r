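---
title: "Genome-wide cluster analysis: methods and design choices"
author: "coreclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide cluster analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coreclust)
```

# Overview

coreclust implements a genome-wide heatmap analysis workflow for
feature-by-sample molecular matrices, organised as four chained stages —
core-gene selection, consensus estimation of the number of clusters,
silhouette-based core-sample filtering, and an updated heatmap — plus two
companion analyses: cluster-of-clusters integration of multiple platforms
(CrC) and bootstrap significance testing of gene sets (SoC). This
vignette documents the statistical procedures, the tunable parameters and
their defaults, the numerical conventions, and the design choices made
where the methodology is genuinely open, so that users know exactly what
the package computes and why.

# Data model and input conventions

The central container is `FeatureMatrix`, a thin `SummarizedExperiment`
holding one numeric assay (features in rows, samples in columns), an
optional categorical feature grouping (at most 6 levels) and zero or more
categorical sample-annotation tracks (at most 10 levels each). Those caps
mirror the display limits of the annotation colour bars.

Delimited-text input follows a fixed layout: row 1 is the sample-id
header, rows 2..(dataStartRow − 1) are sample-annotation tracks, column 1
holds feature ids and columns 2..(dataStartCol − 1) feature tracks. A
file with ER/PR/HER2 tracks and a gene-group column therefore has its
numeric block starting at row 5, column 3. Rows containing any
non-numeric or missing cell are *rejected at ingestion* with a report
naming the file row and column (no imputation is attempted); a strict
mode errors on the first offending cell instead.

Three value transforms cover common upstream conventions:
`log2_count` (log2(x + 1) for expression counts), `beta_to_m`
(log2((1 + β)/(1 − β)) for methylation beta values, strictly increasing
on [0, 1) with 0 mapped to 0), and `shift_nonneg` for copy-number segment
means. The shift is defined as adding the absolute value of the global
minimum so that the post-transform minimum is exactly 0; adding the
*signed* minimum would move an already-negative matrix further down,
which cannot be the intent of a nonnegativity rescaling. The applied
offset is stored in the object's metadata so the transform is invertible
and auditable.

# Core genes: measures of spread and percentile cutoffs

Three spread measures are available per feature: the sample variance
(n − 1 denominator), the median absolute deviation about the median
scaled by 1.4826 (so it estimates the SD under normality), and the
inter-quartile range Q3 − Q1. All quantiles in the package — the IQR
itself and every percentile cutoff — use linear interpolation between
order statistics (type 7), the default of R and of most spreadsheet
software. The cutoff rule defaults to *strictly above* the percentile;
`at_or_above` is available because "above the 99th percentile" is
ambiguous at ties.

For sparse data (e.g. variant allele frequencies), single measures are
unstable: many features tie at zero spread under one measure but not
another. The integrated selector therefore ranks features under two or
more measures (ascending, rank 1 = smallest, ties averaged so rank sums
are preserved), sums the ranks per feature, and applies the percentile
rule to the rank-sum distribution. Because ranks are invariant to any
strictly increasing transform of the underlying values, this selection
depends only on the orderings, a property the test suite checks
explicitly. The percentile is applied to raw rank sums rather than a
rescaled score; with two measures inducing identical orderings the
integrated selection coincides with the single-measure selection at the
same percentile.

# Clustering primitives

All stages share one set of primitives. Scaling options are `row_z`
(feature-wise z-scores, sample SD), `col_z`, and `row_then_col_z`; the
combined option applies rows first, then columns — the order matters and
is fixed so that repeated runs agree, with the choice recorded in the
ledger. Zero-spread vectors scale to all zeros with a warning rather
than an error, since constant features are common after filtering.

Distances: `one_minus_pearson` and `one_minus_spearman` (range [0, 2]),
`euclidean`, `manhattan`, and `canberra` defined as
Σ|x − y|/(|x| + |y|) with 0/0 terms contributing 0. The Canberra
convention is implemented in-package because the common library variant
uses |x + y| denominators and rescales omitted terms, which behaves
poorly on the sparse data this distance is intended for. Distances on
samples are computed on the scaled matrix whenever scaling is enabled;
this pairing is recorded.

Linkages: `ward_d` applies the Ward Lance–Williams update to the
*unsquared* input distances (the classic "ward.D" semantics, distinct
from ward.D2 which squares them), `average` (UPGMA), `mcquitty` (WPGMA),
`complete`, `single`. Agglomeration is deterministic for a fixed input
ordering, which together with mandatory seeds makes every tree
reproducible. Tree cuts renumber clusters by order of first appearance
along the leaf order, so "cluster 1" is always the leftmost cluster and
labels are stable across platforms.

# Consensus clustering and the number of clusters

For each repetition, ⌈pItem · n⌉ samples (default pItem = 0.8) and
⌈pFeature · p⌉ features (default 1.0) are drawn *without replacement*,
the sub-matrix is clustered once, and the tree is cut at every k in the
candidate range (default 2..6, 100 repetitions). The consensus matrix at
k divides pairwise co-clustering counts by pairwise co-sampling counts —
the standard definition; 0/0 (a pair never co-sampled) is reported as 0
with a warning naming the sample. With pItem = 1 and a deterministic
inner clustering the consensus entries are exactly 0/1 regardless of the
number of repetitions, a property used as a test oracle.

A(k) is the area under the empirical CDF of the upper-triangle consensus
entries over [0, 1]; a perfectly dichotomous matrix concentrated on
{0, 1} has A equal to the fraction of zero entries. The relative
delta-area is Δ(2) = A(2) and Δ(k) = (A(k) − A(k−1))/A(k−1) for k > 2.
Automatic selection returns the *largest* k whose Δ exceeds a knee
threshold (default 0.1, configurable); when none does, the smallest
candidate k is returned with a warning. Because the original
methodology selects k visually from the CDF and delta-area plots, a
`user_fixed` policy is provided as well, and whichever policy was used is
recorded in the ledger. Final assignments at each k come from
hierarchically clustering 1 − M_k with the inner linkage, mirroring the
reference consensus-clustering implementation.

# Core samples by silhouette widths

At the selected k, each sample's silhouette width
s(i) = (b(i) − a(i))/max(a(i), b(i)) is computed on the *same* distance
matrix used for the clustering being evaluated (recorded pairing);
singleton clusters receive width 0 by convention. Filtering removes
samples with width strictly below their cluster's threshold — retained
means width ≥ threshold — because published analyses phrase the rule as
removing samples with widths *less than* the cut. Thresholds are
per-cluster user inputs (they are data-driven in practice, e.g. 0.15 and
0.34 in a two-cluster analysis); since no selection rule for them is
established, the package also offers an automatic rule — retain
s(i) ≥ mean cluster width − 1 within-cluster SD — behind the
`thresholds = "auto"` flag, which is the workflow default so that
unattended runs are possible. Raising a threshold can only shrink the
retained set (tested monotonicity), and a cluster losing all samples is
dropped downstream with a warning.

# Cluster-of-clusters (CrC) integration

Per-platform cluster assignments on shared samples are merged into a
binary membership matrix: one indicator row per platform sub-cluster, in
platform order then cluster index. Within a platform the rows partition
the samples, so every column sums to the number of platforms — an
invariant asserted on every build. The default cap of three platforms is
a validated parameter, configurable upward. The membership matrix is
clustered on samples with Euclidean distance and ward.D by default;
either a fixed k or the same consensus machinery may decide the number of
combined clusters. Interpretation outputs are deliberately descriptive,
not inferential: per platform and combined cluster, a five-number summary
of the pooled core-feature values and an "increased"/"decreased" call
comparing the cluster median to the platform's overall median; and
chi-squared contingency tests (Pearson, no continuity correction by
default, with Yates' correction behind a flag) between any two
labelings, flagged when any expected count falls below 1. For display
the heatmap clusters both axes of the binary matrix, but only the sample
labels carry meaning.

# Gene-set significance (SoC)

The separation statistic is the adjusted Rand index between the partition
obtained by clustering samples on the gene-set rows alone (cut at
g = number of groups) and the known group labels. The ARI was chosen
because it is label-permutation invariant, extends to more than two
groups, has expectation 0 under independence, and admits an exact
pair-counting oracle for testing; the statistic is pluggable and its name
is recorded in every result so alternative statistics are never silently
conflated. B random feature sets of the same size (default B = 1000) are
drawn from the genome-wide matrix — without replacement within a draw,
because a "gene set" with duplicated members is ill-defined for row
clustering; by default the tested set's own genes remain in the pool
("random gene sets of the same size" implies unrestricted draws), with
exclusion available behind a flag. The p-value uses the add-one form
(1 + #{null ≥ observed})/(B + 1), bounded below by 1/(B + 1) and never 0.

One behaviour of this statistic is worth knowing: when the observed gene
set separates the groups *perfectly* (ARI = 1), any null draw that also
reaches ARI = 1 ties with the observed value and inflates p. Null draws
can reach perfection when the feature pool is small relative to the
signature and individual markers are very strong, because a random draw
then frequently catches a marker strong enough to drive the clustering on
its own. Significance of a signature is therefore only meaningful
against a genuinely genome-wide background — which is exactly how the
workflow is specified to be used.

# Provenance and replay

Every workflow stage appends a step to a `ProvenanceRecord`: step name,
the complete parameter map it consumed (including the seed), elapsed
seconds, content fingerprints of inputs and outputs, and the package
version. The ledger serializes to YAML and back losslessly; elapsed
times are recorded for reporting but excluded from equality comparisons.
`replayGWH()` re-executes a run from the recorded configuration and, on
the same input, reproduces identical core genes, consensus matrices,
retained samples, final labels and heatmap leaf orders — a contract the
acceptance tests enforce, together with an exhaustiveness check that
every output-affecting parameter of each workflow appears in its ledger.
Heatmap renders always emit a text sidecar with the exact row/column leaf
orders and a YAML file with every display parameter. Annotation colours
come from a fixed, documented palette (level i of any track maps to
palette colour i), so repeated renders are identical; the palette is the
package's own choice.

# Synthetic study conditions

The generator `makePlantedMatrix()` emulates genome-wide data with known
truth: k balanced sample clusters; a fraction of informative features
whose cluster means are separated by `effect` within-cluster SD units,
each feature assigning the mean levels to clusters in its own random
order; the remainder pure Gaussian noise; optional zero-inflation for
variant-like sparsity. Defaults are the package's reference study
conditions — 100 features, 60 samples, k = 2, effect 4, noise SD 1 — the
sizes at which the consensus-recovery properties are stated. The
informative fraction defaults to 0.2: one feature in five carrying
signal keeps the planted structure detectable by spread filtering
without making every feature a marker, in line with the fraction of a
transcriptome that typically tracks a strong subtype distinction.
`makeMultiomic()` layers per-platform concordance on a shared truth
partition: each sample keeps its truth cluster on a platform with the
given probability, otherwise it is reassigned uniformly among the other
clusters, and the platform's matrix is planted around those labels.

What the generator does *not* emulate: count-distribution marginals,
feature-feature correlation beyond the planted means, batch structure,
or outlier samples. Passing recovery tests on these fixtures
demonstrates the machinery is correct and calibrated, not that any
particular real dataset has recoverable structure.

Problem sizes used by the test suite and the acceptance script — e.g.
consensus recovery over 20 seeds at n = 60 samples and 100 features with
100 repetitions, SoC calibration over 200 replicates at B = 200, a
25-gene signature in a 1000-feature pool — are the package's chosen
reference scales: large enough for the asymptotic behaviour (uniform null
p-values, ≥ 95% recovery) to be visible, small enough to run routinely.

# Known limitations

- The clustering menu is hierarchical only (no k-means, density or graph
  clustering), matching the workflow it implements.
- Consensus k selection by the delta-area knee is a heuristic; on data
  with nested or weak structure the CDF curves should be inspected
  (they are returned in full) rather than trusting the automatic choice.
- Silhouette thresholds for core samples have no principled selection
  rule; the automatic mean − 1 SD rule is a pragmatic default, not an
  inference.
- CrC integration is strictly result-merging on cluster indicators; it
  cannot recover joint structure invisible to every single platform
  (no latent-factor integration).
- SoC p-values have resolution 1/(B + 1) and, as noted above, are
  conservative when random background sets can separate the groups
  perfectly.
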