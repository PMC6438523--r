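# coreclust

Genome-wide cluster analysis for feature-by-sample molecular data
(expression, methylation, copy number, variants), built for analysts who
need heatmap results that can be *replicated*: every stage runs from
recorded parameters and seeds, and every run emits a ledger sufficient to
reproduce it exactly.

The package implements one coherent workflow plus two companions:

1. **Genome-wide heatmap (GWH) analysis** of a single data type:

   - **Core genes.** A "most variable" feature set is selected by a
     measure of spread — sample variance (VAR), scaled median absolute
     deviation (MAD = 1.4826 · med|x − med x|), or inter-quartile range
     (IQR = Q3 − Q1, type-7 quantiles) — keeping features above a
     percentile cutoff (e.g. IQR above the 99th percentile). For sparse
     data, an *integrated* selector ranks features under two measures
     (typically IQR + MAD), sums the ranks, and applies the percentile
     cutoff to the rank sums.
   - **Number of clusters.** Resampling consensus clustering: with
     repetitions *b* = 1..B, draw ⌈0.8·n⌉ samples, cluster them
     hierarchically (default 1 − Pearson distance, average linkage), and
     form for each k the consensus matrix
     M_k(i,j) = #co-clustered / #co-sampled. The number of clusters is
     estimated from the relative increase in the area under the CDF of the
     consensus values, Δ(k) = (A(k) − A(k−1)) / A(k−1).
   - **Core samples.** Silhouette widths
     s(i) = (b(i) − a(i)) / max(a(i), b(i)) are computed at the selected
     k; samples with width below a per-cluster threshold are removed.
   - **Updated heatmap.** Core genes × core samples are re-clustered
     (default row-then-column z-scores, 1 − Pearson, ward.D) and rendered
     with annotation colour bars; leaf orders and all parameters are
     written alongside the image.

2. **Combined-results cluster (CrC) analysis** integrates cluster results
   from up to three platforms on the same samples: each platform's
   sub-clusters become indicator rows of a binary membership matrix
   (every column sums to the number of platforms), which is itself
   clustered (default Euclidean + ward.D) into combined clusters.
   Interpretation aids: per-platform five-number summaries with
   increased/decreased calls, and chi-squared contingency tests of
   association between labelings.

3. **Significance of clusters (SoC)** asks whether a gene set separates
   labelled sample groups better than chance: the observed separation
   (adjusted Rand index between the gene-set-driven hierarchical partition
   and the known groups) is compared against B random same-size gene sets
   drawn from the genome-wide matrix, with the add-one empirical p-value
   (1 + #{null ≥ observed}) / (B + 1).

## Worked example

```r
library(coreclust)

# a synthetic dataset with two planted sample clusters: 200 features,
# 60 samples, 10% informative features shifted by 6 SD between clusters
fx <- makePlantedMatrix(nFeatures = 200, nSamples = 60,
                        informativeFraction = 0.1, effect = 6, seed = 1)

res <- runGWH(fx$matrix, measures = "IQR", percentile = 90,
              reps = 100, seed = 1)
length(res$coreGenes)
#> [1] 20
res$consensus
#> ConsensusResult: k in {2, 3, 4, 5, 6}; 60 samples
#>   delta-area: k=2: 0.508; k=3: 0.068; k=4: 0.067; k=5: 0.054; k=6: 0.067
#>   selected k = 2
res$silhouette
#> SilhouetteReport: 60 samples in 2 clusters; mean width 0.940
#>   retained 45 / 60 core samples
```

The IQR filter at the 90th percentile recovers exactly the 20 planted
informative features; only Δ(2) = 0.508 exceeds the knee threshold (0.1),
so two clusters are selected; the automatic silhouette rule (mean width −
1 SD per cluster) retains 45 core samples; and the final labels agree
perfectly with the planted truth (cross-tabulating `res$finalLabels`
against `fx$labels` gives a diagonal table — adjusted Rand index 1).

Testing a 25-gene signature (per-gene 2-SD shift) against a 1000-gene
background:

```r
sig <- makePlantedMatrix(nFeatures = 1000, nSamples = 40, k = 2,
                         informativeFraction = 0.025, effect = 2, seed = 2)
socBootstrap(sig$matrix, sig$informative, sig$labels, B = 200, seed = 2)
#> SoCResult: adjusted_rand_index = 1.0000; p = 0.004975 (B = 200)
```

The signature separates the groups perfectly and beats all 200 random
sets, so p = 1/201.

Every run carries its ledger: `res$ledger` lists each stage with its full
parameter map, seed and elapsed time, `writeProvenance()` /
`readProvenance()` serialize it, and `replayGWH(fx$matrix, res$ledger)`
re-executes the workflow to identical labels and leaf orders.

A command-line front end over the same functions is installed at
`inst/scripts/coreclust.R` (subcommands: `ingest`, `core-genes`,
`consensus`, `core-samples`, `gwh`, `crc`, `soc`, `fixtures`).

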