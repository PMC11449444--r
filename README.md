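# regenphase

Temporal phase analysis of regeneration time-course transcriptomes.

Axolotls (*Ambystoma mexicanum*) regenerate complex structures — limbs, and
also large resection defects of the lower jaw — through wound healing,
blastema formation and tissue redifferentiation. Bulk RNA-seq time courses
of such processes are typically analysed by clustering standardized gene
trajectories and grouping the clusters into named temporal phases
(e.g. *5 dpi peak*, *general rise*), then asking how much of the programme
two structures share. `regenphase` packages that entire chain as tested,
seedable, tidyverse-style functions, for anyone analysing low-replicate
regeneration (or other injury-response) time courses:

1. **Normalisation** — counts per million (CPM): plain library-size scaling,
   `cpm[g,s] = counts[g,s] / sum_g counts[g,s] * 1e6`, and replicate
   averaging into per-time profiles.
2. **Filtering** — four stages: mean CPM ≥ 0.8; sample variance ≥ 0.4;
   max CPM over time > 20; max/min fold change above a multiplier that
   depends on the gene's minimum expression (5 below 1 CPM, 3 up to 5 CPM,
   2 above).
3. **Standardisation** — per-gene z-scores over time (mean 0, sd 1,
   denominator n−1).
4. **Cluster number** — the gap statistic,
   `Gap(k) = (1/B) Σ_b log W*_kb − log W_k`, with uniform range-box
   reference sets and the first-crossing rule
   `Gap(k) ≥ Gap(k+1) − s_{k+1}`.
5. **Clustering** — k-means (Lloyd iterations, k-means++ starts, best of
   `n_init` restarts), with a per-gene *cluster score*: the Pearson
   correlation of a gene's z-profile with its centroid. Genes with
   score > 0.75 are the *genes of interest*.
6. **Phase grouping** — a deterministic centroid rule (peak time +
   monotonicity within tolerance) assigns clusters to named phase groups;
   down-regulated centroids peaking in the intact sample stay unassigned.
7. **Cross-structure comparison** — shared genes by identifier, the
   jaw-group × limb-group overlap-percentage matrix, and the fraction of
   early shared genes that are 3-hour transients in the limb.
8. **Morphometry** — defect size relative to (hemi)mandible perimeter,
   shoelace polygon areas, landmark angles, percent perimeter change.
9. **Simulation** — negative-binomial count generator with planted temporal
   archetypes (including a paired jaw/limb mode over one gene universe) and
   a defect-closure morphometry cohort, so every stage can be validated
   against known ground truth.

## Worked example

```r
library(regenphase)

paired <- simulate_paired_counts(seed = 7)          # jaw + limb, one gene universe
cpm <- compute_cpm(paired$jaw$counts)
tp  <- average_replicates(cpm, paired$jaw$metadata, "jaw")
rep <- apply_filters(cpm, tp)
print(rep)
#> Expression filter report
#>   input genes: 480
#>   after mean     480
#>   after variance 480
#>   after max      480
#>   after ratio    357

zp  <- zscore_profiles(subset_profile(tp, rep$kept_gene_ids))
gap <- select_k_gap(zp, k_range = 1:8, B = 50, seed = 7)
print(gap)
#> Gap statistic over k = 1-8  (B = 50 )
#>   selected k* = 5

cr  <- cluster_kmeans(zp, gap$k_star, seed = 7)
goi <- select_genes_of_interest(cr)                  # Pearson score > 0.75
pa  <- assign_gene_phases(cr, goi, phase_config("jaw"))
print(pa)
#> Phase assignment (jaw): 356 genes of interest
#> # A tibble: 5 x 4
#>   cluster label        peak_time_hours n_genes
#>     <int> <chr>                  <dbl>   <int>
#> 1       1 5 dpi peak               120     101
#> 2       2 general rise             840     100
#> 3       3 14 dpi peak              336     100
#> 4       4 unassigned                 0      52
#> 5       5 35 dpi peak              840       3
```

The filter report shows 357 of 480 simulated genes surviving (the planted
flat genes fail the fold-change stage); the gap statistic picks 5 clusters,
and the phase rule labels them: three peak groups, a steadily rising group,
and one unassigned cluster of down-regulated genes peaking in the intact
sample. The same chain runs end to end, including the limb and the
cross-structure comparison, with one call:

```r
res <- run_pipeline(pipeline_config(jaw = paired$jaw, limb = paired$limb,
                                    k = "auto", k_range = 1:8, seed = 7))
print(res)
#> regenphase pipeline result
#>   jaw: 480 genes in, 357 genes of interest, k = 7
#>   limb: 480 genes in, 380 genes of interest, k = 8
#>   shared genes: 292 (81.79% of jaw)
```

`run_pipeline(..., out_dir = "out/")` additionally writes per-stage TSVs
(`*_clusters.tsv`, `*_gap.tsv`, `*_phases.tsv`, `overlap.tsv`, ...) and a
machine-readable `summary.json` recording every seed and threshold; reruns
with the same config are byte-identical. `tidy()`, `glance()` and
`autoplot()` methods are provided for the gap curve, the clustering, the
phase assignment and the overlap heatmap.

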