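---
title: "Methods: temporal phase analysis of regeneration time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal phase analysis of regeneration time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regenphase)
```

## The problem

Regenerating axolotl structures are profiled by bulk RNA-seq over sparse
time grids with very few biological replicates — here two animals per time
point, jaw samples at intact, 5, 14 and 35 days post injury (dpi), limb
samples from 3 hours to 28 days post amputation (hpa/dpa). The analytical
question is not differential expression at a single contrast but the
*shape* of each gene's trajectory: which genes peak early, which peak
during blastema stages, which rise steadily — and how much of that temporal
programme two different structures share. `regenphase` implements that
analysis as a deterministic, seedable pipeline. All times are internally
hours since injury (intact = 0, 5 dpi = 120 h, 3 hpa = 3 h) so both
structures live on one axis; the original labels are preserved for
reporting.

## Normalisation and replicate handling

Counts are normalised to counts per million by plain library-size scaling —
no between-sample scaling factors — so each sample's CPM column sums to
one million. Whether any additional scaling is appropriate is
study-specific; here it is deliberately the simplest reading of
"counts per million", and it is the only normalisation the pipeline
applies. Replicates are arithmetically averaged per time point *before*
standardisation, because the clustered objects are temporal profiles over
time points, not individual samples.

## Expression filtering

With n = 2 replicates, variance estimates per gene are unreliable, so the
pipeline relies on four conservative screens rather than formal tests.
A gene is kept iff:

1. mean CPM over all samples ≥ `theta_mean` (default 0.8);
2. sample variance over all samples (denominator n−1) ≥ `theta_var`
   (default 0.4);
3. maximum replicate-averaged CPM over time > `theta_max` (default 20,
   strict);
4. max/min CPM ratio over time strictly exceeds a multiplier that depends
   on the gene's minimum: 5 when min < 1 CPM, 3 when 1 ≤ min < 5, 2 when
   min ≥ 5. The denominator is floored at `ratio_floor_epsilon = 0.1` so
   genes that drop to zero do not divide by zero.

Stages 1–2 act on per-sample CPM (replicates included), stages 3–4 on the
replicate-averaged profile; both choices are configurable. Boundary
conventions are exactly as stated: values *below* a threshold are removed
in stages 1–2 (so equality survives), while stages 3–4 require a strict
excess. The abundance-dependent multiplier is this package's own fully
specified step function; it encodes the usual intuition that low-abundance
genes need a larger fold change before their dynamics are trusted, and both
breakpoints and multipliers are exposed in `filter_config()`. Raising any
threshold can only shrink the kept set, and the filter is idempotent —
both properties are exercised in the test suite.

## Standardisation

Surviving profiles are converted to per-gene z-scores over time
(mean 0, sd 1, denominator n−1). This discards absolute expression level
and compares shapes only. Genes with zero variance across time cannot be
standardised and raise an explicit error listing the offenders; in
practice the ratio filter removes them first.

## Choosing the number of clusters

The number of clusters is selected by the gap statistic. For each
candidate k, `W_k` is the total within-cluster sum of squared Euclidean
distances to centroids; B reference data sets (default 50) are drawn
uniformly over the per-dimension range box of the observed z-profiles, and

\[ \mathrm{Gap}(k) = \tfrac1B \sum_b \log W^*_{kb} - \log W_k , \qquad
   s_k = \mathrm{sd}_b(\log W^*_{kb}) \sqrt{1 + 1/B} . \]

The selected `k*` is the smallest k with
`Gap(k) >= Gap(k+1) - s_{k+1}`; if the rule never fires inside the
candidate range the k maximising the gap is used as a fallback. The
uniform range-box reference is the simplest variant of the method; the
reference clusterings use fewer k-means restarts (default 5) than the
final clustering, since they only need a representative dispersion, not an
optimal one. On planted-archetype fixtures (k ∈ {2,…,5}, 300 genes,
centre separation ≥ 5 noise sd) the rule recovers the planted k in at
least 90% of seeded runs — verified in the acceptance tests.

## Clustering and cluster scores

k-means uses Lloyd iterations from k-means++ starts, best of
`n_init = 25` restarts by within-cluster sum of squares, implemented in
C++ against R's RNG so a single `seed` makes runs bit-reproducible. A
cluster that empties during iteration is re-seeded at the point farthest
from its centroid (documented behaviour, not an error). This is a
deliberate, reproducible contract rather than an ecosystem default
(classical R k-means defaults to Hartigan–Wong with random starts); on
well-separated data both reach the same optimum — a cross-check in the
test suite — but on real data the exact cluster count and memberships can
legitimately differ between implementations, so cluster *numbers* from
other analyses of similar data (e.g. 15 jaw and 23 limb clusters) are
reference expectations, not contracts.

Each gene receives a cluster score: the Pearson correlation between its
z-profile and its centroid. Genes with score strictly greater than
`theta_r = 0.75` are the *genes of interest*; everything downstream uses
only these. With only a handful of time points, moderately high
correlations arise by chance, so this screen removes genes the clustering
cannot represent rather than certifying the rest individually.

## Phase groups

The historical practice of assigning clusters to named phase groups by
visual inspection is replaced by an explicit rule applied to each centroid
(z-scores over times `t_1 < … < t_T`):

1. if the peak (argmax) is at the intact time point, the cluster is
   **unassigned** — a down-regulated pattern;
2. else if the peak is at the final time point and the centroid never
   steps down by more than τ = 0.25 z-units, the cluster is
   **general rise**;
3. otherwise the cluster is labelled by the bin containing its peak time —
   jaw: point bins at 120 h (*5 dpi peak*), 336 h (*14 dpi peak*) and
   840 h (*35 dpi peak*); limb: half-open intervals (0, 72] h
   (*early peak*), (72, 336] h (*mid peak*) and (336, 672] h
   (*late rise*). A non-monotone centroid peaking at the final time falls
   into the last bin; a peak in no bin is unassigned.

The rule depends only on orderings and differences, so it is invariant to
adding a constant and (rescaling τ accordingly) to positive rescaling.
τ = 0.25 is small enough that genuine intermediate dips are not smoothed
away but large enough to ignore replicate jitter on a 4–10 point grid; it
is exposed in `phase_config()`. Note an intrinsic ambiguity of sparse
grids: a peak at the *final* sampled time is indistinguishable from a
monotone rise unless the profile dips on the way, which is why rule 2
takes precedence and why the simulator derives its planted truth labels by
applying this same rule to the noiseless archetype shapes. Genes inherit
their cluster's label; genes in unassigned clusters stay in the
genes-of-interest universe but are excluded from phase-restricted
statistics.

## Cross-structure comparison

Shared genes are the exact identifier intersection of the two
genes-of-interest lists (both structures quantified against the same
genome annotation; no ortholog mapping). For jaw group g and limb group h,

\[ \mathrm{pct}(g,h) = 100 \cdot
   \frac{|S \cap G_g \cap H_h|}{|S \cap G_g|} , \]

with S the shared set; shared genes of g sitting in unassigned limb
clusters leave the row summing below 100% (the unaccounted remainder), and
empty denominators are reported as missing, never as zero. The
early-transient fraction is the percentage of a gene set whose limb
z-profile peaks at 3 hpa and has returned to the intact level or lower by
1 dpa: `z(24 h) <= z(0) + tol`, with tolerance 0 by default ("basal or
lower" taken literally on the z scale) and exposed for sensitivity
analysis, since defining basal on the raw CPM scale instead is an equally
defensible reading.

## Morphometry

Inputs are coordinate and length tables — the output of manual tracing —
not images. The module provides the arithmetic: defect length as a
percentage of hemimandible and full-mandible perimeter, shoelace polygon
areas (absolute value; collinear vertices give 0), interior landmark
angles in [0°, 180°] via the dot product, and percent perimeter reduction
relative to intact. Defect areas recorded once tissue continuity is
observed are explicit zeros, not missing values. Group testing
(ANOVA/post-hoc) is left to standard routines; the module emits tidy
per-animal tables ready for them.

## The synthetic generator

`simulate_counts()` draws counts negative-binomially with mean
`mu_g(t) * librarySize / 1e6` and dispersion φ (variance m + φm², φ = 0
giving Poisson), with per-sample library sizes uniform on 8–12 million —
a deliberately desk-scale depth; real studies sequence deeper, which only
tightens the noise. Defaults mirror the study design the package targets:
two replicates per time point, the jaw grid {0, 120, 336, 840} h and the
limb grid {0, 3, 6, 12, 24, 72, 168, 336, 504, 672} h. Archetypes are
Gaussian peaks, a logistic rise, flat genes and an intact-peak
(down-regulated) shape, with baseline 2 CPM and 25-fold amplitude so that
planted signal genes clear the filters by construction.
`simulate_paired_counts()` generates both structures over one gene
universe with a pairing table linking each gene's jaw and limb archetype —
most early jaw genes early in the limb (a majority as 3 h transients), mid
jaw genes split between early and mid limb phases, rising jaw genes mostly
mid — so shared-gene and overlap statistics have ground truth.
`simulate_morphometry()` emulates the macroscopic closure dynamics:
contraction within 1 dpi, a plateau, second closure from 7 dpi reaching
zero by 35 dpi, an angle minimum at 35 dpi, and a resected/intact
perimeter ratio ending at 0.908 at 90 dpi, over a cohort of 12 animals
with a 5 mm defect on an ~11.55 mm hemimandible (~24.15 mm full
perimeter).

What the simulator does *not* emulate: mapping and quantification noise,
batch effects, realistic library-composition drift (strong co-regulated
signal shifts CPM of everything else; the generator shows this effect but
real compositional structure is richer), continuous biology between
archetypes, and correlated genes. Passing recovery tests therefore shows
the pipeline is correct and well-calibrated under its stated model, not
that real data will cluster this cleanly.

## Problem sizes and numerical choices

The test and acceptance runs use 200–480 genes per structure, k ranges up
to 10, B = 50 reference sets and 20-seed recovery experiments — sizes
chosen so the whole suite runs in about a minute on one core while leaving
every statistical property measurable. Seeds: every stochastic stage takes
an explicit seed; the pipeline derives per-structure sub-seeds from one
master seed and records all of them in `summary.json`, and reruns are
byte-identical. Degenerate inputs are handled explicitly: zero library
sizes, zero-variance genes, empty gene sets (missing, not zero), empty
clusters (farthest-point reseed), collinear polygons and coincident
landmarks.

## Known limitations

* Cluster counts and memberships on real data depend on the k-means
  variant and the gap-statistic reference; only the full contract
  (seed, initialisation, restarts, reference, selection rule) makes a run
  reproducible.
* The phase rule can label edge-case centroids differently from a human
  curator, particularly profiles peaking at the final time point (see the
  sparse-grid ambiguity above).
* CPM without between-sample factors is sensitive to composition effects;
  for designs with strong global shifts a different normalisation may be
  preferable upstream.
* The four filter thresholds are screens, not tests; they are tuned for
  n = 2 designs and should be revisited for richer designs.
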