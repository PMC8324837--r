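---
title: "ionvox: models and methods for subnuclear neighborhood analysis of ion-beam imaging volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ionvox methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionvox)
```

## The problem

Secondary-ion mass spectrometry imaging (NanoSIMS) rasterizes a cell with a
cesium primary beam and mass-analyzes the sputtered secondary ions pixel by
pixel, producing one 2D ion-count image per isotope per plane; serial
erosion yields a multichannel 3D count volume at ~30 nm lateral resolution.
With isotope-tagged antibodies against subnuclear markers (nucleolin for
nucleoli, SC35 for nuclear speckles, H3K9me3 for heterochromatin, H3K27Ac
for euchromatin, phosphorus for bulk DNA) plus natively detectable drugs
such as cisplatin (via its Pt atom), such volumes can resolve which
subnuclear microenvironments a drug partitions into. `ionvox` implements
the downstream computational pipeline: denoising, voxel featurization,
neighborhood identification, spatial interaction statistics,
per-neighborhood drug quantification, an RNA splicing score for the
transcriptional consequence of such drugs, and SIMS metrology calculators —
all testable end to end on synthetic phantoms with known ground truth.

## Data model

Arrays are indexed `[z, y, x]` with 0-based pixel coordinates in the
original acquisition frame; TIFF pages are z-ascending. A `multiplex_volume`
holds one integer count stack per isotope channel plus a YAML manifest.
Border trimming and z-restriction update an explicit origin offset, so
voxel centers always remain expressed in original-frame pixels — the
interaction radius below is defined in those units.

## KNN density denoising

Low-current acquisitions are sparse; the informative distinction is signal
*density*, not intensity. Per channel, the planes are summed, and for every
positive pixel the mean Euclidean distance to its k = 25 nearest other
positive pixels is computed (kd-tree search). Pixels above a distance
cutoff are discarded and the resulting mask is applied to every z-plane.
The cutoff is not a published constant; by default the package takes the
Otsu threshold of the mean-distance distribution, which sits in the valley
between the dense-signal and sparse-noise modes. "Positive" means summed
count > 0 exactly: counts are integers, and the filter is defined on
density, not brightness. The filter is invariant to translation and 90°
rotation, and on blob-plus-uniform-noise simulations recovers true-signal
pixels with F1 ≥ 0.9 (see `test-preprocess.R`).

## Voxel features and normalizations

A 3D sliding window (e.g. 10×10×5 px with 5×5×3 step) is applied to every
channel and each fully contained window becomes one "voxel" carrying the
per-channel mean count. Partial edge windows are dropped — a truncated
window would bias the mean. Window counts per axis follow
`floor((L - w)/s) + 1`, verified against exhaustive enumeration.

Three normalization schemes mirror the three analysis presets:

* **nuclear** (3×3×10 window, nucleus-masked, z-score): channel-wise
  `(x - mean)/sd` with the *population* SD — this is normalization, not
  inference, and the choice is stated so tests can be exact.
* **iterative** (KNN denoise, 100 px border, 10×10×5/5×5×3 window):
  `log2(x + 1e-4)`; the pseudocount avoids zeros while leaving counts ≥ 1
  essentially unchanged.
* **multidrug** (12 px border, 3×3×7/2×2×5 window over the middle 40
  planes): per FOV, each non-drug channel is scaled to mean 1 and mapped
  linearly so its 20th percentile → 0 and 95th → 1 (clipped). Percentiles
  use linear interpolation between order statistics (R type 7). The mean
  scaling is affinely absorbed by the percentile map — a test asserts the
  equivalence — but is kept as documented procedure. The drug channel is
  instead clip-normalized *globally* (`(x - 0.01)/0.04`, clamped to [0, 1]):
  untreated cells contain no drug, and a per-FOV rescaling would fabricate
  signal there. Voxels in the bottom 20% of carbon are dropped per FOV
  (stable sort, exactly `floor(0.2 n)` rows) as not associated with
  organic material.

"Middle 40 planes" is implemented as a centered slab with the extra plane,
for odd remainders, on the shallow side. Constant channels normalize to
zeros with a warning rather than an error, so degenerate synthetic inputs
do not kill a pipeline run.

## Neighborhood identification

Voxels are clustered either directly in feature space (Ward linkage,
Euclidean distance — the linkage is not published; Ward is the standard
choice for compact feature clusters and is deterministic) or on a 2D
Barnes-Hut t-SNE embedding (perplexity 30, 1000 iterations, fixed seed)
cut into 40 clusters. The published analyses merged clusters manually by
profile similarity; `ionvox` reifies that as (a) an explicit user-supplied
merge map, or (b) an automatic fallback that Ward-clusters the initial
cluster profiles down to the requested final count. The fallback uses
Euclidean distance on profiles rather than profile correlation:
correlation is undefined, and numerically arbitrary, for the near-constant
profiles that clipping normalizations produce (a uniformly low cytoplasmic
cluster), and correlation-based merging was observed to scatter such
clusters arbitrarily. Channels per preset: the nuclear preset clusters on
the five structural markers (drug held out for quantification); the
iterative preset adds the drug channel; the multidrug preset uses all
channels except carbon and drug.

## Interaction statistics

Two voxels interact when their centers are within 5 px (3D Euclidean).
For K neighborhoods the observed K×K matrix counts unordered interacting
pairs, diagonal included, each pair once — an ordered-pair convention
would rescale observed and permuted counts alike and cancel from the
enrichment, which a test asserts. The null shuffles the neighborhood
annotation over the voxels (within one FOV, never across FOVs), holding
geometry fixed; the neighbor-pair set is therefore built once (kd-tree
radius search + exact distance filter) and only label counting is repeated
over the 1000 permutations. One-sided p-values use strict inequalities
with the add-one correction,

$$p_{>} = \frac{\#\{\text{perm} > \text{obs}\} + 1}{N_{\text{perm}} + 1},$$

so ties count toward neither tail and the smallest attainable p is
`1/(N_perm + 1)`; with sparse counts this is conservative, which is
documented rather than "fixed". Enrichment is
`log2(observed / mean(permuted))`, reported as `NaN` when either side is
zero — the quantity is undefined there and the raw counts are preserved.
On ≤ 300 voxels the implementation is bit-identical to a naive all-pairs
oracle fed the same permutation stream, and under spatially random labels
the fraction of (pair, tail) tests with p < 0.05 sits within three
binomial standard errors of 0.05 over 200 replicates (the pair-level tests
within one replicate share a permutation stream, so the binomial band is
slightly approximate).

## Drug quantification and condition comparison

Per neighborhood the drug channel is summarized as raw count distributions
and, on the multidrug clip scale, as the fraction of positive voxels per
FOV — "positive" defaulting to a clip-normalized value > 0, i.e. a raw
voxel mean above the 0.01 lower clip limit, the only positivity notion the
normalization defines. Conditions are compared per neighborhood with a
two-sided Wilcoxon rank-sum test on per-FOV fractions: exact enumeration
of all rank assignments with midranks for total n ≤ 12 (base R's exact
path refuses ties), normal approximation with tie correction above. The
FOV is the experimental unit, matching the per-FOV normalization.

## Splicing score

Intron coverage tracks unspliced pre-mRNA. Per gene, a binomial GLM of
exon fragments out of (exon + intron) with condition as the sole covariate
gives a Wald p-value; genes are selected at BH-adjusted p < 0.05, and the
effect is visualized with the score

$$IE = \log_2 \frac{\sum_{\text{treatment reps}} \text{exon}/\text{intron}}
                   {\sum_{\text{control reps}} \text{exon}/\text{intron}},$$

summing *per-replicate ratios* as stated (under unequal depths this
differs from summing counts first; the choice is implemented as printed
and noted here). IE is exactly antisymmetric under swapping condition
labels and invariant to rescaling any single replicate. Zero-intron
replicates make IE undefined; such genes are flagged `NA` rather than
silently pseudocounted (a pseudocount option exists, default off). The GLM
is fit per gene with no shared dispersion — the published model is a
per-gene logistic regression, not a count-model framework.

**A calibration caveat.** The binomial GLM assumes exon | total is
binomial, which holds when counts are Poisson. With biologically
overdispersed (negative-binomial) counts the per-gene test is strongly
anti-conservative — in our simulations even dispersion 0.01 drives the
null any-rejection rate to ~1. The package's null-FDR validation therefore
simulates in the Poisson limit (`dispersion = 0`), the regime where the
test's assumptions hold; the synthetic-data generator defaults to
dispersion 0.05 (a typical cell-line value) for effect-recovery tests,
where the bias is immaterial. Users applying the model to real replicates
should treat the per-gene p-values as liberal in the presence of
overdispersion — a limitation of the published model, reproduced
faithfully.

## Metrology

Lateral resolution uses the knife-edge 84–16% criterion: the profile is
normalized to plateaus estimated as medians of the outer 20% of samples on
each side, and the distance between the interpolated 16% and 84% crossings
is reported. For a Gaussian edge of width σ this equals 2σ (Φ(1) ≈ 0.8413);
for a linear ramp of length L it is 0.68 L. The estimator is invariant to
affine intensity transforms and scan reversal; a transition is declared
undetectable when the plateau difference is within three robust SDs of the
plateau noise. Smoothing is available but off by default — the estimator
definition stays pure. Axial calibration divides a known sample thickness
by the number of planes needed to erode it, with a helper that finds the
erosion depth as the first crossing of half the asymptotic
substrate/organic signal ratio. Isotope barcode capacity counts unordered
k-subsets of n channels by exhaustive enumeration cross-checked against
`choose(n, k)` — seven channels with triple labeling give 35
distinguishable identities.

## The synthetic-data generator

Phantoms are label volumes painted from parametric geometries (ellipsoids,
shells, sphere sets) with a fixed precedence order — speckle > nucleolus >
perinucleolar rim > heterochromatin > envelope/lamina > euchromatin >
cytoplasm > background — mirroring the visual nesting of subnuclear
domains and making labels unambiguous. Channels are independent Poisson
draws with per-pixel mean `intensity_matrix[structure, channel]`; counts-
based SIMS detection is well approximated by Poisson and no dead-time or
background term is added. Drug partitioning is a per-structure multiplier
on a base intensity (speckle-enriched 3×, heterochromatin-depleted 0.3×, a
nuclear-excluded variant for untreated-like cells); no quantitative
per-structure enrichment ratios are published, so these multipliers are
free parameters of the phantom, not calibrated values. Everything is
bit-reproducible given the seed.

Two canonical configurations ship with the package. `default_phantom_config()`
is a whole cell (cytoplasm, nucleus with lamina, nucleolus with rim,
speckle and heterochromatin blobs). `five_structure_phantom_config()` is an
intranuclear region of interest for recovery benchmarks: euchromatin base
plus nucleolus, speckles, heterochromatin foci and lamina-associated
domains as z-spanning columns, each with one dominant marker and sizes
large relative to a 10 px window. The column geometry and blob sizes were
chosen so that boundary-mixture windows — which have no single true label
and bound any achievable agreement — stay a small minority; with them the
full denoise→feature→log2→Ward pipeline recovers ground truth at ARI
≈ 0.9. For the multidrug scenario the drug base intensity is 0.03
counts/pixel so that voxel means fall in the 0.01–0.05 range the global
clip normalization presumes — the clip limits themselves pin down the
count scale of the real acquisitions.

What the phantoms do *not* emulate: sputtering physics, topography and
matrix effects, charge drift, detector dead time, anisotropic PSFs, and
the irregular morphology of real nuclei. Passing recovery tests therefore
demonstrates correctness of the computation under the stated statistical
model, not robustness to instrument artifacts.

## Problem sizes and numerical choices

Benchmarks run at desk scale by design: the recovery phantom is
20×500×500 px with 8000 voxels sampled before Ward clustering (the
published analyses likewise sample 5000–20 000 voxels per FOV before
clustering); the two-condition comparison uses ten 50×120×120 px FOVs
with 300 voxels sampled per FOV; calibration uses 200 replicates of 150
voxels at 200 permutations; the null-FDR study uses 100 simulations of
150 genes. Ties in the carbon filter break by stable row order; tied
Wilcoxon statistics use midranks; hierarchical clustering is deterministic
for a fixed input order; every stochastic step takes an explicit seed and
restores the caller's RNG state.

## Known limitations

* The KNN cutoff default (Otsu) assumes a bimodal distance distribution;
  on uniformly dense channels it degrades to trimming the sparse tail.
* Automatic profile-based merging is a reproducible surrogate for expert
  annotation, not a replacement; an explicit merge map always takes
  precedence.
* Permutation p-values are conservative under heavy ties (strict
  inequalities, as published).
* The splicing GLM is anti-conservative under overdispersion (above).
* `NaN` enrichments for zero counts are propagated, never imputed.
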