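# ionvox

Subcellular neighborhood analysis for multiplexed secondary-ion mass
spectrometry (SIMS/NanoSIMS) imaging volumes.

High-resolution ion-beam imaging rasterizes a cell with a cesium primary
beam and records one ion-count image per isotope channel per depth plane,
yielding a multichannel 3D count volume at ~30 nm lateral resolution.
With isotope-tagged antibodies against subnuclear markers (nucleolin,
SC35, H3K9me3, H3K27Ac, phosphorus/DNA) and natively detectable drugs
(cisplatin via its Pt atom), such volumes can resolve which subnuclear
microenvironments — nucleoli, nuclear speckles, heterochromatin,
euchromatin, lamina — a drug partitions into. `ionvox` is the analysis
side of that experiment, for imaging scientists and computational
biologists working with NanoSIMS (or similarly structured multichannel
volumetric count) data.

## What it computes

* **Denoising** — k-nearest-neighbor density filtering of sparse channels:
  a positive pixel is kept when the mean Euclidean distance to its k = 25
  nearest positive neighbors on the plane-summed image is below a cutoff.
* **Voxel features** — 3D sliding-window mean ion counts per channel, with
  the published normalization schemes (z-score; log2(x + 1e-4); per-FOV
  20–95 percentile map; global 0.01–0.05 clip for the drug channel).
* **Neighborhoods** — Ward hierarchical clustering of voxel features, or
  clustering of a Barnes-Hut t-SNE embedding, with reproducible profile
  based merging of clusters.
* **Interaction maps** — voxels interact when their centers are within
  r = 5 px:

  $$p_{>} = \frac{\#\{\mathrm{perm} > \mathrm{obs}\} + 1}{N_{\mathrm{perm}} + 1},
    \qquad
    \mathrm{log_2FE} = \log_2 \frac{\mathrm{obs}}{\mathrm{mean(perm)}}$$

  over label-shuffle permutations holding geometry fixed (one-sided
  p-values on either tail).
* **Drug quantification** — per-neighborhood count distributions,
  positive-voxel fractions per FOV, exact-midrank two-sided Wilcoxon
  comparison between conditions.
* **Splicing score** — per-gene binomial GLM of exon vs intron fragment
  counts with BH correction, and
  $IE = \log_2 \left[ \sum_{\mathrm{treat}} \mathrm{exon}/\mathrm{intron}
  \,/\, \sum_{\mathrm{ctrl}} \mathrm{exon}/\mathrm{intron} \right]$,
  where IE < 0 means reduced splicing under treatment.
* **Metrology** — knife-edge 84–16% lateral resolution (= 2σ for a
  Gaussian edge), ion-yield/resolution tradeoff regression, axial sputter
  rate, isotope barcode capacity.
* **Synthetic phantoms** — Poisson count volumes over parametric
  subnuclear geometries with exact ground-truth labels, plus
  negative-binomial exon/intron count tables, so the whole pipeline is
  testable without instrument data.

## Worked example

Simulate a 20×500×500 px intranuclear region with five structure classes,
run the iterative pipeline (denoise → 10×10×5 window → log2 → Ward k = 5),
and test neighborhood interactions:

```r
library(ionvox)

cfg     <- five_structure_phantom_config(dims = c(20, 500, 500), seed = 101)
phantom <- generate_nuclear_phantom(cfg)
phantom$volume
#> multiplex_volume 'fov1': 7 channel(s), dims (z,y,x) = 20 x 500 x 500
#>   12C    carbon         total counts 1.51e+08
#>   19F    nucleolin      total counts 1.305e+07
#>   31P    DNA            total counts 1.147e+08
#>   81Br   H3K9me3        total counts 1.957e+07
#>   127I   H3K27Ac        total counts 8.942e+07
#>   194Pt  cisplatin      total counts 7.32e+07
#>   197Au  SC35           total counts 2.947e+07

conf   <- utils::modifyList(preset_config("iterative"),
                            list(n_sample = 8000, k_initial = 5, k_final = 5))
voxels <- extract_voxels(phantom$volume, conf, seed = 1)
model  <- identify_neighborhoods(voxels, conf, seed = 1)
model
#> neighborhood_model: 8000 voxels, 5 -> 5 clusters, channels: 197Au, 81Br, 31P, 19F, 127I, 194Pt
#>   197Au  81Br   31P   19F  127I 194Pt
#> 1 2.372 1.576 4.460 1.035 4.293 3.910
#> 2 0.661 2.432 5.274 0.227 1.953 2.640
#> 3 0.007 4.906 5.321 0.002 0.013 1.591
#> 4 5.222 0.151 3.958 0.990 3.391 4.852
#> 5 0.127 0.141 3.696 4.789 1.241 3.320
```

The profiles (log2 mean counts) identify the clusters: 1 = euchromatin
(high H3K27Ac), 2 = lamina-associated domains (high P), 3 =
heterochromatin (high H3K9me3), 4 = speckles (high SC35, and the highest
cisplatin — the drug partitions into speckles), 5 = nucleolus (high
nucleolin). Against the phantom's ground-truth labels the clustering
reaches an adjusted Rand index of **0.90**:

```r
truth <- voxel_majority_labels(voxels, phantom$truth$label_volume)
mclust::adjustedRandIndex(model$labels, truth)
#> [1] 0.9040436

res <- permutation_test(as.matrix(voxels[, c("x", "y", "z")]),
                        model$labels, radius = 5, n_perm = 1000, seed = 1)
head(significant_edges(res, alpha = 0.05))
#>   a b sign     weight           p
#> 1 1 1    1  0.6475097 0.000999001
#> 2 2 2    1  2.7800726 0.000999001
#> 3 3 3    1  3.5870084 0.000999001
#> 4 4 4    1  3.1687475 0.000999001
#> 5 5 5    1  3.7309627 0.000999001
#> 6 1 2   -1 -2.8533304 0.000999001
```

Every structure self-associates (enriched diagonals, p at the attainable
floor 1/1001) and distinct structures avoid each other (depleted
off-diagonals) — the spatial organization the phantom was built with.

The splicing analysis on a simulated count table (20% of genes with their
exon/intron ratio halved under treatment):

```r
counts <- generate_splicing_counts(300, n_replicates = 3, frac_affected = 0.2,
                                   effect_fold = 0.5, mean_depth = 500,
                                   dispersion = 0.05, seed = 42)
splice <- analyze_splicing(counts)
splicing_summary(splice)[c("n_significant", "median_IE")]
#> $n_significant
#> [1] 165
#>
#> $median_IE
#> [1] -0.4334685
```

The truly affected significant genes recover a median IE near
log2(0.5) = −1; the overall significant-gene median sits nearer zero
because the per-gene binomial test is anti-conservative under
negative-binomial dispersion and also flags null genes (see the methods
vignette, `vignettes/ionvox-methods.Rmd`, for this caveat).

A thin command-line wrapper for the preset pipelines lives at
`inst/cli/ionvox.R` (`simulate` and `run` subcommands over a YAML config).

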