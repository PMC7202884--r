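# evoregions

Evolutionary regionalization of tree assemblages: given a temporally
calibrated genus-level phylogeny and site-by-genus presence/absence data,
`evoregions` delimits the major evolutionary groups of assemblages,
identifies the lineages that define them, quantifies how much phylogenetic
diversity is restricted to each group, and asks whether climate or
geography better explains group membership. It is aimed at plant
biogeographers and community phylogeneticists studying questions like the
tropics–extratropics divide in tree lineage composition, where the central
issue is whether phylogenetic niche conservatism or dispersal limitation
structures diversity.

## The method

The pipeline's core quantity is the one-complement of the PhyloSor index
between two assemblages *i* and *j*:

```
d_ij = 1 − BL_ij / (0.5 · (BL_i + BL_j))
```

where `BL_ij` is the summed length of phylogeny branches with descendant
tips in **both** assemblages, and `BL_i`, `BL_j` are the rooted
phylogenetic diversities (PD, in millions of years) of each assemblage.
`d_ij` is 0 when the two assemblages contain identical tip sets and exactly
1 when they form two reciprocally monophyletic clades sharing no branches.
Around this dissimilarity the package provides:

* **Regionalization** — k-means (Lloyd's algorithm, best of `n_init`
  restarts) on the dissimilarity matrix, with Elbow (TSS second-difference)
  and average-silhouette-width selection of the number of groups.
* **Ordination** — an evolutionary PCA: SVD of the column-centred,
  row-Hellinger-transformed site × branch matrix (each branch weighted by
  its length), giving site scores and clade loadings.
* **Indicator analysis** — specificity `A = P(site ∈ group | genus
  present)`, fidelity `B = P(genus present | site ∈ group)` and the
  statistic `sqrt(A·B)`, over single groups and group combinations, for
  genera and for phylogeny nodes (with non-nested indicator-clade
  selection).
* **PD partition** — pruning genera with specificity > 0.6 for a group (or
  combination) and subtracting, yielding the PD restricted to each group
  and the PD shared across all, an exact decomposition of the total.
* **Classifiability** — random-forest comparison of a climatic model (MAT,
  MAP, TS, CWD) versus a geographic model (continent, latitude, longitude);
  binomial grid-cell mixed models ranked by AIC; correspondence of the K=2
  split with binary tropics delimitations (latitude band, freezing line).
* **Synthetic data** — a generator that plants either niche-conserved
  (frost-filtered) or dispersal-limited community assembly on a simulated
  Yule phylogeny with Brownian niche traits, so every stage is testable
  end to end with known truth.

## Worked example

```r
library(evoregions)

sim <- simulate_dataset(n_genera = 150, n_sites = 400, seed = 2024)
sim
#> <evo_sim> 150 genera, 400 sites, seed 2024
#>   planted cold-restricted PD fraction: 0.097

d  <- phylosor_complement(sim$assemblages, sim$tree)
cl <- cluster_assemblages(d, k = 2, seed = 1)
cl
#> <evo_clusters> k = 2, 400 sites, TSS = 1567, mean silhouette = 0.347
#> group
#>   1   2
#> 122 278

delimitation_correspondence(sim$covariates, cl$labels)
#> # A tibble: 2 × 3
#>   delimitation match_fraction tropical_cluster
#> 1 C1_latitude           0.652 2
#> 2 freezing              0.995 1

partition_pd(sim$assemblages, sim$tree,
             indicators = indval_genera(sim$assemblages, cl$labels))
#> <pd_partition> total PD = 3165, shared across all groups = 238.5 (7.5%)
#>   combo n_pruned restricted_pd
#> 1 1           18          307.
#> 2 2          132         2619.

compare_classifiers(sim$covariates, cl$labels, seed = 2)
#> <classifier_comparison> 400 sites, 500 trees
#>   climate OOB accuracy:   97.2%
#>   geography OOB accuracy: 68.0%
```

Reading these numbers: the two evolutionary groups recovered from the
dissimilarities alone coincide with the freezing/non-freezing divide at
99.5% of sites (the latitude band does much worse, 65% — the cold group
includes high-elevation low-latitude sites). The smaller, extratropical
group (122 sites) holds 307/3165 ≈ 9.7% of the total PD as restricted
diversity, recovering the planted 0.097. Climate classifies sites into
their group far better than geography (97.2% vs 68.0% out-of-bag),
the signature of niche conservatism rather than dispersal limitation.

`run_pipeline()` chains all stages behind one config list and writes
per-stage CSV/JSON outputs with checksummed caching; see
`?run_pipeline` and the vignette in `vignettes/` for the modelling
details and parameter guidance.

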