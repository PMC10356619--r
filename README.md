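# tissuearch

Multiscale spatial architecture analysis for cell-typed multiplexed-imaging
data.

After segmentation and cell typing, a multiplexed imaging experiment (CODEX
and similar) reduces each tissue section to a table of cells with
coordinates and type labels. For layered tissues such as the human
intestine, `tissuearch` asks how those cells are *organized*, and whether
that organization differs between anatomical groups (small bowel, SB,
versus colon, CL):

- **Same-cell density** — per type, the mean distance to the 5 nearest
  same-type cells divided by the maximal-dispersion spacing
  `sqrt(area / N_t)`; 0 = tightly aggregated, ~1 = maximally dispersed.
- **Multiscale structures** — k-nearest-neighbour composition windows
  clustered with k-means into multicellular neighbourhoods (k = 10, 30
  clusters), then re-windowed into communities (k = 100) and tissue units
  (k = 300), with fold-enrichment matrices, SB-vs-CL conservation
  differences, and concentric enrichment profiles around anchor cells.
- **Hierarchy and spatial context** — a directed graph linking each level
  to the next (largest-share and ≥15%-of-upper edges), and per-cell
  minimal label combinations covering ≥85% of a window, linked into a
  containment graph.
- **Tissue motifs** — adjacency of contiguous same-label patches
  (Delaunay-based cell adjacency, pruned), tested against a
  maximum-entropy label-permutation null with Bonferroni (×2×tests)
  correction.
- **Colocalization** — the colocalization quotient
  `CLQ_{A→B} = (C_{A→B}/N_A) / (N_B/(N−1))`, per-sample matrices, Welch
  tests between groups with BH adjustment.
- **Ligand–receptor nomination** — for colocalized type pairs, Wilcoxon
  rank-sum tests of ligand/receptor expression between groups on a
  cell × gene count matrix, BH per (type, role) family, both-significant
  both-up nomination, and a gene-label permutation test of the validation
  success rate on an independent panel.

A seeded synthetic generator produces layered-intestine cell maps (zonation
bands, crypts with Paneth-like anchors, follicles, plasma bands, planted
group shifts and a group-restricted Plasma→TA attraction) and
negative-binomial expression matrices with planted fold-changes, so every
stage is exercised against known ground truth.

## Worked example

```r
library(tissuearch)

tpl <- intestine_template()
m <- generate_tissue(tpl$zones, tpl$structures, noise = 0.05, seed = 3)
m
#> cell_map: 9704 cells, 12 types, sample 'S1', area 1e+06

head(same_cell_density(m, k = 5), 4)
#>   sample_id   cell_type n_cells mean_score tested
#> 1        S1       Bcell     289  0.7599561   TRUE
#> 2        S1        CD8T     622  0.8879123   TRUE
#> 3        S1 Endothelial     748  0.8751569   TRUE
#> 4        S1  Enterocyte    1412  0.7572357   TRUE

clq(m, k = 10)["Plasma", "TA"]
#> [1] 1.645543
```

B cells are the most aggregated type here (score 0.76 — they sit in the
follicle), and the Plasma→TA colocalization quotient is well above 1
because this section carries both the plasma band and the planted
attraction. Clustering the k = 10 windows and asking for each cell's
85% spatial context then summarizes the section's interfaces:

```r
w  <- composition_windows(m, k = 10)
nb <- cluster_windows(w, n_clusters = 10, seed = 1)
head(context_combinations(m, nb, k = 100), 3)[, c("combination", "count")]
#>                                                           combination count
#> 1                                   neighbourhood_08+neighbourhood_10  1371
#> 2 neighbourhood_01+neighbourhood_02+neighbourhood_03+neighbourhood_09  1201
#> 3 neighbourhood_02+neighbourhood_03+neighbourhood_05+neighbourhood_09  1101
```

## The analysis workflow

The numbered drivers under `analysis/` run the full study on a simulated
cohort (4 donors × jejunum/sigmoid, ~78,000 cells) and write tables
(TSV) and graphs (GraphML) under `results/`:

```sh
Rscript analysis/01_simulate.R 1            # cohort + expression matrices
Rscript analysis/02_composition_density.R 1 # composition, density, covariate
Rscript analysis/03_architecture.R 1        # neighbourhoods..tissue units
Rscript analysis/04_context_motifs.R 1      # spatial context + motifs
Rscript analysis/05_colocalization_lr.R 1   # CLQ + ligand-receptor
```

Last driver's narrative on seed 1:

```
28 ordered type pairs more colocalized in CL (BH p < 0.05)
6 ligand-receptor nominations across 1 cell-type pair(s)
validation: 6/6 predictions confirmed (100.0%), permutation p = 0.0001
CLQ Plasma->TA: CL 1.64 vs SB 1.19
```

i.e. the pipeline recovers the six planted Plasma-ligand / TA-receptor
effects and the CL-restricted colocalization they were paired with.

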