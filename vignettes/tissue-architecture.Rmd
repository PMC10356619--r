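---
title: "Multiscale tissue architecture from cell-typed spatial maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale tissue architecture from cell-typed spatial maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuearch)
```

# The problem

Multiplexed antibody imaging (CODEX and relatives) yields, after
segmentation and cell typing, a table of cells with coordinates and type
labels for each tissue section. tissuearch analyses the *organization* of
such maps for layered tissues like the human intestine: how tightly each
cell type aggregates, which conserved multicellular structures the types
form at successive scales, how those structures nest into one another and
interface spatially, which structure pairs are adjacent more often than
chance, which cell-type pairs colocalize differently between anatomical
groups (small bowel, SB, versus colon, CL), and which ligand--receptor
gene pairs could sustain a group-specific colocalization.

Because each stage makes distributional assumptions about its input, the
package ships a synthetic generator that produces cell maps carrying
exactly those assumptions, with known ground truth. Every test and the
acceptance script run against it.

# The statistics

## Same-cell density

For a cell of type $t$, let $d_i$ be the mean Euclidean distance to its
$k$ nearest neighbours of the same type (self excluded; $k = 5$ by
default). The score is
$$ s_i = \frac{d_i}{\sqrt{A / N_t}}, $$
where $A$ is the section area and $N_t$ the type count. The denominator is
the characteristic spacing of a maximally dispersed arrangement of $N_t$
points over $A$, so scores near 0 mean tight aggregation and scores near 1
mean the type is as spread out as the section allows. Scores are not
clipped at 1: slightly larger values occur for types pushed to the section
margin. The ratio makes the score invariant under translation, rotation,
and joint rescaling of coordinates and area. Types with $N_t \le k$ are
flagged missing rather than scored. Area defaults to the convex-hull area
of the section's cells and can be overridden per sample when the true
imaged area is known.

## Windows, neighbourhoods, communities, tissue units

The window of cell $i$ is $i$ plus its $k - 1$ nearest cells (total $k$;
whether the index cell counts itself is configurable since either
convention appears in the literature). The window's label-composition
vector (fractions summing to 1, no z-scoring) feeds k-means with 10
restarts and a fixed seed. Defaults follow the multiscale recipe:
cell-type windows of $k = 10$ overclustered to 30 *multicellular
neighbourhoods*; neighbourhood-label windows of $k = 100$ clustered to 20
*communities*; community-label windows of $k = 300$ clustered to 20
*tissue units*. Overclustering is deliberate — merging clusters into named
structures is an interpretive step, so `merge_clusters()` applies only an
explicit user mapping. `suggest_merges()` can propose one (complete-linkage
correlation clustering of enrichment profiles at a cut of $1 - 0.9$, or
Ward clustering of centroid distances when a target count is given) but
never applies it silently. Windows never cross section boundaries; ties in
distance are broken by cell id so runs are reproducible regardless of
input order.

## Enrichment and conservation

`enrichment_matrix()` reports fold-enrichment: the fraction of a
constituent label inside a structure divided by its overall fraction. The
cell-weighted column sums equal 1 exactly (mass conservation), which the
tests verify on random maps. Group conservation is the difference of the
SB and CL enrichment matrices over shared labels, with rows and columns
ranked by total absolute difference — the top row is the least conserved
structure.

## Hierarchy graph

Consecutive levels are joined by directed edges lower → upper. A lower
label connects to the upper label receiving the largest share of its cells
(`argmax`), and to every upper label of which it makes up at least 15%
(`threshold`). The edge weight is the share of the *upper* structure
contributed by the lower label; the share-of-lower reading of the rule is
the `argmax` criterion itself, and both reasons are recorded per edge so a
reader can separate them. Edge weights into any upper node therefore sum
to at most 1, with equality when every contributor is drawn.

## Spatial context

For each cell, the labels of its $k$-nearest window are sorted by
descending count (ties lexicographically) and the minimal prefix whose
cumulative fraction reaches 85% is the cell's spatial context — one label
deep inside a structure, a set at an interface. The threshold comparison
is `>=` by default with a strict variant, since "more than" and "at least"
both appear in common usage of the rule. Combinations are unordered;
counts are pooled over cells, combinations above a 0.1% frequency floor
are linked into a containment graph (edges between combinations one label
apart).

## Tissue motifs

Motifs are tested on patches, not cells. Cell adjacency is the Delaunay
triangulation pruned at a maximum edge length (default 3 x the median
Delaunay edge — parameter-light and robust to lumens and tears; degenerate
point sets fall back to a symmetrized 6-NN adjacency with a warning).
Instances are connected same-label components of at least 3 cells;
instance graphs from a group's sections are unioned. The observed
statistic for an unordered label pair is the number of instance edges
joining them; the null permutes instance labels uniformly over the fixed
graph — the maximum-entropy null given the label multiset — and the
one-sided enrichment p-value uses the add-one correction, so its floor is
$1/(n_{\mathrm{perm}} + 1)$. Only pairs observed at least 5 times are
tested; the correction multiplies p by twice the number of tested pairs,
capped at 1. Note the interaction between this Bonferroni factor and the
permutation floor: with $m$ tested pairs, significance at 0.05 requires
$n_{\mathrm{perm}} > 40m$, which is why the cohort-scale analysis driver
raises the permutation count to 5,000.

## Colocalization quotient

$$ \mathrm{CLQ}_{A \to B} =
   \frac{C_{A \to B} / N_A}{N_B / (N - 1)}, $$
with $C_{A \to B}$ the average fraction of type-B cells among the $k = 10$
nearest neighbours of each type-A cell, and $(N_A - 1)$ replacing $N_B$
for the self-pair. The direction is "B among the neighbours of A"
(the original Leslie--Kronenfeld convention). Under random labelling the
expectation is 1; the package also provides label-permutation z-scores as
a calibration diagnostic. Cross-group comparison is a Welch two-sided
t-test per ordered pair over per-sample CLQs, BH-adjusted across pairs.

## Ligand--receptor nomination and validation

For each colocalized type pair (ligand type, receptor type; typically the
BH-significant CL > SB rows of the CLQ test) and each ligand--receptor
gene pair, discovery uses two-sided Wilcoxon rank-sum tests of CL versus
SB expression (normal approximation with tie correction), BH-adjusted
within each (cell type, gene role) family, and nominates pairs with both
adjusted p below 0.05 and both means higher in CL. Validation on an
independent matrix uses one-sided (CL > SB) Wilcoxon tests; a prediction
succeeds when both genes are BH-significant. The null permutes the
validation matrix's *gene labels* uniformly — preserving every count and
annotation — and recounts successes; p carries the add-one correction.

# The synthetic generator

`generate_tissue()` draws cell positions from a homogeneous Poisson
process per horizontal zone (so nearest-neighbour distances have realistic
variance), assigns types from zone compositions, then applies structures
in order: *bands* override composition in a y-interval; *crypts* blend the
crypt composition with the zone's, with a weight decaying linearly to zero
at the crypt rim (graded enrichment toward the base; the linear form is
the simplest such decay), and place anchor cells (Paneth-like) exactly
within a quarter-radius of the centre; *follicles* override two concentric
discs with inner and outer compositions; *attraction* relocates a
Bernoulli(strength) subset of a source type to uniform points within a
radius of random target cells, giving direct control over the planted CLQ.
A final noise step resamples a fraction of types uniformly over the type
universe — deliberately not from the local composition, so noise strictly
degrades spatial signal. All generators are pure functions of (config,
seed).

The default template (`intestine_template()`) is a 1000 x 1000 tissue of
about 10,000 cells in three bands — mucosa (55% of height), submucosa
(25%), muscularis (20%) — over 12 types, with six crypts (restricted to
the SB group, as are their Paneth anchors), one follicle, a plasma-dense
band under the crypts, and a Plasma → TA attraction restricted to CL. The
default cohort is 4 donors x 2 regions (one SB, one CL; about 80,000 cells
total), with small group composition shifts (CD8T +0.05 in SB;
SmoothMuscle +0.05, Endothelial −0.02 in CL) and 5% type noise. These
sizes keep a full pipeline run around a minute while leaving every
per-type count large enough for the statistics to be in their asymptotic
regime.

`generate_expression()` draws negative-binomial counts with mean
$\mu_0 \cdot 2^{\sum \mathrm{lfc}}$ (baseline mean 5, dispersion 2) per
(cell type, group) arm, with planted log2 fold-changes on chosen
(gene, type, group) triples.

What the generator does *not* emulate: cell morphology and segmentation
error, marker spillover, spatially varying density gradients within a
zone, donor-level batch effects, and dropout structure of real
transcript counts. Passing tests therefore demonstrate correctness of the
statistics and recoverability of planted structure under the stated
model, not robustness to those real-data artifacts.

# Numerical and design choices

- **Tie-breaking.** All nearest-neighbour ties are broken by cell id;
  label-count ties in spatial contexts are broken lexicographically. This
  makes every output byte-reproducible for a given seed.
- **k-means.** Hartigan--Wong with 10 restarts; if its quick-transfer
  stage stalls (which happens on the heavily duplicated rows that
  k-discretized window fractions produce), the clustering retries with
  MacQueen's algorithm under the same seed.
- **Degenerate inputs.** Types with too few cells are flagged missing,
  never zero; a category with no cells produces no rows rather than 0/0;
  zero-variance vectors make correlations `NA` with a flag; collinear or
  duplicated point sets switch the triangulation to a kNN adjacency with
  a warning.
- **Output formatting.** Analysis tables print numerics at 6 significant
  digits; cell tables round-trip coordinates at 17 significant digits so
  a write/read cycle reproduces doubles exactly.
- **Permutation p-values.** Always add-one corrected. They are valid but
  discrete; in particular the validation success count is an integer that
  under a complete null is almost surely zero both observed and permuted,
  so its permutation p collapses to 1 rather than being uniform — a
  property of any such conjunction statistic, worth remembering when
  interpreting "calibration" for it.
- **Problem sizes.** The test suite and acceptance script use 150--10,000
  cells per map, cohorts of 8 sections (~78,000 cells), 100
  ligand--receptor pairs at 2,000 cells per arm, and 199--5,000
  permutations, chosen so planted effects sit well inside the power of
  each test at those sizes.

# Known limitations

- Cluster merging quality depends on the overclustering level; the Ward
  suggestion recovers three planted bands at ARI 0.82--0.93 over seeds,
  so a fifth of runs sit near the 0.8 mark rather than far above it.
- The motif null fixes the instance graph and permutes labels; it does not
  model uncertainty in the patch segmentation itself.
- CLQ group tests treat sections as exchangeable replicates; donors
  contributing several sections are not modelled hierarchically.
- The Wilcoxon normal approximation is used throughout; exact p-values
  for tiny validation panels (< ~10 cells per arm) would differ.

# A worked run

```{r, eval = FALSE}
tpl <- intestine_template()
m <- generate_tissue(tpl$zones, tpl$structures, noise = 0.05, seed = 3)
d <- same_cell_density(m, k = 5)
q <- clq(m, k = 10)
w <- composition_windows(m, k = 10)
nb <- cluster_windows(w, n_clusters = 10, seed = 1)
ctx <- context_combinations(m, nb, k = 100)
head(ctx)
```

The numbered scripts under `analysis/` run the same stages over a full
simulated cohort and write their tables and graphs under `results/`.
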