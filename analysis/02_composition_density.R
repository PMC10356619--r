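#!/usr/bin/env Rscript
# Composition and aggregation: compartment-normalized cell-type percentages,
# SB-vs-CL group tests, the same-cell density score per type, the BMI-like
# covariate correlation, and the concentric profile around Paneth cells.
suppressMessages(library(tissuearch))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
dir.create("results", showWarnings = FALSE)
maps <- read_cell_table("results/data/cells.csv")
donors <- read.delim("results/data/donors.tsv")

category_map <- c(
  Enterocyte = "epithelial", Goblet = "epithelial", Paneth = "epithelial",
  Stem = "epithelial", TA = "epithelial",
  Plasma = "immune", CD8T = "immune", Bcell = "immune",
  Macrophage = "immune",
  Fibroblast = "stromal", Endothelial = "stromal",
  SmoothMuscle = "stromal")
comp <- compartment_percentages(maps, category_map)
allr <- comp[comp$category == "all", ]
tests <- compare_groups(data.frame(unit = allr$donor_id, group = allr$group,
                                   feature = allr$cell_type,
                                   value = allr$percentage))
dens <- do.call(rbind, c(lapply(maps, same_cell_density, k = 5),
                         list(make.row.names = FALSE)))

cells <- do.call(rbind, lapply(maps, function(m) m$cells))
mac <- vapply(split(cells, cells$donor_id),
              function(cc) mean(cc$cell_type == "Macrophage"), 0)
corr <- correlate_with_covariate(
  data.frame(donor_id = names(mac), value = mac), donors)

sb <- maps[vapply(maps, function(m) m$cells$group[1], "") == "SB"]
paneth <- do.call(rbind, lapply(sb, concentric_enrichment,
                                anchor_type = "Paneth",
                                radii = seq(10, 60, by = 10)))

write_results(list(composition = comp, composition_tests = tests,
                   density = dens, paneth_concentric = paneth),
              list(), "results/composition_density", force = TRUE)

sig <- tests$feature[tests$tested & tests$p < 0.05]
message(sprintf("group-different types (raw p<0.05): %s",
                paste(sig, collapse = ", ")))
bytype <- tapply(dens$mean_score, dens$cell_type, mean, na.rm = TRUE)
message(sprintf("most aggregated type: %s (density score %.2f); most dispersed: %s (%.2f)",
                names(which.min(bytype)), min(bytype, na.rm = TRUE),
                names(which.max(bytype)), max(bytype, na.rm = TRUE)))
message(sprintf("macrophage fraction vs covariate: r = %.2f (p = %.3g, n = %d)",
                corr$r, corr$p, corr$n))
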