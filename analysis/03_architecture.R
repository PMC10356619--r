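#!/usr/bin/env Rscript
# Multiscale architecture: kNN composition windows clustered into
# multicellular neighbourhoods (k = 10, overclustered to 30), communities
# (windows of 100 neighbourhood labels, 20 clusters) and tissue units
# (windows of 300 community labels), the cell-type enrichment of each
# neighbourhood, the SB-vs-CL conservation delta, and the multilevel
# hierarchy graph.
suppressMessages(library(tissuearch))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
cfg <- analysis_config(seed = seed)
maps <- read_cell_table("results/data/cells.csv")
groups <- vapply(maps, function(m) m$cells$group[1], "")

universe <- sort(unique(unlist(lapply(maps, function(m) m$cells$cell_type))))
wins <- do.call(rbind, lapply(maps, composition_windows,
                              k = cfg$k_window_nbhd,
                              label_universe = universe))
nbhd <- cluster_windows(wins, cfg$n_clusters_nbhd, seed = cfg$seed,
                        level = "neighbourhood")
comm <- derive_level(maps, nbhd, k = cfg$k_window_comm,
                     n_clusters = cfg$n_clusters_comm, seed = cfg$seed,
                     level = "community")
tisu <- derive_level(maps, comm, k = cfg$k_window_tissue,
                     n_clusters = cfg$n_clusters_comm, seed = cfg$seed,
                     level = "tissue_unit")

ids <- unlist(lapply(maps, function(m) m$cells$cell_id))
ctype <- label_assignment(ids, unlist(lapply(maps, function(m)
  m$cells$cell_type)), "cell_type")
hier <- build_hierarchy_graph(list(ctype, nbhd, comm, tisu),
                              threshold = cfg$hierarchy_threshold)

enr <- enrichment_matrix(nbhd, ctype)
group_enrichment <- function(g) {
  gids <- unlist(lapply(maps[groups == g], function(m) m$cells$cell_id))
  enrichment_matrix(
    label_assignment(gids, nbhd$label[match(gids, nbhd$cell_id)], "nbhd"),
    label_assignment(gids, ctype$label[match(gids, ctype$cell_id)],
                     "cell_type"))
}
cd <- conservation_delta(group_enrichment("SB"), group_enrichment("CL"))

enr_df <- data.frame(label = rownames(enr), as.data.frame(unclass(enr)),
                     check.names = FALSE)
delta_df <- data.frame(label = rownames(cd$delta),
                       as.data.frame(unclass(cd$delta)), check.names = FALSE)
write_results(list(neighbourhoods = as.data.frame(nbhd),
                   communities = as.data.frame(comm),
                   tissue_units = as.data.frame(tisu),
                   neighbourhood_enrichment = enr_df,
                   conservation_delta = delta_df),
              list(hierarchy = hier), "results/architecture", force = TRUE)

message(sprintf("%d neighbourhoods, %d communities, %d tissue units; hierarchy: %d nodes, %d edges",
                length(unique(nbhd$label)), length(unique(comm$label)),
                length(unique(tisu$label)), igraph::vcount(hier),
                igraph::ecount(hier)))
message(sprintf("least conserved neighbourhood between SB and CL: %s (sum|delta| = %.2f; top cell type: %s)",
                cd$row_order[1], cd$row_score[1], cd$col_order[1]))
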