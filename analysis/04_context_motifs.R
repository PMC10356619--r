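#!/usr/bin/env Rscript
# Spatial context and tissue motifs: per-cell minimal neighbourhood-label
# combinations under the 85% rule with the containment graph, and per-group
# permutation tests of community-community adjacency motifs on patch
# instance graphs.
suppressMessages(library(tissuearch))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
# with ~50-60 tested pairs the Bonferroni factor (2 x n_tests) needs a p
# resolution finer than the 1/1001 floor of the default permutation count,
# so the motif null uses 5,000 permutations here
cfg <- analysis_config(seed = seed, n_permutations = 5000)
maps <- read_cell_table("results/data/cells.csv")
groups <- vapply(maps, function(m) m$cells$group[1], "")

nbhd_df <- read.delim("results/architecture/neighbourhoods.tsv")
nbhd <- label_assignment(nbhd_df$cell_id, nbhd_df$label, "neighbourhood")
comm_df <- read.delim("results/architecture/communities.tsv")
comm <- label_assignment(comm_df$cell_id, comm_df$label, "community")

ctx <- pool_combinations(lapply(maps, context_combinations,
                               assignment = nbhd, k = cfg$k_window_comm,
                               threshold = cfg$context_threshold))
ctx_graph <- combination_graph(ctx, min_freq = cfg$context_min_freq)

motifs <- list(); graphs <- list(context_graph = ctx_graph)
for (g in sort(unique(groups))) {
  ug <- union_graphs(lapply(maps[groups == g], label_instances,
                            assignment = comm))
  graphs[[paste0("instances_", g)]] <- instance_igraph(ug)
  motifs[[g]] <- motif_test(ug, n_permutations = cfg$n_permutations,
                            seed = cfg$seed,
                            min_instances = cfg$motif_min_instances)
}

write_results(c(list(context_combinations = ctx),
                setNames(motifs, paste0("motifs_", names(motifs)))),
              graphs, "results/context_motifs", force = TRUE)

message(sprintf("%d spatial-context combinations (%d above the %.1f%% plotting floor)",
                nrow(ctx), sum(ctx$frequency > cfg$context_min_freq),
                100 * cfg$context_min_freq))
for (g in names(motifs)) {
  sig <- motifs[[g]][motifs[[g]]$tested & !is.na(motifs[[g]]$p_adj) &
                     motifs[[g]]$p_adj < cfg$alpha, ]
  message(sprintf("%s: %d significant motif(s) of %d tested", g, nrow(sig),
                  sum(motifs[[g]]$tested)))
}
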