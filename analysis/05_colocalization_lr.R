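#!/usr/bin/env Rscript
# Colocalization and ligand-receptor nomination: per-section CLQ matrices,
# SB-vs-CL Welch tests per ordered type pair, nomination of ligand-receptor
# pairs on colocalized (CL > SB) type pairs from the discovery expression
# matrix, and the gene-label permutation test of the validation success
# rate.
suppressMessages(library(tissuearch))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
cfg <- analysis_config(seed = seed)
maps <- read_cell_table("results/data/cells.csv")
groups <- vapply(maps, function(m) m$cells$group[1], "")

clqs <- lapply(maps, clq, k = cfg$k_clq)
ctests <- clq_group_test(clqs, groups)
coloc <- ctests[ctests$tested & ctests$p_adj < cfg$alpha &
                ctests$direction == "CL>SB", ]
message(sprintf("%d ordered type pairs more colocalized in CL (BH p < %.2f)",
                nrow(coloc), cfg$alpha))

pairs <- read_lr_pairs("results/data/lr_pairs.csv")
disc <- read_expression("results/data/expression_discovery.csv")
cell_pairs <- data.frame(type_l = coloc$type_a, type_r = coloc$type_b)
cell_pairs <- cell_pairs[cell_pairs$type_l %in% disc$cells$cell_type &
                         cell_pairs$type_r %in% disc$cells$cell_type, ,
                         drop = FALSE]
nom <- lr_differential(disc, pairs, cell_pairs, alpha = cfg$alpha)
message(sprintf("%d ligand-receptor nominations across %d cell-type pair(s)",
                nrow(nom), length(unique(paste(nom$cell_type_l,
                                               nom$cell_type_r)))))

val <- read_expression("results/data/expression_validation.csv")
perm <- success_rate_permutation(val, nom,
                                 n_permutations = cfg$lr_n_permutations,
                                 seed = cfg$seed, alpha = cfg$alpha)
message(sprintf("validation: %d/%d predictions confirmed (%.1f%%), permutation p = %.2g",
                perm$observed, perm$n_matching, 100 * perm$rate, perm$p))

mean_clq <- function(g, a, b) mean(vapply(clqs[groups == g],
                                          function(m) m[a, b], 0))
message(sprintf("CLQ Plasma->TA: CL %.2f vs SB %.2f",
                mean_clq("CL", "Plasma", "TA"),
                mean_clq("SB", "Plasma", "TA")))

perm_df <- data.frame(observed = perm$observed, n_matching = perm$n_matching,
                      rate = perm$rate, p = perm$p,
                      n_dropped = perm$n_dropped)
write_results(list(clq_tests = ctests, lr_nominations = nom,
                   lr_validation = perm_df),
              list(), "results/colocalization_lr", force = TRUE)
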