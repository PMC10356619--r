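#!/usr/bin/env Rscript
# Simulate the study cohort: 4 donors x {jejunum (SB), sigmoid (CL)} on the
# layered-intestine template (~10,000 cells per section), a BMI-like donor
# covariate tied to the macrophage fraction, and discovery + validation
# expression matrices with ligand-receptor effects planted in the colon
# (Plasma ligands, TA receptors) -- the same pairing whose spatial
# attraction the template plants in CL sections.
suppressMessages(library(tissuearch))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(
  covariate = list(cell_type = "Macrophage", slope = 2500, intercept = 25,
                   sd = 0.5),
  seed = seed)
coh <- generate_cohort(cfg)
write_cell_table(coh$cellmaps, "results/data/cells.csv")
write.table(coh$donors, "results/data/donors.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

n_pairs <- 40L; n_hit <- 6L
genes <- c(sprintf("LIG%02d", 1:n_pairs), sprintf("REC%02d", 1:n_pairs))
pairs <- data.frame(ligand = sprintf("LIG%02d", 1:n_pairs),
                    receptor = sprintf("REC%02d", 1:n_pairs),
                    source = "synthetic")
write.csv(pairs, "results/data/lr_pairs.csv", row.names = FALSE,
          quote = FALSE)
effects <- rbind(
  data.frame(gene = sprintf("LIG%02d", 1:n_hit), cell_type = "Plasma",
             group = "CL", log2fc = 1.5),
  data.frame(gene = sprintf("REC%02d", 1:n_hit), cell_type = "TA",
             group = "CL", log2fc = 1.5))
expr_cfg <- expression_config(genes, cell_types = c("Plasma", "TA", "CD8T"),
                              effects = effects,
                              cells_per_type_per_group = 1000L)
write_expression(generate_expression(expr_cfg, seed = seed),
                 "results/data/expression_discovery.csv")
val_cfg <- expression_config(genes, cell_types = c("Plasma", "TA", "CD8T"),
                             effects = effects,
                             cells_per_type_per_group = 300L)
write_expression(generate_expression(val_cfg, seed = seed + 1L),
                 "results/data/expression_validation.csv")

tot <- sum(vapply(coh$cellmaps, function(m) nrow(m$cells), 0))
message(sprintf("cohort: %d sections, %d cells total; %d L-R pairs (%d with planted CL effects)",
                length(coh$cellmaps), tot, n_pairs, n_hit))
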