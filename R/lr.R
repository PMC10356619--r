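# Vectorized Wilcoxon rank-sum p-values (normal approximation with tie and
# continuity corrections, mirroring wilcox.test(exact = FALSE)), computed for
# every column of a count matrix at once.
rank_sum_p <- function(mat, idx1, idx2, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  n1 <- length(idx1); n2 <- length(idx2)
  sub <- mat[c(idx1, idx2), , drop = FALSE]
  out <- numeric(ncol(mat))
  for (g in seq_len(ncol(mat))) {
    r <- rank(sub[, g])
    w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    nt <- table(sub[, g])
    tie <- sum(nt^3 - nt)
    mu <- n1 * n2 / 2
    sigma <- sqrt((n1 * n2 / 12) *
                  ((n1 + n2 + 1) - tie / ((n1 + n2) * (n1 + n2 - 1))))
    if (sigma == 0) { out[g] <- 1; next }
    if (alternative == "greater") {
      out[g] <- stats::pnorm((w - mu - 0.5) / sigma, lower.tail = FALSE)
    } else {
      z <- w - mu
      z <- (z - sign(z) * 0.5) / sigma
      out[g] <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  names(out) <- colnames(mat)
  out
}

#' Colocalization-guided ligand-receptor nomination
#'
#' For every significantly colocalized cell-type pair (ligand type, receptor
#' type) and every ligand-receptor gene pair, tests whether the ligand is
#' differentially expressed in the ligand type between colon and small bowel
#' (two-sided Wilcoxon rank-sum) and likewise the receptor in the receptor
#' type. P-values are Benjamini-Hochberg adjusted within each
#' (cell type, gene role) family. A pair is nominated when both adjusted
#' p-values fall below `alpha` and both genes have higher mean expression in
#' the colon.
#'
#' @param expr An `expression_matrix` (see [generate_expression()]) or list
#'   with `counts` (cells x genes) and `cells` (`cell_type`, `group`).
#' @param pairs Ligand-receptor pair table ([read_lr_pairs()]).
#' @param cell_pairs data.frame `type_l, type_r` of colocalized cell-type
#'   pairs (e.g. significant `CL>SB` rows of [clq_group_test()]).
#' @param alpha Adjusted-p cut-off.
#' @param min_cells Minimum cells per (type, group) arm; smaller arms are
#'   skipped with a warning.
#' @return data.frame of nominations `cell_type_l, cell_type_r, ligand,
#'   receptor, ligand_log2fc, receptor_log2fc, ligand_p_adj, receptor_p_adj,
#'   direction`; attribute `"all_tests"` holds every tested combination.
#' @export
lr_differential <- function(expr, pairs, cell_pairs, alpha = 0.05,
                            min_cells = 3L) {
  stopifnot_cols(cell_pairs, c("type_l", "type_r"), "cell_pairs")
  counts <- expr$counts
  ann <- expr$cells
  miss <- setdiff(unique(c(pairs$ligand, pairs$receptor)), colnames(counts))
  if (length(miss)) {
    warning("gene(s) absent from expression matrix, pairs skipped: ",
            paste(miss, collapse = ", "))
    pairs <- pairs[!(pairs$ligand %in% miss | pairs$receptor %in% miss), ,
                   drop = FALSE]
  }
  usable_type <- function(ty) {
    ncl <- sum(ann$cell_type == ty & ann$group == "CL")
    nsb <- sum(ann$cell_type == ty & ann$group == "SB")
    if (ncl < min_cells || nsb < min_cells) {
      warning("cell type '", ty, "' has < ", min_cells,
              " cells in a group; skipped")
      return(FALSE)
    }
    TRUE
  }
  types <- unique(c(cell_pairs$type_l, cell_pairs$type_r))
  ok <- vapply(types, usable_type, TRUE)
  cell_pairs <- cell_pairs[cell_pairs$type_l %in% types[ok] &
                           cell_pairs$type_r %in% types[ok], , drop = FALSE]
  # per (type, gene): two-sided p and log2 fold change CL vs SB
  cache <- new.env(parent = emptyenv())
  type_stats <- function(ty, genes) {
    key <- ty
    if (is.null(cache[[key]])) {
      i_cl <- which(ann$cell_type == ty & ann$group == "CL")
      i_sb <- which(ann$cell_type == ty & ann$group == "SB")
      p <- rank_sum_p(counts, i_cl, i_sb, "two.sided")
      m_cl <- colMeans(counts[i_cl, , drop = FALSE])
      m_sb <- colMeans(counts[i_sb, , drop = FALSE])
      lfc <- log2((m_cl + 0.5) / (m_sb + 0.5))
      cache[[key]] <- list(p = p, lfc = lfc, up = m_cl > m_sb)
    }
    lapply(cache[[key]], `[`, genes)
  }
  rows <- list()
  for (cp in seq_len(nrow(cell_pairs))) {
    tl <- cell_pairs$type_l[cp]; tr <- cell_pairs$type_r[cp]
    if (nrow(pairs) == 0L) next
    sl <- type_stats(tl, pairs$ligand)
    sr <- type_stats(tr, pairs$receptor)
    rows[[cp]] <- data.frame(
      cell_type_l = tl, cell_type_r = tr,
      ligand = pairs$ligand, receptor = pairs$receptor,
      ligand_log2fc = unname(sl$lfc), receptor_log2fc = unname(sr$lfc),
      ligand_p = unname(sl$p), receptor_p = unname(sr$p),
      ligand_up = unname(sl$up), receptor_up = unname(sr$up),
      stringsAsFactors = FALSE)
  }
  all_tests <- do.call(rbind, rows)
  if (is.null(all_tests) || nrow(all_tests) == 0L) {
    empty <- data.frame(cell_type_l = character(0), cell_type_r = character(0),
                        ligand = character(0), receptor = character(0),
                        ligand_log2fc = numeric(0), receptor_log2fc = numeric(0),
                        ligand_p_adj = numeric(0), receptor_p_adj = numeric(0),
                        direction = character(0), stringsAsFactors = FALSE)
    attr(empty, "all_tests") <- all_tests
    return(empty)
  }
  # BH within each (cell type, gene role) family
  fam_l <- paste0(all_tests$cell_type_l, ":ligand")
  fam_r <- paste0(all_tests$cell_type_r, ":receptor")
  all_tests$ligand_p_adj <- stats::ave(all_tests$ligand_p, fam_l,
                                       FUN = function(p) stats::p.adjust(p, "BH"))
  all_tests$receptor_p_adj <- stats::ave(all_tests$receptor_p, fam_r,
                                         FUN = function(p) stats::p.adjust(p, "BH"))
  hit <- all_tests$ligand_p_adj < alpha & all_tests$receptor_p_adj < alpha &
         all_tests$ligand_up & all_tests$receptor_up
  nom <- all_tests[hit, c("cell_type_l", "cell_type_r", "ligand", "receptor",
                          "ligand_log2fc", "receptor_log2fc",
                          "ligand_p_adj", "receptor_p_adj"), drop = FALSE]
  nom$direction <- rep("CL>SB", nrow(nom))
  rownames(nom) <- NULL
  attr(nom, "all_tests") <- all_tests
  nom
}

#' Gene-label permutation test of validation success
#'
#' Given nominations from discovery data and an independent validation
#' expression matrix (e.g. a targeted spatial-transcriptomics panel), a
#' prediction is a validation success when a one-sided Wilcoxon rank-sum
#' test (colon > small bowel) is Benjamini-Hochberg significant for both the
#' ligand in its cell type and the receptor in its cell type. The null
#' permutes the gene labels of the validation matrix uniformly (preserving
#' every count and annotation) and recounts successes; the empirical p-value
#' carries the add-one correction, so its floor is
#' `1 / (n_permutations + 1)`. Predictions whose cell types or genes are not
#' present in the validation data are dropped and counted.
#'
#' @param validation_expr An `expression_matrix`.
#' @param predictions Nomination table with columns `cell_type_l,
#'   cell_type_r, ligand, receptor`.
#' @param n_permutations Number of gene-label permutations.
#' @param seed Integer seed.
#' @param alpha BH-adjusted significance cut-off.
#' @return List `observed` (success count), `rate`, `p`, `n_matching`,
#'   `n_dropped`, `null_counts`.
#' @export
success_rate_permutation <- function(validation_expr, predictions,
                                     n_permutations = 10000L, seed = 1L,
                                     alpha = 0.05) {
  counts <- validation_expr$counts
  ann <- validation_expr$cells
  genes <- colnames(counts)
  types <- unique(ann$cell_type)
  keep <- predictions$cell_type_l %in% types &
          predictions$cell_type_r %in% types &
          predictions$ligand %in% genes & predictions$receptor %in% genes
  n_dropped <- sum(!keep)
  pred <- predictions[keep, , drop = FALSE]
  if (nrow(pred) == 0L)
    stop("no prediction matches the validation cell types/genes")
  used_types <- unique(c(pred$cell_type_l, pred$cell_type_r))
  # one-sided p for every gene in every used type, computed once: a gene-label
  # permutation only relabels columns, so null successes are lookups
  P <- matrix(NA_real_, nrow = length(genes), ncol = length(used_types),
              dimnames = list(genes, used_types))
  for (ty in used_types) {
    i_cl <- which(ann$cell_type == ty & ann$group == "CL")
    i_sb <- which(ann$cell_type == ty & ann$group == "SB")
    if (length(i_cl) < 2 || length(i_sb) < 2)
      stop("validation type '", ty, "' lacks cells in a group")
    P[, ty] <- rank_sum_p(counts, i_cl, i_sb, "greater")
  }
  lig_i <- match(pred$ligand, genes)
  rec_i <- match(pred$receptor, genes)
  lig_t <- match(pred$cell_type_l, used_types)
  rec_t <- match(pred$cell_type_r, used_types)
  count_success <- function(gene_map) {
    pl <- P[cbind(gene_map[lig_i], lig_t)]
    pr <- P[cbind(gene_map[rec_i], rec_t)]
    adj <- stats::p.adjust(c(pl, pr), method = "BH")
    m <- length(pl)
    sum(adj[seq_len(m)] < alpha & adj[m + seq_len(m)] < alpha)
  }
  observed <- count_success(seq_along(genes))
  null_counts <- integer(n_permutations)
  with_seed(seed, {
    for (i in seq_len(n_permutations)) {
      null_counts[i] <- count_success(sample.int(length(genes)))
    }
  })
  list(observed = observed, rate = observed / nrow(pred),
       p = (1 + sum(null_counts >= observed)) / (n_permutations + 1),
       n_matching = nrow(pred), n_dropped = n_dropped,
       null_counts = null_counts)
}
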