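#' Run the full tissue-architecture pipeline on a cohort
#'
#' Chains every stage with the settings of an [analysis_config()]:
#' composition windows (k = `k_window_nbhd`) clustered into multicellular
#' neighbourhoods, communities (k = `k_window_comm`) and tissue units
#' (k = `k_window_tissue`) derived by re-windowing labels, the multilevel
#' hierarchy graph, spatial-context combinations and their containment
#' graph, per-group motif tests on community instance graphs, per-sample
#' colocalization quotients with SB-vs-CL tests, compartment-normalized
#' composition with group tests, and same-cell density scores. When
#' `out_dir` is given, all tables and graphs are written via
#' [write_results()]; outputs are byte-identical across reruns with the same
#' inputs, config and seed.
#'
#' @param cellmaps Named list of [cell_map()]s (e.g. from
#'   [generate_cohort()]).
#' @param config An [analysis_config()].
#' @param out_dir Optional output directory.
#' @param category_map Optional cell_type -> category map for
#'   [compartment_percentages()]; types missing from it are reported as
#'   `"unassigned"`.
#' @param force Passed to [write_results()].
#' @return List with `neighbourhoods`, `communities`, `tissue_units`
#'   (label assignments), `hierarchy` (igraph), `context` (combination
#'   table), `context_graph`, `motifs` (per-group list), `clq_per_sample`,
#'   `clq_tests`, `composition`, `composition_tests`, `density`, and
#'   `manifest` when written.
#' @export
run_pipeline <- function(cellmaps, config = analysis_config(),
                         out_dir = NULL, category_map = NULL, force = FALSE) {
  stopifnot(length(cellmaps) >= 1)
  groups <- vapply(cellmaps, function(m) m$cells$group[1], "")
  type_universe <- sort(unique(unlist(lapply(cellmaps, function(m)
    m$cells$cell_type))))

  # cell types -> neighbourhoods
  wins <- do.call(rbind, lapply(cellmaps, function(m)
    composition_windows(m, k = config$k_window_nbhd,
                        label_universe = type_universe)))
  attr(wins, "k") <- config$k_window_nbhd
  nbhd <- cluster_windows(wins, n_clusters = config$n_clusters_nbhd,
                          seed = config$seed, level = "neighbourhood")
  # neighbourhoods -> communities -> tissue units
  comm <- derive_level(cellmaps, nbhd, k = config$k_window_comm,
                       n_clusters = config$n_clusters_comm,
                       seed = config$seed, level = "community")
  tisu <- derive_level(cellmaps, comm, k = config$k_window_tissue,
                       n_clusters = config$n_clusters_comm,
                       seed = config$seed, level = "tissue_unit")
  ctype <- label_assignment(
    unlist(lapply(cellmaps, function(m) m$cells$cell_id)),
    unlist(lapply(cellmaps, function(m) m$cells$cell_type)), "cell_type")
  hier <- build_hierarchy_graph(list(ctype, nbhd, comm, tisu),
                                threshold = config$hierarchy_threshold)

  # spatial context over neighbourhood labels
  ctx_list <- lapply(cellmaps, function(m)
    context_combinations(m, nbhd, k = min(config$k_window_comm,
                                          nrow(m$cells)),
                         threshold = config$context_threshold))
  ctx <- pool_combinations(ctx_list)
  ctx_graph <- combination_graph(ctx, min_freq = config$context_min_freq)

  # motifs per group on community instance graphs
  motifs <- list()
  for (g in sort(unique(groups))) {
    gl <- lapply(cellmaps[groups == g], function(m)
      label_instances(m, comm))
    motifs[[g]] <- motif_test(union_graphs(gl),
                              n_permutations = config$n_permutations,
                              seed = config$seed,
                              min_instances = config$motif_min_instances)
  }

  clq_per_sample <- lapply(cellmaps, clq, k = config$k_clq)
  clq_tests <- if (length(unique(groups)) == 2)
    clq_group_test(clq_per_sample, groups) else NULL

  if (is.null(category_map)) {
    category_map <- stats::setNames(rep("unassigned", length(type_universe)),
                                    type_universe)
  }
  comp <- compartment_percentages(cellmaps, category_map,
                                  allow_unassigned = TRUE)
  comp_tests <- NULL
  if (length(unique(groups)) == 2) {
    allrows <- comp[comp$category == "all", ]
    comp_tests <- compare_groups(data.frame(
      unit = allrows$sample_id, group = allrows$group,
      feature = allrows$cell_type, value = allrows$percentage))
  }
  dens <- do.call(rbind, c(lapply(cellmaps, same_cell_density,
                                  k = config$k_density),
                           list(make.row.names = FALSE)))

  res <- list(neighbourhoods = nbhd, communities = comm, tissue_units = tisu,
              hierarchy = hier, context = ctx, context_graph = ctx_graph,
              motifs = motifs, clq_per_sample = clq_per_sample,
              clq_tests = clq_tests, composition = comp,
              composition_tests = comp_tests, density = dens)
  if (!is.null(out_dir)) {
    tables <- list(
      neighbourhoods = as.data.frame(nbhd),
      communities = as.data.frame(comm),
      tissue_units = as.data.frame(tisu),
      context_combinations = ctx,
      composition = comp,
      density = dens)
    if (!is.null(comp_tests)) tables$composition_tests <- comp_tests
    if (!is.null(clq_tests)) tables$clq_tests <- clq_tests
    for (g in names(motifs)) tables[[paste0("motifs_", g)]] <- motifs[[g]]
    graphs <- list(hierarchy = hier, context_graph = ctx_graph)
    res$manifest <- write_results(tables, graphs, out_dir, config = config,
                                  force = force)
  }
  invisible(res)
}

#' Pool spatial-context combinations over samples
#'
#' @param ctx_list List of [context_combinations()] outputs.
#' @return Combined combination table with counts summed and frequencies over
#'   the pooled cell count.
#' @export
pool_combinations <- function(ctx_list) {
  n_tot <- sum(vapply(ctx_list, function(x) attr(x, "n_cells"), 0))
  all <- do.call(rbind, ctx_list)
  agg <- stats::aggregate(count ~ combination + size, data = all, FUN = sum)
  agg <- agg[order(-agg$count, agg$combination), , drop = FALSE]
  agg$frequency <- agg$count / n_tot
  rownames(agg) <- NULL
  agg[, c("combination", "size", "count", "frequency")]
}
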