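#' Derive the next structural level by re-windowing labels
#'
#' Communities are found exactly like multicellular neighbourhoods, but the
#' windows are taken over neighbourhood labels with a larger size (k = 100 by
#' default); tissue units repeat the machinery over community labels at
#' k = 300. This wraps [composition_windows()] + [cluster_windows()] over a
#' list of samples, pooling windows before clustering so labels are shared
#' across the cohort.
#'
#' @param cellmaps `cell_map` or list of them.
#' @param lower [label_assignment()] covering all cells (e.g. neighbourhood
#'   labels), or `NULL` for cell types.
#' @param k Window size.
#' @param n_clusters Number of k-means clusters.
#' @param seed Integer seed.
#' @param level Name of the derived level.
#' @return A [label_assignment()] for all cells.
#' @export
derive_level <- function(cellmaps, lower = NULL, k, n_clusters, seed = 1L,
                         level = "community") {
  if (inherits(cellmaps, "cell_map")) cellmaps <- list(cellmaps)
  universe <- if (is.null(lower)) {
    sort(unique(unlist(lapply(cellmaps, function(m) m$cells$cell_type))))
  } else sort(unique(lower$label))
  wins <- lapply(cellmaps, function(m) {
    asg <- if (is.null(lower)) type_assignment(m) else lower
    composition_windows(m, asg, k = k, label_universe = universe)
  })
  w <- do.call(rbind, wins)
  attr(w, "k") <- k
  cluster_windows(w, n_clusters = n_clusters, seed = seed, level = level)
}

#' Multilevel tissue hierarchy graph
#'
#' Connects consecutive structural levels (cell type, neighbourhood,
#' community, tissue unit) into a directed graph: a lower label gets an edge
#' to the upper label that receives the largest share of its cells
#' (`reason = "argmax"`), and to every upper label of which it constitutes at
#' least `threshold` of the cells (`reason = "threshold"`). Edge weight is
#' the share of the upper structure made up by the lower label; node size is
#' the fraction of all cells carrying the label.
#'
#' @param levels Ordered list of [label_assignment()]s (lowest first), all
#'   covering the same cells.
#' @param threshold Minimum share-of-upper for a threshold edge.
#' @return `igraph` directed graph with vertex attributes `level`, `label`,
#'   `fraction` and edge attributes `weight`, `reason`.
#' @export
build_hierarchy_graph <- function(levels, threshold = 0.15) {
  stopifnot(length(levels) >= 2, threshold > 0, threshold < 1)
  ids <- levels[[1]]$cell_id
  for (lv in levels[-1]) {
    if (nrow(lv) != length(ids) || !setequal(lv$cell_id, ids))
      stop("all levels must cover the same cells")
  }
  n <- length(ids)
  nodes <- list(); edges <- list()
  for (li in seq_along(levels)) {
    lv <- levels[[li]]
    lvname <- attr(lv, "level")
    if (is.null(lvname)) lvname <- paste0("level", li)
    tab <- table(lv$label)
    nodes[[li]] <- data.frame(
      name = paste0(lvname, ":", names(tab)), level = lvname,
      label = names(tab), fraction = as.numeric(tab) / n,
      stringsAsFactors = FALSE)
  }
  for (li in seq_len(length(levels) - 1L)) {
    lo <- levels[[li]]; up <- levels[[li + 1L]]
    lo_lab <- lo$label[match(ids, lo$cell_id)]
    up_lab <- up$label[match(ids, up$cell_id)]
    joint <- table(lo_lab, up_lab)                  # n(l, u)
    upper_n <- colSums(joint)
    share_of_upper <- sweep(joint, 2, upper_n, "/") # n(l,u) / n(u)
    for (l in rownames(joint)) {
      to_arg <- colnames(joint)[which.max(joint[l, ])]  # largest share of l's cells
      hit <- colnames(joint)[share_of_upper[l, ] >= threshold & joint[l, ] > 0]
      targets <- union(to_arg, hit)
      for (u in targets) {
        edges[[length(edges) + 1L]] <- data.frame(
          from = paste0(nodes[[li]]$level[1], ":", l),
          to = paste0(nodes[[li + 1L]]$level[1], ":", u),
          weight = share_of_upper[l, u],
          reason = if (u == to_arg) "argmax" else "threshold",
          stringsAsFactors = FALSE)
      }
    }
  }
  vdf <- do.call(rbind, nodes)
  edf <- do.call(rbind, edges)
  igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
}
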