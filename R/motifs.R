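#' Instance graph of contiguous same-label patches
#'
#' Motif testing works on segmented patches, not single cells: cell adjacency
#' is the Delaunay triangulation of the cell centroids with edges longer than
#' `max_edge` removed (default three times the median Delaunay edge length, a
#' parameter-light prune that severs spurious long-range links across lumens
#' and tears); instances are connected components of same-label cells with at
#' least `min_cells` members; two instances are joined whenever any retained
#' cell-level edge crosses between them. Degenerate point sets (all collinear
#' or duplicated coordinates) fall back to a symmetrized 6-nearest-neighbour
#' adjacency with a warning.
#'
#' @param cellmap A [cell_map()].
#' @param assignment [label_assignment()] (e.g. community labels).
#' @param max_edge Maximum retained cell-adjacency edge length; `NULL` for
#'   3x the median Delaunay edge length.
#' @param min_cells Minimum cells per instance.
#' @return List of class `instance_graph`: `instances` (data.frame
#'   `instance_id, label, size, sample_id`), `edges` (data.frame
#'   `from, to` of instance ids), `members` (list of cell-id vectors),
#'   `samples` (character).
#' @export
label_instances <- function(cellmap, assignment, max_edge = NULL,
                            min_cells = 3L) {
  stopifnot(inherits(cellmap, "cell_map"), min_cells >= 2L)
  cells <- cellmap$cells
  n <- nrow(cells)
  if (n < 3L) stop("need at least 3 cells")
  lab <- aligned_labels(cellmap, assignment)
  adj <- cell_adjacency(cells$x, cells$y, max_edge)
  # same-label connected components
  same <- adj[lab[adj[, 1]] == lab[adj[, 2]], , drop = FALSE]
  g <- igraph::graph_from_edgelist(same, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  sizes <- tabulate(comp)
  keep_comp <- which(sizes >= min_cells)
  inst_of_cell <- rep(NA_integer_, n)
  inst_id <- match(comp, keep_comp)         # NA for dropped components
  inst_of_cell <- inst_id
  if (!length(keep_comp))
    return(structure(list(
      instances = data.frame(instance_id = character(0), label = character(0),
                             size = integer(0), sample_id = character(0),
                             stringsAsFactors = FALSE),
      edges = data.frame(from = character(0), to = character(0),
                         stringsAsFactors = FALSE),
      members = list(), samples = cells$sample_id[1]),
      class = "instance_graph"))
  sid <- cells$sample_id[1]
  ids <- sprintf("%s_i%04d", sid, seq_along(keep_comp))
  inst <- data.frame(
    instance_id = ids,
    label = vapply(keep_comp, function(cc) lab[match(cc, comp)], ""),
    size = sizes[keep_comp], sample_id = sid, stringsAsFactors = FALSE)
  members <- lapply(keep_comp, function(cc) cells$cell_id[comp == cc])
  names(members) <- ids
  a <- inst_of_cell[adj[, 1]]; b <- inst_of_cell[adj[, 2]]
  ok <- !is.na(a) & !is.na(b) & a != b
  ep <- unique(cbind(pmin(a[ok], b[ok]), pmax(a[ok], b[ok])))
  edges <- data.frame(from = ids[ep[, 1]], to = ids[ep[, 2]],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(instances = inst, edges = edges, members = members,
                 samples = sid), class = "instance_graph")
}

# Delaunay adjacency with a max-edge prune; kNN fallback for degenerate sets.
cell_adjacency <- function(x, y, max_edge = NULL) {
  n <- length(x)
  dup <- anyDuplicated(cbind(x, y)) > 0
  del <- if (dup) NULL else tryCatch(
    suppressWarnings(deldir::deldir(x, y))$delsgs, error = function(e) NULL)
  if (is.null(del)) {
    warning("degenerate point set; using symmetrized 6-NN adjacency")
    k <- min(6L, n - 1L)
    idx <- knn_indices(x, y, k)
    e <- cbind(rep(seq_len(n), k), as.vector(idx))
  } else {
    e <- cbind(del$ind1, del$ind2)
  }
  len <- sqrt((x[e[, 1]] - x[e[, 2]])^2 + (y[e[, 1]] - y[e[, 2]])^2)
  if (is.null(max_edge)) max_edge <- 3 * stats::median(len)
  e <- e[len <= max_edge, , drop = FALSE]
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  e
}

#' Union of instance graphs across imaging regions
#'
#' @param graphs List of `instance_graph`s with disjoint instance/cell id
#'   spaces (ids are sample-prefixed, so distinct samples are always safe).
#' @return A single `instance_graph`.
#' @export
union_graphs <- function(graphs) {
  stopifnot(length(graphs) >= 1)
  ids <- unlist(lapply(graphs, function(g) g$instances$instance_id))
  if (anyDuplicated(ids)) stop("instance id collision across graphs")
  structure(list(
    instances = do.call(rbind, c(lapply(graphs, `[[`, "instances"),
                                 list(make.row.names = FALSE))),
    edges = do.call(rbind, c(lapply(graphs, `[[`, "edges"),
                             list(make.row.names = FALSE))),
    members = do.call(c, lapply(graphs, `[[`, "members")),
    samples = unlist(lapply(graphs, `[[`, "samples"))),
    class = "instance_graph")
}

#' Export an instance graph as igraph
#'
#' @param graph An `instance_graph`.
#' @return Undirected `igraph` with vertex attributes `label`, `size`,
#'   `sample_id`.
#' @export
instance_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                vertices = graph$instances)
}

#' Permutation test for tissue motifs
#'
#' A motif is an unordered pair of structure labels whose patch instances
#' are adjacent in the tissue more often than expected. The observed
#' statistic is the number of instance edges joining the two labels; the
#' null shuffles instance labels uniformly over the fixed instance graph
#' (equivalently, a sequence of random transpositions of the label
#' assignment), preserving the label multiset and the graph — the maximum
#' entropy null. One-sided (enrichment) empirical p-values use the add-one
#' correction; Bonferroni adjustment multiplies by twice the number of
#' tested pairs (capped at 1). Pairs observed fewer than `min_instances`
#' times are reported but not tested.
#'
#' @param graph An `instance_graph` (typically a [union_graphs()] over one
#'   group's regions).
#' @param n_permutations Number of label permutations (>= 99).
#' @param seed Integer seed.
#' @param min_instances Minimum observed adjacent-pair count for testing.
#' @param two_sided Also flag depletion (doubles the one-sided p, capped).
#' @return data.frame `label_a, label_b, observed, null_mean, null_sd, p,
#'   p_adj, tested` sorted by `p` then labels.
#' @export
motif_test <- function(graph, n_permutations = 1000L, seed = 1L,
                       min_instances = 5L, two_sided = FALSE) {
  stopifnot(n_permutations >= 99L)
  inst <- graph$instances
  labs <- sort(unique(inst$label))
  if (length(labs) < 2L || nrow(graph$edges) == 0L)
    return(data.frame(label_a = character(0), label_b = character(0),
                      observed = integer(0), null_mean = numeric(0),
                      null_sd = numeric(0), p = numeric(0),
                      p_adj = numeric(0), tested = logical(0)))
  L <- length(labs)
  lcode <- match(inst$label, labs)
  e1 <- match(graph$edges$from, inst$instance_id)
  e2 <- match(graph$edges$to, inst$instance_id)
  pair_key <- function(code) {
    a <- code[e1]; b <- code[e2]
    (pmin(a, b) - 1L) * L + pmax(a, b)   # unordered pair -> integer key
  }
  nkey <- L * L
  obs <- tabulate(pair_key(lcode), nbins = nkey)
  ge <- integer(nkey); nsum <- numeric(nkey); nsq <- numeric(nkey)
  with_seed(seed, {
    for (p in seq_len(n_permutations)) {
      perm <- lcode[sample.int(length(lcode))]
      cnt <- tabulate(pair_key(perm), nbins = nkey)
      ge <- ge + (cnt >= obs)
      nsum <- nsum + cnt
      nsq <- nsq + cnt^2
    }
  })
  keys <- which(obs > 0 | nsum > 0)
  a <- (keys - 1L) %/% L + 1L
  b <- (keys - 1L) %% L + 1L
  res <- data.frame(label_a = labs[a], label_b = labs[b],
                    observed = obs[keys],
                    null_mean = nsum[keys] / n_permutations,
                    null_sd = sqrt(pmax(0, nsq[keys] / n_permutations -
                                          (nsum[keys] / n_permutations)^2)),
                    p = (1 + ge[keys]) / (n_permutations + 1),
                    stringsAsFactors = FALSE)
  res$tested <- res$observed >= min_instances
  if (two_sided) res$p <- pmin(1, 2 * pmin(res$p, 1 - res$p + 1 / (n_permutations + 1)))
  res$p[!res$tested] <- NA_real_
  n_tested <- sum(res$tested)
  res$p_adj <- pmin(1, res$p * 2 * n_tested)
  res[order(res$p, res$label_a, res$label_b), , drop = FALSE]
}
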