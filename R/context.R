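#' Spatial-context combinations
#'
#' For each cell, the labels of its `k`-nearest-neighbour window are sorted
#' by descending count (count ties broken lexicographically) and the minimal
#' prefix whose cumulative fraction reaches `threshold` becomes that cell's
#' spatial context: a single label inside a homogeneous structure, a label
#' set at the interface between structures. Combinations are unordered and
#' canonically sorted for identity.
#'
#' @param cellmap A [cell_map()].
#' @param assignment Label assignment windowed over (e.g. neighbourhood or
#'   community labels).
#' @param k Window size (100 for neighbourhood contexts, 300 for community
#'   contexts by default in [analysis_config()]).
#' @param threshold Cumulative fraction to reach (default 0.85). Reaching the
#'   threshold exactly counts (`strict = FALSE`); `strict = TRUE` requires
#'   strictly exceeding it.
#' @param cell_filter Optional logical/index vector selecting the cells whose
#'   contexts are counted (e.g. mucosa-only), applied to the cell_id-sorted
#'   cell table; windows still draw on all cells.
#' @param strict Use a strict `>` comparison against `threshold`.
#' @return data.frame `combination` ("+"-joined sorted labels), `size`,
#'   `count`, `frequency` (of filtered cells), sorted by descending count;
#'   attribute `"per_cell"` maps each filtered cell to its combination,
#'   attribute `"n_cells"` the filtered cell count.
#' @export
context_combinations <- function(cellmap, assignment, k, threshold = 0.85,
                                 cell_filter = NULL, strict = FALSE) {
  stopifnot(threshold > 0, threshold < 1)
  w <- composition_windows(cellmap, assignment, k = k)
  if (!is.null(cell_filter)) w <- w[cell_filter, , drop = FALSE]
  if (nrow(w) == 0L) stop("cell filter removed every cell")
  labs <- colnames(w)
  per_cell <- character(nrow(w))
  for (i in seq_len(nrow(w))) {
    v <- w[i, ]
    o <- order(-v, labs)           # descending count, lexicographic ties
    cs <- cumsum(v[o])
    m <- if (strict) match(TRUE, cs > threshold)
         else match(TRUE, cs >= threshold - 1e-12)
    if (is.na(m)) m <- length(cs)  # numerically defensive; rows sum to 1
    per_cell[i] <- paste(sort(labs[o[seq_len(m)]]), collapse = "+")
  }
  tab <- sort(table(per_cell), decreasing = TRUE)
  res <- data.frame(combination = names(tab),
                    size = lengths(strsplit(names(tab), "+", fixed = TRUE)),
                    count = as.integer(tab),
                    frequency = as.integer(tab) / nrow(w),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "per_cell") <- data.frame(cell_id = rownames(w),
                                      combination = per_cell,
                                      stringsAsFactors = FALSE)
  attr(res, "n_cells") <- nrow(w)
  attr(res, "threshold") <- threshold
  res
}

#' Spatial-context combination graph
#'
#' Keeps combinations above a frequency floor and connects each combination
#' to every retained combination containing it with exactly one extra label,
#' producing the sublayer containment graph of spatial contexts.
#'
#' @param combinations Output of [context_combinations()] (possibly pooled:
#'   any data.frame with `combination`, `count`, `frequency`).
#' @param min_freq Frequency floor (combinations at or below it are dropped).
#' @return Directed acyclic `igraph`; vertex attributes `size` (cardinality),
#'   `count`, `frequency`.
#' @export
combination_graph <- function(combinations, min_freq = 0.001) {
  keep <- combinations[combinations$frequency > min_freq, , drop = FALSE]
  if (nrow(keep) == 0L) {
    warning("no combination exceeds the frequency floor")
    return(igraph::make_empty_graph(directed = TRUE))
  }
  sets <- strsplit(keep$combination, "+", fixed = TRUE)
  card <- lengths(sets)
  edges <- character(0)
  for (i in seq_along(sets)) {
    for (j in which(card == card[i] + 1L)) {
      if (all(sets[[i]] %in% sets[[j]]))
        edges <- c(edges, keep$combination[i], keep$combination[j])
    }
  }
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(keep$combination, size = card, count = keep$count,
                     frequency = keep$frequency)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  g
}
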