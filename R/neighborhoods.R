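#' Per-cell label assignments
#'
#' A label assignment attaches one structural label per cell at a given level
#' (`cell_type`, `neighbourhood`, `community`, `tissue_unit`, or any user
#' level). Assignments are the currency passed between windowing, clustering
#' and graph-building stages.
#'
#' @param cell_id Character vector of cell ids.
#' @param label Character vector of labels, same length.
#' @param level Level name.
#' @param meta Optional list of clustering metadata (k, n_clusters, seed, ...).
#' @return data.frame (`cell_id`, `label`) of class `label_assignment` with
#'   attributes `level` and `meta`.
#' @export
label_assignment <- function(cell_id, label, level, meta = list()) {
  stopifnot(length(cell_id) == length(label))
  if (anyNA(label) || any(!nzchar(label))) stop("every cell must be labelled")
  df <- data.frame(cell_id = as.character(cell_id),
                   label = as.character(label), stringsAsFactors = FALSE)
  attr(df, "level") <- level
  attr(df, "meta") <- meta
  class(df) <- c("label_assignment", "data.frame")
  df
}

#' @describeIn label_assignment The trivial assignment: each cell labelled by
#'   its own cell type.
#' @param cellmap A [cell_map()].
#' @export
type_assignment <- function(cellmap) {
  label_assignment(cellmap$cells$cell_id, cellmap$cells$cell_type,
                   "cell_type")
}

# labels aligned to a cellmap's (cell_id-sorted) rows
aligned_labels <- function(cellmap, assignment) {
  i <- match(cellmap$cells$cell_id, assignment$cell_id)
  if (anyNA(i)) stop("assignment does not cover all cells of the map")
  assignment$label[i]
}

#' k-nearest-neighbour composition windows
#'
#' For each cell, the fractional composition of the `k`-cell window centred
#' on it: the cell itself plus its `k - 1` nearest cells by Euclidean
#' distance (or its `k` nearest with `include_self = FALSE`), over the labels
#' of `assignment`. Windows never cross sample boundaries because a
#' [cell_map()] holds a single section. Distance ties are broken by cell_id
#' order.
#'
#' @param cellmap A [cell_map()].
#' @param assignment Label assignment giving the windowed level; default the
#'   cell types.
#' @param k Window size in cells.
#' @param include_self Count the index cell as part of its own window.
#' @param label_universe Optional fixed column set (so windows from several
#'   samples share columns).
#' @return Numeric matrix, one row per cell (rownames = cell_id, rows sum to
#'   1), one column per label; attributes `k` and `level`.
#' @export
composition_windows <- function(cellmap, assignment = NULL, k,
                                include_self = TRUE, label_universe = NULL) {
  stopifnot(inherits(cellmap, "cell_map"))
  if (is.null(assignment)) assignment <- type_assignment(cellmap)
  cells <- cellmap$cells
  n <- nrow(cells)
  if (k > n) stop("window size k = ", k, " exceeds cell count ", n)
  lab <- aligned_labels(cellmap, assignment)
  if (is.null(label_universe)) label_universe <- sort(unique(lab))
  code <- match(lab, label_universe)
  if (anyNA(code)) stop("labels outside the declared universe")
  L <- length(label_universe)
  n_nb <- if (include_self) k - 1L else k
  counts <- matrix(0, nrow = n, ncol = L,
                   dimnames = list(cells$cell_id, label_universe))
  if (include_self) counts[cbind(seq_len(n), code)] <- 1
  if (n_nb > 0L) {
    idx <- knn_indices(cells$x, cells$y, n_nb)
    rows <- seq_len(n)
    for (j in seq_len(n_nb)) {
      cj <- code[idx[, j]]
      ij <- cbind(rows, cj)
      counts[ij] <- counts[ij] + 1
    }
  }
  w <- counts / k
  attr(w, "k") <- k
  attr(w, "level") <- attr(assignment, "level")
  w
}

#' Cluster composition windows into structures
#'
#' k-means over window composition vectors (10 restarts, best inertia,
#' seeded), deliberately overclustering so that distinct structures are not
#' merged prematurely; [merge_clusters()] (optionally guided by
#' [suggest_merges()]) then reduces them to named structures. With
#' `group_by`, clustering runs independently within each group and labels are
#' prefixed with the group name, for region-wise characterization.
#'
#' @param windows Window matrix (rows may be pooled over samples with
#'   `rbind`; rownames must be cell ids).
#' @param n_clusters Number of clusters.
#' @param seed Integer seed; identical seed gives identical labels.
#' @param level Level name for the resulting assignment.
#' @param prefix Label prefix (default the level name).
#' @param group_by Optional character vector (one entry per row) of group
#'   names.
#' @return A [label_assignment()].
#' @export
cluster_windows <- function(windows, n_clusters, seed = 1L,
                            level = "neighbourhood", prefix = NULL,
                            group_by = NULL) {
  if (is.null(prefix)) prefix <- level
  if (!is.null(group_by)) {
    stopifnot(length(group_by) == nrow(windows))
    parts <- lapply(sort(unique(group_by)), function(g) {
      rows <- group_by == g
      if (!any(rows)) stop("empty group: ", g)
      sub <- cluster_windows(windows[rows, , drop = FALSE], n_clusters,
                             seed = seed, level = level,
                             prefix = paste0(g, ".", prefix))
      sub
    })
    out <- do.call(rbind, lapply(parts, as.data.frame))
    return(label_assignment(out$cell_id, out$label, level,
                            meta = list(n_clusters = n_clusters, seed = seed,
                                        per_group = TRUE)))
  }
  n_distinct <- nrow(unique(windows))
  if (n_clusters > n_distinct)
    stop("n_clusters (", n_clusters, ") exceeds distinct window rows (",
         n_distinct, ")")
  # Hartigan-Wong can stall its quick-transfer stage on the heavily
  # duplicated rows that k-discretized window fractions produce; MacQueen
  # converges cleanly there, so retry with it when that happens
  km <- with_seed(seed, withCallingHandlers(
    stats::kmeans(windows, centers = n_clusters, nstart = 10,
                  iter.max = 100),
    warning = function(w) {
      if (grepl("Quick-TRANSfer", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  if (any(km$ifault == 4L))
    km <- with_seed(seed,
      stats::kmeans(windows, centers = n_clusters, nstart = 10,
                    iter.max = 100, algorithm = "MacQueen"))
  lab <- sprintf("%s_%02d", prefix, km$cluster)
  out <- label_assignment(rownames(windows), lab, level,
                          meta = list(k = attr(windows, "k"),
                                      n_clusters = n_clusters, seed = seed))
  centers <- km$centers
  rownames(centers) <- sprintf("%s_%02d", prefix, seq_len(nrow(centers)))
  attr(out, "centers") <- centers
  out
}

#' Merge clustered labels into named structures
#'
#' @param assignment A [label_assignment()].
#' @param mapping Named character vector `old_label -> merged_label`, covering
#'   every label in the assignment.
#' @return The relabelled assignment.
#' @export
merge_clusters <- function(assignment, mapping) {
  missing <- setdiff(unique(assignment$label), names(mapping))
  if (length(missing))
    stop("mapping does not cover label(s): ", paste(missing, collapse = ", "))
  label_assignment(assignment$cell_id, unname(mapping[assignment$label]),
                   attr(assignment, "level"),
                   meta = c(attr(assignment, "meta"), list(merged = TRUE)))
}

#' Suggest cluster merges from profile similarity
#'
#' Groups clusters whose enrichment (or centroid) profiles are similar:
#' with `cor_threshold`, complete-linkage correlation clustering cut at
#' `1 - cor_threshold`; with `n_target`, Ward clustering of the Euclidean
#' centroid distances into a fixed number of structures. The suggestion is
#' returned as a mapping for [merge_clusters()]; it is never applied
#' automatically — merging structures is an interpretive step.
#'
#' @param profiles Numeric matrix, one row per cluster label (e.g. an
#'   [enrichment_matrix()] or k-means centers).
#' @param cor_threshold Merge clusters correlated at or above this value.
#' @param n_target Alternatively, the number of merged labels wanted.
#' @param prefix Prefix of merged label names.
#' @return Named character vector `old_label -> merged_label`.
#' @export
suggest_merges <- function(profiles, cor_threshold = 0.9, n_target = NULL,
                           prefix = "structure") {
  if (nrow(profiles) == 1L)
    return(stats::setNames(sprintf("%s_01", prefix), rownames(profiles)))
  if (is.null(n_target)) {
    d <- stats::as.dist(1 - stats::cor(t(profiles)))
    d[!is.finite(d)] <- 2
    grp <- stats::cutree(stats::hclust(d, method = "complete"),
                         h = 1 - cor_threshold)
  } else {
    grp <- stats::cutree(stats::hclust(stats::dist(profiles),
                                       method = "ward.D2"),
                         k = min(n_target, nrow(profiles)))
  }
  stats::setNames(sprintf("%s_%02d", prefix, grp), rownames(profiles))
}

#' Fold-enrichment of lower-level labels within upper-level structures
#'
#' `enrichment(u, c)` is the fraction of lower-label `c` among cells carrying
#' upper label `u`, divided by the fraction of `c` among all cells. Values
#' above 1 mean the structure is enriched for that constituent. The
#' cell-weighted average of each column over structures equals 1 (mass
#' conservation), which downstream code relies on.
#'
#' @param upper,lower [label_assignment()]s covering the same cells.
#' @return Numeric matrix labels x lower-labels with attributes `weights`
#'   (fraction of cells per upper label) and `overall` (overall lower-label
#'   fractions).
#' @export
enrichment_matrix <- function(upper, lower) {
  i <- match(upper$cell_id, lower$cell_id)
  if (anyNA(i) || nrow(upper) != nrow(lower))
    stop("upper and lower assignments must cover the same cells")
  lo <- lower$label[i]
  up <- upper$label
  n <- length(up)
  overall <- table(lo) / n
  keep <- names(overall)[overall > 0]
  tab <- table(factor(up), factor(lo, levels = keep))
  frac <- tab / rowSums(tab)
  enr <- sweep(frac, 2, as.numeric(overall[keep]), "/")
  out <- matrix(as.numeric(enr), nrow = nrow(tab),
                dimnames = list(rownames(tab), keep))
  attr(out, "weights") <- as.numeric(table(factor(up)) / n)
  names(attr(out, "weights")) <- rownames(out)
  attr(out, "overall") <- stats::setNames(as.numeric(overall[keep]), keep)
  out
}

#' Between-group conservation difference of enrichment matrices
#'
#' `delta = E_SB - E_CL` over the shared labels and cell types, with rows and
#' columns ordered by descending total absolute difference, so the least
#' conserved structures and constituents come first.
#'
#' @param e_sb,e_cl Enrichment matrices from the two groups.
#' @return List `delta` (ordered matrix), `row_order`, `col_order`,
#'   `row_score`, `col_score` (the total absolute differences).
#' @export
conservation_delta <- function(e_sb, e_cl) {
  labs <- intersect(rownames(e_sb), rownames(e_cl))
  typs <- intersect(colnames(e_sb), colnames(e_cl))
  if (!length(labs) || !length(typs))
    stop("enrichment matrices share no labels/types")
  dropped <- c(setdiff(union(rownames(e_sb), rownames(e_cl)), labs),
               setdiff(union(colnames(e_sb), colnames(e_cl)), typs))
  if (length(dropped))
    warning("dropped non-shared label(s)/type(s): ",
            paste(dropped, collapse = ", "))
  d <- e_sb[labs, typs, drop = FALSE] - e_cl[labs, typs, drop = FALSE]
  rs <- rowSums(abs(d)); cs <- colSums(abs(d))
  ro <- order(-rs, rownames(d)); co <- order(-cs, colnames(d))
  list(delta = d[ro, co, drop = FALSE],
       row_order = rownames(d)[ro], col_order = colnames(d)[co],
       row_score = rs[ro], col_score = cs[co])
}

#' Concentric composition profiles around an anchor cell type
#'
#' Around every cell of `anchor_type`, collects the cells inside growing
#' windows (cumulative disks, or annuli) of the given radii, pools counts
#' over anchors, and reports composition and fold-enrichment relative to the
#' overall composition. Anchor-type cells themselves are excluded from the
#' pooled counts and from the reference composition, so the profile describes
#' the anchor's surroundings.
#'
#' @param cellmap A [cell_map()].
#' @param anchor_type Anchor cell type (>= 1 cell required).
#' @param radii Strictly increasing positive radii, coordinate units.
#' @param mode `"cumulative"` disks or `"annulus"` rings.
#' @return data.frame `radius, cell_type, count, fraction, enrichment`.
#' @export
concentric_enrichment <- function(cellmap, anchor_type, radii,
                                  mode = c("cumulative", "annulus")) {
  mode <- match.arg(mode)
  stopifnot(all(radii > 0), all(diff(radii) > 0))
  cells <- cellmap$cells
  anchors <- which(cells$cell_type == anchor_type)
  if (!length(anchors)) stop("no cells of anchor type '", anchor_type, "'")
  others <- which(cells$cell_type != anchor_type)
  types <- sort(unique(cells$cell_type[others]))
  R <- length(radii)
  ann <- matrix(0, nrow = R, ncol = length(types),
                dimnames = list(NULL, types))
  if (length(others)) {
    tcode <- factor(cells$cell_type[others], levels = types)
    for (a in anchors) {  # pooled over anchors; a cell near two anchors counts twice
      d <- sqrt((cells$x[others] - cells$x[a])^2 +
                (cells$y[others] - cells$y[a])^2)
      bin <- findInterval(d, radii, left.open = TRUE) + 1L
      inr <- bin <= R
      if (any(inr))
        ann <- ann + table(factor(bin[inr], levels = seq_len(R)),
                           tcode[inr])
    }
  }
  counts <- if (mode == "cumulative") apply(ann, 2, cumsum) else ann
  counts <- matrix(counts, nrow = R, dimnames = list(NULL, types))
  overall <- as.numeric(table(factor(cells$cell_type[others],
                                     levels = types))) / length(others)
  out <- list()
  for (r in seq_len(R)) {
    tot <- sum(counts[r, ])
    frac <- if (tot > 0) counts[r, ] / tot else rep(NA_real_, length(types))
    out[[r]] <- data.frame(radius = radii[r], cell_type = types,
                           count = as.numeric(counts[r, ]),
                           fraction = as.numeric(frac),
                           enrichment = as.numeric(frac) / overall,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "mode") <- mode
  attr(res, "anchor_type") <- anchor_type
  attr(res, "n_anchors") <- length(anchors)
  rownames(res) <- NULL
  res
}
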