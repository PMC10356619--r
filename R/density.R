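#' Cell-type percentages normalized within compartments
#'
#' Raw cell-type percentages of a whole section are dominated by whichever
#' compartment the section happened to capture; normalizing each type to its
#' own grouping (epithelial / immune / stromal) makes composition comparable
#' across sections. For each sample and category this computes the percentage
#' of every member type among the cells of that category, plus an `all`
#' category over all cells.
#'
#' @param cellmaps `cell_map` or list of them.
#' @param category_map Named character vector or two-column data.frame
#'   (`cell_type`, `category`) assigning each type to a category.
#' @param allow_unassigned Map types absent from `category_map` to
#'   `"unassigned"` instead of erroring.
#' @return data.frame with columns `sample_id, donor_id, region, group,
#'   category, cell_type, n_cells, percentage`; within each
#'   (sample, category) the percentages sum to 100.
#' @export
compartment_percentages <- function(cellmaps, category_map,
                                    allow_unassigned = FALSE) {
  if (inherits(cellmaps, "cell_map")) cellmaps <- list(cellmaps)
  if (is.data.frame(category_map)) {
    stopifnot_cols(category_map, c("cell_type", "category"), "category map")
    category_map <- stats::setNames(category_map$category,
                                    category_map$cell_type)
  }
  cells <- pool_cells(cellmaps)
  unmapped <- setdiff(unique(cells$cell_type), names(category_map))
  if (length(unmapped)) {
    if (!allow_unassigned)
      stop("cell type(s) not in category map: ",
           paste(sort(unmapped), collapse = ", "))
    category_map[unmapped] <- "unassigned"
  }
  cells$category <- unname(category_map[cells$cell_type])
  out <- list()
  for (s in split(cells, cells$sample_id)) {
    meta <- s[1, c("sample_id", "donor_id", "region", "group")]
    for (cat in c(sort(unique(s$category)), "all")) {
      sub <- if (cat == "all") s else s[s$category == cat, , drop = FALSE]
      if (nrow(sub) == 0L) next
      tab <- table(sub$cell_type)
      out[[length(out) + 1L]] <- data.frame(
        meta, category = cat, cell_type = names(tab),
        n_cells = as.integer(tab),
        percentage = 100 * as.numeric(tab) / nrow(sub),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Welch t-tests between sample groups
#'
#' Two-sided Welch t-test per feature (cell type, neighbourhood, ...) between
#' the small-bowel and colon groups, on per-donor (or per-sample) values. Raw
#' p-values are reported alongside Benjamini-Hochberg adjusted ones; rows
#' with fewer than two observations in either group are flagged missing
#' rather than tested.
#'
#' @param values data.frame with columns `unit` (donor or sample id),
#'   `group`, `feature`, `value`.
#' @return data.frame `feature, mean_SB, mean_CL, t, p, p_adj, n_SB, n_CL,
#'   tested`.
#' @export
compare_groups <- function(values) {
  stopifnot_cols(values, c("unit", "group", "feature", "value"), "values")
  feats <- sort(unique(values$feature))
  res <- data.frame(feature = feats, mean_SB = NA_real_, mean_CL = NA_real_,
                    t = NA_real_, p = NA_real_, p_adj = NA_real_,
                    n_SB = 0L, n_CL = 0L, tested = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(feats)) {
    v <- values[values$feature == feats[i], ]
    a <- v$value[v$group == "SB"]
    b <- v$value[v$group == "CL"]
    res$n_SB[i] <- length(a); res$n_CL[i] <- length(b)
    res$mean_SB[i] <- if (length(a)) mean(a) else NA_real_
    res$mean_CL[i] <- if (length(b)) mean(b) else NA_real_
    if (length(a) >= 2 && length(b) >= 2) {
      if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b)) {
        res$t[i] <- 0; res$p[i] <- 1; res$tested[i] <- TRUE
      } else if (stats::var(a) + stats::var(b) > 0) {
        tt <- stats::t.test(a, b, var.equal = FALSE)
        res$t[i] <- unname(tt$statistic); res$p[i] <- tt$p.value
        res$tested[i] <- TRUE
      }
    }
  }
  res$p_adj[res$tested] <- stats::p.adjust(res$p[res$tested], method = "BH")
  res
}

#' Same-cell density score
#'
#' For each cell, the mean Euclidean distance to its `k` nearest neighbours
#' of the same cell type (self excluded), divided by the maximal-dispersion
#' spacing of that type, `sqrt(area / N_t)` — the characteristic spacing if
#' the `N_t` cells of the type were spread evenly over the section. Scores
#' near 0 mean tight same-type aggregation; scores near 1 mean the type is as
#' spread out as it could be. Types with `N_t <= k` are flagged missing.
#'
#' @param cellmap A [cell_map()].
#' @param k Number of same-type nearest neighbours (default 5).
#' @param keep_cell_scores Also return the per-cell scores.
#' @return data.frame `sample_id, cell_type, n_cells, mean_score, tested`;
#'   with `keep_cell_scores`, attribute `"cell_scores"` holds a per-cell
#'   data.frame.
#' @export
same_cell_density <- function(cellmap, k = 5L, keep_cell_scores = FALSE) {
  stopifnot(inherits(cellmap, "cell_map"))
  cells <- cellmap$cells
  if (!is.finite(cellmap$area) || cellmap$area <= 0)
    stop("cell map area must be known and > 0")
  types <- sort(unique(cells$cell_type))
  res <- data.frame(sample_id = cells$sample_id[1], cell_type = types,
                    n_cells = NA_integer_, mean_score = NA_real_,
                    tested = FALSE, stringsAsFactors = FALSE)
  per_cell <- list()
  for (i in seq_along(types)) {
    idx <- which(cells$cell_type == types[i])
    nt <- length(idx)
    res$n_cells[i] <- nt
    if (nt <= k) next
    nn <- knn_indices(cells$x[idx], cells$y[idx], k)
    d <- knn_distances(cells$x[idx], cells$y[idx], nn)
    dmax <- sqrt(cellmap$area / nt)
    score <- rowMeans(d) / dmax
    res$mean_score[i] <- mean(score)
    res$tested[i] <- TRUE
    if (keep_cell_scores)
      per_cell[[types[i]]] <- data.frame(cell_id = cells$cell_id[idx],
                                         cell_type = types[i], score = score,
                                         stringsAsFactors = FALSE)
  }
  if (keep_cell_scores)
    attr(res, "cell_scores") <- do.call(rbind, c(per_cell,
                                                 list(make.row.names = FALSE)))
  res
}

#' Pearson correlation of per-donor values with a donor covariate
#'
#' @param per_donor data.frame `donor_id, value` (e.g. a cell-type fraction).
#' @param covariate data.frame `donor_id, covariate` (e.g. BMI).
#' @return list `r`, `p`, `n`; `r` is `NA` with a `"degenerate"` flag when
#'   either vector has zero variance.
#' @export
correlate_with_covariate <- function(per_donor, covariate) {
  stopifnot_cols(per_donor, c("donor_id", "value"), "per_donor")
  stopifnot_cols(covariate, c("donor_id", "covariate"), "covariate")
  m <- merge(per_donor, covariate, by = "donor_id")
  m <- m[stats::complete.cases(m[, c("value", "covariate")]), ]
  if (nrow(m) < 3) stop("need at least 3 paired observations")
  if (stats::var(m$value) == 0 || stats::var(m$covariate) == 0)
    return(list(r = NA_real_, p = NA_real_, n = nrow(m), degenerate = TRUE))
  ct <- stats::cor.test(m$value, m$covariate, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(m),
       degenerate = FALSE)
}
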