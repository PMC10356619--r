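#' Construct a cell map
#'
#' A cell map is one imaged section's worth of segmented cells: coordinates,
#' a cell-type label and sample/donor/region metadata, plus the section area
#' used as the denominator of density statistics. Cells are stored sorted by
#' `cell_id` so that all distance tie-breaks are reproducible.
#'
#' @param cells data.frame with columns `cell_id`, `x`, `y`, `cell_type`,
#'   `sample_id` and optionally `donor_id`, `region`, `group`, `compartment`
#'   (missing optional columns are filled with `"unknown"`).
#' @param area Section area in squared coordinate units; when `NULL` it is
#'   computed as the area of the convex hull of the coordinates.
#' @return An object of class `cell_map`: a list with `cells` (data.frame) and
#'   `area` (scalar).
#' @export
cell_map <- function(cells, area = NULL) {
  stopifnot_cols(cells, c("cell_id", "x", "y", "cell_type", "sample_id"),
                 "cell table")
  cells$cell_id <- as.character(cells$cell_id)
  for (opt in c("donor_id", "region", "group", "compartment")) {
    if (is.null(cells[[opt]])) cells[[opt]] <- "unknown"
    cells[[opt]] <- as.character(cells[[opt]])
  }
  cells$cell_type <- as.character(cells$cell_type)
  if (anyDuplicated(cells$cell_id))
    stop("duplicate cell_id within sample '", cells$sample_id[1], "'")
  if (!is.numeric(cells$x) || !is.numeric(cells$y) ||
      !all(is.finite(cells$x)) || !all(is.finite(cells$y)))
    stop("coordinates must be finite numerics")
  if (any(!nzchar(cells$cell_type)) || anyNA(cells$cell_type))
    stop("every cell_type must be non-empty")
  cells <- cells[order(cells$cell_id), , drop = FALSE]
  rownames(cells) <- NULL
  if (is.null(area)) area <- hull_area(cells$x, cells$y)
  if (!is.finite(area) || area <= 0) stop("area must be > 0")
  structure(list(cells = cells, area = area), class = "cell_map")
}

# convex-hull (shoelace) area of a point set
hull_area <- function(x, y) {
  if (length(unique(paste(x, y))) < 3) return(NA_real_)
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("cell_map: %d cells, %d types, sample '%s', area %.4g\n",
              nrow(x$cells), length(unique(x$cells$cell_type)),
              x$cells$sample_id[1], x$area))
  invisible(x)
}

#' Read a segmented cell table into cell maps
#'
#' Accepts the CSV/TSV output of any segmentation + cell-typing pipeline with
#' one row per cell. The table is split by `sample_id` into one [cell_map()]
#' per imaged section.
#'
#' @param path CSV or TSV file with columns
#'   `cell_id,x,y,cell_type,sample_id[,donor_id,region,group,compartment]`.
#' @param area_override Optional named numeric vector (names = sample ids)
#'   or single value giving the section area; the convex-hull area is used
#'   otherwise.
#' @return Named list of `cell_map` objects, one per `sample_id`.
#' @export
read_cell_table <- function(path, area_override = NULL) {
  if (!file.exists(path)) stop("cell table not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  stopifnot_cols(df, c("cell_id", "x", "y", "cell_type", "sample_id"),
                 basename(path))
  for (cc in c("x", "y")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad))
      stop("non-numeric ", cc, " at row ", bad[1], " of ", basename(path))
    df[[cc]] <- v
  }
  maps <- lapply(split(df, df$sample_id), function(s) {
    ar <- NULL
    if (!is.null(area_override)) {
      ar <- if (is.null(names(area_override))) area_override[1]
            else unname(area_override[s$sample_id[1]])
      if (is.na(ar)) ar <- NULL
    }
    cell_map(s, area = ar)
  })
  maps[order(names(maps))]
}

#' Write cell maps back to a single cell table
#'
#' Inverse of [read_cell_table()]: concatenates the per-sample tables in
#' sample then cell_id order, with a fixed column order, so a read/write
#' round trip reproduces the cell maps field for field.
#'
#' @param cellmaps A `cell_map` or list of them.
#' @param path Output file; `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cellmaps, path) {
  if (inherits(cellmaps, "cell_map")) cellmaps <- list(cellmaps)
  cols <- c("cell_id", "x", "y", "cell_type", "sample_id", "donor_id",
            "region", "group", "compartment")
  df <- do.call(rbind, lapply(cellmaps, function(m) m$cells[, cols]))
  rownames(df) <- NULL
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df$x <- sprintf("%.17g", df$x)   # round-trippable doubles
  df$y <- sprintf("%.17g", df$y)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# pooled cell table across a list of cell maps
pool_cells <- function(cellmaps) {
  do.call(rbind, c(lapply(cellmaps, function(m) m$cells),
                   list(make.row.names = FALSE)))
}
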