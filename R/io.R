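#' Write analysis tables and graphs with a manifest
#'
#' Tables are written as TSV with a header, fixed column order and numeric
#' fields formatted to 6 significant digits; graphs as GraphML. A JSON
#' manifest records file names, row/node counts and a hash of the
#' configuration, so identical inputs + config + seed give byte-identical
#' output trees.
#'
#' @param tables Named list of data.frames (may be empty).
#' @param graphs Named list of `igraph` objects (may be empty).
#' @param out_dir Output directory, created if needed.
#' @param config Optional `analysis_config` recorded (and hashed) in the
#'   manifest.
#' @param force Overwrite existing files (default FALSE: a name collision is
#'   an error).
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
write_results <- function(tables = list(), graphs = list(), out_dir,
                          config = NULL, force = FALSE) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, 2) != 0) stop("output directory not writable: ", out_dir)
  entries <- list()
  emit <- function(fname) {
    p <- file.path(out_dir, fname)
    if (file.exists(p) && !force)
      stop("refusing to overwrite existing file: ", p, " (use force = TRUE)")
    p
  }
  for (nm in names(tables)) {
    p <- emit(paste0(nm, ".tsv"))
    df <- as.data.frame(tables[[nm]])
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], format_num)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    entries[[length(entries) + 1L]] <-
      list(file = paste0(nm, ".tsv"), kind = "table",
           rows = nrow(tables[[nm]]))
  }
  for (nm in names(graphs)) {
    p <- emit(paste0(nm, ".graphml"))
    igraph::write_graph(graphs[[nm]], p, format = "graphml")
    entries[[length(entries) + 1L]] <-
      list(file = paste0(nm, ".graphml"), kind = "graph",
           nodes = igraph::vcount(graphs[[nm]]),
           edges = igraph::ecount(graphs[[nm]]))
  }
  manifest <- list(files = entries,
                   config_hash = if (is.null(config)) NA_character_
                                 else config_hash(config))
  mp <- emit("manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

# md5 of the canonical JSON serialization of a config
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Read a ligand-receptor pair table
#'
#' Two-column CSV in the style of curated ligand-receptor databases
#' (FANTOM5 and successors): `ligand,receptor[,source]`. Duplicate pairs are
#' dropped.
#'
#' @param path CSV file.
#' @return data.frame with columns `ligand`, `receptor`, `source`.
#' @export
read_lr_pairs <- function(path) {
  if (!file.exists(path)) stop("ligand-receptor table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot_cols(df, c("ligand", "receptor"), basename(path))
  if (is.null(df$source)) df$source <- "user"
  if (any(!nzchar(df$ligand)) || any(!nzchar(df$receptor)))
    stop("empty gene name in ligand-receptor table")
  df <- df[!duplicated(df[, c("ligand", "receptor")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write / read a cell x gene expression matrix as dense CSV
#'
#' Annotation columns (`cell_id`, `cell_type`, `group`, `sample_id`) come
#' first, followed by one integer column per gene.
#'
#' @param expr An `expression_matrix` (see [generate_expression()]).
#' @param path CSV file.
#' @return `path` (write) / an `expression_matrix` (read).
#' @export
write_expression <- function(expr, path) {
  df <- cbind(expr$cells, as.data.frame(expr$counts, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ann_cols <- c("cell_id", "cell_type", "group", "sample_id")
  stopifnot_cols(df, ann_cols, basename(path))
  counts <- as.matrix(df[, setdiff(names(df), ann_cols), drop = FALSE])
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, cells = df[, ann_cols]),
            class = "expression_matrix")
}
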