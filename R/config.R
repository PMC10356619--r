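#' Analysis configuration
#'
#' Bundles every tunable constant of the pipeline with the defaults used
#' throughout: composition windows of 10 nearest neighbours overclustered to
#' 30 clusters for multicellular neighbourhoods, windows of 100 (communities)
#' and 300 (tissue units) with 20 clusters, 5 same-type neighbours for the
#' density score, 10 neighbours for the colocalization quotient, the 85%
#' spatial-context rule with a 0.1% plotting frequency floor, the 15%
#' hierarchy-edge threshold, a minimum of 5 observed instances per motif, and
#' 1,000 / 10,000 permutations for motif and ligand-receptor tests.
#'
#' @param k_window_nbhd Window size (cells, incl. the index cell) for
#'   neighbourhood windows.
#' @param k_window_comm Window size for community windows.
#' @param k_window_tissue Window size for tissue-unit windows.
#' @param n_clusters_nbhd Number of k-means clusters for neighbourhood windows.
#' @param n_clusters_comm Number of k-means clusters for community and
#'   tissue-unit windows.
#' @param k_density Number of same-type nearest neighbours in the density score.
#' @param k_clq Number of nearest neighbours in the colocalization quotient.
#' @param context_threshold Cumulative window fraction a spatial-context
#'   combination must reach.
#' @param context_min_freq Minimum combination frequency retained in the
#'   combination graph.
#' @param hierarchy_threshold Minimum share of an upper structure a lower label
#'   must constitute to draw a hierarchy edge.
#' @param motif_min_instances Minimum observed adjacent-instance-pair count for
#'   a motif to be tested.
#' @param n_permutations Permutations for the motif null.
#' @param lr_n_permutations Permutations for the ligand-receptor validation null.
#' @param alpha Significance level for adjusted p-values.
#' @param seed Integer seed used by every stochastic stage.
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(k_window_nbhd = 10L, k_window_comm = 100L,
                            k_window_tissue = 300L, n_clusters_nbhd = 30L,
                            n_clusters_comm = 20L, k_density = 5L,
                            k_clq = 10L, context_threshold = 0.85,
                            context_min_freq = 0.001,
                            hierarchy_threshold = 0.15,
                            motif_min_instances = 5L,
                            n_permutations = 1000L,
                            lr_n_permutations = 10000L,
                            alpha = 0.05, seed = 1L) {
  cfg <- list(
    k_window_nbhd = as.integer(k_window_nbhd),
    k_window_comm = as.integer(k_window_comm),
    k_window_tissue = as.integer(k_window_tissue),
    n_clusters_nbhd = as.integer(n_clusters_nbhd),
    n_clusters_comm = as.integer(n_clusters_comm),
    k_density = as.integer(k_density),
    k_clq = as.integer(k_clq),
    context_threshold = context_threshold,
    context_min_freq = context_min_freq,
    hierarchy_threshold = hierarchy_threshold,
    motif_min_instances = as.integer(motif_min_instances),
    n_permutations = as.integer(n_permutations),
    lr_n_permutations = as.integer(lr_n_permutations),
    alpha = alpha,
    seed = as.integer(seed)
  )
  counts <- c("k_window_nbhd", "k_window_comm", "k_window_tissue",
              "n_clusters_nbhd", "n_clusters_comm", "k_density", "k_clq",
              "motif_min_instances", "n_permutations", "lr_n_permutations")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop("config field '", nm, "' must be a count >= 1")
  }
  fracs <- c("context_threshold", "context_min_freq", "hierarchy_threshold")
  for (nm in fracs) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0 || cfg[[nm]] >= 1)
      stop("config field '", nm, "' must lie in (0, 1)")
  }
  if (!is.finite(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("config field 'alpha' must lie in (0, 1)")
  class(cfg) <- "analysis_config"
  cfg
}

#' Read an analysis configuration from JSON or YAML
#'
#' Unknown fields are rejected; omitted fields keep their defaults.
#'
#' @param path Path to a JSON (`.json`) or YAML (`.yml`/`.yaml`) file whose
#'   keys mirror the arguments of [analysis_config()].
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
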