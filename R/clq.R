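#' Colocalization quotient matrix
#'
#' For every ordered pair of cell types (A, B), the colocalization quotient
#' \deqn{CLQ_{A \to B} = \frac{C_{A \to B} / N_A}{N_B / (N - 1)}}
#' where \eqn{C_{A \to B}} is the average fraction of type-B cells among the
#' `k` nearest neighbours (self excluded) of each type-A cell, `N` the total
#' cell count and \eqn{N_A, N_B} the type counts; for A = B the denominator
#' uses \eqn{(N_A - 1)/(N - 1)}. Under random labelling CLQ is about 1;
#' values above 1 mean B is over-represented next to A. The direction is "B
#' counted among the neighbours of A" (Leslie & Kronenfeld convention).
#'
#' @param cellmap A [cell_map()].
#' @param k Number of nearest neighbours (default 10).
#' @return Numeric types x types matrix (rows = A, cols = B); attributes
#'   `N`, `type_counts`, `C` (the raw mean neighbour fractions), `k`.
#' @export
clq <- function(cellmap, k = 10L) {
  stopifnot(inherits(cellmap, "cell_map"))
  cells <- cellmap$cells
  n <- nrow(cells)
  if (k >= n) stop("k must be smaller than the cell count")
  types <- sort(unique(cells$cell_type))
  idx <- knn_indices(cells$x, cells$y, k)
  clq_from_idx(cells$cell_type, types, idx, k)
}

# CLQ from precomputed neighbour indices (labels may be permuted freely)
clq_from_idx <- function(cell_type, types, idx, k) {
  n <- length(cell_type)
  tc <- as.integer(table(factor(cell_type, levels = types)))
  names(tc) <- types
  code <- match(cell_type, types)
  # mean neighbour-type fractions per focal type
  nb_frac <- matrix(0, nrow = n, ncol = length(types))
  rows <- seq_len(n)
  for (j in seq_len(k)) {
    ij <- cbind(rows, code[idx[, j]])
    nb_frac[ij] <- nb_frac[ij] + 1
  }
  nb_frac <- nb_frac / k
  C <- rowsum(nb_frac, group = code, reorder = TRUE) / tc  # C[A, B]
  dimnames(C) <- list(types, types)
  denom <- matrix(tc, nrow = length(types), ncol = length(types),
                  byrow = TRUE)
  diag(denom) <- tc - 1L              # self-pair: (N_A - 1) / (N - 1)
  m <- C / (denom / (n - 1))
  m[denom <= 0] <- NA_real_           # self-pair needs N_A >= 2
  attr(m, "N") <- n
  attr(m, "type_counts") <- tc
  attr(m, "C") <- C
  attr(m, "k") <- k
  m
}

#' Label-permutation z-scores for CLQ matrices
#'
#' Shuffles the cell-type labels over the fixed coordinates, recomputes the
#' CLQ matrix, and returns per-pair z-scores of the observed CLQ against the
#' permutation null — a calibration diagnostic (z approximately standard
#' normal under random labelling) and an effect-size scale.
#'
#' @param cellmap A [cell_map()].
#' @param k Neighbour count.
#' @param n_permutations Number of label shuffles.
#' @param seed Integer seed.
#' @return List `z` (matrix), `observed`, `null_mean`, `null_sd`.
#' @export
clq_permutation_z <- function(cellmap, k = 10L, n_permutations = 50L,
                              seed = 1L) {
  cells <- cellmap$cells
  types <- sort(unique(cells$cell_type))
  idx <- knn_indices(cells$x, cells$y, k)     # fixed across permutations
  obs <- clq_from_idx(cells$cell_type, types, idx, k)
  s <- obs * 0; s2 <- obs * 0
  with_seed(seed, {
    for (i in seq_len(n_permutations)) {
      v <- clq_from_idx(cells$cell_type[sample.int(nrow(cells))], types,
                        idx, k)
      s <- s + v; s2 <- s2 + v^2
    }
  })
  mu <- s / n_permutations
  sd <- sqrt(pmax(0, s2 / n_permutations - mu^2))
  list(z = (obs - mu) / sd, observed = obs, null_mean = mu, null_sd = sd)
}

#' Cross-group tests of colocalization quotients
#'
#' Welch two-sided t-test per ordered type pair of per-sample CLQ values
#' between the SB and CL groups, Benjamini-Hochberg adjusted across all
#' tested pairs.
#'
#' @param clq_per_sample Named list of [clq()] matrices, one per sample.
#' @param groups Named character vector sample_id -> group (`"SB"`/`"CL"`).
#' @return data.frame `type_a, type_b, mean_SB, mean_CL, t, p, p_adj,
#'   direction, n_SB, n_CL, tested`.
#' @export
clq_group_test <- function(clq_per_sample, groups) {
  stopifnot(length(clq_per_sample) >= 2)
  vals <- list()
  for (sid in names(clq_per_sample)) {
    m <- clq_per_sample[[sid]]
    df <- expand.grid(type_a = rownames(m), type_b = colnames(m),
                      stringsAsFactors = FALSE)
    df$value <- as.vector(m)
    df$unit <- sid
    df$group <- unname(groups[sid])
    vals[[sid]] <- df[!is.na(df$value), , drop = FALSE]
  }
  v <- do.call(rbind, vals)
  v$feature <- paste(v$type_a, v$type_b, sep = "->")
  res <- compare_groups(v[, c("unit", "group", "feature", "value")])
  ab <- strsplit(res$feature, "->", fixed = TRUE)
  res$type_a <- vapply(ab, `[`, "", 1)
  res$type_b <- vapply(ab, `[`, "", 2)
  res$direction <- ifelse(res$mean_CL > res$mean_SB, "CL>SB", "SB>=CL")
  res[, c("type_a", "type_b", "mean_SB", "mean_CL", "t", "p", "p_adj",
          "direction", "n_SB", "n_CL", "tested")]
}
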