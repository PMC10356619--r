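# Independent brute-force oracles (plain R, all-pairs distances) against
# which the package's kd-tree / triangulation implementations are checked.

# random cell map with iid type labels (CSR labelling)
random_map <- function(n, n_types = 4, seed = 1, width = 100, height = 100,
                       sample_id = "S1") {
  withr::with_seed(seed, {
    cell_map(data.frame(
      cell_id = sprintf("%s_c%05d", sample_id, seq_len(n)),
      x = runif(n, 0, width), y = runif(n, 0, height),
      cell_type = sample(LETTERS[seq_len(n_types)], n, replace = TRUE),
      sample_id = sample_id, stringsAsFactors = FALSE),
      area = width * height)
  })
}

# all-pairs kNN indices with (distance, index) ordering, self excluded
bf_knn <- function(x, y, k) {
  n <- length(x)
  t(vapply(seq_len(n), function(i) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    d[i] <- Inf
    order(d, seq_len(n))[seq_len(k)]
  }, integer(k)))
}

bf_windows <- function(cellmap, labels, k, include_self = TRUE) {
  cells <- cellmap$cells
  universe <- sort(unique(labels))
  n <- nrow(cells)
  nb <- if (include_self) k - 1 else k
  idx <- if (nb > 0) bf_knn(cells$x, cells$y, nb) else NULL
  out <- matrix(0, n, length(universe),
                dimnames = list(cells$cell_id, universe))
  for (i in seq_len(n)) {
    members <- if (include_self) c(i, idx[i, ]) else idx[i, ]
    tab <- table(factor(labels[members], levels = universe))
    out[i, ] <- as.numeric(tab) / k
  }
  out
}

bf_clq <- function(cellmap, k) {
  cells <- cellmap$cells
  n <- nrow(cells)
  types <- sort(unique(cells$cell_type))
  idx <- bf_knn(cells$x, cells$y, k)
  m <- matrix(NA_real_, length(types), length(types),
              dimnames = list(types, types))
  for (a in types) {
    ai <- which(cells$cell_type == a)
    for (b in types) {
      cab <- mean(vapply(ai, function(i)
        sum(cells$cell_type[idx[i, ]] == b) / k, 0))
      nb <- sum(cells$cell_type == b) - (a == b)
      if (nb <= 0) next
      m[a, b] <- cab / (nb / (n - 1))
    }
  }
  m
}

bf_enrichment <- function(upper_labels, lower_labels) {
  us <- sort(unique(upper_labels)); ls <- sort(unique(lower_labels))
  n <- length(upper_labels)
  out <- matrix(NA_real_, length(us), length(ls), dimnames = list(us, ls))
  for (u in us) {
    inu <- upper_labels == u
    for (l in ls) {
      out[u, l] <- (sum(inu & lower_labels == l) / sum(inu)) /
                   (sum(lower_labels == l) / n)
    }
  }
  out
}

bf_context <- function(cellmap, labels, k, threshold = 0.85) {
  w <- bf_windows(cellmap, labels, k, include_self = TRUE)
  combos <- apply(w, 1, function(v) {
    o <- order(-v, colnames(w))
    cs <- cumsum(v[o])
    m <- which(cs >= threshold - 1e-12)[1]
    paste(sort(colnames(w)[o[seq_len(m)]]), collapse = "+")
  })
  table(combos)
}

# adjacency of cell pairs at distance <= max_edge restricted to a given
# edge set is not reproducible without the triangulation, so the instance
# oracle recomputes components from the same pruned edge list but with an
# independent union-find
bf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(edges)) for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, 0L)
}
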