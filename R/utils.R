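# Internal helpers shared across modules.

# k nearest neighbours with deterministic tie-breaking.
# Returns an n x k integer matrix of neighbour indices into (x, y), self
# excluded, each row ordered by (distance, index). `query` may name a subset
# of indices to search from (default: all points, self excluded per row).
# Ties at the k-th distance are resolved by ascending index, which equals
# cell_id order when callers sort cells by cell_id first.
knn_indices <- function(x, y, k, query = NULL) {
  n <- length(x)
  pts <- cbind(x, y)
  if (is.null(query)) query <- seq_len(n)
  if (k >= n) stop("k must be smaller than the number of points")
  # fetch extra neighbours so boundary ties can be re-broken by index
  kk <- min(n, k + 1L + 8L)
  nn <- RANN::nn2(pts, pts[query, , drop = FALSE], k = kk)
  idx <- nn$nn.idx
  d <- nn$nn.dists
  out <- matrix(0L, nrow = length(query), ncol = k)
  for (i in seq_along(query)) {
    ii <- idx[i, ]
    dd <- d[i, ]
    keep <- ii != query[i]
    ii <- ii[keep]
    dd <- dd[keep]
    o <- order(dd, ii)
    sel <- o[seq_len(k)]
    # exactness guard: if the (k+extra) window was saturated by ties we fall
    # back to a full scan for this row
    if (length(o) > k && dd[o[k]] == dd[o[length(o)]] && kk < n) {
      alld <- sqrt((x - x[query[i]])^2 + (y - y[query[i]])^2)
      alld[query[i]] <- Inf
      o2 <- order(alld, seq_len(n))
      out[i, ] <- o2[seq_len(k)]
    } else {
      out[i, ] <- ii[sel]
    }
  }
  out
}

# distances paired with knn_indices output
knn_distances <- function(x, y, idx, query = NULL) {
  if (is.null(query)) query <- seq_len(length(x))
  d <- matrix(0, nrow = nrow(idx), ncol = ncol(idx))
  for (j in seq_len(ncol(idx))) {
    d[, j] <- sqrt((x[idx[, j]] - x[query])^2 + (y[idx[, j]] - y[query])^2)
  }
  d
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Format numbers for stable TSV output: 6 significant digits, no scientific
# notation drift across platforms.
format_num <- function(v) {
  ifelse(is.na(v), "NA", formatC(v, digits = 6, format = "g"))
}

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing mandatory column(s): ", paste(miss, collapse = ", "))
}
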