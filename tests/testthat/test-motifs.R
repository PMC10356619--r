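# blob helper: square patch of one label at an offset
blob <- function(label, cx, cy, n = 20, spread = 5, seed = 1) {
  withr::with_seed(seed, data.frame(
    x = runif(n, cx - spread, cx + spread),
    y = runif(n, cy - spread, cy + spread),
    lab = label))
}

blob_map <- function(..., sample_id = "s1") {
  b <- do.call(rbind, list(...))
  cells <- data.frame(cell_id = sprintf("%s_c%03d", sample_id, seq_len(nrow(b))),
                      x = b$x, y = b$y, cell_type = b$lab,
                      sample_id = sample_id)
  m <- cell_map(cells, area = diff(range(b$x)) * diff(range(b$y)))
  list(map = m, assignment = type_assignment(m))
}

test_that("compact blobs become single instances; far blobs stay unlinked", {
  one <- blob_map(blob("A", 10, 10, seed = 1))
  g1 <- label_instances(one$map, one$assignment, max_edge = 10)
  expect_equal(nrow(g1$instances), 1)
  expect_equal(nrow(g1$edges), 0)
  two <- blob_map(blob("A", 10, 10, seed = 2), blob("A", 300, 10, seed = 3))
  g2 <- label_instances(two$map, two$assignment, max_edge = 20)
  expect_equal(nrow(g2$instances), 2)
  expect_equal(nrow(g2$edges), 0)          # gap exceeds max_edge
  expect_true(all(g2$instances$label == "A"))
})

test_that("instance adjacency matches brute-force components and linking", {
  trio <- blob_map(blob("A", 10, 10, seed = 4), blob("B", 22, 10, seed = 5),
                   blob("C", 400, 400, seed = 6))
  g <- label_instances(trio$map, trio$assignment, max_edge = 15)
  expect_equal(nrow(g$instances), 3)
  edf <- g$edges
  labs <- setNames(g$instances$label, g$instances$instance_id)
  pairs <- sort(paste(pmin(labs[edf$from], labs[edf$to]),
                      pmax(labs[edf$from], labs[edf$to])))
  expect_equal(pairs, "A B")               # only A and B touch
  # oracle: same pruned edge list, independent union-find components
  cells <- trio$map$cells
  adj <- tissuearch:::cell_adjacency(cells$x, cells$y, 15)
  same <- adj[cells$cell_type[adj[, 1]] == cells$cell_type[adj[, 2]], ,
              drop = FALSE]
  comp <- bf_components(nrow(cells), same)
  keep <- as.integer(names(which(table(comp) >= 3)))
  expect_equal(length(keep), 3)
  got_members <- lapply(g$members, sort)
  want_members <- lapply(keep, function(k) sort(cells$cell_id[comp == k]))
  expect_setequal(lapply(want_members, paste, collapse = ","),
                  lapply(got_members, paste, collapse = ","))
})

test_that("instances respect the minimum cell count", {
  mini <- blob_map(blob("A", 10, 10, n = 2, seed = 7),
                   blob("B", 30, 30, n = 20, seed = 8))
  g <- label_instances(mini$map, mini$assignment, max_edge = 15,
                       min_cells = 3)
  expect_equal(g$instances$label, "B")     # the 2-cell A patch is dropped
})

test_that("degenerate (duplicated) point sets fall back to kNN adjacency", {
  cells <- data.frame(cell_id = sprintf("c%02d", 1:12),
                      x = rep(c(0, 1, 2), 4), y = rep(c(0, 1), each = 6),
                      cell_type = rep(c("A", "B"), each = 6),
                      sample_id = "s")
  cells$x[4] <- cells$x[1]; cells$y[4] <- cells$y[1]  # exact duplicate
  m <- cell_map(cells, area = 10)
  expect_warning(g <- label_instances(m, type_assignment(m), max_edge = 5),
                 "degenerate")
  expect_gte(nrow(g$instances), 1)
})

test_that("unions concatenate instances and ids must not collide", {
  a <- blob_map(blob("A", 10, 10, seed = 9), blob("B", 30, 10, seed = 10),
                sample_id = "s1")
  b <- blob_map(blob("A", 10, 10, seed = 11), blob("B", 30, 10, seed = 12),
                blob("C", 60, 10, seed = 13), sample_id = "s2")
  ga <- label_instances(a$map, a$assignment, max_edge = 15)
  gb <- label_instances(b$map, b$assignment, max_edge = 15)
  u <- union_graphs(list(ga, gb))
  expect_equal(nrow(u$instances), nrow(ga$instances) + nrow(gb$instances))
  expect_equal(nrow(u$edges), nrow(ga$edges) + nrow(gb$edges))
  expect_error(union_graphs(list(ga, ga)), "collision")
  # no cross edges -> motif counts add over the union
  ca <- motif_test(ga, 100, seed = 1, min_instances = 1)
  cb <- motif_test(gb, 100, seed = 1, min_instances = 1)
  cu <- motif_test(u, 100, seed = 1, min_instances = 1)
  for (i in seq_len(nrow(cu))) {
    oa <- ca$observed[ca$label_a == cu$label_a[i] & ca$label_b == cu$label_b[i]]
    ob <- cb$observed[cb$label_a == cu$label_a[i] & cb$label_b == cu$label_b[i]]
    expect_equal(cu$observed[i], sum(oa, ob))
  }
})

test_that("motif counts are symmetric and p-values seed-deterministic", {
  maps <- lapply(1:3, function(i)
    blob_map(blob("A", 10, 10, seed = i), blob("B", 22, 10, seed = i + 10),
             blob("A", 40, 10, seed = i + 20), sample_id = paste0("s", i)))
  u <- union_graphs(lapply(maps, function(x)
    label_instances(x$map, x$assignment, max_edge = 15)))
  r1 <- motif_test(u, 200, seed = 3, min_instances = 1)
  r2 <- motif_test(u, 200, seed = 3, min_instances = 1)
  expect_identical(r1, r2)
  # each unordered pair appears once; minimum attainable p respected
  expect_false(any(duplicated(paste(r1$label_a, r1$label_b))))
  expect_true(all(r1$label_a <= r1$label_b))
  expect_gte(min(r1$p, na.rm = TRUE), 1 / 201)
  expect_true(all(r1$p_adj >= r1$p, na.rm = TRUE))
})

test_that("pairs below the instance floor are flagged untested", {
  x <- blob_map(blob("A", 10, 10, seed = 1), blob("B", 22, 10, seed = 2))
  g <- label_instances(x$map, x$assignment, max_edge = 15)
  r <- motif_test(g, 100, seed = 1, min_instances = 5)
  ab <- r[r$label_a == "A" & r$label_b == "B", ]
  expect_equal(ab$observed, 1)             # one adjacent pair only
  expect_false(ab$tested)
  expect_true(is.na(ab$p))
})

test_that("a planted checkerboard pair is detected after Bonferroni", {
  # alternating A/B patches in a row, plus far-away distractor labels
  hits <- vapply(1:50, function(s) {
    blobs <- lapply(0:7, function(i)
      blob(if (i %% 2 == 0) "A" else "B", 12 * i + 10, 10, n = 10,
           spread = 4, seed = s * 100 + i))
    blobs <- c(blobs, lapply(0:5, function(i)
      blob(paste0("D", i %% 3), 12 * i + 10, 500, n = 10, spread = 4,
           seed = s * 100 + 50 + i)))
    x <- do.call(blob_map, c(blobs, list(sample_id = paste0("s", s))))
    g <- label_instances(x$map, x$assignment, max_edge = 12)
    r <- motif_test(g, 1000, seed = s, min_instances = 5)
    ab <- r[r$label_a == "A" & r$label_b == "B", ]
    nrow(ab) == 1 && isTRUE(ab$tested) && !is.na(ab$p_adj) && ab$p_adj < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("the permutation null preserves graph and label multiset", {
  # the null only relabels instances: observed pair counts over all pairs
  # must sum to the fixed edge count in every draw; spot-check via the
  # reported null means
  x <- blob_map(blob("A", 10, 10, seed = 1), blob("B", 22, 10, seed = 2),
                blob("A", 34, 10, seed = 3), blob("B", 46, 10, seed = 4))
  g <- label_instances(x$map, x$assignment, max_edge = 15)
  r <- motif_test(g, 500, seed = 9, min_instances = 1)
  expect_equal(sum(r$null_mean), nrow(g$edges))
  expect_equal(sum(r$observed), nrow(g$edges))
})
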