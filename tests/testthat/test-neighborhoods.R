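test_that("windows over a homogeneous map are one-hot", {
  m <- random_map(50, n_types = 1, seed = 1)
  w <- composition_windows(m, k = 10)
  expect_true(all(w[, "A"] == 1))
})

test_that("windows match the all-pairs brute force on a listed toy map", {
  cells <- data.frame(
    cell_id = sprintf("c%d", 1:8),
    x = c(0, 1, 0, 1, 10, 11, 10, 11), y = c(0, 0, 1, 1, 0, 0, 1, 1),
    cell_type = c("A", "A", "B", "B", "A", "B", "B", "B"),
    sample_id = "s")
  m <- cell_map(cells, area = 121)
  w <- composition_windows(m, k = 4)
  bf <- bf_windows(m, m$cells$cell_type, 4)
  expect_equal(unclass(w)[, colnames(bf)], bf, ignore_attr = TRUE)
  # and with the index cell excluded from its own window
  w2 <- composition_windows(m, k = 4, include_self = FALSE)
  bf2 <- bf_windows(m, m$cells$cell_type, 4, include_self = FALSE)
  expect_equal(unclass(w2)[, colnames(bf2)], bf2, ignore_attr = TRUE)
})

test_that("window rows sum to one and ignore input cell order", {
  for (s in 1:10) {
    m <- random_map(100, n_types = 3, seed = s)
    w <- composition_windows(m, k = 7)
    expect_lt(max(abs(rowSums(w) - 1)), 1e-9)
  }
  m <- random_map(60, n_types = 3, seed = 21)
  shuf <- withr::with_seed(1, m$cells[sample(nrow(m$cells)), ])
  m2 <- cell_map(shuf, area = m$area)
  w1 <- composition_windows(m, k = 6)
  w2 <- composition_windows(m2, k = 6)
  expect_equal(w1[order(rownames(w1)), ], w2[order(rownames(w2)), ],
               ignore_attr = TRUE)
})

test_that("clustering separates planted compositions and is deterministic", {
  w <- rbind(matrix(rep(c(0.9, 0.1), each = 30), ncol = 2),
             matrix(rep(c(0.1, 0.9), each = 30), ncol = 2))
  w <- w + withr::with_seed(2, matrix(rnorm(120, 0, 0.01), ncol = 2))
  rownames(w) <- sprintf("c%02d", 1:60)
  a1 <- cluster_windows(w, 2, seed = 5)
  truth <- rep(1:2, each = 30)
  expect_equal(mclust::adjustedRandIndex(a1$label, truth), 1)
  a2 <- cluster_windows(w, 2, seed = 5)
  expect_identical(a1$label, a2$label)
  expect_error(cluster_windows(w, 100, seed = 1), "distinct")
})

test_that("per-group clustering prefixes labels and keeps groups separate", {
  w <- matrix(runif(80), ncol = 2,
              dimnames = list(sprintf("c%02d", 1:40), c("A", "B")))
  gb <- rep(c("SB", "CL"), each = 20)
  a <- cluster_windows(w, 2, seed = 1, group_by = gb)
  expect_true(all(grepl("^(SB|CL)\\.", a$label)))
  expect_equal(nrow(a), 40)
})

test_that("merge mappings relabel, must be surjective onto their image", {
  a <- label_assignment(sprintf("c%d", 1:6),
                        c("n1", "n1", "n2", "n2", "n3", "n3"), "nbhd")
  idm <- setNames(c("n1", "n2", "n3"), c("n1", "n2", "n3"))
  expect_identical(merge_clusters(a, idm)$label, a$label)
  mg <- setNames(c("u", "u", "v"), c("n1", "n2", "n3"))
  merged <- merge_clusters(a, mg)
  expect_setequal(unique(merged$label), c("u", "v"))
  expect_error(merge_clusters(a, mg[1:2]), "n3")
})

test_that("merged enrichment equals the cell-weighted constituent average", {
  m <- random_map(400, n_types = 3, seed = 9)
  w <- composition_windows(m, k = 8)
  a <- cluster_windows(w, 6, seed = 1)
  ct <- type_assignment(m)
  e6 <- enrichment_matrix(a, ct)
  mg <- setNames(c("u1", "u1", "u1", "u2", "u2", "u2"),
                 sort(unique(a$label)))
  e2 <- enrichment_matrix(merge_clusters(a, mg), ct)
  wts <- attr(e6, "weights")
  for (u in c("u1", "u2")) {
    parts <- names(mg)[mg == u]
    ww <- wts[parts] / sum(wts[parts])
    expect_equal(e2[u, ], colSums(e6[parts, , drop = FALSE] * ww),
                 tolerance = 1e-12)
  }
})

test_that("enrichment matches forced arithmetic and conserves mass", {
  lab <- c(rep("u1", 2), rep("u2", 6))
  ct <- c("A", "B", rep(c("A", "B", "B", "B"), 1), "B", "B")
  up <- label_assignment(sprintf("c%d", 1:8), lab, "up")
  lo <- label_assignment(sprintf("c%d", 1:8), ct, "cell_type")
  e <- enrichment_matrix(up, lo)
  # u1 is 50% A, overall A is 25% -> enrichment 2
  expect_equal(e["u1", "A"], 2)
  single <- label_assignment(sprintf("c%d", 1:8), rep("u", 8), "up")
  expect_true(all(enrichment_matrix(single, lo) == 1))
  for (s in 1:10) {
    m <- random_map(200, n_types = 4, seed = s)
    w <- composition_windows(m, k = 5)
    a <- cluster_windows(w, 4, seed = s)
    em <- enrichment_matrix(a, type_assignment(m))
    wsum <- colSums(em * attr(em, "weights"))
    expect_lt(max(abs(wsum - 1)), 1e-6)
    bf <- bf_enrichment(a$label[match(m$cells$cell_id, a$cell_id)],
                        m$cells$cell_type)
    expect_equal(unclass(em), bf[rownames(em), colnames(em)],
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("enrichment deviations from 1 shrink with map size under shuffling", {
  dev <- vapply(c(1000, 10000), function(n) {
    m <- random_map(n, n_types = 4, seed = 3)
    shuffled <- m
    shuffled$cells$cell_type <- withr::with_seed(4,
      sample(m$cells$cell_type))
    w <- composition_windows(shuffled, k = 10)
    a <- cluster_windows(w, 5, seed = 1)
    em <- enrichment_matrix(a, type_assignment(shuffled))
    max(abs(em - 1))
  }, 0)
  expect_lt(dev[2], dev[1])
})

test_that("conservation delta is zero at equality and ranks planted change", {
  e <- matrix(c(1, 2, 0.5, 1), 2, 2,
              dimnames = list(c("u1", "u2"), c("A", "B")))
  cd <- conservation_delta(e, e)
  expect_true(all(cd$delta == 0))
  e2 <- e; e2["u2", "B"] <- e2["u2", "B"] + 1
  cd2 <- conservation_delta(e2, e)
  expect_equal(cd2$row_order[1], "u2")
  expect_equal(cd2$col_order[1], "B")
})

test_that("group-restricted crypt dominates the conservation delta", {
  tpl <- list(
    zones = list(zone_spec("z", c(0, 1), 0.03,
                           c(A = 0.55, B = 0.40, P = 0.05))),
    structures = list(crypt_spec(rbind(c(130, 130), c(350, 350),
                                       c(130, 370)), 70,
                                 c(P = 0.9, A = 0.1), "P",
                                 anchor_count = 3, group = "SB")))
  coh <- generate_cohort(cohort_config(donors = 2, template = tpl,
                                       deltas = list(SB = NULL, CL = NULL),
                                       noise = 0, width = 500, height = 500,
                                       seed = 42))
  grp <- vapply(coh$cellmaps, function(m) m$cells$group[1], "")
  universe <- c("A", "B", "P")
  wins <- do.call(rbind, lapply(coh$cellmaps, composition_windows, k = 10,
                                label_universe = universe))
  nb <- cluster_windows(wins, 6, seed = 1)
  emat <- function(g) {
    ids <- unlist(lapply(coh$cellmaps[grp == g],
                         function(m) m$cells$cell_id))
    sub <- nb[nb$cell_id %in% ids, ]
    ctypes <- unlist(lapply(coh$cellmaps[grp == g],
                            function(m) m$cells$cell_type))
    up <- label_assignment(sub$cell_id, sub$label, "nbhd")
    lo <- label_assignment(ids, ctypes, "cell_type")
    enrichment_matrix(up, lo)
  }
  cd <- conservation_delta(emat("SB"), emat("CL"))
  # the least-conserved neighbourhood must be the crypt-like (P-enriched) one
  e_sb <- emat("SB")
  crypt_label <- rownames(e_sb)[which.max(e_sb[, "P"])]
  expect_equal(cd$row_order[1], crypt_label)
})

test_that("concentric profiles match the hand-countable ring toy", {
  # one anchor; 6 B cells on a ring of radius 5; 6 C cells beyond max radius
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  cells <- data.frame(
    cell_id = sprintf("c%02d", 1:13),
    x = c(0, 5 * cos(th), 40 + 3 * cos(th)),
    y = c(0, 5 * sin(th), 40 + 3 * sin(th)),
    cell_type = c("P", rep("B", 6), rep("C", 6)), sample_id = "s")
  m <- cell_map(cells, area = 2500)
  prof <- concentric_enrichment(m, "P", radii = c(2, 6, 10))
  b6 <- prof[prof$radius == 6 & prof$cell_type == "B", ]
  expect_equal(b6$enrichment, 2)          # fraction 1 vs overall 0.5
  expect_equal(b6$count, 6)
  r2 <- prof[prof$radius == 2, ]
  expect_true(all(r2$count == 0))         # nothing inside the smallest disk
  # cumulative counts are non-decreasing in radius
  for (tt in unique(prof$cell_type))
    expect_true(all(diff(prof$count[prof$cell_type == tt]) >= 0))
  expect_error(concentric_enrichment(m, "Z", c(1, 2)), "anchor")
})

test_that("suggested merges group correlated enrichment profiles", {
  prof <- rbind(a = c(5, 1, 0.2), b = c(4.8, 1.1, 0.25),
                c = c(0.1, 0.9, 6), d = c(0.2, 1, 5.5))
  mg <- suggest_merges(prof, cor_threshold = 0.9)
  expect_equal(mg[["a"]], mg[["b"]])
  expect_equal(mg[["c"]], mg[["d"]])
  expect_false(mg[["a"]] == mg[["c"]])
})
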