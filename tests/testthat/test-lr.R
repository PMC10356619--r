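test_that("CLQ reproduces the printed-formula toys", {
  m <- cell_map(data.frame(cell_id = c("a1", "b1", "b2"),
                           x = c(0, 1, 2), y = 0,
                           cell_type = c("A", "B", "B"), sample_id = "s"),
                area = 2)
  q <- clq(m, k = 1)
  expect_equal(q["A", "B"], 1)             # (1/1) / (2/2)
  far <- cell_map(data.frame(cell_id = sprintf("c%d", 1:4),
                             x = c(0, 1, 100, 101), y = 0,
                             cell_type = c("A", "A", "B", "B"),
                             sample_id = "s"), area = 101)
  q2 <- clq(far, k = 1)
  expect_equal(q2["A", "B"], 0)            # fully segregated
  expect_gt(q2["A", "A"], 0)
})

test_that("CLQ matches the all-pairs brute force on a random map", {
  m <- random_map(150, n_types = 3, seed = 31)
  expect_lt(max(abs(clq(m, 10) - bf_clq(m, 10)), na.rm = TRUE), 1e-12)
  # single-cell self pair undefined
  cells <- m$cells
  cells$cell_type[1] <- "Z"
  mz <- cell_map(cells, area = m$area)
  expect_true(is.na(clq(mz, 5)["Z", "Z"]))
})

test_that("CLQ is invariant to translation, rotation and uniform scaling", {
  m <- random_map(200, n_types = 3, seed = 32)
  base <- clq(m, 8)
  cells <- m$cells
  th <- 1.1; s <- 2.4
  cells2 <- cells
  cells2$x <- s * (cos(th) * cells$x - sin(th) * cells$y) + 17
  cells2$y <- s * (sin(th) * cells$x + cos(th) * cells$y) - 3
  expect_equal(unclass(clq(cell_map(cells2, area = m$area * s^2), 8)),
               unclass(base), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("group CLQ tests flag the planted attraction pair", {
  zones <- list(zone_spec("z", c(0, 1), 0.02,
                          c(Plasma = 0.3, TA = 0.3, Other = 0.4)))
  hits <- vapply(1:20, function(s) {
    maps <- list()
    for (d in 1:4) {
      maps[[paste0("sb", d)]] <- generate_tissue(
        zones, list(), width = 400, height = 400, noise = 0,
        seed = s * 100 + d, sample_id = paste0("sb", d), group = "SB")
      maps[[paste0("cl", d)]] <- generate_tissue(
        zones, list(attraction_spec("Plasma", "TA", 0.5, 8)),
        width = 400, height = 400, noise = 0, seed = s * 100 + 50 + d,
        sample_id = paste0("cl", d), group = "CL")
    }
    groups <- vapply(maps, function(m) m$cells$group[1], "")
    res <- clq_group_test(lapply(maps, clq, k = 10), groups)
    row <- res[res$type_a == "Plasma" & res$type_b == "TA", ]
    isTRUE(row$tested) && row$p_adj < 0.05 && row$direction == "CL>SB"
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("group-permuted CLQ tests reject at about the nominal rate", {
  maps <- lapply(1:8, function(d) {
    m <- random_map(400, n_types = 3, seed = 300 + d,
                    sample_id = paste0("s", d))
    m
  })
  names(maps) <- paste0("s", 1:8)
  qs <- lapply(maps, clq, k = 10)
  withr::with_seed(77, {
    ps <- replicate(200, {
      groups <- setNames(sample(rep(c("SB", "CL"), 4)), names(maps))
      clq_group_test(qs, groups)$p
    })
  })
  rate <- mean(ps < 0.05, na.rm = TRUE)
  n <- sum(!is.na(ps))
  band <- qbinom(c(0.025, 0.975), n, 0.05) / n
  expect_gte(rate, band[1] * 0.8); expect_lte(rate, band[2] * 1.2)
})

test_that("vectorized rank-sum matches wilcox.test with ties", {
  withr::with_seed(41, {
    mat <- matrix(rnbinom(600, mu = 4, size = 2), ncol = 3,
                  dimnames = list(NULL, c("g1", "g2", "g3")))
  })
  i1 <- 1:80; i2 <- 81:200
  p2 <- tissuearch:::rank_sum_p(mat, i1, i2, "two.sided")
  pg <- tissuearch:::rank_sum_p(mat, i1, i2, "greater")
  for (g in 1:3) {
    expect_equal(p2[g],
                 wilcox.test(mat[i1, g], mat[i2, g], exact = FALSE)$p.value,
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(pg[g],
                 wilcox.test(mat[i1, g], mat[i2, g], exact = FALSE,
                             alternative = "greater")$p.value,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

make_lr_setup <- function(n_pairs = 20, n_hit = 4, lfc = 1.5,
                          cells_per_arm = 500, seed = 1) {
  genes <- c(sprintf("L%02d", seq_len(n_pairs)),
             sprintf("R%02d", seq_len(n_pairs)))
  pairs <- data.frame(ligand = sprintf("L%02d", seq_len(n_pairs)),
                      receptor = sprintf("R%02d", seq_len(n_pairs)),
                      source = "synthetic")
  hit <- seq_len(n_hit)
  effects <- if (n_hit == 0) NULL else rbind(
    data.frame(gene = sprintf("L%02d", hit), cell_type = "Plasma",
               group = "CL", log2fc = lfc),
    data.frame(gene = sprintf("R%02d", hit), cell_type = "TA",
               group = "CL", log2fc = lfc))
  cfg <- expression_config(genes, cell_types = c("Plasma", "TA"),
                           baseline_mean = 5, dispersion = 2,
                           effects = effects,
                           cells_per_type_per_group = cells_per_arm)
  list(expr = generate_expression(cfg, seed = seed), pairs = pairs,
       hit = sprintf("L%02d", hit))
}

test_that("nomination requires both genes up and significant", {
  s <- make_lr_setup(n_pairs = 10, n_hit = 3, seed = 5)
  cp <- data.frame(type_l = "Plasma", type_r = "TA")
  nom <- lr_differential(s$expr, s$pairs, cp)
  expect_setequal(nom$ligand, s$hit)
  expect_true(all(nom$ligand_log2fc > 0 & nom$receptor_log2fc > 0))
  # ligand up but receptor flat -> not nominated
  half <- s$pairs
  half$receptor <- rev(half$receptor)  # pair hits' ligands with flat receptors
  nomh <- lr_differential(s$expr, half, cp)
  expect_false(any(nomh$ligand %in% s$hit &
                   !(nomh$receptor %in% sub("L", "R", s$hit))))
})

test_that("swapped group labels nominate at no more than the alpha rate", {
  s <- make_lr_setup(n_pairs = 20, n_hit = 0, cells_per_arm = 200, seed = 6)
  cp <- data.frame(type_l = "Plasma", type_r = "TA")
  n_nom <- vapply(1:20, function(i) {
    e <- s$expr
    e$cells$group <- withr::with_seed(i, sample(e$cells$group))
    nrow(lr_differential(e, s$pairs, cp))
  }, 0L)
  expect_gte(mean(n_nom == 0), 0.95)
})

test_that("missing genes are skipped with a warning", {
  s <- make_lr_setup(n_pairs = 5, n_hit = 2, cells_per_arm = 100, seed = 7)
  pairs2 <- rbind(s$pairs, data.frame(ligand = "NOPE", receptor = "R01",
                                      source = "synthetic"))
  expect_warning(lr_differential(s$expr, pairs2,
                                 data.frame(type_l = "Plasma",
                                            type_r = "TA")), "NOPE")
})

test_that("validation permutation p has the add-one floor and detects signal", {
  s <- make_lr_setup(n_pairs = 15, n_hit = 5, cells_per_arm = 300, seed = 8)
  cp <- data.frame(type_l = "Plasma", type_r = "TA")
  nom <- lr_differential(s$expr, s$pairs, cp)
  expect_gte(nrow(nom), 3)
  val <- make_lr_setup(n_pairs = 15, n_hit = 5, cells_per_arm = 300,
                       seed = 9)$expr   # independent draw, same effects
  res <- success_rate_permutation(val, nom, n_permutations = 999, seed = 1)
  expect_gte(res$observed, 1)
  expect_lt(res$p, 0.01)
  expect_gte(res$p, 1 / 1000)            # +1-corrected floor
  expect_equal(res$n_matching, nrow(nom))
  # unmatched predictions are dropped and counted
  nom2 <- rbind(nom[, c("cell_type_l", "cell_type_r", "ligand", "receptor")],
                data.frame(cell_type_l = "Ghost", cell_type_r = "TA",
                           ligand = "L01", receptor = "R01"))
  res2 <- success_rate_permutation(val, nom2, n_permutations = 199, seed = 2)
  expect_equal(res2$n_dropped, 1)
})
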