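#' @name synthetic-specs
#' @title Building blocks for synthetic tissue
#'
#' @description
#' Seeded generators that emulate the statistical structure of cell-typed
#' multiplexed-imaging data of layered intestine: horizontal zonation bands
#' (mucosa / submucosa / muscularis), crypt units carrying a rare anchor type
#' at their base, lymphoid follicles with distinct inner and outer zones,
#' dense bands, and an explicit "attraction" structure that relocates a
#' fraction of one cell type next to another to plant a known colocalization
#' signal. Positions are drawn from a homogeneous Poisson process per zone so
#' nearest-neighbour distances have realistic variance; a final noise step
#' resamples a fraction of cell types uniformly, strictly degrading spatial
#' signal.
#'
#' `zone_spec()` describes one horizontal band; `crypt_spec()`,
#' `follicle_spec()`, `band_spec()` and `attraction_spec()` describe
#' structures layered on top. All compositions are named probability vectors
#' (renormalized if slightly off 1; an error beyond 1e-9 of mass).
NULL

norm_comp <- function(p, what = "composition") {
  if (is.null(names(p)) || any(!nzchar(names(p))))
    stop(what, " must be a named probability vector")
  if (any(p < 0)) stop(what, " has negative entries")
  s <- sum(p)
  if (abs(s - 1) > 1e-9) stop(what, " must sum to 1 (got ", format(s), ")")
  p / s
}

#' @rdname synthetic-specs
#' @param name Zone name (also written to the cells' `compartment` field).
#' @param y_range Length-2 fraction pair in \[0,1\] of tissue height.
#' @param intensity Poisson intensity, cells per squared coordinate unit.
#' @param composition Named probability vector over cell types.
#' @export
zone_spec <- function(name, y_range, intensity, composition) {
  stopifnot(length(y_range) == 2, y_range[1] < y_range[2],
            y_range[1] >= 0, y_range[2] <= 1, intensity > 0)
  list(kind = "zone", name = name, y_range = y_range, intensity = intensity,
       composition = norm_comp(composition, paste0("zone '", name, "'")))
}

#' @rdname synthetic-specs
#' @param centers Two-column matrix (or length-2 vector) of circle centres in
#'   coordinate units.
#' @param radius Circle radius (> 0), coordinate units.
#' @param anchor_type Cell type placed exactly at each crypt base.
#' @param anchor_count Anchors per crypt.
#' @param group Restrict the structure to samples of this group
#'   (`NULL` = all samples).
#' @export
crypt_spec <- function(centers, radius, composition, anchor_type,
                       anchor_count = 3L, group = NULL) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  stopifnot(radius > 0, anchor_count >= 0)
  list(kind = "crypt", centers = centers, radius = radius,
       composition = norm_comp(composition, "crypt composition"),
       anchor_type = anchor_type, anchor_count = as.integer(anchor_count),
       group = group)
}

#' @rdname synthetic-specs
#' @param center Length-2 centre of the follicle.
#' @param r_inner,r_outer Inner and outer radii (0 < r_inner < r_outer).
#' @param inner_composition,outer_composition Named probability vectors for
#'   the two follicle zones.
#' @export
follicle_spec <- function(center, r_inner, r_outer, inner_composition,
                          outer_composition, group = NULL) {
  stopifnot(length(center) == 2, r_inner > 0, r_outer > r_inner)
  list(kind = "follicle", center = as.numeric(center), r_inner = r_inner,
       r_outer = r_outer,
       inner_composition = norm_comp(inner_composition, "inner follicle"),
       outer_composition = norm_comp(outer_composition, "outer follicle"),
       group = group)
}

#' @rdname synthetic-specs
#' @param y_band Length-2 pair, absolute y extent of the band in coordinate
#'   units.
#' @export
band_spec <- function(y_band, composition, group = NULL) {
  stopifnot(length(y_band) == 2, y_band[1] < y_band[2])
  list(kind = "band", y_band = as.numeric(y_band),
       composition = norm_comp(composition, "band composition"),
       group = group)
}

#' @rdname synthetic-specs
#' @param source_type,target_type Cell types: a `strength` fraction of
#'   source cells is relocated to within `radius` of a random target cell.
#' @param strength Relocation probability in \[0,1\].
#' @export
attraction_spec <- function(source_type, target_type, strength, radius,
                            group = NULL) {
  stopifnot(strength >= 0, strength <= 1, radius > 0)
  list(kind = "attraction", source_type = source_type,
       target_type = target_type, strength = strength, radius = radius,
       group = group)
}

sample_types <- function(n, comp) {
  if (n == 0L) return(character(0))
  sample(names(comp), n, replace = TRUE, prob = comp)
}

#' Generate one synthetic tissue section
#'
#' @param zones List of [zone_spec()]s; their `y_range`s must tile \[0,1\]
#'   without overlap.
#' @param structures List of crypt/follicle/band/attraction specs, applied in
#'   order after zone sampling.
#' @param width,height Tissue extent in coordinate units.
#' @param noise Fraction of cells whose type is finally resampled uniformly
#'   over all types.
#' @param seed Integer seed; identical `(arguments, seed)` give an identical
#'   map.
#' @param sample_id,donor_id,region,group Metadata written to every cell.
#' @return A [cell_map()] whose cells carry an extra `zone` column with the
#'   generating zone (ground truth for recovery tests); `compartment` is set
#'   to the zone name.
#' @export
generate_tissue <- function(zones, structures = list(), width = 1000,
                            height = 1000, noise = 0, seed = 1L,
                            sample_id = "S1", donor_id = "D1",
                            region = "R1", group = "SB") {
  stopifnot(noise >= 0, noise < 1)
  ord <- order(vapply(zones, function(z) z$y_range[1], 0))
  zones <- zones[ord]
  lo <- vapply(zones, function(z) z$y_range[1], 0)
  hi <- vapply(zones, function(z) z$y_range[2], 0)
  if (abs(lo[1]) > 1e-9 || abs(hi[length(hi)] - 1) > 1e-9 ||
      (length(zones) > 1 && any(abs(lo[-1] - hi[-length(hi)]) > 1e-9)))
    stop("zones must tile [0,1] in y without overlap")
  for (s in structures) {
    ctr <- switch(s$kind, crypt = s$centers, follicle = rbind(s$center), NULL)
    if (!is.null(ctr) &&
        (any(ctr[, 1] < 0 | ctr[, 1] > width | ctr[, 2] < 0 | ctr[, 2] > height)))
      stop("structure centre outside tissue bounds")
    if (s$kind == "band" && (s$y_band[1] < 0 || s$y_band[2] > height))
      stop("band outside tissue bounds")
  }
  universe <- sort(unique(unlist(lapply(c(zones, structures), function(s)
    c(names(c(s$composition, s$inner_composition, s$outer_composition)),
      s$anchor_type)))))

  with_seed(seed, {
    xs <- ys <- numeric(0); ty <- zn <- character(0)
    for (z in zones) {
      a <- width * height * (z$y_range[2] - z$y_range[1])
      n <- stats::rpois(1, z$intensity * a)
      xs <- c(xs, stats::runif(n, 0, width))
      ys <- c(ys, stats::runif(n, height * z$y_range[1], height * z$y_range[2]))
      ty <- c(ty, sample_types(n, z$composition))
      zn <- c(zn, rep(z$name, n))
    }
    for (s in structures) {
      if (s$kind == "band") {
        hit <- which(ys >= s$y_band[1] & ys <= s$y_band[2])
        ty[hit] <- sample_types(length(hit), s$composition)
      } else if (s$kind == "crypt") {
        for (ci in seq_len(nrow(s$centers))) {
          d <- sqrt((xs - s$centers[ci, 1])^2 + (ys - s$centers[ci, 2])^2)
          hit <- which(d <= s$radius)
          # blend weight decays linearly to 0 at the crypt rim
          w <- 1 - d[hit] / s$radius
          take <- stats::runif(length(hit)) < w
          ty[hit[take]] <- sample_types(sum(take), s$composition)
          if (s$anchor_count > 0) {
            r0 <- 0.25 * s$radius * sqrt(stats::runif(s$anchor_count))
            th <- stats::runif(s$anchor_count, 0, 2 * pi)
            ax <- s$centers[ci, 1] + r0 * cos(th)
            ay <- s$centers[ci, 2] + r0 * sin(th)
            xs <- c(xs, ax); ys <- c(ys, ay)
            ty <- c(ty, rep(s$anchor_type, s$anchor_count))
            zi <- findInterval(ay / height, c(0, hi), rightmost.closed = TRUE)
            zn <- c(zn, vapply(zi, function(i) zones[[max(1, min(i, length(zones)))]]$name, ""))
          }
        }
      } else if (s$kind == "follicle") {
        d <- sqrt((xs - s$center[1])^2 + (ys - s$center[2])^2)
        inner <- which(d <= s$r_inner)
        outer <- which(d > s$r_inner & d <= s$r_outer)
        ty[inner] <- sample_types(length(inner), s$inner_composition)
        ty[outer] <- sample_types(length(outer), s$outer_composition)
      } else if (s$kind == "attraction") {
        tgt <- which(ty == s$target_type)
        src <- which(ty == s$source_type)
        if (length(tgt) == 0L || length(src) == 0L) {
          warning("attraction structure skipped: missing ",
                  if (length(tgt) == 0L) s$target_type else s$source_type)
        } else {
          move <- src[stats::runif(length(src)) < s$strength]
          anchor <- tgt[sample.int(length(tgt), length(move), replace = TRUE)]
          rr <- s$radius * sqrt(stats::runif(length(move)))
          th <- stats::runif(length(move), 0, 2 * pi)
          xs[move] <- pmin(pmax(xs[anchor] + rr * cos(th), 0), width)
          ys[move] <- pmin(pmax(ys[anchor] + rr * sin(th), 0), height)
        }
      }
    }
    if (noise > 0) {
      flip <- which(stats::runif(length(ty)) < noise)
      ty[flip] <- universe[sample.int(length(universe), length(flip),
                                      replace = TRUE)]
    }
    n <- length(xs)
    cells <- data.frame(
      cell_id = sprintf("%s_c%07d", sample_id, seq_len(n)),
      x = xs, y = ys, cell_type = ty, sample_id = sample_id,
      donor_id = donor_id, region = region, group = group,
      compartment = zn, zone = zn, stringsAsFactors = FALSE)
    cell_map(cells, area = width * height)
  })
}

#' Default layered-intestine template
#'
#' Three zones (mucosa 55% of the height, submucosa 25%, muscularis 20%) over
#' a 12-type repertoire, with six crypt units anchored by Paneth-like cells at
#' the mucosal base, one two-zone follicle, and a plasma-dense band beneath
#' the crypts. Intensities give roughly 10,000 cells on the default
#' 1000 x 1000 tissue. Crypts (and their Paneth anchors) are restricted to the
#' small-bowel group, mirroring their anatomical distribution; a plasma-to-TA
#' attraction restricted to the colon group plants a group-specific
#' colocalization signal.
#'
#' @return List with elements `zones` and `structures`, directly usable by
#'   [generate_tissue()] / [cohort_config()].
#' @export
intestine_template <- function() {
  mucosa <- c(Enterocyte = 0.26, Goblet = 0.12, TA = 0.15, Stem = 0.05,
              Paneth = 0.02, Plasma = 0.15, CD8T = 0.08, Bcell = 0.02,
              Macrophage = 0.05, Fibroblast = 0.05, Endothelial = 0.04,
              SmoothMuscle = 0.01)
  submucosa <- c(Fibroblast = 0.39, Endothelial = 0.25, SmoothMuscle = 0.10,
                 Macrophage = 0.08, CD8T = 0.05, Plasma = 0.07, Bcell = 0.01,
                 Enterocyte = 0.01, Goblet = 0.01, TA = 0.01, Stem = 0.01,
                 Paneth = 0.01)
  muscularis <- c(SmoothMuscle = 0.70, Fibroblast = 0.12, Endothelial = 0.08,
                  Macrophage = 0.04, CD8T = 0.02, Plasma = 0.02,
                  Enterocyte = 0.005, Goblet = 0.005, TA = 0.005,
                  Stem = 0.005)
  zones <- list(
    zone_spec("mucosa", c(0, 0.55), 0.012, mucosa),
    zone_spec("submucosa", c(0.55, 0.80), 0.006, submucosa),
    zone_spec("muscularis", c(0.80, 1), 0.008, muscularis))
  crypt_comp <- c(Stem = 0.35, TA = 0.35, Paneth = 0.20, Enterocyte = 0.10)
  crypt_centers <- cbind(seq(120, 880, length.out = 6), rep(480, 6))
  structures <- list(
    crypt_spec(crypt_centers, radius = 40, composition = crypt_comp,
               anchor_type = "Paneth", anchor_count = 5, group = "SB"),
    follicle_spec(c(820, 300), r_inner = 45, r_outer = 85,
                  inner_composition = c(Bcell = 0.80, CD8T = 0.10,
                                        Macrophage = 0.10),
                  outer_composition = c(Bcell = 0.40, Plasma = 0.30,
                                        CD8T = 0.20, Macrophage = 0.10)),
    band_spec(c(500, 545), c(Plasma = 0.60, CD8T = 0.10, Fibroblast = 0.20,
                             TA = 0.10)),
    attraction_spec("Plasma", "TA", strength = 0.5, radius = 15,
                    group = "CL"))
  list(zones = zones, structures = structures)
}

#' Cohort configuration
#'
#' @param donors Number of donors.
#' @param regions List of `list(name =, group =)` entries (one sample per
#'   donor x region); groups must be `"SB"` or `"CL"`.
#' @param deltas Named list (`SB`, `CL`) of named numeric vectors of additive
#'   cell-type fraction shifts applied to every zone composition of that
#'   group (clipped at 0, then renormalized).
#' @param template List with `zones` and `structures`
#'   (default [intestine_template()]).
#' @param noise,width,height Passed to [generate_tissue()].
#' @param covariate `NULL`, or `list(cell_type =, slope =, intercept =, sd =)`
#'   describing a donor-level covariate generated as a linear function of that
#'   donor's pooled fraction of `cell_type` plus Gaussian noise (a BMI-like
#'   variable for correlation tests).
#' @param seed Integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(donors = 4L,
                          regions = list(list(name = "jejunum", group = "SB"),
                                         list(name = "sigmoid", group = "CL")),
                          deltas = list(SB = c(CD8T = 0.05),
                                        CL = c(SmoothMuscle = 0.05,
                                               Endothelial = -0.02)),
                          template = intestine_template(),
                          noise = 0.05, width = 1000, height = 1000,
                          covariate = NULL, seed = 1L) {
  stopifnot(donors >= 1, length(regions) >= 1, noise >= 0, noise < 1)
  for (r in regions) stopifnot(r$group %in% c("SB", "CL"))
  structure(list(donors = as.integer(donors), regions = regions,
                 deltas = deltas, template = template, noise = noise,
                 width = width, height = height, covariate = covariate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

shift_composition <- function(comp, delta) {
  if (is.null(delta) || length(delta) == 0L) return(comp)
  hit <- intersect(names(delta), names(comp))
  comp[hit] <- comp[hit] + delta[hit]
  extra <- setdiff(names(delta), names(comp))
  if (length(extra)) comp <- c(comp, pmax(delta[extra], 0))
  comp <- pmax(comp, 0)
  if (sum(comp) <= 0) stop("composition shift removed all mass")
  comp / sum(comp)
}

#' Generate a synthetic cohort
#'
#' One [cell_map()] per donor x region. Group-level composition shifts are
#' applied to the zone compositions; structures carrying a `group` tag are
#' only placed in samples of that group.
#'
#' @param config A [cohort_config()].
#' @return List with `cellmaps` (named list of cell maps) and `donors`
#'   (data.frame `donor_id`, `covariate`; `covariate` is `NA` when no
#'   covariate model is configured).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    seeds <- sample.int(2^31 - 2, config$donors * length(config$regions) + 1L)
  })
  maps <- list()
  i <- 0L
  for (d in seq_len(config$donors)) {
    donor <- sprintf("D%02d", d)
    for (r in config$regions) {
      i <- i + 1L
      delta <- config$deltas[[r$group]]
      zones <- lapply(config$template$zones, function(z) {
        z$composition <- shift_composition(z$composition, delta)
        z
      })
      structs <- Filter(function(s) is.null(s$group) || s$group == r$group,
                        config$template$structures)
      sid <- sprintf("%s_%s", donor, r$name)
      maps[[sid]] <- generate_tissue(zones, structs, config$width,
                                     config$height, config$noise,
                                     seed = seeds[i], sample_id = sid,
                                     donor_id = donor, region = r$name,
                                     group = r$group)
    }
  }
  donors <- data.frame(donor_id = sprintf("D%02d", seq_len(config$donors)),
                       covariate = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(config$covariate)) {
    cv <- config$covariate
    frac <- vapply(donors$donor_id, function(dn) {
      cells <- pool_cells(maps[vapply(maps, function(m)
        m$cells$donor_id[1], "") == dn])
      mean(cells$cell_type == cv$cell_type)
    }, 0)
    donors$covariate <- with_seed(seeds[length(seeds)],
      cv$intercept + cv$slope * frac + stats::rnorm(length(frac), 0, cv$sd))
  }
  list(cellmaps = maps, donors = donors)
}

#' Expression configuration
#'
#' @param genes Character vector of gene names.
#' @param cell_types Character vector of cell types simulated.
#' @param groups Groups simulated (default `c("SB", "CL")`).
#' @param baseline_mean Negative-binomial mean count per gene with no effect.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param effects data.frame `gene, cell_type, group, log2fc` of planted
#'   fold-changes (multiplicative on the mean: `2^log2fc`).
#' @param cells_per_type_per_group Cells simulated per (type, group) arm.
#' @return An object of class `expression_config`.
#' @export
expression_config <- function(genes, cell_types, groups = c("SB", "CL"),
                              baseline_mean = 5, dispersion = 2,
                              effects = NULL,
                              cells_per_type_per_group = 500L) {
  stopifnot(length(genes) >= 1, length(cell_types) >= 1,
            baseline_mean > 0, dispersion > 0,
            cells_per_type_per_group >= 1)
  if (is.null(effects))
    effects <- data.frame(gene = character(), cell_type = character(),
                          group = character(), log2fc = numeric())
  stopifnot_cols(effects, c("gene", "cell_type", "group", "log2fc"), "effects")
  bad <- setdiff(effects$gene, genes)
  if (length(bad)) stop("effect on unknown gene(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(effects$cell_type, cell_types)
  if (length(bad)) stop("effect on unknown cell type(s): ", paste(bad, collapse = ", "))
  structure(list(genes = genes, cell_types = cell_types, groups = groups,
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 effects = effects,
                 cells_per_type_per_group = as.integer(cells_per_type_per_group)),
            class = "expression_config")
}

#' Generate a synthetic cell x gene count matrix
#'
#' Counts are negative binomial with mean
#' `baseline_mean * 2^(sum of applicable planted effects)` and fixed
#' dispersion, emulating single-nucleus / targeted-transcriptomics counts for
#' ligand-receptor differential testing.
#'
#' @param config An [expression_config()].
#' @param seed Integer seed.
#' @return List of class `expression_matrix`: `counts` (cells x genes integer
#'   matrix with gene column names) and `cells` (data.frame `cell_id`,
#'   `cell_type`, `group`, `sample_id`).
#' @export
generate_expression <- function(config, seed = 1L) {
  stopifnot(inherits(config, "expression_config"))
  with_seed(seed, {
    arms <- expand.grid(cell_type = config$cell_types, group = config$groups,
                        stringsAsFactors = FALSE)
    ncell <- nrow(arms) * config$cells_per_type_per_group
    counts <- matrix(0L, nrow = ncell, ncol = length(config$genes),
                     dimnames = list(NULL, config$genes))
    ann <- data.frame(cell_id = sprintf("e%06d", seq_len(ncell)),
                      cell_type = rep(arms$cell_type,
                                      each = config$cells_per_type_per_group),
                      group = rep(arms$group,
                                  each = config$cells_per_type_per_group),
                      sample_id = "expr1", stringsAsFactors = FALSE)
    for (a in seq_len(nrow(arms))) {
      rows <- which(ann$cell_type == arms$cell_type[a] &
                    ann$group == arms$group[a])
      lfc <- numeric(length(config$genes))
      names(lfc) <- config$genes
      eff <- config$effects[config$effects$cell_type == arms$cell_type[a] &
                            config$effects$group == arms$group[a], ]
      if (nrow(eff)) {
        agg <- tapply(eff$log2fc, eff$gene, sum)
        lfc[names(agg)] <- agg
      }
      mu <- config$baseline_mean * 2^lfc
      for (g in seq_along(config$genes)) {
        counts[rows, g] <- stats::rnbinom(length(rows), mu = mu[g],
                                          size = config$dispersion)
      }
    }
    structure(list(counts = counts, cells = ann), class = "expression_matrix")
  })
}
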