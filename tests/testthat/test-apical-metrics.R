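# Adjacency, ring-2 neighbour selection, the neighbour-referenced ratios and
# their invariances, the sister-pair filter, the median split and the Tuj1
# cross-tabulation.

test_that("adjacency respects the shared-boundary threshold", {
  lab <- matrix(1L, 6, 10)
  lab[, 6:10] <- 2L                      # 10-pixel straight border
  g <- build_adjacency(lab)
  expect_equal(g[c("from", "to")], data.frame(from = 1L, to = 2L))
  # diagonal single-pixel touch: one shared pair, below k = 3
  lab2 <- matrix(0L, 4, 4)
  lab2[1:2, 1:2] <- 1L; lab2[3:4, 3:4] <- 2L
  expect_equal(nrow(build_adjacency(lab2, min_shared = 3)), 0)
  expect_equal(nrow(build_adjacency(lab2, min_shared = 1)), 1)
})

test_that("adjacency equals the brute-force pixel-scan oracle", {
  for (seed in 1:20) {
    mos <- random_test_mosaic(sample(10:50, 1), seed = seed)
    got <- build_adjacency(mos$label)[c("from", "to")]
    want <- oracle_adjacency(mos$label)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

# a hexagonal-like lattice of square cells for deterministic ring structure
grid_cells <- function(k = 5, cell = 6) {
  lab <- matrix(0L, k * cell, k * cell)
  id <- 0L
  for (i in seq_len(k)) for (j in seq_len(k)) {
    id <- id + 1L
    lab[((i - 1) * cell + 1):(i * cell), ((j - 1) * cell + 1):(j * cell)] <- id
  }
  lab
}

test_that("ring-2 selection matches a BFS oracle on a regular lattice", {
  lab <- grid_cells(5)
  g <- build_adjacency(lab)
  cells <- measure_apical_cells(lab, matrix(0, nrow(lab), ncol(lab)))
  cells$transfected <- cells$cell_id == 13L   # centre of the 5x5 grid
  sel <- select_neighbors(13L, g, cells)
  expect_equal(nrow(sel), 4)
  expect_true(all(sel$ring == 2L))
  dist <- oracle_bfs_dist(g, cells$cell_id, 13L)
  expect_true(all(dist[as.character(sel$neighbor_id)] == 2))
  # none of the selected ring-2 cells touches the focal cell
  ring1 <- c(g$to[g$from == 13], g$from[g$to == 13])
  expect_length(intersect(sel$neighbor_id, ring1), 0)
})

test_that("selection falls back to ring 1 and fails below four candidates", {
  lab <- grid_cells(3)   # 3x3 grid: centre cell 5 has 4 ring-1, 4 ring-2
  g <- build_adjacency(lab)
  cells <- measure_apical_cells(lab, matrix(0, nrow(lab), ncol(lab)))
  cells$transfected <- cells$cell_id == 5L
  sel <- select_neighbors(5L, g, cells)
  expect_true(all(sel$ring == 2L))
  # make all ring-2 cells transfected: fallback to ring 1
  cells$transfected <- cells$cell_id %in% c(5L, 1L, 3L, 7L, 9L)
  sel2 <- select_neighbors(5L, g, cells)
  expect_true(all(sel2$ring == 1L))
  # corner focal with only 3 eligible cells in rings 1-2
  lab3 <- grid_cells(2)
  g3 <- build_adjacency(lab3)
  cells3 <- measure_apical_cells(lab3, matrix(0, nrow(lab3), ncol(lab3)))
  cells3$transfected <- cells3$cell_id == 1L
  expect_error(select_neighbors(1L, g3, cells3), "only 3 eligible")
})

test_that("equidistant candidates are tie-broken by ascending id", {
  lab <- grid_cells(5)
  g <- build_adjacency(lab)
  cells <- measure_apical_cells(lab, matrix(0, nrow(lab), ncol(lab)))
  cells$transfected <- cells$cell_id == 13L
  sel <- select_neighbors(13L, g, cells)
  # the four diagonal ring-2 cells are the nearest and equidistant; ties
  # resolve by ascending id
  expect_equal(sel$neighbor_id, c(7L, 9L, 17L, 19L))
})

test_that("selection agrees with a BFS oracle on random mosaics", {
  checked <- 0L
  for (seed in 1:20) {
    mos <- random_test_mosaic(40, H = 50, W = 50, seed = seed + 100)
    g <- build_adjacency(mos$label)
    cells <- measure_apical_cells(mos$label,
                                  matrix(0, nrow(mos$label),
                                         ncol(mos$label)))
    withr::with_seed(seed, {
      cells$transfected <- runif(nrow(cells)) < 0.2
    })
    dist_ok <- FALSE
    for (f in cells$cell_id[cells$transfected]) {
      sel <- tryCatch(select_neighbors(f, g, cells),
                      error = function(e) NULL)
      if (is.null(sel)) next
      dist <- oracle_bfs_dist(g, cells$cell_id, f)
      expect_true(all(dist[as.character(sel$neighbor_id)] == sel$ring))
      expect_true(all(!cells$transfected[match(sel$neighbor_id,
                                               cells$cell_id)]))
      expect_equal(anyDuplicated(sel$neighbor_id), 0)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 20)
})

test_that("area and junction ratios follow their definitions", {
  expect_equal(apical_area_ratio(4, c(4, 4, 4, 4)), 1)
  expect_equal(apical_area_ratio(2, c(4, 4, 4, 4)), 0.5)
  expect_equal(junction_intensity_ratio(30, c(30, 30, 30, 30), 10), 1)
  expect_equal(junction_intensity_ratio(20, c(30, 30, 30, 30), 10), 0.5)
  suppressWarnings(
    expect_error(junction_intensity_ratio(20, c(5, 5, 5, 5), 10),
                 "denominator"))
  expect_warning(junction_intensity_ratio(20, c(5, 50, 50, 50), 10),
                 "sign-flip")
})

test_that("ratios are invariant to spatial rescaling and intensity gain", {
  expect_equal(apical_area_ratio(8, c(16, 16, 12, 20)),
               apical_area_ratio(8 * 4, c(16, 16, 12, 20) * 4))
  a <- junction_intensity_ratio(40, c(55, 60, 50, 58), 12)
  b <- junction_intensity_ratio(40 * 2.5, c(55, 60, 50, 58) * 2.5, 12 * 2.5)
  expect_equal(a, b)
})

test_that("sister-pair filter removes adjacent transfected pairs symmetrically", {
  cells <- data.frame(cell_id = 1:5,
                      transfected = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  g <- data.frame(from = c(1, 2, 3, 4), to = c(2, 4, 5, 5))
  out <- pair_filter(cells, g)
  expect_setequal(out$cell_id, c(3, 4, 5))   # pair {1,2} dropped, 3 isolated
  expect_equal(attr(out, "n_removed"), 2L)
})

test_that("pair filter recalls planted pairs and spares isolated cells", {
  mos <- generate_apical_mosaic(mosaic_sim_params(
    n_cells = 150, transfected_frac = 0.1, constriction = 1,
    junction_factor = 1, seed = 41))
  g <- build_adjacency(mos$label)
  cells <- mos$truth[c("cell_id", "transfected")]
  # plant sister pairs: transfect a neighbour of three transfected cells
  tr <- cells$cell_id[cells$transfected]
  planted <- integer(0)
  for (f in tr[1:3]) {
    nb <- setdiff(c(g$to[g$from == f], g$from[g$to == f]), tr)
    nb <- setdiff(nb, planted)
    if (length(nb)) {
      cells$transfected[cells$cell_id == nb[1]] <- TRUE
      planted <- c(planted, f, nb[1])
    }
  }
  out <- pair_filter(cells, g)
  expect_length(intersect(out$cell_id, planted), 0)   # 100% recall
})

test_that("median split uses the control threshold, equality -> large", {
  sp <- split_small_large(c(0.5, 0.62, 0.7), c(0.4, 0.62, 0.9))
  expect_equal(sp$threshold, 0.62)
  expect_equal(as.character(sp$labels), c("small", "large", "large"))
  # brute-force comparison on random ratio sets
  withr::with_seed(3, {
    r <- runif(50); ctrl <- runif(30)
    sp2 <- split_small_large(r, ctrl)
    expect_equal(as.character(sp2$labels),
                 ifelse(r < median(ctrl), "small", "large"))
  })
  expect_error(split_small_large(1, numeric(0)), "empty")
})

test_that("Tuj1 cross-tabulation conserves counts", {
  labels <- factor(c("small", "small", "large", "large", "small"),
                   levels = c("small", "large"))
  tuj1 <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  ct <- crosstab_tuj1(labels, tuj1, ratios = c(0.2, 0.3, 1, 1.2, 0.5))
  expect_equal(sum(ct$table), 5)
  expect_equal(ct$table["large", "Tuj1+"][[1]], 0)   # all Tuj1+ are small
  expect_equal(unname(ct$mean_ratio[["Tuj1+"]]), 0.25)
  expect_error(crosstab_tuj1(labels, c(NA, tuj1[-1])), "Tuj1 call")
})

test_that("generative constriction and junction factors are recovered", {
  mos <- generate_apical_mosaic(mosaic_sim_params(
    n_cells = 200, constriction = 0.5, junction_factor = 0.6,
    diff_frac = 1, seed = 77))
  cells <- measure_apical_cells(mos$label, mos$junction,
                                mos$truth[c("cell_id", "transfected",
                                            "differentiating")])
  g <- build_adjacency(mos$label)
  ratios <- apical_ratios(cells, g,
                          background = mos$params$junction_background)
  d <- mos$truth$differentiating[match(ratios$cell_id,
                                       mos$truth$cell_id)]
  expect_gt(sum(d), 5)
  expect_lt(abs(mean(ratios$area_ratio[d]) - 0.5), 0.08)
  expect_lt(abs(mean(ratios$junction_ratio[d]) - 0.6), 0.08)
})

test_that("Tuj1 enrichment among small cells is recovered from simulation", {
  hits <- 0L
  for (seed in 1:10) {
    mos <- generate_apical_mosaic(mosaic_sim_params(
      n_cells = 150, constriction = 0.4, junction_factor = 0.5,
      transfected_frac = 0.2, diff_frac = 0.5, seed = seed))
    cells <- measure_apical_cells(mos$label, mos$junction,
                                  mos$truth[c("cell_id", "transfected")])
    # Tuj1 conditioned on the differentiating state
    withr::with_seed(seed, {
      d <- mos$truth$differentiating
      cells$tuj1 <- ifelse(d, runif(nrow(cells)) < 0.8,
                           runif(nrow(cells)) < 0.05)
    })
    g <- build_adjacency(mos$label)
    ratios <- apical_ratios(cells, g,
                            background = mos$params$junction_background)
    ctrl <- ratios$area_ratio[!ratios$tuj1]
    if (length(ctrl) < 3 || sum(ratios$tuj1) < 3) next
    sp <- split_small_large(ratios$area_ratio, ctrl)
    tab <- crosstab_tuj1(sp$labels, ratios$tuj1)$table + 0.5
    or <- tab["small", "Tuj1+"] * tab["large", "Tuj1-"] /
      (tab["small", "Tuj1-"] * tab["large", "Tuj1+"])
    if (or > 1) hits <- hits + 1L
  }
  expect_gte(hits, 9)
})
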