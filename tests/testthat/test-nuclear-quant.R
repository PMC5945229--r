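# Per-nucleus measurement, the two-anchor normalization and its invariances,
# cross-session re-anchoring, fold changes, and the ellipse colour-code map.

square_label <- function(H = 20, W = 20, r1 = 3, r2 = 12, id = 1L) {
  lab <- matrix(0L, H, W)
  lab[r1:r2, r1:r2] <- id
  lab
}

test_that("measurement on a uniform square is exact", {
  lab <- matrix(0L, 20, 20); lab[5:14, 3:12] <- 1L
  ch <- list(VNP = matrix(7, 20, 20))
  rec <- measure_nuclei(lab, ch)
  expect_equal(rec$area, 100L)
  expect_equal(rec$mean_VNP, 7)
  expect_equal(rec$x, mean(2:11))   # 0-based centroid
  expect_equal(rec$y, mean(4:13))
})

test_that("moment ellipse recovers generative axes within 5%", {
  H <- 80; W <- 80
  lab <- matrix(0L, H, W)
  idx <- epimosaic:::.ellipse_pixels(40, 40, 20, 10, pi / 6, H, W)
  lab[idx] <- 1L
  rec <- measure_nuclei(lab, list(VNP = matrix(0, H, W)))
  expect_lt(abs(rec$major - 40) / 40, 0.05)
  expect_lt(abs(rec$minor - 20) / 20, 0.05)
  # orientation folded to a half-circle
  ang <- rec$orientation %% pi
  expect_lt(min(abs(ang - pi / 6), abs(ang - pi / 6 - pi)), 0.05)
})

test_that("empty label images give empty record frames", {
  rec <- measure_nuclei(matrix(0L, 5, 5), list(VNP = matrix(1, 5, 5)))
  expect_equal(nrow(rec), 0)
  expect_true(all(c("cell_id", "area", "mean_VNP") %in% names(rec)))
})

test_that("measured means equal the brute-force per-pixel oracle", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      lab <- matrix(sample(0:4, 15 * 15, replace = TRUE), 15, 15)
      ch <- matrix(runif(15 * 15, 0, 100), 15, 15)
      rec <- measure_nuclei(lab, list(VNP = ch))
      orc <- oracle_label_means(lab, ch)
      expect_equal(rec$mean_VNP, unname(orc[as.character(rec$cell_id)]))
    }
  })
})

test_that("dimension mismatches and duplicate marker ids are rejected", {
  lab <- square_label()
  expect_error(measure_nuclei(lab, list(VNP = matrix(0, 5, 5))),
               "dimensions")
  mk <- data.frame(cell_id = c(1, 1), hucd = c(TRUE, FALSE))
  expect_error(measure_nuclei(lab, list(VNP = matrix(0, 20, 20)), mk),
               "duplicate")
})

fake_records <- function(vnp, hucd, region = "included",
                         side = "non_electroporated") {
  data.frame(cell_id = seq_along(vnp), mean_VNP = vnp, hucd = hucd,
             region = region, side = side)
}

test_that("background is the mean over HuCD+ included records", {
  rec <- fake_records(c(10, 20, 100), c(TRUE, TRUE, FALSE))
  expect_equal(estimate_background(rec), 15)
  rec2 <- fake_records(c(7, 7, 7), c(TRUE, TRUE, TRUE))
  expect_equal(estimate_background(rec2), 7)
  rec3 <- fake_records(c(10, 20), c(TRUE, TRUE),
                       region = "excluded_zone")
  expect_error(estimate_background(rec3), "HuCD\\+")
})

test_that("two-anchor normalization maps the anchors to 0 and 1", {
  rec <- fake_records(c(10, 20, 40, 60, 32.5),
                      c(TRUE, TRUE, FALSE, FALSE, NA))
  rec$hucd[5] <- FALSE
  mod <- fit_normalization(rec)
  expect_equal(mod$b, 15)
  out <- normalize_vnp(rec, mod)
  # neurons {10,20} -> b = 15; HuCD- {40,60,32.5} -> m = 44.1666...
  expect_equal(mean(out$vnp_norm[out$hucd]), 0, tolerance = 1e-12)
  expect_equal(mean(out$vnp_norm[!out$hucd]), 1, tolerance = 1e-12)
  # linear midpoint under explicit anchors
  mid <- normalize_vnp(data.frame(mean_VNP = 32.5),
                       normalization_model(15, 50))
  expect_equal(mid$vnp_norm, 0.5)
  expect_error(normalization_model(50, 15), "degenerate")
})

test_that("normalization is affine-invariant", {
  withr::with_seed(8, {
    rec <- fake_records(runif(40, 5, 200), rep(c(TRUE, FALSE), 20))
    v1 <- normalize_vnp(rec, fit_normalization(rec))$vnp_norm
    rec2 <- rec
    rec2$mean_VNP <- 3.7 * rec$mean_VNP + 12
    v2 <- normalize_vnp(rec2, fit_normalization(rec2))$vnp_norm
    expect_lt(max(abs(v1 - v2)), 1e-9)
  })
})

test_that("anchor identities hold on a simulated section", {
  sec <- generate_transverse_section(section_sim_params(seed = 44))
  rec <- measure_nuclei(sec$label, sec$channels, sec$markers)
  rec <- flag_regions(rec, sec$params$height, sec$params$width,
                      sec$params$excluded_bands)
  out <- normalize_vnp(rec, fit_normalization(rec))
  inc <- out$region == "included"
  expect_lt(abs(mean(out$vnp_norm[inc & out$hucd])), 1e-9)
  expect_lt(abs(mean(out$vnp_norm[inc & !out$hucd]) - 1), 1e-9)
})

test_that("cross-session factors invert per-session references", {
  s1 <- fake_records(c(100, 100), c(TRUE, TRUE))
  s2 <- fake_records(c(50, 50), c(TRUE, TRUE))
  f <- cross_session_normalize(list(s1, s2))
  expect_equal(unname(f), c(1, 2))
  expect_equal(unname(cross_session_normalize(list(s1))), 1)
  s3 <- fake_records(c(50, 50), c(TRUE, TRUE), side = "electroporated")
  expect_error(cross_session_normalize(list(s1, s3)), "session2")
})

test_that("a global gain change is undone by cross-session scaling", {
  sec <- generate_transverse_section(section_sim_params(seed = 55))
  rec <- measure_nuclei(sec$label, sec$channels, sec$markers)
  rec <- flag_regions(rec, sec$params$height, sec$params$width,
                      sec$params$excluded_bands)
  dim1 <- rec
  dim1$mean_VNP <- rec$mean_VNP * 0.5
  f <- cross_session_normalize(list(a = rec, b = dim1))
  scaled1 <- f[["a"]] * rec$mean_VNP
  scaled2 <- f[["b"]] * dim1$mean_VNP
  cls <- sec$truth$class
  for (k in unique(cls)) {
    m1 <- mean(scaled1[cls == k]); m2 <- mean(scaled2[cls == k])
    expect_lt(abs(m1 - m2) / m1, 0.02)
  }
})

test_that("fold change is the ratio of background-subtracted means", {
  expect_equal(fold_change(30, 15), 2)
  x <- c(4, 8, 15)
  expect_equal(fold_change(x, x), 1)
  expect_error(fold_change(10, -5), "control mean")
})

test_that("palette bins honour their boundaries", {
  pal <- map_palette()
  eps <- 1e-9
  for (k in seq_along(pal$breaks)) {
    lo <- palette_bin(pal$breaks[k] - eps, pal)
    hi <- palette_bin(pal$breaks[k] + eps, pal)
    at <- palette_bin(pal$breaks[k], pal)
    expect_equal(hi, lo + 1L)
    expect_equal(at, hi)   # boundary value belongs to the upper bin
  }
  expect_equal(palette_bin(-10, pal), 1L)
  expect_equal(palette_bin(10, pal), length(pal$colors))
})

test_that("the intensity map draws one ellipse per record in id order", {
  rec <- data.frame(cell_id = c(2L, 1L), x = c(10, 12), y = c(10, 12),
                    major = c(8, 8), minor = c(6, 6), orientation = 0,
                    vnp_norm = c(0.9, 0.1),
                    region = c("included", "included"))
  map <- render_intensity_map(rec, 24, 24)
  pal <- map_palette()
  b1 <- palette_bin(0.1, pal); b2 <- palette_bin(0.9, pal)
  # both colours present; overlap painted by the later (higher) id
  expect_setequal(setdiff(unique(as.integer(map)), 0L), c(b1, b2))
  expect_equal(map[11, 11], b2)   # overlap pixel: id 2 (v' = 0.9) drawn last
  # same-bin records share a colour
  rec$vnp_norm <- c(0.31, 0.33)
  map2 <- render_intensity_map(rec, 24, 24)
  expect_equal(setdiff(unique(as.integer(map2)), 0L),
               palette_bin(0.32, pal))
  # excluded records use the excluded colour
  rec$region <- c("excluded_zone", "excluded_zone")
  map3 <- render_intensity_map(rec, 24, 24)
  expect_equal(setdiff(unique(as.integer(map3)), 0L),
               length(pal$colors) + 1L)
})

test_that("out-of-bounds ellipses are clipped, not fatal", {
  rec <- data.frame(cell_id = 1L, x = 1, y = 1, major = 10, minor = 8,
                    orientation = 0, vnp_norm = 0.5, region = "included")
  map <- render_intensity_map(rec, 16, 16)
  expect_equal(attr(map, "clipped"), 1L)
  expect_gt(sum(map > 0), 0)
})
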