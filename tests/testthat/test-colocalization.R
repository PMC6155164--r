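test_that("overlap counting matches hand-computed masks", {
  g <- grid_spec(c(0, 0), c(20, 20), pixel_nm = 20)
  a <- make_set(list(rect_mask(g, 2:6, 2:6)), g, channel = "naDNA")
  b_same <- make_set(list(rect_mask(g, 2:6, 2:6)), g, channel = "p")
  # identity: every cluster overlaps, area = total area
  ov <- count_overlaps(a, b_same)
  expect_equal(ov$n_overlaps, 1L)
  expect_equal(ov$overlap_area_nm2, 25 * 400)
  # disjoint: zero
  b_far <- make_set(list(rect_mask(g, 12:16, 12:16)), g)
  expect_equal(count_overlaps(a, b_far),
               list(n_overlaps = 0L, overlap_area_nm2 = 0))
  # hand-drawn 5x5 masks with a 2x3 intersection: 6 px = 2400 nm^2, n = 1
  b_part <- make_set(list(rect_mask(g, 5:9, 4:6)), g)
  ov2 <- count_overlaps(a, b_part)
  expect_equal(ov2$n_overlaps, 1L)
  expect_equal(ov2$overlap_area_nm2, 6 * 400)
  # grid mismatch is an error
  g2 <- grid_spec(c(0, 0), c(21, 20), pixel_nm = 20)
  expect_error(count_overlaps(a, make_set(list(rect_mask(g2, 1, 1)), g2)),
               "different grids")
})

test_that("randomization is uniform, shape-preserving, and seed-stable", {
  g <- grid_spec(c(0, 0), c(12, 12), pixel_nm = 20)
  roi <- rect_roi(c(0, 240), c(0, 240))
  msk <- roi_mask(roi, g)
  one <- make_set(list(rect_mask(g, 3, 3)), g)
  # chi-squared uniformity of a 1-px cluster over the 144 ROI pixels
  draws <- vapply(1:2016, function(s)
    randomize_clusters(one, roi, seed = s, mask = msk)$pixels[[1]],
    integer(1))
  counts <- tabulate(draws, nbins = 144)
  chi <- sum((counts - mean(counts))^2 / mean(counts))
  expect_gt(stats::pchisq(chi, df = 143, lower.tail = FALSE), 0.01)
  # conservation: areas, pixel counts and cluster count survive exactly
  set.seed(9)
  cfg <- scene_config(n_nadna_foci = 20, n_protein_clusters = c(RPA = 20),
                      seed = 31)
  sc <- generate_nucleus_scene(cfg)
  seg <- segment_scene(sc$locs, sc$roi)
  rs <- randomize_clusters(seg$sets$RPA, sc$roi, seed = 77, mask = seg$mask)
  expect_equal(n_clusters(rs), n_clusters(seg$sets$RPA))
  expect_equal(rs$clusters$area_nm2, seg$sets$RPA$clusters$area_nm2)
  expect_equal(lengths(rs$pixels), lengths(seg$sets$RPA$pixels))
  expect_true(all(unlist(rs$pixels) %in% which(seg$mask)))
  # same seed, same placement
  rs2 <- randomize_clusters(seg$sets$RPA, sc$roi, seed = 77, mask = seg$mask)
  expect_identical(rs, rs2)
  # ROI equal to the cluster's own bounding box: the one feasible position
  tight_roi <- rect_roi(c(40, 80), c(40, 80))   # mask = pixels (2:3, 2:3)
  sq <- make_set(list(rect_mask(g, 5:6, 5:6)), g)   # 2x2 at (5,5)
  forced <- randomize_clusters(sq, tight_roi, seed = 1)
  expect_setequal(forced$pixels[[1]],
                  which(rect_mask(g, 2:3, 2:3)))
  # an oversized cluster cannot be placed
  big <- make_set(list(rect_mask(g, 0:9, 0:9)), g)
  expect_error(randomize_clusters(big, tight_roi, seed = 1,
                                  max_retries = 50L),
               "cannot be placed")
})

test_that("the coefficient is the observed-to-simulated-mean ratio", {
  # observed 10 against 20 simulations averaging 5: exactly 2
  r <- coloc_ratio(10, rep(c(4, 6), 10))
  expect_identical(r$coefficient, 2)
  expect_true(is.na(r$flag))
  # zero simulated overlap: flagged, not infinite
  r0 <- coloc_ratio(3, rep(0, 20))
  expect_true(is.na(r0$coefficient))
  expect_equal(r0$flag, "insufficient-randomization-overlap")
  # full result object: enrichment direction and determinism
  cfg <- scene_config(n_nadna_foci = 30, n_protein_clusters = c(RPA = 30),
                      colocalized_fraction = 0.9,
                      background_density_um2 = 0, seed = 41)
  sc <- generate_nucleus_scene(cfg)
  seg <- segment_scene(sc$locs, sc$roi)
  res <- colocalization_coefficient(seg$sets$naDNA, seg$sets$RPA, sc$roi,
                                    seed = 13, mask = seg$mask)
  expect_equal(res$n_sims, 20L)
  expect_length(res$sim_counts, 20L)
  expect_gt(res$coefficient_area, 1)    # engineered enrichment
  expect_gt(res$coefficient_number, 1)
  res2 <- colocalization_coefficient(seg$sets$naDNA, seg$sets$RPA, sc$roi,
                                     seed = 13, mask = seg$mask)
  expect_identical(res, res2)
})

test_that("the coefficient is invariant under whole-pixel scene translation", {
  shift <- 20 * 11
  cfg <- scene_config(n_nadna_foci = 25, n_protein_clusters = c(RPA = 25),
                      colocalized_fraction = 0.5, seed = 51)
  sc <- generate_nucleus_scene(cfg)
  g <- grid_for_bbox(range(sc$roi$vertices[, 1]) + c(0, shift),
                     range(sc$roi$vertices[, 2]) + c(0, shift))
  run_at <- function(dx) {
    locs <- sc$locs
    locs$x_nm <- locs$x_nm + dx
    locs$y_nm <- locs$y_nm + dx
    roi <- nucleus_roi(sc$roi$vertices + dx, id = "n")
    seg <- segment_scene(locs, roi, grid = g)
    colocalization_coefficient(seg$sets$naDNA, seg$sets$RPA, roi,
                               seed = 7, mask = seg$mask)
  }
  a <- run_at(0)
  b <- run_at(shift)
  expect_equal(b$n_real, a$n_real)
  expect_equal(b$area_real_nm2, a$area_real_nm2)
  expect_equal(b$coefficient_area, a$coefficient_area, tolerance = 1e-12)
})

test_that("mean coefficient rises with the generated colocalized fraction", {
  frac <- c(0, 0.3, 0.6, 0.9)
  mean_coef <- vapply(seq_along(frac), function(i) {
    vals <- vapply(1:4, function(r) {
      cfg <- scene_config(n_nadna_foci = 40,
                          n_protein_clusters = c(RPA = 40),
                          colocalized_fraction = frac[i],
                          background_density_um2 = 0,
                          seed = 600 + 10 * i + r)
      sc <- generate_nucleus_scene(cfg)
      seg <- segment_scene(sc$locs, sc$roi)
      colocalization_coefficient(seg$sets$naDNA, seg$sets$RPA, sc$roi,
                                 seed = derive_seed(800, 10 * i + r),
                                 mask = seg$mask)$coefficient_area
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_coef) > 0))
})

test_that("population summaries compute sem, Welch t and stars", {
  df <- data.frame(condition = rep(c("ctl", "cpt"), each = 3),
                   timepoint = 2,
                   coefficient = c(1, 1.1, 0.9, 1, 1.1, 0.9))
  # identical groups: t = 0, p = 1
  s <- summarize_population(df, reference = "ctl")
  row <- s[s$condition == "cpt", ]
  expect_equal(row$t, 0, tolerance = 1e-12)
  expect_equal(row$p, 1, tolerance = 1e-12)
  expect_equal(row$sem, stats::sd(c(1, 1.1, 0.9)) / sqrt(3))
  expect_equal(row$stars, "ns")
  # zero-variance groups: finite t via the epsilon guard, flagged
  dfz <- data.frame(condition = rep(c("ctl", "cpt"), each = 3),
                    timepoint = 0,
                    coefficient = c(1, 1, 1, 2, 2, 2))
  sz <- summarize_population(dfz, reference = "ctl")
  rz <- sz[sz$condition == "cpt", ]
  expect_lt(rz$p, 1e-3)
  expect_equal(rz$flag, "degenerate-variance")
  # separated groups at n = 20: overwhelming significance
  set.seed(12)
  dfp <- data.frame(condition = rep(c("ctl", "cpt"), each = 20),
                    timepoint = 2,
                    coefficient = c(rnorm(20, 1, 0.1), rnorm(20, 1.5, 0.1)))
  sp <- summarize_population(dfp, reference = "ctl")
  expect_lt(sp[sp$condition == "cpt", ]$p, 1e-4)
  expect_equal(sp[sp$condition == "cpt", ]$stars, "****")
  # groups with n < 2 are flagged and carry no sem
  df1 <- data.frame(condition = c("ctl", "ctl", "cpt"), timepoint = 1,
                    coefficient = c(1, 1.2, 3))
  s1 <- summarize_population(df1, reference = "ctl")
  expect_equal(s1[s1$condition == "cpt", ]$flag, "n<2")
  expect_true(is.na(s1[s1$condition == "cpt", ]$sem))
})

test_that("timecourse heatmaps assemble and reject duplicates", {
  one <- data.frame(protein = "RPA", timepoint = 2, mean = 1.5)
  m <- build_timecourse_heatmap(one)
  expect_equal(dim(m), c(1L, 1L))
  expect_equal(m["RPA", "2"], 1.5)
  multi <- data.frame(protein = rep(c("RPA", "RAD51"), each = 3),
                      timepoint = rep(c(0, 2, 8), 2),
                      mean = c(1, 3, 2, 1, 2, 4))
  m2 <- build_timecourse_heatmap(multi)
  expect_equal(dim(m2), c(2L, 3L))
  expect_equal(m2["RPA", ], c("0" = 1, "2" = 3, "8" = 2))
  expect_error(build_timecourse_heatmap(rbind(one, one)), "duplicate")
  expect_warning(m0 <- build_timecourse_heatmap(one[0, ]), "empty")
  expect_equal(dim(m0), c(0L, 0L))
})
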