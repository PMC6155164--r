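test_that("protein presence follows the intersection-or-radius rule", {
  g <- grid_spec(c(0, 0), c(40, 40), pixel_nm = 20)
  na <- make_set(list(rect_mask(g, 10:12, 10:12)), g, channel = "naDNA")
  # overlapping masks: present regardless of center distance
  pA <- make_set(list(rect_mask(g, 12:14, 10:12)), g, channel = "A")
  # center 300 nm away, no intersection: absent at radius 250
  pB <- make_set(list(rect_mask(g, 26, 11)), g, channel = "B")
  # naDNA com = (230,230); B com = (530,230) -> 300 nm
  rec <- identify_foci(na, list(A = pA, B = pB),
                       association_radius_nm = 250)
  expect_equal(nrow(rec), 1L)
  expect_true(rec$A)
  expect_false(rec$B)
  # widen the radius: B becomes present
  rec2 <- identify_foci(na, list(A = pA, B = pB),
                        association_radius_nm = 320)
  expect_true(rec2$B)
  # naDNA clusters with no protein are excluded but counted
  lonely <- make_set(list(rect_mask(g, 10:12, 10:12),
                          rect_mask(g, 30:32, 30:32)), g, channel = "naDNA")
  rec3 <- identify_foci(lonely, list(A = pA), association_radius_nm = 250)
  expect_equal(nrow(rec3), 1L)
  expect_equal(attr(rec3, "n_nadna_only"), 1L)
})

test_that("focus recall against generator ground truth exceeds 95%", {
  mix <- c("RPA-only" = 0.3, "both" = 0.5, "RAD51-only" = 0.2)
  pop <- generate_focus_population(300, class_mixture = mix, seed = 61)
  rec <- identify_foci_cohort(pop$nuclei, pop$proteins)
  # every true focus should have >= 1 record within 300 nm, right nucleus
  hit <- vapply(seq_len(nrow(pop$foci)), function(i) {
    r <- rec[rec$nucleus == pop$foci$nucleus[i], ]
    any(sqrt((r$com_x_nm - pop$foci$x_nm[i])^2 +
               (r$com_y_nm - pop$foci$y_nm[i])^2) < 300)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("population fractions sum to one and match the generator mixture", {
  g <- grid_spec(c(0, 0), c(40, 40), pixel_nm = 20)
  na <- make_set(list(rect_mask(g, 10:12, 10:12)), g, channel = "naDNA")
  pA <- make_set(list(rect_mask(g, 12:14, 10:12)), g, channel = "A")
  pB <- make_set(list(rect_mask(g, 9, 10:12)), g, channel = "B")
  rec <- identify_foci(na, list(A = pA, B = pB))
  pf <- classify_population(rec, c("A", "B"))
  expect_equal(pf$fractions[["both"]], 1)
  expect_equal(sum(pf$fractions), 1)
  expect_equal(pf$prevalence, 1)
  # convergence: recovered fractions within 3 binomial s.d. of the mixture
  mix <- c("RPA-only" = 0.3, "both" = 0.5, "RAD51-only" = 0.2)
  pop <- generate_focus_population(1000, class_mixture = mix, seed = 62)
  rec2 <- identify_foci_cohort(pop$nuclei, pop$proteins)
  pf2 <- classify_population(rec2, c("RPA", "RAD51"))
  n <- pf2$n_foci
  expect_lt(abs(pf2$fractions[["both"]] - 0.5), 3 * sqrt(0.25 / n) + 0.02)
  expect_lt(abs(pf2$fractions[["RPA-only"]] - 0.3),
            3 * sqrt(0.3 * 0.7 / n) + 0.02)
  expect_error(classify_population(rec2[0, ], c("RPA", "RAD51")),
               "no foci")
})

test_that("intrafoci distances are Euclidean between associated centers", {
  g <- grid_spec(c(0, 0), c(60, 60), pixel_nm = 20)
  na <- make_set(list(rect_mask(g, 10:12, 10:12)), g, channel = "naDNA")
  # coincident single-pixel clusters: distance zero
  p0 <- make_set(list(rect_mask(g, 11, 11)), g)
  rec0 <- identify_foci(na, list(A = p0, B = p0))
  expect_equal(intrafoci_distances(rec0, list(A = p0, B = p0),
                                   c("A", "B")), 0)
  # 3-4-5 triangle: centers (0,0) and (300,400) nm apart -> 500 nm
  pA <- make_set(list(rect_mask(g, 11, 11)), g)
  pB <- make_set(list(rect_mask(g, 26, 31)), g)  # +15 px x, +20 px y
  recAB <- identify_foci(na, list(A = pA, B = pB),
                         association_radius_nm = 600)
  expect_equal(intrafoci_distances(recAB, list(A = pA, B = pB),
                                   c("A", "B")), 500)
  # no qualifying focus: empty with a warning
  pC <- make_set(list(rect_mask(g, 50, 50)), g)
  recC <- identify_foci(na, list(A = pA, C = pC))
  expect_warning(d <- intrafoci_distances(recC, list(A = pA, C = pC),
                                          c("A", "C")), "no foci")
  expect_length(d, 0)
})

test_that("pipeline-measured intrafoci distances follow the displacement model", {
  mix <- c(both = 1)
  pop <- generate_focus_population(600, class_mixture = mix, seed = 63)
  sets_by_nuc <- lapply(pop$nuclei, function(nu)
    segment_scene(nu$locs, nu$roi, channels = c("naDNA", pop$proteins)))
  d <- unlist(lapply(sets_by_nuc, function(sc) {
    rec <- identify_foci(sc$sets$naDNA, sc$sets[pop$proteins])
    intrafoci_distances(rec, sc$sets[pop$proteins], pop$proteins)
  }))
  expect_gte(length(d), 500)
  # pair separations are generated from the reference model, so the
  # measured distances should follow it (KS, alpha = 0.01)
  ks <- suppressWarnings(stats::ks.test(d, "pnorm", 135, fwhm_to_sd(75)))
  expect_gt(ks$p.value, 0.01)
})

test_that("single-Gaussian fits recover center and width at efficiency", {
  est <- t(vapply(1:60, function(r) {
    set.seed(1000 + r)
    d <- rnorm(500, 135, fwhm_to_sd(75))
    f <- fit_distance_distribution(d[d > 0], model = "single")
    c(f$components$center_nm, f$components$fwhm_nm)
  }, numeric(2)))
  # centers within 5% in >= 95% of replicates
  expect_gte(mean(abs(est[, 1] - 135) / 135 < 0.05), 0.95)
  # width: unbiased to ~2% (any unbiased width estimator at n = 500 keeps
  # a ~3% relative sd, so per-replicate bands are set at 10%)
  expect_lt(abs(mean(est[, 2]) - 75) / 75, 0.02)
  expect_gte(mean(abs(est[, 2] - 75) / 75 < 0.10), 0.95)
  # distal sample: classification flips
  set.seed(2)
  f2 <- fit_distance_distribution(rnorm(500, 250, fwhm_to_sd(75)))
  expect_equal(f2$classification, "distal")
  expect_equal(f2$model, "single")
})

test_that("classification boundaries are exact", {
  expect_equal(classify_center(97.5), "proximal")
  expect_equal(classify_center(172.5), "proximal")
  expect_equal(classify_center(97.4), "indeterminate")
  expect_equal(classify_center(175), "indeterminate")
  expect_equal(classify_center(180), "indeterminate")
  expect_equal(classify_center(180 + 1e-9), "distal")
  expect_equal(classify_center(300), "distal")
})

test_that("bimodal samples switch to the fixed-plus-free double model", {
  set.seed(3)
  d <- c(rnorm(400, 135, fwhm_to_sd(75)), rnorm(400, 300, 50))
  f <- fit_distance_distribution(d[d > 0], model = "auto")
  expect_equal(f$model, "double")
  expect_equal(f$classification, "mixed")
  expect_equal(f$components$center_nm[1], 135)
  expect_equal(f$components$fwhm_nm[1], 75)
  expect_true(f$components$fixed[1])
  expect_lt(abs(f$components$center_nm[2] - 300), 15)
  # a short sample warns
  expect_warning(fit_distance_distribution(rnorm(30, 135, 30)), "unstable")
})

test_that("likelihood maps concentrate on rings at the fitted centers", {
  set.seed(4)
  f <- fit_distance_distribution(rnorm(500, 135, fwhm_to_sd(75)))
  m <- likelihood_map_2d(f, extent_nm = 300, pixel_nm = 5)
  expect_equal(max(m), 1)
  ax <- seq(-300, 300, by = 5)
  r <- sqrt(outer(ax^2, ax^2, "+"))
  peak_r <- r[which.max(m)]
  expect_lt(abs(peak_r - f$components$center_nm), 7)
  # two components: ridge amplitudes in the fitted ratio
  set.seed(5)
  d2 <- c(rnorm(600, 135, fwhm_to_sd(75)), rnorm(300, 320, 40))
  f2 <- fit_distance_distribution(d2[d2 > 0])
  m2 <- likelihood_map_2d(f2, extent_nm = 450, pixel_nm = 5)
  ax2 <- seq(-450, 450, by = 5)
  r2 <- sqrt(outer(ax2^2, ax2^2, "+"))
  ring <- function(cn) max(m2[abs(r2 - cn) < 2.5])
  amp <- f2$components$amplitude
  expect_equal(ring(f2$components$center_nm[2]) /
                 ring(f2$components$center_nm[1]),
               amp[2] / amp[1], tolerance = 0.1)
  # near-zero FWHM degenerates to a ring of the right radius
  f3 <- f
  f3$components$fwhm_nm <- 3
  m3 <- likelihood_map_2d(f3, extent_nm = 300, pixel_nm = 1)
  axf <- seq(-300, 300, by = 1)
  rf <- sqrt(outer(axf^2, axf^2, "+"))
  on_ring <- abs(rf - f$components$center_nm) < 1.5
  expect_gt(max(m3[on_ring]), 0.99)
  expect_lt(max(m3[abs(rf - f$components$center_nm) > 15]), 1e-6)
})
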