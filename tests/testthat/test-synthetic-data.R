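test_that("scene generation honours configuration and records ground truth", {
  # fully colocalized, no background: every protein cluster links to a focus
  cfg <- scene_config(n_nadna_foci = 15, n_protein_clusters = c(RPA = 20),
                      colocalized_fraction = 1, background_density_um2 = 0,
                      seed = 11)
  sc <- generate_nucleus_scene(cfg)
  prot <- sc$truth$clusters[sc$truth$clusters$channel == "RPA", ]
  expect_equal(nrow(prot), 20L)
  expect_false(any(is.na(prot$focus_id)))
  expect_true(all(prot$focus_id %in% sc$truth$foci$focus_id))
  # no protein clusters requested: table holds only naDNA (+ background)
  cfg0 <- scene_config(n_nadna_foci = 10, n_protein_clusters = c(RPA = 0),
                       background_density_um2 = 0, seed = 12)
  sc0 <- generate_nucleus_scene(cfg0)
  expect_identical(unique(as.character(sc0$locs$channel)), "naDNA")
  # invalid mixtures are rejected up front
  expect_error(scene_config(class_mixture = c("RPA-only" = .6, both = .5)),
               "sum to 1")
  expect_error(scene_config(colocalized_fraction = 1.2), "0, 1")
})

test_that("sampled focus classes follow the configured mixture", {
  mix <- c("RPA-only" = 0.5, "both" = 0.5)
  n <- 4000L
  cfg <- scene_config(locs_per_cluster = c(naDNA = 10, protein = 10))
  pop <- generate_focus_population(n, class_mixture = mix, seed = 21,
                                   config = cfg)
  counts <- table(pop$foci$class)
  # binomial oracle: 3 s.d. band around np
  sd3 <- 3 * sqrt(n * 0.5 * 0.5)
  expect_lt(abs(counts[["both"]] - n * 0.5), sd3)
  expect_equal(sum(counts), n)
  # single focus, reproducible
  one_a <- generate_focus_population(1, class_mixture = mix, seed = 5)
  one_b <- generate_focus_population(1, class_mixture = mix, seed = 5)
  expect_equal(nrow(one_a$foci), 1L)
  expect_identical(one_a, one_b)
  expect_error(
    generate_focus_population(5, class_mixture = c(nonsense = 1), seed = 1),
    "unknown focus class")
})

test_that("fixed seeds reproduce scenes bit-identically; different seeds agree in law", {
  cfg <- scene_config(n_nadna_foci = 30, seed = 33)
  a <- generate_nucleus_scene(cfg)
  b <- generate_nucleus_scene(cfg)
  expect_identical(a, b)
  cfg2 <- scene_config(n_nadna_foci = 30, seed = 34)
  c2 <- generate_nucleus_scene(cfg2)
  expect_false(identical(a$locs, c2$locs))
  # same generating law: focus centers are iid uniform in the nucleus, so
  # their coordinates from different seeds are KS-indistinguishable
  big1 <- generate_nucleus_scene(scene_config(
    n_nadna_foci = 400, locs_per_cluster = 5, seed = 35))
  big2 <- generate_nucleus_scene(scene_config(
    n_nadna_foci = 400, locs_per_cluster = 5, seed = 36))
  ks <- suppressWarnings(stats::ks.test(big1$truth$foci$x_nm,
                                        big2$truth$foci$x_nm))
  expect_gt(ks$p.value, 0.01)
})

test_that("colocalized displacements follow the Gaussian distance model", {
  cfg <- scene_config(n_nadna_foci = 600,
                      n_protein_clusters = c(RPA = 600),
                      colocalized_fraction = 1, background_density_um2 = 0,
                      locs_per_cluster = c(naDNA = 5, protein = 5),
                      nucleus = circle_roi(c(0, 0), 12000), seed = 44)
  sc <- generate_nucleus_scene(cfg)
  cl <- sc$truth$clusters
  prot <- cl[cl$channel == "RPA", ]
  foci <- sc$truth$foci
  d <- sqrt((prot$x_nm - foci$x_nm[prot$focus_id])^2 +
              (prot$y_nm - foci$y_nm[prot$focus_id])^2)
  expect_gte(length(d), 500)
  ks <- suppressWarnings(
    stats::ks.test(d, "pnorm", 135, fwhm_to_sd(75)))
  expect_gt(ks$p.value, 0.01)
})

test_that("background localization counts are Poisson with the configured density", {
  dens <- 5
  cfg <- scene_config(n_nadna_foci = 0, n_protein_clusters = c(RPA = 0),
                      background_density_um2 = dens, seed = 55)
  sc <- generate_nucleus_scene(cfg)
  area <- roi_area_um2(sc$roi)
  lambda <- dens * area
  for (ch in c("naDNA", "RPA")) {
    n_ch <- sum(sc$locs$channel == ch)
    expect_lt(abs(n_ch - lambda), 4 * sqrt(lambda))
  }
})

test_that("bead fields reproduce the requested warp and spacing", {
  # identity warp, zero noise: channels coincide
  bf <- generate_bead_field(40, 30000, warp = identity_warp(),
                            noise_sd_nm = 0, seed = 7)
  expect_equal(bf$warped$x_nm, bf$reference$x_nm, tolerance = 1e-12)
  expect_equal(bf$warped$y_nm, bf$reference$y_nm, tolerance = 1e-12)
  # minimum spacing enforced
  d <- stats::dist(cbind(bf$reference$x_nm, bf$reference$y_nm))
  expect_gte(min(d), 2000)
  # pure translation: every displacement exactly (+50, 0)
  bt <- generate_bead_field(40, 30000, warp = translation_warp(50, 0),
                            noise_sd_nm = 0, seed = 8)
  expect_equal(bt$warped$x_nm - bt$reference$x_nm, rep(50, 40))
  expect_equal(bt$warped$y_nm - bt$reference$y_nm, rep(0, 40))
  # known warp + noise: mean displacement tracks the warp field
  w <- example_warp(30000)
  n <- 400L
  bw <- generate_bead_field(n, 30000, warp = w, noise_sd_nm = 3, seed = 9,
                            min_spacing_nm = 1000)
  truth <- apply_warp(w, bw$truth$positions_nm[, 1],
                      bw$truth$positions_nm[, 2])
  # displacement errors are N(0, sd ~ sqrt(2)*3 nm): mean within 5 s.e.
  err_x <- bw$warped$x_nm - truth$x
  expect_lt(abs(mean(err_x)), 5 * sqrt(2) * 3 / sqrt(n))
  # infeasible packing is refused
  expect_error(generate_bead_field(1000, 10000, seed = 1),
               "placement error")
})

test_that("frame synthesis places photons where the molecules are", {
  # one bright molecule: brightest pixel adjacent to its true position
  l1 <- loc_table(1550, 2450)
  st <- generate_frames(l1, c(40, 40), pixel_nm = 100, psf_fwhm_nm = 300,
                        photons_per_molecule = 20000, background_level = 0,
                        seed = 3)
  peak <- which(st[, , 1] == max(st[, , 1]), arr.ind = TRUE)[1, ]
  expect_equal(unname(peak["row"]), 16)  # 1550 nm -> pixel 16 (1-based)
  expect_equal(unname(peak["col"]), 25)
  # empty table: pure background
  st0 <- generate_frames(loc_table(numeric(0), numeric(0)), c(16, 16),
                         pixel_nm = 100, psf_fwhm_nm = 300,
                         background_level = 7, n_frames = 3, seed = 4)
  expect_equal(mean(st0), 7, tolerance = 0.1)
  # photon budget: total ~ n*P + bg*npx*nframes, within Poisson error
  n_mol <- 100L
  set.seed(10)
  lm_ <- loc_table(runif(n_mol, 2000, 6000), runif(n_mol, 2000, 6000))
  lm_$frame <- sample.int(10, n_mol, replace = TRUE)
  P <- 2000; bg <- 5
  stm <- generate_frames(lm_, c(80, 80), 100, 300, P, bg, n_frames = 10,
                         seed = 5)
  expected <- n_mol * P + bg * 80 * 80 * 10
  expect_lt(abs(sum(stm) - expected), 5 * sqrt(expected))
  # frame-stack TIFF round trip is exact for 16-bit counts
  tf <- tempfile(fileext = ".tif")
  write_frames(st0, tf)
  back <- read_frames(tf, pixel_nm = 100)
  expect_equal(unclass(back)[seq_along(st0)], as.numeric(st0))
})
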