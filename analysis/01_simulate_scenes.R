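#!/usr/bin/env Rscript
# Simulate the study's raw inputs with known ground truth: one multicolor
# nucleus scene (naDNA + RPA + RAD51 localizations inside a nuclear ROI), a
# two-channel fiducial bead field with a known chromatic warp, and a short
# raw frame stack for the localizer. Everything downstream (02-04) starts
# from these files.

suppressPackageStartupMessages(library(smlmcoloc))
set.seed(1)
outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

## A damaged-cell-like nucleus: 60 naDNA foci, RPA and RAD51 clusters with
## most RPA colocalized (early resection) and fewer RAD51.
cfg <- scene_config(
  n_nadna_foci = 60,
  n_protein_clusters = c(RPA = 60, RAD51 = 40),
  colocalized_fraction = c(RPA = 0.7, RAD51 = 0.4),
  seed = 101)
scene <- generate_nucleus_scene(cfg)
write_localizations(scene$locs, file.path(outdir, "scene_locs.csv"))
write_roi(scene$roi, file.path(outdir, "scene_roi.json"))
jsonlite::write_json(scene$truth[c("foci", "clusters")],
                     file.path(outdir, "scene_truth.json"),
                     auto_unbox = TRUE, digits = NA)
message(sprintf("scene: %d localizations over %s channels, ROI %.1f um^2",
                nrow(scene$locs),
                paste(unique(scene$locs$channel), collapse = "/"),
                roi_area_um2(scene$roi)))

## Bead field for chromatic calibration: 100 beads, 40 x 40 um, degree-3
## warp (max displacement ~150 nm), 3 nm localization noise per axis.
warp <- example_warp(40000)
beads <- generate_bead_field(100, 40000, warp = warp, noise_sd_nm = 3,
                             seed = 102)
write_localizations(beads$reference, file.path(outdir, "beads_red.csv"))
write_localizations(beads$warped, file.path(outdir, "beads_blue.csv"))
message("bead field: 100 beads per channel written")

## A short raw stack (100 nm camera pixels, 300 nm PSF) for the localizer.
set.seed(103)
n_mol <- 120
frame_locs <- data.frame(
  x_nm = runif(n_mol, 500, 12300), y_nm = runif(n_mol, 500, 12300),
  frame = sample.int(30, n_mol, replace = TRUE), channel = "red",
  intensity = 1, precision_nm = 10)
stack <- generate_frames(frame_locs, c(128, 128), pixel_nm = 100,
                         psf_fwhm_nm = 300, photons_per_molecule = 4000,
                         background_level = 20, n_frames = 30, seed = 104)
write_frames(stack, file.path(outdir, "raw_stack.tif"))
write_localizations(frame_locs, file.path(outdir, "raw_truth.csv"))
message("raw stack: 30 frames, 120 molecules")
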