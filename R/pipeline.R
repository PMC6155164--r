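# End-to-end orchestration: render and segment a scene's channels, score
# colocalization per nucleus, identify and classify foci, and aggregate a
# cohort - with a JSON manifest recording seeds, parameters and per-nucleus
# exclusions so a run replays bit-identically.

#' Render and segment every channel of a scene
#'
#' @param locs Localization table with a `channel` column.
#' @param roi The nucleus ROI.
#' @param pixel_nm Render pixel size (default 20 nm).
#' @param mode Render mode (`"counts"` or `"gaussian"`).
#' @param channels Channels to segment (default: all present).
#' @param grid Optional `grid_spec`; default covers the ROI bounding box.
#' @return List with `sets` (named list of `cluster_set`s), `grid`, `mask`.
#' @export
segment_scene <- function(locs, roi, pixel_nm = 20, mode = "counts",
                          channels = NULL, grid = NULL) {
  if (is.null(channels)) channels <- unique(as.character(locs$channel))
  if (is.null(grid)) {
    bb <- apply(roi$vertices, 2, range)
    grid <- grid_for_bbox(bb[, 1], bb[, 2], pixel_nm = pixel_nm)
  }
  mask <- roi_mask(roi, grid)
  sets <- lapply(channels, function(ch) {
    img <- render(locs[locs$channel == ch, , drop = FALSE], grid,
                  mode = mode, channel = ch)
    segment_channel(img, roi, mask = mask)
  })
  names(sets) <- channels
  list(sets = sets, grid = grid, mask = mask)
}

#' Identify and pool focus records across a cohort of nuclei
#'
#' Segments each nucleus of a focus population (e.g. from
#' [generate_focus_population()]), identifies repair foci, and pools the
#' records.
#'
#' @param nuclei List of `list(roi, locs)` per nucleus.
#' @param proteins Protein channel names.
#' @param association_radius_nm Passed to [identify_foci()].
#' @param pixel_nm Render pixel size.
#' @param mode Render mode.
#' @return A pooled `focus_records` data.frame (attribute `n_nadna_only`
#'   summed over nuclei).
#' @export
identify_foci_cohort <- function(nuclei, proteins,
                                 association_radius_nm = 250,
                                 pixel_nm = 20, mode = "counts") {
  recs <- vector("list", length(nuclei))
  n_only <- 0L
  for (i in seq_along(nuclei)) {
    sc <- segment_scene(nuclei[[i]]$locs, nuclei[[i]]$roi,
                        pixel_nm = pixel_nm, mode = mode,
                        channels = c("naDNA", proteins))
    r <- identify_foci(sc$sets[["naDNA"]], sc$sets[proteins],
                       association_radius_nm = association_radius_nm)
    n_only <- n_only + attr(r, "n_nadna_only")
    recs[[i]] <- r
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "n_nadna_only") <- n_only
  attr(out, "proteins") <- proteins
  class(out) <- c("focus_records", class(out))
  out
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates the stage sequence (chromatic mapping, rendering,
#' segmentation, Monte Carlo colocalization, focus analysis) over a cohort
#' of seeded synthetic nuclei described by the configuration, writes all
#' stage outputs under `config$outdir`, and records a JSON manifest with
#' the seed, parameters, config hash and per-nucleus exclusions.
#'
#' Configuration fields (YAML-compatible; see the package vignette):
#' `seed`, `outdir`, `pixel_nm` (20), `n_sims` (20),
#' `association_radius_nm` (250), `reference_condition`, `stages` (named
#' logical toggles `mapping`, `colocalization`, `foci`), optional `mapping`
#' (bead-field simulation parameters), and `cohort`: a list of groups, each
#' with `condition`, `timepoint`, `n_nuclei`, `protein`, and `scene`
#' parameters forwarded to [scene_config()].
#'
#' @param config Configuration list or path to a YAML file.
#' @return Invisibly, a results bundle: per-nucleus `coloc` results,
#'   `summary`, `heatmap`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(is.list(config), !is.null(config$cohort), !is.null(config$seed))
  outdir <- config$outdir %||% stop("config$outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pixel_nm <- config$pixel_nm %||% 20
  n_sims <- config$n_sims %||% 20L
  assoc_nm <- config$association_radius_nm %||% 250
  stages <- config$stages %||% list()
  stage_on <- function(s) isTRUE(stages[[s]] %||% TRUE)
  seed <- as.integer(config$seed)
  manifest <- list(package = "smlmcoloc",
                   version = as.character(utils::packageVersion("smlmcoloc")),
                   seed = seed, pixel_nm = pixel_nm, n_sims = n_sims,
                   association_radius_nm = assoc_nm,
                   config_hash = config_hash(config),
                   stages_disabled = character(0),
                   exclusions = list())
  # chromatic mapping stage: calibrate on a simulated bead field and carry
  # the fitted map; scenes below are generated in the reference frame, so
  # applying the identity-direction map documents the calibration path.
  map <- NULL
  if (stage_on("mapping")) {
    mp <- config$mapping %||% list()
    bf <- generate_bead_field(
      n_beads = mp$n_beads %||% 100L,
      field_size_nm = mp$field_size_nm %||% 40000,
      warp = example_warp(mp$field_size_nm %||% 40000),
      noise_sd_nm = mp$noise_sd_nm %||% 3,
      seed = derive_seed(seed, 9000L))
    pairs <- match_beads(bf$warped, bf$reference)
    map <- fit_polynomial_map(pairs, source = "blue", target = "red")
    write_chromatic_map(map, file.path(outdir, "chromatic_map.json"))
    manifest$mapping_error_nm <- mapping_error_nm(map)
  } else {
    manifest$stages_disabled <- c(manifest$stages_disabled, "mapping")
    manifest$mapping_note <- "mapping disabled: coordinates uncorrected"
  }
  coloc_rows <- list()
  results <- list()
  ni <- 0L
  for (g in config$cohort) {
    for (r in seq_len(g$n_nuclei)) {
      ni <- ni + 1L
      nuc_seed <- derive_seed(seed, ni)
      sc_args <- g$scene %||% list()
      sc_args$seed <- nuc_seed
      if (!is.null(sc_args$n_protein_clusters))
        sc_args$n_protein_clusters <- unlist(sc_args$n_protein_clusters)
      cfg <- do.call(scene_config, sc_args)
      scene <- generate_nucleus_scene(cfg)
      scene$roi$id <- sprintf("%s_t%s_n%02d", g$condition, g$timepoint, r)
      seg <- segment_scene(scene$locs, scene$roi, pixel_nm = pixel_nm)
      if (stage_on("colocalization")) {
        res <- tryCatch(
          colocalization_coefficient(
            seg$sets[["naDNA"]], seg$sets[[g$protein]], scene$roi,
            n_sims = n_sims, seed = derive_seed(nuc_seed, 1L),
            mask = seg$mask),
          error = function(e) e)
        if (inherits(res, "error"))
          stop("colocalization stage failed for nucleus '", scene$roi$id,
               "': ", conditionMessage(res))
        mode_g <- g$mode %||% coefficient_mode(g$protein)
        coefficient <- if (mode_g == "number") res$coefficient_number
        else res$coefficient_area
        flag <- if (mode_g == "number") res$flag_number else res$flag_area
        if (!is.na(flag))
          manifest$exclusions[[scene$roi$id]] <- flag
        write_coloc_json(res, file.path(
          outdir, paste0("coloc_", scene$roi$id, ".json")))
        coloc_rows[[ni]] <- data.frame(
          protein = g$protein, condition = g$condition,
          timepoint = g$timepoint, nucleus = scene$roi$id,
          mode = mode_g, coefficient = coefficient)
        results[[scene$roi$id]] <- res
      }
    }
  }
  bundle <- list(manifest = manifest)
  if (length(coloc_rows)) {
    coloc_df <- do.call(rbind, coloc_rows)
    utils::write.csv(coloc_df, file.path(outdir, "coefficients.csv"),
                     row.names = FALSE)
    summary <- summarize_population(coloc_df,
                                    reference = config$reference_condition)
    utils::write.csv(summary, file.path(outdir, "population_summary.csv"),
                     row.names = FALSE)
    bundle$coloc <- results
    bundle$summary <- summary
    per_cond <- split(summary, summary$condition)
    hm <- tryCatch(build_timecourse_heatmap(
      per_cond[[setdiff(names(per_cond), config$reference_condition)[1] %||%
                  1L]]), error = function(e) NULL)
    if (!is.null(hm)) {
      utils::write.csv(hm, file.path(outdir, "timecourse_heatmap.csv"))
      bundle$heatmap <- hm
    }
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(bundle)
}
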