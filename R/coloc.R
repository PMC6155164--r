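# Monte Carlo randomization colocalization. The observed overlap (number or
# area) between two channels' cluster sets is ratioed to the average overlap
# across simulations in which one channel's clusters are rigidly relocated
# to uniform random positions inside the nucleus ROI. A coefficient of 1
# means the observed overlap equals chance expectation for that nucleus; 2
# means a doubling above chance.

#' Count and measure overlaps between two cluster sets
#'
#' The overlap *area* is the total area of the pixelwise intersection of the
#' two channels' union masks (symmetric). The overlap *number* is the count
#' of clusters of `set_a` (by convention the fixed / nascent-DNA channel)
#' that intersect at least one cluster of `set_b` (asymmetric).
#'
#' @param set_a,set_b `cluster_set`s on the same grid.
#' @return List with `n_overlaps` and `overlap_area_nm2`.
#' @export
count_overlaps <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "cluster_set"), inherits(set_b, "cluster_set"))
  if (!same_grid(set_a$grid, set_b$grid))
    stop("cluster sets are on different grids")
  mask_b <- set_union_mask(set_b)
  n_overlaps <- sum(vapply(set_a$pixels, function(p) any(mask_b[p]),
                           logical(1)))
  mask_a <- set_union_mask(set_a)
  overlap_px <- sum(mask_a & mask_b)
  list(n_overlaps = as.integer(n_overlaps),
       overlap_area_nm2 = overlap_px * set_a$grid$pixel_nm^2)
}

#' Relocate clusters uniformly at random within an ROI
#'
#' Each cluster's pixel mask is rigidly translated (no rotation by default)
#' to a uniform random position at which the whole mask lies inside the ROI;
#' shapes and areas are preserved exactly and relocated clusters may overlap
#' one another. Candidate anchors are drawn by rejection sampling over the
#' in-ROI pixels with a retry cap.
#'
#' @param set A `cluster_set`.
#' @param roi The `nucleus_roi` to redistribute within.
#' @param seed Integer seed (required for reproducibility).
#' @param mask Optional precomputed ROI mask.
#' @param allow_rotation If `TRUE`, each cluster is additionally rotated by a
#'   random multiple of 90 degrees (pixel-exact). Off by default.
#' @param max_retries Rejection-sampling cap per cluster.
#' @return A new `cluster_set` with identical areas and pixel counts.
#' @export
randomize_clusters <- function(set, roi, seed, mask = NULL,
                               allow_rotation = FALSE, max_retries = 10000L) {
  stopifnot(inherits(set, "cluster_set"), inherits(roi, "nucleus_roi"))
  grid <- set$grid
  if (is.null(mask)) mask <- roi_mask(roi, grid)
  roi_lin <- which(mask)
  if (length(roi_lin) == 0L) stop("ROI mask is empty on this grid")
  nx <- grid$dim_px[1]; ny <- grid$dim_px[2]
  roi_ij <- lin_to_px(grid, roi_lin)
  local_seed(seed, {
    new_pixels <- vector("list", length(set$pixels))
    shift_px <- matrix(0L, length(set$pixels), 2)
    for (k in seq_along(set$pixels)) {
      p <- lin_to_px(grid, set$pixels[[k]])
      oi <- p$ix; oj <- p$iy
      if (allow_rotation) {
        rot <- sample.int(4L, 1L) - 1L
        for (r in seq_len(rot)) { tmp <- oi; oi <- -oj; oj <- tmp }
      }
      # offsets relative to the mask's reference pixel (its first pixel)
      di <- oi - oi[1]; dj <- oj - oj[1]
      ri <- range(di); rj <- range(dj)
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        a <- sample.int(length(roi_lin), 1L)
        ai <- roi_ij$ix[a]; aj <- roi_ij$iy[a]
        if (ai + ri[1] < 0L || ai + ri[2] >= nx ||
            aj + rj[1] < 0L || aj + rj[2] >= ny) next
        lin <- px_to_lin(grid, ai + di, aj + dj)
        if (all(mask[lin])) {
          new_pixels[[k]] <- lin
          shift_px[k, ] <- c(ai - p$ix[1], aj - p$iy[1])
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("randomization failed: cluster ", set$clusters$id[k],
             " (", length(p$ix), " px) cannot be placed inside ROI '",
             roi$id, "' within ", max_retries, " retries")
    }
    out <- set
    out$pixels <- new_pixels
    out$clusters$com_x_nm <- set$clusters$com_x_nm + shift_px[, 1] * grid$pixel_nm
    out$clusters$com_y_nm <- set$clusters$com_y_nm + shift_px[, 2] * grid$pixel_nm
    out
  })
}

#' Normalize an observed overlap by simulated overlaps
#'
#' The colocalization coefficient: observed overlap divided by the mean of
#' the simulated overlaps. Returns `NA` with an
#' `insufficient-randomization-overlap` flag when the simulation mean is
#' zero (rather than an infinite ratio).
#'
#' @param observed Observed overlap (number or area).
#' @param simulated Vector of simulated overlaps.
#' @return List with `coefficient` and `flag` (character or `NA`).
#' @export
coloc_ratio <- function(observed, simulated) {
  stopifnot(length(simulated) >= 1L, observed >= 0, all(simulated >= 0))
  m <- mean(simulated)
  if (m == 0)
    return(list(coefficient = NA_real_,
                flag = "insufficient-randomization-overlap"))
  list(coefficient = observed / m, flag = NA_character_)
}

#' Monte Carlo colocalization coefficient for one nucleus
#'
#' Runs `n_sims` cluster randomizations of the `set_random` channel (the
#' protein channel, keeping the fixed channel's "real" distribution),
#' recomputes overlaps against `set_fixed` each time, and ratios the real
#' overlap number and area to the simulation means.
#'
#' @param set_fixed Cluster set kept in place (convention: nascent DNA).
#' @param set_random Cluster set redistributed in each simulation.
#' @param roi The nucleus ROI.
#' @param n_sims Number of randomizations (default 20).
#' @param seed Master seed; per-simulation sub-seeds come from
#'   [derive_seed()].
#' @param mask Optional precomputed ROI mask.
#' @param allow_rotation Passed to [randomize_clusters()].
#' @return A `coloc_result`: nucleus id, channel pair, real overlap number
#'   and area, the simulated values, both coefficients, flags, seed.
#' @export
colocalization_coefficient <- function(set_fixed, set_random, roi,
                                       n_sims = 20L, seed,
                                       mask = NULL, allow_rotation = FALSE) {
  stopifnot(n_sims >= 1L)
  if (!same_grid(set_fixed$grid, set_random$grid))
    stop("cluster sets are on different grids")
  if (is.null(mask)) mask <- roi_mask(roi, set_fixed$grid)
  real <- count_overlaps(set_fixed, set_random)
  sim_counts <- integer(n_sims)
  sim_areas <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    rs <- randomize_clusters(set_random, roi, seed = derive_seed(seed, s),
                             mask = mask, allow_rotation = allow_rotation)
    ov <- count_overlaps(set_fixed, rs)
    sim_counts[s] <- ov$n_overlaps
    sim_areas[s] <- ov$overlap_area_nm2
  }
  rn <- coloc_ratio(real$n_overlaps, sim_counts)
  ra <- coloc_ratio(real$overlap_area_nm2, sim_areas)
  structure(list(
    nucleus = roi$id,
    channel_fixed = set_fixed$channel,
    channel_random = set_random$channel,
    n_real = real$n_overlaps,
    area_real_nm2 = real$overlap_area_nm2,
    sim_counts = sim_counts,
    sim_areas_nm2 = sim_areas,
    n_sims = as.integer(n_sims),
    coefficient_number = rn$coefficient,
    coefficient_area = ra$coefficient,
    flag_number = rn$flag,
    flag_area = ra$flag,
    seed = seed
  ), class = "coloc_result")
}

#' Per-protein default coefficient mode
#'
#' Overlap *number* is used for proteins whose clusters stay discrete
#' (MRE11, BRCA1, CtIP, BLM); overlap *area* for proteins expected to
#' accumulate over time (gH2AX, RPA, RAD51, RAD52, BRCA2). Unknown proteins
#' default to `"area"`.
#'
#' @param protein Character vector of protein names.
#' @return Character vector, `"number"` or `"area"`.
#' @export
coefficient_mode <- function(protein) {
  number_set <- c("MRE11", "BRCA1", "CTIP", "BLM")
  ifelse(toupper(protein) %in% number_set, "number", "area")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "<coloc_result> nucleus '%s' (%s vs randomized %s):\n", x$nucleus,
    x$channel_fixed, x$channel_random))
  cat(sprintf("  number: real %d / sim mean %.2f -> coefficient %.3f%s\n",
              x$n_real, mean(x$sim_counts), x$coefficient_number,
              if (!is.na(x$flag_number)) paste0(" [", x$flag_number, "]") else ""))
  cat(sprintf("  area:   real %.0f / sim mean %.0f nm^2 -> coefficient %.3f%s\n",
              x$area_real_nm2, mean(x$sim_areas_nm2), x$coefficient_area,
              if (!is.na(x$flag_area)) paste0(" [", x$flag_area, "]") else ""))
  invisible(x)
}
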