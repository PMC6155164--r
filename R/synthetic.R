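# Seeded synthetic-scene generator. Real acquisitions in this assay are
# nuclei containing nascent-DNA (naDNA) replication/repair foci plus protein
# clusters, a configurable fraction of which sit at foci, displaced from the
# focus center by a Gaussian-distance model; the remainder and a uniform
# background are spatially random. The generator reproduces that statistical
# structure with full ground truth so every downstream stage can be
# validated against known truth.

#' Channel-specific default localization precisions (nm)
#'
#' Typical single-molecule fitting uncertainties for the red, blue and green
#' channels of a three-color STORM acquisition.
#' @format Named numeric vector (nm).
#' @export
CHANNEL_PRECISION_NM <- c(red = 9.5, blue = 9.3, green = 17.7)

#' Scene configuration for the synthetic generator
#'
#' @param nucleus A `nucleus_roi`, or `NULL` for the default circular
#'   nucleus of 10 um diameter.
#' @param n_nadna_foci Number of naDNA foci.
#' @param n_protein_clusters Named integer vector: clusters per protein
#'   channel.
#' @param colocalized_fraction Named (or scalar) fraction in [0, 1] of each
#'   protein's clusters that sit at a naDNA focus.
#' @param class_mixture Optional named probabilities over focus classes
#'   (e.g. `c("RPA-only" = .714, both = .221, "RAD51-only" = .065)`); when
#'   given, protein clusters are placed per focus class instead of by
#'   `colocalized_fraction` counts.
#' @param cluster_radius_range Protein cluster radius range (nm).
#' @param nadna_radius_range naDNA focus radius range (nm).
#' @param displacement_model `list(center_nm, fwhm_nm)` for the scalar
#'   distance between a colocalized protein cluster center and its focus
#'   center (direction uniform on [0, 2pi)).
#' @param background_density_um2 Uniform background localizations per um^2
#'   per channel.
#' @param locs_per_cluster Mean localizations per cluster; scalar, or named
#'   with entries `naDNA` and `protein`. Counts are log-normal
#'   (`locs_sdlog`), floored at 5.
#' @param locs_sdlog Log-sd of the localization-count distribution.
#' @param localization_precision_nm Per-localization isotropic Gaussian
#'   noise s.d. (nm); scalar or named per channel.
#' @param seed Integer seed; a fixed seed makes every output bit-identical.
#' @return A validated `scene_config`.
#' @export
scene_config <- function(nucleus = NULL,
                         n_nadna_foci = 60L,
                         n_protein_clusters = c(RPA = 60L, RAD51 = 60L),
                         colocalized_fraction = 0.5,
                         class_mixture = NULL,
                         cluster_radius_range = c(40, 100),
                         nadna_radius_range = c(50, 100),
                         displacement_model = list(center_nm = 135,
                                                   fwhm_nm = 75),
                         background_density_um2 = 0.5,
                         locs_per_cluster = c(naDNA = 200, protein = 80),
                         locs_sdlog = 0.4,
                         localization_precision_nm = 9.5,
                         seed = 1L) {
  if (is.null(nucleus)) nucleus <- circle_roi(c(0, 0), 5000)
  stopifnot(inherits(nucleus, "nucleus_roi"),
            n_nadna_foci >= 0,
            all(n_protein_clusters >= 0),
            !is.null(names(n_protein_clusters)),
            all(cluster_radius_range > 0), all(nadna_radius_range > 0),
            displacement_model$center_nm >= 0,
            displacement_model$fwhm_nm > 0,
            background_density_um2 >= 0,
            all(locs_per_cluster > 0), locs_sdlog >= 0,
            all(localization_precision_nm > 0))
  proteins <- names(n_protein_clusters)
  if (length(colocalized_fraction) == 1L && is.null(names(colocalized_fraction)))
    colocalized_fraction <- stats::setNames(
      rep(colocalized_fraction, length(proteins)), proteins)
  if (any(colocalized_fraction < 0 | colocalized_fraction > 1))
    stop("colocalized_fraction must lie in [0, 1]")
  if (!is.null(class_mixture)) {
    if (any(class_mixture < 0 | class_mixture > 1))
      stop("class_mixture probabilities must lie in [0, 1]")
    if (abs(sum(class_mixture) - 1) > 1e-9)
      stop("class_mixture must sum to 1 (got ", sum(class_mixture), ")")
  }
  structure(list(nucleus = nucleus, n_nadna_foci = as.integer(n_nadna_foci),
                 n_protein_clusters = n_protein_clusters,
                 colocalized_fraction = colocalized_fraction,
                 class_mixture = class_mixture,
                 cluster_radius_range = cluster_radius_range,
                 nadna_radius_range = nadna_radius_range,
                 displacement_model = displacement_model,
                 background_density_um2 = background_density_um2,
                 locs_per_cluster = locs_per_cluster,
                 locs_sdlog = locs_sdlog,
                 localization_precision_nm = localization_precision_nm,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# empty localization table with the package's canonical columns
empty_locs <- function() {
  data.frame(x_nm = numeric(0), y_nm = numeric(0), frame = integer(0),
             channel = character(0), intensity = numeric(0),
             precision_nm = numeric(0))
}

make_locs <- function(x, y, channel, precision_nm, n_frames = 2000L) {
  n <- length(x)
  if (n == 0L) return(empty_locs())
  data.frame(x_nm = x, y_nm = y,
             frame = sample.int(n_frames, n, replace = TRUE),
             channel = channel,
             intensity = stats::rlnorm(n, log(1000), 0.3),
             precision_nm = precision_nm)
}

precision_for <- function(config, channel) {
  p <- config$localization_precision_nm
  if (!is.null(names(p)) && channel %in% names(p)) unname(p[channel])
  else unname(p[1])
}

locs_mean_for <- function(config, channel) {
  m <- config$locs_per_cluster
  if (!is.null(names(m))) {
    if (channel %in% names(m)) return(unname(m[channel]))
    if (channel == "naDNA" && "naDNA" %in% names(m)) return(unname(m["naDNA"]))
    if ("protein" %in% names(m) && channel != "naDNA")
      return(unname(m["protein"]))
  }
  unname(m[1])
}

# localizations of one cluster: isotropic Gaussian of sd = radius/2 around
# the center, plus per-localization precision noise
sample_cluster_locs <- function(center, radius_nm, n_mean, sdlog,
                                precision_nm) {
  n <- max(5L, round(stats::rlnorm(1, log(n_mean) - sdlog^2 / 2, sdlog)))
  sd_tot <- sqrt((radius_nm / 2)^2 + precision_nm^2)
  cbind(stats::rnorm(n, center[1], sd_tot), stats::rnorm(n, center[2], sd_tot))
}

# scalar displacement distance from the Gaussian model (rejection at r < 0),
# uniform direction
sample_displacement <- function(n, model) {
  mu <- model$center_nm; s <- fwhm_to_sd(model$fwhm_nm)
  r <- stats::rnorm(n, mu, s)
  while (any(bad <- r < 0)) r[bad] <- stats::rnorm(sum(bad), mu, s)
  th <- stats::runif(n, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th))
}

# Cluster-center offsets for the proteins present at one focus. A lone
# protein sits at a model-drawn distance from the focus center; when two
# proteins share a focus the model describes their *mutual* separation (it
# is calibrated on double-labeled pairs), so the pair is placed
# symmetrically about the focus center with separation drawn from the model.
protein_offsets <- function(present, model) {
  n <- length(present)
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  if (n == 1L) return(sample_displacement(1L, model))
  d <- sample_displacement(1L, model)
  rbind(d / 2, -d / 2)
}

# resolve class definitions: class name -> protein channels present
resolve_classes <- function(mixture, proteins, classes = NULL) {
  if (!is.null(classes)) {
    missing <- setdiff(names(mixture), names(classes))
    if (length(missing))
      stop("unknown focus class(es): ", paste(missing, collapse = ", "))
    return(classes[names(mixture)])
  }
  out <- lapply(names(mixture), function(nm) {
    if (nm %in% c("both", "mixed")) return(proteins)
    only <- sub("[-_ ]only$", "", nm)
    if (only %in% proteins) return(only)
    stop("unknown focus class '", nm, "': use '<protein>-only', 'both', ",
         "'mixed', or supply `classes` explicitly")
  })
  stats::setNames(out, names(mixture))
}

#' Generate a full synthetic nucleus scene
#'
#' Produces a localization table for the naDNA channel, each protein
#' channel, and uniform background, together with the nucleus ROI and a
#' ground-truth record of every cluster and focus assignment.
#'
#' Cluster member localizations are drawn from an isotropic Gaussian of
#' s.d. = radius/2 around the cluster center, convolved with the
#' localization precision. Colocalized protein clusters are displaced from
#' their focus center by a distance from the displacement model in a
#' uniform random direction. Cluster centers must lie inside the ROI
#' (member localizations may spill over the boundary, as real foci touch
#' the nuclear edge).
#'
#' @param config A `scene_config`.
#' @return List with `locs` (localization table), `roi`, and `truth`
#'   (`foci` and `clusters` data.frames plus the config).
#' @export
generate_nucleus_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  local_seed(config$seed, {
    roi <- config$nucleus
    proteins <- names(config$n_protein_clusters)
    foci <- data.frame(focus_id = integer(0), x_nm = numeric(0),
                       y_nm = numeric(0), class = character(0))
    clusters <- data.frame(cluster_id = integer(0), channel = character(0),
                           x_nm = numeric(0), y_nm = numeric(0),
                           radius_nm = numeric(0), focus_id = integer(0),
                           n_locs = integer(0))
    locs_list <- list()
    cl_id <- 0L
    add_cluster <- function(channel, center, radius, focus_id) {
      cl_id <<- cl_id + 1L
      pts <- sample_cluster_locs(center, radius,
                                 locs_mean_for(config, channel),
                                 config$locs_sdlog,
                                 precision_for(config, channel))
      locs_list[[length(locs_list) + 1L]] <<-
        make_locs(pts[, 1], pts[, 2], channel, precision_for(config, channel))
      clusters[nrow(clusters) + 1L, ] <<-
        list(cl_id, channel, center[1], center[2], radius,
             if (is.na(focus_id)) NA_integer_ else as.integer(focus_id),
             nrow(pts))
    }
    # naDNA foci
    nf <- config$n_nadna_foci
    if (nf > 0L) {
      ctr <- runif_in_roi(roi, nf)
      cls <- if (!is.null(config$class_mixture))
        sample(names(config$class_mixture), nf, replace = TRUE,
               prob = config$class_mixture)
      else rep(NA_character_, nf)
      foci <- data.frame(focus_id = seq_len(nf), x_nm = ctr[, 1],
                         y_nm = ctr[, 2], class = cls)
      radn <- stats::runif(nf, config$nadna_radius_range[1],
                           config$nadna_radius_range[2])
      for (i in seq_len(nf)) add_cluster("naDNA", ctr[i, ], radn[i], i)
    }
    # protein clusters
    if (!is.null(config$class_mixture) && nf > 0L) {
      cdef <- resolve_classes(config$class_mixture, proteins)
      for (i in seq_len(nf)) {
        present <- cdef[[foci$class[i]]]
        offs <- protein_offsets(present, config$displacement_model)
        for (k in seq_along(present)) {
          add_cluster(present[k],
                      c(foci$x_nm[i] + offs[k, 1], foci$y_nm[i] + offs[k, 2]),
                      stats::runif(1, config$cluster_radius_range[1],
                                   config$cluster_radius_range[2]), i)
        }
      }
    } else {
      for (ch in proteins) {
        n_ch <- config$n_protein_clusters[[ch]]
        if (n_ch == 0L) next
        n_col <- round(config$colocalized_fraction[[ch]] * n_ch)
        if (n_col > 0L && nf == 0L)
          stop("colocalized clusters requested but the scene has no foci")
        rad <- stats::runif(n_ch, config$cluster_radius_range[1],
                            config$cluster_radius_range[2])
        if (n_col > 0L) {
          host <- sample.int(nf, n_col, replace = n_col > nf)
          d <- sample_displacement(n_col, config$displacement_model)
          for (i in seq_len(n_col))
            add_cluster(ch, c(foci$x_nm[host[i]] + d[i, 1],
                              foci$y_nm[host[i]] + d[i, 2]), rad[i], host[i])
        }
        if (n_ch - n_col > 0L) {
          free <- runif_in_roi(roi, n_ch - n_col)
          for (i in seq_len(n_ch - n_col))
            add_cluster(ch, free[i, ], rad[n_col + i], NA)
        }
      }
    }
    # uniform background per channel
    if (config$background_density_um2 > 0) {
      for (ch in c("naDNA", proteins)) {
        nb <- stats::rpois(1, config$background_density_um2 * roi_area_um2(roi))
        if (nb > 0L) {
          pts <- runif_in_roi(roi, nb)
          locs_list[[length(locs_list) + 1L]] <-
            make_locs(pts[, 1], pts[, 2], ch, precision_for(config, ch))
        }
      }
    }
    locs <- if (length(locs_list)) do.call(rbind, locs_list) else empty_locs()
    rownames(locs) <- NULL
    list(locs = locs, roi = roi,
         truth = list(foci = foci, clusters = clusters, config = config))
  })
}

#' Generate a population of classed repair foci
#'
#' Each focus carries one class sampled from `class_mixture`; protein
#' clusters are placed only for the channels present in that class,
#' displaced from the focus center per the displacement model. Foci are laid
#' out on jittered grids inside square nuclei so neighbouring foci stay well
#' separated (spacing >> the focus association radius); every nucleus
#' carries its own ROI.
#'
#' @param n_foci Total number of foci (>= 1).
#' @param proteins Character vector of the two protein channel names.
#' @param class_mixture Named probabilities (summing to 1) over classes such
#'   as `"<A>-only"`, `"<B>-only"`, `"both"`.
#' @param displacement_model `list(center_nm, fwhm_nm)`.
#' @param seed Integer seed.
#' @param foci_per_nucleus Foci per synthetic nucleus (default 100).
#' @param focus_spacing_nm Grid pitch between foci (default 1500 nm).
#' @param classes Optional explicit class definitions (named list of
#'   channel vectors) overriding name parsing.
#' @param config Optional `scene_config` supplying cluster radii, counts and
#'   precisions (nucleus/class fields are ignored).
#' @return List with `nuclei` (per-nucleus `list(roi, locs)`), `foci`
#'   (ground-truth data.frame: nucleus, focus_id, x/y, class, per-protein
#'   presence), and `proteins`.
#' @export
generate_focus_population <- function(n_foci, proteins = c("RPA", "RAD51"),
                                      class_mixture,
                                      displacement_model = list(
                                        center_nm = 135, fwhm_nm = 75),
                                      seed = 1L,
                                      foci_per_nucleus = 100L,
                                      focus_spacing_nm = 1500,
                                      classes = NULL,
                                      config = NULL) {
  stopifnot(n_foci >= 1L, length(proteins) >= 1L)
  if (abs(sum(class_mixture) - 1) > 1e-9)
    stop("class_mixture must sum to 1 (got ", sum(class_mixture), ")")
  cdef <- resolve_classes(class_mixture, proteins, classes)
  if (is.null(config)) config <- scene_config(seed = seed)
  local_seed(seed, {
    n_nuc <- ceiling(n_foci / foci_per_nucleus)
    nuclei <- vector("list", n_nuc)
    foci_rows <- vector("list", n_nuc)
    remaining <- n_foci
    fid <- 0L
    for (nuc in seq_len(n_nuc)) {
      nf <- min(remaining, foci_per_nucleus)
      remaining <- remaining - nf
      side <- ceiling(sqrt(nf))
      margin <- 600
      jitter <- focus_spacing_nm / 7.5   # keeps min separation > 1000 nm
      slots <- sample.int(side * side, nf)
      gx <- ((slots - 1L) %% side + 0.5) * focus_spacing_nm +
        stats::runif(nf, -jitter, jitter)
      gy <- ((slots - 1L) %/% side + 0.5) * focus_spacing_nm +
        stats::runif(nf, -jitter, jitter)
      lim <- side * focus_spacing_nm + margin
      roi <- rect_roi(c(-margin, lim), c(-margin, lim),
                      id = sprintf("nucleus_%03d", nuc))
      cls <- sample(names(class_mixture), nf, replace = TRUE,
                    prob = class_mixture)
      locs_list <- list()
      pres <- matrix(FALSE, nf, length(proteins),
                     dimnames = list(NULL, proteins))
      for (i in seq_len(nf)) {
        rad_na <- stats::runif(1, config$nadna_radius_range[1],
                               config$nadna_radius_range[2])
        pts <- sample_cluster_locs(c(gx[i], gy[i]), rad_na,
                                   locs_mean_for(config, "naDNA"),
                                   config$locs_sdlog,
                                   precision_for(config, "naDNA"))
        locs_list[[length(locs_list) + 1L]] <-
          make_locs(pts[, 1], pts[, 2], "naDNA",
                    precision_for(config, "naDNA"))
        present <- cdef[[cls[i]]]
        offs <- protein_offsets(present, displacement_model)
        for (k in seq_along(present)) {
          ch <- present[k]
          pres[i, ch] <- TRUE
          ctr <- c(gx[i] + offs[k, 1], gy[i] + offs[k, 2])
          rad <- stats::runif(1, config$cluster_radius_range[1],
                              config$cluster_radius_range[2])
          pts <- sample_cluster_locs(ctr, rad, locs_mean_for(config, ch),
                                     config$locs_sdlog,
                                     precision_for(config, ch))
          locs_list[[length(locs_list) + 1L]] <-
            make_locs(pts[, 1], pts[, 2], ch, precision_for(config, ch))
        }
      }
      locs <- do.call(rbind, locs_list)
      rownames(locs) <- NULL
      nuclei[[nuc]] <- list(roi = roi, locs = locs)
      foci_rows[[nuc]] <- data.frame(nucleus = roi$id,
                                     focus_id = fid + seq_len(nf),
                                     x_nm = gx, y_nm = gy, class = cls,
                                     pres)
      fid <- fid + nf
    }
    foci <- do.call(rbind, foci_rows)
    rownames(foci) <- NULL
    list(nuclei = nuclei, foci = foci, proteins = proteins)
  })
}

#' Geometric clusters placed uniformly at random in an ROI
#'
#' Builds a `cluster_set` of pixelated disks whose positions are uniform
#' over all placements fully inside the ROI - the same placement law the
#' Monte Carlo randomization uses, which makes these sets an exact
#' complete-spatial-randomness (CSR) null for the colocalization
#' coefficient.
#'
#' @param n_clusters Number of disks.
#' @param radius_range nm radius range (sampled uniformly).
#' @param roi A `nucleus_roi`.
#' @param grid A `grid_spec` covering the ROI.
#' @param seed Integer seed.
#' @param channel Channel label.
#' @param mask Optional precomputed ROI mask.
#' @param max_retries Placement retry cap per cluster.
#' @return A `cluster_set`.
#' @export
simulate_csr_clusters <- function(n_clusters, radius_range, roi, grid, seed,
                                  channel = "protein", mask = NULL,
                                  max_retries = 10000L) {
  if (is.null(mask)) mask <- roi_mask(roi, grid)
  roi_lin <- which(mask)
  if (length(roi_lin) == 0L) stop("ROI mask is empty on this grid")
  nx <- grid$dim_px[1]; ny <- grid$dim_px[2]
  roi_ij <- lin_to_px(grid, roi_lin)
  local_seed(seed, {
    radii <- stats::runif(n_clusters, radius_range[1], radius_range[2])
    pixels <- vector("list", n_clusters)
    com <- matrix(NA_real_, n_clusters, 2)
    for (k in seq_len(n_clusters)) {
      rp <- ceiling(radii[k] / grid$pixel_nm)
      d <- expand.grid(di = -rp:rp, dj = -rp:rp)
      keep <- (d$di * grid$pixel_nm)^2 + (d$dj * grid$pixel_nm)^2 <=
        radii[k]^2
      di <- d$di[keep]; dj <- d$dj[keep]
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        a <- sample.int(length(roi_lin), 1L)
        ai <- roi_ij$ix[a]; aj <- roi_ij$iy[a]
        ii <- ai + di; jj <- aj + dj
        if (min(ii) < 0L || max(ii) >= nx || min(jj) < 0L || max(jj) >= ny)
          next
        lin <- px_to_lin(grid, ii, jj)
        if (all(mask[lin])) {
          pixels[[k]] <- lin
          ctr <- px_center_nm(grid, ai, aj)
          com[k, ] <- c(ctr$x, ctr$y)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("placement failed: cluster of radius ", round(radii[k]),
             " nm cannot be placed inside ROI '", roi$id, "' within ",
             max_retries, " retries")
    }
    clusters <- data.frame(id = seq_len(n_clusters), n_px = lengths(pixels),
                           area_nm2 = lengths(pixels) * grid$pixel_nm^2,
                           com_x_nm = com[, 1], com_y_nm = com[, 2])
    structure(list(clusters = clusters, pixels = pixels, threshold = NA_real_,
                   channel = channel, grid = grid, roi_id = roi$id,
                   roi_area_nm2 = roi$area_nm2),
              class = "cluster_set")
  })
}
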