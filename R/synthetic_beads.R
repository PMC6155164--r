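# Synthetic fiducial bead fields and raw frame stacks. Bead fields emulate
# multicolor Tetraspeck acquisitions used to calibrate the chromatic map: a
# reference channel of well-separated beads, and a second channel that is a
# known polynomial warp of the first plus localization noise.

#' Polynomial warp (ground-truth chromatic distortion)
#'
#' A pair of total-degree-`degree` bivariate polynomials mapping (x, y) nm
#' to warped (x', y') nm. Coefficients are over monomials `u^i v^j` of the
#' normalized coordinates `u = (x - center)/scale`.
#'
#' @param coef_x,coef_y Coefficient vectors over [poly_exponents()] rows.
#' @param degree Total degree (<= 3 for the fitting round-trip guarantees).
#' @param center,scale Normalization of the input coordinates.
#' @return A `poly_warp` object.
#' @export
poly_warp <- function(coef_x, coef_y, degree = 3L, center = c(0, 0),
                      scale = 1) {
  ex <- poly_exponents(degree)
  stopifnot(length(coef_x) == nrow(ex), length(coef_y) == nrow(ex))
  structure(list(exponents = ex, coef_x = coef_x, coef_y = coef_y,
                 degree = as.integer(degree), center = center, scale = scale),
            class = "poly_warp")
}

#' @rdname poly_warp
#' @export
identity_warp <- function() {
  ex <- poly_exponents(1L)
  cx <- as.numeric(ex$i == 1 & ex$j == 0)
  cy <- as.numeric(ex$i == 0 & ex$j == 1)
  poly_warp(cx, cy, degree = 1L)
}

#' @rdname poly_warp
#' @param dx,dy Translation in nm.
#' @export
translation_warp <- function(dx, dy) {
  w <- identity_warp()
  w$coef_x[w$exponents$i == 0 & w$exponents$j == 0] <- dx
  w$coef_y[w$exponents$i == 0 & w$exponents$j == 0] <- dy
  w
}

#' Smooth example chromatic distortion of a field
#'
#' A fixed degree-3 warp whose displacement grows towards the field edges,
#' reaching roughly `max_disp_nm` at the corners - the typical magnitude and
#' shape of chromatic offsets across a camera field.
#'
#' @param field_size_nm Field edge length (nm).
#' @param max_disp_nm Approximate maximum displacement (nm).
#' @return A `poly_warp`.
#' @export
example_warp <- function(field_size_nm = 40000, max_disp_nm = 150) {
  # displacement polynomial in u, v in [-0.5, 0.5]; max |disp| ~ 1 unit,
  # scaled to max_disp_nm
  ex <- poly_exponents(3L)
  key <- paste(ex$i, ex$j)
  disp_x <- stats::setNames(numeric(nrow(ex)), key)
  disp_y <- stats::setNames(numeric(nrow(ex)), key)
  disp_x[c("1 0", "0 1", "1 1", "2 0", "0 2", "3 0")] <-
    c(0.84, 0.50, 1.00, 0.68, -0.84, 0.60)
  disp_y[c("1 0", "0 1", "1 1", "0 2", "2 1", "0 3")] <-
    c(-0.42, 0.76, -0.84, 1.00, 0.72, -0.50)
  cx <- disp_x * max_disp_nm
  cy <- disp_y * max_disp_nm
  # add the identity in normalized coordinates: x = u * scale + center
  sc <- field_size_nm
  cx[key == "1 0"] <- cx[key == "1 0"] + sc
  cy[key == "0 1"] <- cy[key == "0 1"] + sc
  cx[key == "0 0"] <- cx[key == "0 0"] + field_size_nm / 2
  cy[key == "0 0"] <- cy[key == "0 0"] + field_size_nm / 2
  poly_warp(unname(cx), unname(cy), degree = 3L,
            center = c(field_size_nm / 2, field_size_nm / 2), scale = sc)
}

#' Apply a warp to coordinates
#' @param warp A `poly_warp`.
#' @param x,y nm coordinates.
#' @return List with warped `x`, `y`.
#' @export
apply_warp <- function(warp, x, y) {
  X <- poly_design((x - warp$center[1]) / warp$scale,
                   (y - warp$center[2]) / warp$scale, warp$exponents)
  list(x = as.numeric(X %*% warp$coef_x), y = as.numeric(X %*% warp$coef_y))
}

#' Generate a two-channel synthetic bead field
#'
#' Reference-channel beads are uniform over the square field with a minimum
#' pairwise spacing (default 2 um) so cross-channel matching is unambiguous;
#' the second channel is the warp of the reference plus isotropic Gaussian
#' localization noise (applied to both channels).
#'
#' @param n_beads Number of beads.
#' @param field_size_nm Field edge length (nm).
#' @param warp A `poly_warp` (ground truth distortion).
#' @param noise_sd_nm Localization noise s.d. per coordinate (nm).
#' @param seed Integer seed.
#' @param min_spacing_nm Minimum pairwise bead distance.
#' @param channels Length-2 channel labels (source first).
#' @return List with `reference` and `warped` localization tables (rows in
#'   bead order) and `truth` (true positions, warp, seed).
#' @export
generate_bead_field <- function(n_beads = 100L, field_size_nm = 40000,
                                warp = identity_warp(), noise_sd_nm = 0,
                                seed = 1L, min_spacing_nm = 2000,
                                channels = c("blue", "red")) {
  stopifnot(inherits(warp, "poly_warp"), n_beads >= 1L, noise_sd_nm >= 0)
  # crude packing feasibility: disks of radius spacing/2 must fit
  if (n_beads * pi * (min_spacing_nm / 2)^2 > 0.6 * field_size_nm^2)
    stop("placement error: ", n_beads, " beads cannot satisfy a ",
         min_spacing_nm, " nm spacing in a ", field_size_nm, " nm field")
  local_seed(seed, {
    pos <- matrix(NA_real_, n_beads, 2)
    got <- 0L; tries <- 0L
    while (got < n_beads) {
      tries <- tries + 1L
      if (tries > 200000L)
        stop("placement error: bead spacing constraint unsatisfiable")
      cand <- stats::runif(2, 0, field_size_nm)
      if (got == 0L ||
          min((pos[seq_len(got), 1] - cand[1])^2 +
              (pos[seq_len(got), 2] - cand[2])^2) >= min_spacing_nm^2) {
        got <- got + 1L
        pos[got, ] <- cand
      }
    }
    w <- apply_warp(warp, pos[, 1], pos[, 2])
    noise <- function(n) if (noise_sd_nm > 0)
      stats::rnorm(n, 0, noise_sd_nm) else numeric(n)
    reference <- make_locs(pos[, 1] + noise(n_beads),
                           pos[, 2] + noise(n_beads),
                           channels[1], max(noise_sd_nm, 1))
    warped <- make_locs(w$x + noise(n_beads), w$y + noise(n_beads),
                        channels[2], max(noise_sd_nm, 1))
    list(reference = reference, warped = warped,
         truth = list(positions_nm = pos, warp = warp, seed = seed))
  })
}

#' Render localizations into a raw camera frame stack
#'
#' Each localization is drawn as a 2D Gaussian PSF of the stated FWHM,
#' normalized to `photons_per_molecule` photons, on its assigned frame;
#' constant background is added and Poisson photon noise applied to every
#' pixel. Molecules outside the frame are clipped and counted.
#'
#' @param locs Localization table with `x_nm`, `y_nm` and `frame` (1-based).
#' @param frame_dim_px Length-2 frame size in pixels.
#' @param pixel_nm Camera pixel size in nm.
#' @param psf_fwhm_nm PSF full width at half maximum (nm).
#' @param photons_per_molecule Expected photons per molecule.
#' @param background_level Expected background photons per pixel per frame.
#' @param n_frames Number of frames (default: max frame index).
#' @param seed Integer seed for the Poisson noise.
#' @return A `frame_stack`: 3D array (x, y, frame) with attributes
#'   `pixel_nm` and `n_clipped`.
#' @export
generate_frames <- function(locs, frame_dim_px, pixel_nm, psf_fwhm_nm,
                            photons_per_molecule = 500,
                            background_level = 10,
                            n_frames = NULL, seed = 1L) {
  stopifnot(psf_fwhm_nm > 0, length(frame_dim_px) == 2)
  nx <- as.integer(frame_dim_px[1]); ny <- as.integer(frame_dim_px[2])
  if (nrow(locs) > 0L && is.null(locs$frame))
    stop("every localization must be assigned to a frame")
  if (is.null(n_frames))
    n_frames <- if (nrow(locs) > 0L) max(locs$frame) else 1L
  local_seed(seed, {
    stack <- array(background_level, dim = c(nx, ny, n_frames))
    sd_px <- fwhm_to_sd(psf_fwhm_nm) / pixel_nm
    r <- max(2L, ceiling(4 * sd_px))
    n_clipped <- 0L
    for (k in seq_len(nrow(locs))) {
      f <- locs$frame[k]
      if (f < 1L || f > n_frames) { n_clipped <- n_clipped + 1L; next }
      cx <- locs$x_nm[k] / pixel_nm - 0.5    # 0-based pixel-center coords
      cy <- locs$y_nm[k] / pixel_nm - 0.5
      if (cx < -r || cx > nx - 1 + r || cy < -r || cy > ny - 1 + r) {
        n_clipped <- n_clipped + 1L
        next
      }
      i0 <- max(0L, floor(cx) - r); i1 <- min(nx - 1L, floor(cx) + r)
      j0 <- max(0L, floor(cy) - r); j1 <- min(ny - 1L, floor(cy) + r)
      if (i0 > i1 || j0 > j1) { n_clipped <- n_clipped + 1L; next }
      gx <- exp(-((i0:i1) - cx)^2 / (2 * sd_px^2))
      gy <- exp(-((j0:j1) - cy)^2 / (2 * sd_px^2))
      psf <- outer(gx, gy) / (2 * pi * sd_px^2)   # unit-integral Gaussian
      stack[(i0 + 1L):(i1 + 1L), (j0 + 1L):(j1 + 1L), f] <-
        stack[(i0 + 1L):(i1 + 1L), (j0 + 1L):(j1 + 1L), f] +
        photons_per_molecule * psf
    }
    noisy <- array(stats::rpois(length(stack), stack), dim = dim(stack))
    structure(noisy, pixel_nm = pixel_nm, n_clipped = n_clipped,
              class = c("frame_stack", "array"))
  })
}

#' Write / read a frame stack as multi-page 16-bit TIFF
#'
#' @param stack A `frame_stack` (photon counts).
#' @param path File path.
#' @param pixel_nm Pixel size for `read_frames` (not stored in the TIFF).
#' @return `write_frames` returns `path` invisibly; `read_frames` a
#'   `frame_stack`.
#' @export
write_frames <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack)[3]), function(f) {
    m <- pmin(stack[, , f], 65535L) / 65535
    t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path, pixel_nm) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  mats <- lapply(pages, function(p) {
    m <- round(p * 65535)
    t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  })
  stack <- array(0, dim = c(nrow(mats[[1]]), ncol(mats[[1]]), length(mats)))
  for (f in seq_along(mats)) stack[, , f] <- mats[[f]]
  structure(stack, pixel_nm = pixel_nm, n_clipped = 0L,
            class = c("frame_stack", "array"))
}
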