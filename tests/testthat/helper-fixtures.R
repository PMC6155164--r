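# Shared builders for hand-constructed fixtures. Everything is generated in
# code; no data files.

# A cluster_set built from explicit pixel masks (list of logical matrices of
# the grid's dimensions, one per cluster). Centers of mass are unweighted
# pixel-center centroids.
make_set <- function(masks, grid, channel = "A", roi_id = "toy",
                     roi_area_nm2 = prod(grid$dim_px) * grid$pixel_nm^2) {
  p <- grid$pixel_nm
  pixels <- lapply(masks, function(m) which(m))
  com <- t(vapply(pixels, function(lin) {
    ix <- (lin - 1L) %% grid$dim_px[1]
    iy <- (lin - 1L) %/% grid$dim_px[1]
    c(grid$origin_nm[1] + mean(ix + 0.5) * p,
      grid$origin_nm[2] + mean(iy + 0.5) * p)
  }, numeric(2)))
  clusters <- data.frame(id = seq_along(pixels), n_px = lengths(pixels),
                         area_nm2 = lengths(pixels) * p^2,
                         com_x_nm = com[, 1], com_y_nm = com[, 2])
  structure(list(clusters = clusters, pixels = pixels, threshold = NA_real_,
                 channel = channel, grid = grid, roi_id = roi_id,
                 roi_area_nm2 = roi_area_nm2),
            class = "cluster_set")
}

# logical matrix with a filled rectangle of 0-based pixel ranges
rect_mask <- function(grid, ix, iy) {
  m <- matrix(FALSE, grid$dim_px[1], grid$dim_px[2])
  m[ix + 1L, iy + 1L] <- TRUE
  m
}

# localization table at given nm coordinates, single channel
loc_table <- function(x, y, channel = "A", precision_nm = 10) {
  n <- length(x)
  data.frame(x_nm = x, y_nm = y, frame = rep(1L, n),
             channel = rep(channel, length.out = max(n, 0)),
             intensity = rep(1, n),
             precision_nm = rep(precision_nm, length.out = max(n, 0)))
}

# the printed 2 h and 8 h RPA/RAD51 class mixtures (fractions of foci)
mixture_2h <- c("RPA-only" = 0.714, "both" = 0.221, "RAD51-only" = 0.065)
mixture_8h <- c("RAD51-only" = 0.487, "both" = 0.421, "RPA-only" = 0.092)
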