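# Render-grid geometry. All coordinates are in nm; pixels are 0-based with
# half-open bins: pixel (i, j) covers [x0 + i*p, x0 + (i+1)*p) in x and the
# analogous interval in y, where p is the pixel size (20 nm by default).

#' Define a render grid
#'
#' @param origin_nm Numeric length-2: nm coordinates of the lower-left corner
#'   of pixel (0, 0).
#' @param dim_px Integer length-2: number of pixels in x and y.
#' @param pixel_nm Pixel edge length in nm (default 20).
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(origin_nm, dim_px, pixel_nm = 20) {
  stopifnot(length(origin_nm) == 2, length(dim_px) == 2,
            all(dim_px >= 1), pixel_nm > 0)
  structure(list(origin_nm = as.numeric(origin_nm),
                 dim_px = as.integer(dim_px),
                 pixel_nm = as.numeric(pixel_nm)),
            class = "grid_spec")
}

#' Grid covering a bounding box
#'
#' @param xlim,ylim nm ranges to cover.
#' @param pixel_nm Pixel size in nm.
#' @param pad_px Extra pixels of margin on every side.
#' @return A `grid_spec`.
#' @export
grid_for_bbox <- function(xlim, ylim, pixel_nm = 20, pad_px = 2L) {
  nx <- ceiling(diff(range(xlim)) / pixel_nm) + 2L * pad_px
  ny <- ceiling(diff(range(ylim)) / pixel_nm) + 2L * pad_px
  grid_spec(c(min(xlim) - pad_px * pixel_nm, min(ylim) - pad_px * pixel_nm),
            c(nx, ny), pixel_nm)
}

# nm -> 0-based pixel index (floor of half-open bins)
nm_to_px <- function(grid, x, y) {
  list(ix = floor((x - grid$origin_nm[1]) / grid$pixel_nm),
       iy = floor((y - grid$origin_nm[2]) / grid$pixel_nm))
}

# 0-based pixel indices -> nm coordinates of pixel centers
px_center_nm <- function(grid, ix, iy) {
  list(x = grid$origin_nm[1] + (ix + 0.5) * grid$pixel_nm,
       y = grid$origin_nm[2] + (iy + 0.5) * grid$pixel_nm)
}

# linear (1-based, column-major with x fastest) <-> (ix, iy) 0-based
lin_to_px <- function(grid, lin) {
  nx <- grid$dim_px[1]
  list(ix = (lin - 1L) %% nx, iy = (lin - 1L) %/% nx)
}
px_to_lin <- function(grid, ix, iy) ix + iy * grid$dim_px[1] + 1L

same_grid <- function(a, b, tol = 1e-9) {
  all(abs(a$origin_nm - b$origin_nm) < tol) &&
    all(a$dim_px == b$dim_px) && abs(a$pixel_nm - b$pixel_nm) < tol
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d px, %.3g nm/px, origin (%.0f, %.0f) nm\n",
              x$dim_px[1], x$dim_px[2], x$pixel_nm,
              x$origin_nm[1], x$origin_nm[2]))
  invisible(x)
}
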