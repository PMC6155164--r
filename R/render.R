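# Rendering localization tables on the 20 nm grid. Counts mode gives a
# 2D histogram (one count per localization, half-open pixel bins); gaussian
# mode spreads each localization by its own fitted precision, which is the
# usual "probability map" display for SMLM data.

#' Render a localization table to a pixel image
#'
#' @param locs Localization table (data.frame with `x_nm`, `y_nm`; gaussian
#'   mode also uses `precision_nm`).
#' @param grid A `grid_spec`.
#' @param mode `"counts"` (default) or `"gaussian"`.
#' @param channel Channel label stored on the image; defaults to the single
#'   channel present in `locs`.
#' @return A `rendered_image`: list with `pixels` (matrix, x fastest),
#'   `grid`, `channel`, `mode`, and `n_dropped` (localizations outside the
#'   grid, dropped with a count).
#' @export
render <- function(locs, grid, mode = c("counts", "gaussian"),
                   channel = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "grid_spec"))
  if (is.null(channel)) {
    ch <- unique(as.character(locs$channel %||% "unknown"))
    channel <- if (length(ch) == 1L) ch else "multi"
  }
  nx <- grid$dim_px[1]; ny <- grid$dim_px[2]
  img <- matrix(0, nx, ny)
  n_dropped <- 0L
  if (nrow(locs) > 0L) {
    p <- nm_to_px(grid, locs$x_nm, locs$y_nm)
    inside <- p$ix >= 0L & p$ix < nx & p$iy >= 0L & p$iy < ny
    n_dropped <- sum(!inside)
    if (mode == "counts") {
      lin <- px_to_lin(grid, p$ix[inside], p$iy[inside])
      tab <- tabulate(lin, nbins = nx * ny)
      img <- matrix(as.numeric(tab), nx, ny)
    } else {
      prec <- locs$precision_nm
      if (is.null(prec)) stop("gaussian mode needs a 'precision_nm' column")
      xs <- locs$x_nm[inside]; ys <- locs$y_nm[inside]
      ps <- pmax(prec[inside], grid$pixel_nm / 4)
      for (k in seq_along(xs)) {
        sd_px <- ps[k] / grid$pixel_nm
        r <- max(1L, ceiling(3 * sd_px))
        cx <- (xs[k] - grid$origin_nm[1]) / grid$pixel_nm - 0.5
        cy <- (ys[k] - grid$origin_nm[2]) / grid$pixel_nm - 0.5
        i0 <- max(0L, floor(cx) - r); i1 <- min(nx - 1L, floor(cx) + r)
        j0 <- max(0L, floor(cy) - r); j1 <- min(ny - 1L, floor(cy) + r)
        if (i0 > i1 || j0 > j1) next
        gx <- exp(-((i0:i1) - cx)^2 / (2 * sd_px^2))
        gy <- exp(-((j0:j1) - cy)^2 / (2 * sd_px^2))
        ker <- outer(gx, gy)
        ker <- ker / sum(ker)
        img[(i0 + 1L):(i1 + 1L), (j0 + 1L):(j1 + 1L)] <-
          img[(i0 + 1L):(i1 + 1L), (j0 + 1L):(j1 + 1L)] + ker
      }
    }
  }
  structure(list(pixels = img, grid = grid, channel = channel, mode = mode,
                 n_dropped = n_dropped),
            class = "rendered_image")
}

#' Write a rendered image as 16-bit TIFF
#'
#' Pixel values are linearly scaled to the 16-bit range (max -> 65535).
#'
#' @param img A `rendered_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rendered_tiff <- function(img, path) {
  m <- img$pixels
  mx <- max(m)
  if (mx > 0) m <- m / mx
  # transpose: tiff expects row-major (rows = y, top row first)
  tiff::writeTIFF(t(m)[rev(seq_len(ncol(m))), , drop = FALSE], path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf(
    "<rendered_image> channel '%s', %s mode, %d x %d px, sum %.4g, %d dropped\n",
    x$channel, x$mode, x$grid$dim_px[1], x$grid$dim_px[2],
    sum(x$pixels), x$n_dropped))
  invisible(x)
}
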