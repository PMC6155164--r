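# Nucleus regions of interest. In the assay every statistic is computed
# inside a manually outlined nucleus; here ROIs are simple closed polygons
# (circles/ellipses are polygonized) or, equivalently, boolean masks on the
# render grid. Pixel membership is decided by the pixel center.

#' Create a nucleus ROI from polygon vertices
#'
#' @param vertices n x 2 matrix of nm coordinates of a simple closed polygon
#'   (do not repeat the first vertex).
#' @param id Optional nucleus identifier.
#' @return A `nucleus_roi` object with the polygon and its shoelace area.
#' @export
nucleus_roi <- function(vertices, id = "nucleus") {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3,
            all(is.finite(vertices)))
  area <- polygon_area(vertices)
  if (area <= 0) stop("ROI polygon has zero area")
  structure(list(vertices = vertices, id = id, area_nm2 = area),
            class = "nucleus_roi")
}

#' Circular nucleus ROI
#'
#' @param center_nm Length-2 nm center.
#' @param radius_nm Radius in nm.
#' @param n_vertices Number of polygon vertices used to approximate the circle.
#' @param id Nucleus identifier.
#' @return A `nucleus_roi`.
#' @export
circle_roi <- function(center_nm, radius_nm, n_vertices = 128L,
                       id = "nucleus") {
  stopifnot(radius_nm > 0)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  nucleus_roi(cbind(center_nm[1] + radius_nm * cos(th),
                    center_nm[2] + radius_nm * sin(th)), id = id)
}

#' Rectangular nucleus ROI
#' @param xlim,ylim nm extents.
#' @param id Nucleus identifier.
#' @return A `nucleus_roi`.
#' @export
rect_roi <- function(xlim, ylim, id = "nucleus") {
  nucleus_roi(cbind(c(xlim[1], xlim[2], xlim[2], xlim[1]),
                    c(ylim[1], ylim[1], ylim[2], ylim[2])), id = id)
}

#' ROI area in square microns
#' @param roi A `nucleus_roi`.
#' @return Area in um^2.
#' @export
roi_area_um2 <- function(roi) roi$area_nm2 / 1e6

#' Boolean ROI mask on a render grid
#'
#' A pixel belongs to the ROI when its center lies inside the polygon.
#'
#' @param roi A `nucleus_roi`.
#' @param grid A `grid_spec`.
#' @return Logical matrix of dim `grid$dim_px`.
#' @export
roi_mask <- function(roi, grid) {
  nx <- grid$dim_px[1]; ny <- grid$dim_px[2]
  # restrict the point-in-polygon test to the polygon bounding box
  bb <- apply(roi$vertices, 2, range)
  p0 <- nm_to_px(grid, bb[1, 1], bb[1, 2])
  p1 <- nm_to_px(grid, bb[2, 1], bb[2, 2])
  ix <- max(0L, p0$ix):min(nx - 1L, p1$ix)
  iy <- max(0L, p0$iy):min(ny - 1L, p1$iy)
  m <- matrix(FALSE, nx, ny)
  if (length(ix) == 0L || length(iy) == 0L) return(m)
  gx <- grid$origin_nm[1] + (ix + 0.5) * grid$pixel_nm
  gy <- grid$origin_nm[2] + (iy + 0.5) * grid$pixel_nm
  pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  inside <- points_in_polygon(roi$vertices, pts)
  m[cbind(rep(ix + 1L, times = length(iy)),
          rep(iy + 1L, each = length(ix)))] <- inside
  m
}

#' Uniform random points inside an ROI
#'
#' Rejection sampling in the polygon bounding box; used for background
#' localizations and uniform cluster centers.
#'
#' @param roi A `nucleus_roi`.
#' @param n Number of points.
#' @return n x 2 matrix of nm coordinates.
#' @export
runif_in_roi <- function(roi, n) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  bb <- apply(roi$vertices, 2, range)
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 64L)
    cand <- cbind(stats::runif(m, bb[1, 1], bb[2, 1]),
                  stats::runif(m, bb[1, 2], bb[2, 2]))
    keep <- cand[points_in_polygon(roi$vertices, cand), , drop = FALSE]
    take <- min(nrow(keep), n - got)
    if (take > 0L) {
      out[(got + 1L):(got + take), ] <- keep[seq_len(take), , drop = FALSE]
      got <- got + take
    }
  }
  out
}

#' Write / read an ROI as a GeoJSON-style polygon
#'
#' @param roi A `nucleus_roi`.
#' @param path Output file.
#' @return `write_roi` returns `path` invisibly; `read_roi` a `nucleus_roi`.
#' @export
write_roi <- function(roi, path) {
  coords <- rbind(roi$vertices, roi$vertices[1, , drop = FALSE])
  obj <- list(type = "Feature",
              properties = list(id = roi$id, units = "nm"),
              geometry = list(type = "Polygon",
                              coordinates = list(lapply(
                                seq_len(nrow(coords)),
                                function(i) as.numeric(coords[i, ])))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  ring <- obj$geometry$coordinates[[1]]
  verts <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
  if (all(verts[1, ] == verts[nrow(verts), ]))
    verts <- verts[-nrow(verts), , drop = FALSE]
  nucleus_roi(verts, id = obj$properties$id %||% "nucleus")
}

#' @export
print.nucleus_roi <- function(x, ...) {
  cat(sprintf("<nucleus_roi> '%s': %d vertices, area %.2f um^2\n",
              x$id, nrow(x$vertices), roi_area_um2(x)))
  invisible(x)
}
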