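# Chromatic channel registration. Multicolor bead fields (e.g. Tetraspeck
# fiducials) are localized per channel, matched by mutual nearest neighbors,
# and a total-degree-3 bivariate polynomial map per axis is fitted by least
# squares, taking each non-reference channel onto the red/far-red reference.
# Residual bead distances after mapping quantify the registration error.

#' Match beads between two channels by mutual nearest neighbors
#'
#' @param table_a,table_b Localization tables (`x_nm`, `y_nm`) of the same
#'   bead field in two channels. `table_a` is the source (to be mapped),
#'   `table_b` the target/reference.
#' @param max_pair_distance_nm Matching gate (default 500 nm).
#' @return A `bead_pairs` data.frame: `xa, ya, xb, yb, dist_nm`, with
#'   attributes `n_unmatched_a`, `n_unmatched_b`.
#' @export
match_beads <- function(table_a, table_b, max_pair_distance_nm = 500) {
  stopifnot(nrow(table_a) > 0L, nrow(table_b) > 0L)
  A <- cbind(table_a$x_nm, table_a$y_nm)
  B <- cbind(table_b$x_nm, table_b$y_nm)
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  nn_ab <- max.col(-d2, ties.method = "first")           # for each a: nearest b
  nn_ba <- apply(d2, 2, which.min)                       # for each b: nearest a
  ia <- seq_len(nrow(A))
  mutual <- nn_ba[nn_ab] == ia
  dist <- sqrt(d2[cbind(ia, nn_ab)])
  keep <- mutual & dist <= max_pair_distance_nm
  if (!any(keep))
    stop("bead matching failed: 0 mutual pairs within ",
         max_pair_distance_nm, " nm (", nrow(A), " and ", nrow(B),
         " beads; nearest-neighbor distances ",
         paste(signif(range(dist), 3), collapse = "-"), " nm)")
  pairs <- data.frame(xa = A[keep, 1], ya = A[keep, 2],
                      xb = B[nn_ab[keep], 1], yb = B[nn_ab[keep], 2],
                      dist_nm = dist[keep])
  attr(pairs, "n_unmatched_a") <- nrow(A) - sum(keep)
  attr(pairs, "n_unmatched_b") <- nrow(B) - sum(keep)
  class(pairs) <- c("bead_pairs", class(pairs))
  pairs
}

#' Fit a polynomial chromatic map from matched bead pairs
#'
#' Least-squares fit, per output axis, of a total-degree-`degree` bivariate
#' polynomial taking source coordinates `(xa, ya)` to target coordinates
#' `(xb, yb)`. Degree 3 has 10 coefficients per axis.
#'
#' @param pairs A `bead_pairs` data.frame from [match_beads()] (or any
#'   data.frame with `xa, ya, xb, yb`).
#' @param degree Total polynomial degree (default 3).
#' @param source,target Channel labels stored on the map.
#' @return A `chromatic_map`: exponent table, coefficient matrix
#'   (`coef_x`, `coef_y`), per-bead residual distances (nm), and the
#'   training hull for extrapolation flagging.
#' @export
fit_polynomial_map <- function(pairs, degree = 3L, source = "source",
                               target = "target") {
  n_coef <- (degree + 1) * (degree + 2) / 2
  if (nrow(pairs) < n_coef)
    stop("need at least ", n_coef, " bead pairs for degree ", degree,
         " (got ", nrow(pairs), ")")
  if (nrow(pairs) < 30L)
    warning("only ", nrow(pairs), " bead pairs; map may be poorly constrained")
  ex <- poly_exponents(degree)
  # center/scale source coordinates for conditioning; stored with the map
  cx <- mean(pairs$xa); cy <- mean(pairs$ya)
  sc <- max(stats::sd(pairs$xa), stats::sd(pairs$ya), 1)
  X <- poly_design((pairs$xa - cx) / sc, (pairs$ya - cy) / sc, ex)
  qx <- qr(X)
  if (qx$rank < n_coef)
    stop("rank-deficient bead design (rank ", qx$rank, " < ", n_coef,
         "): beads are collinear or degenerate")
  bx <- qr.coef(qx, pairs$xb)
  by <- qr.coef(qx, pairs$yb)
  fx <- X %*% bx; fy <- X %*% by
  res <- sqrt((pairs$xb - fx)^2 + (pairs$yb - fy)^2)
  hull <- grDevices::chull(pairs$xa, pairs$ya)
  structure(list(
    source = source, target = target, degree = as.integer(degree),
    exponents = ex, coef_x = as.numeric(bx), coef_y = as.numeric(by),
    center = c(cx, cy), scale = sc,
    residuals_nm = as.numeric(res),
    hull = cbind(pairs$xa[hull], pairs$ya[hull]),
    n_pairs = nrow(pairs)
  ), class = "chromatic_map")
}

# Evaluate a chromatic map at nm coordinates.
eval_map <- function(map, x, y) {
  X <- poly_design((x - map$center[1]) / map$scale,
                   (y - map$center[2]) / map$scale, map$exponents)
  list(x = as.numeric(X %*% map$coef_x), y = as.numeric(X %*% map$coef_y))
}

#' Apply a chromatic map to a localization table
#'
#' Transforms coordinates into the reference channel's frame; every other
#' column is preserved. Localizations outside the convex hull of the
#' training beads are still corrected but flagged `extrapolated`.
#'
#' @param locs Localization table with `x_nm`, `y_nm`.
#' @param map A `chromatic_map`.
#' @return The table with corrected coordinates and a logical
#'   `extrapolated` column.
#' @export
apply_map <- function(locs, map) {
  stopifnot(inherits(map, "chromatic_map"))
  if (nrow(locs) == 0L) {
    locs$extrapolated <- logical(0)
    return(locs)
  }
  out <- eval_map(map, locs$x_nm, locs$y_nm)
  extrap <- !points_in_polygon(map$hull, cbind(locs$x_nm, locs$y_nm))
  locs$x_nm <- out$x
  locs$y_nm <- out$y
  locs$extrapolated <- extrap
  locs
}

#' Median mapping error (nm)
#' @param map A `chromatic_map`.
#' @return Median residual bead distance after mapping.
#' @export
mapping_error_nm <- function(map) stats::median(map$residuals_nm)

#' Serialize / restore a chromatic map as JSON
#'
#' Coefficients are stored row-major by exponent pair `(i, j)` alongside the
#' channel pair, degree, and normalization constants.
#'
#' @param map A `chromatic_map`.
#' @param path File path.
#' @return `write_chromatic_map` returns `path` invisibly;
#'   `read_chromatic_map` a `chromatic_map`.
#' @export
write_chromatic_map <- function(map, path) {
  obj <- list(source = map$source, target = map$target, degree = map$degree,
              exponents_i = map$exponents$i, exponents_j = map$exponents$j,
              coef_x = map$coef_x, coef_y = map$coef_y,
              center = map$center, scale = map$scale,
              residuals_nm = map$residuals_nm,
              hull_x = map$hull[, 1], hull_y = map$hull[, 2],
              n_pairs = map$n_pairs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_chromatic_map
#' @export
read_chromatic_map <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    source = o$source, target = o$target, degree = as.integer(o$degree),
    exponents = data.frame(i = o$exponents_i, j = o$exponents_j),
    coef_x = o$coef_x, coef_y = o$coef_y, center = o$center, scale = o$scale,
    residuals_nm = o$residuals_nm, hull = cbind(o$hull_x, o$hull_y),
    n_pairs = o$n_pairs
  ), class = "chromatic_map")
}

#' @export
print.chromatic_map <- function(x, ...) {
  cat(sprintf(
    "<chromatic_map> %s -> %s, degree %d (%d pairs): median residual %.2f nm\n",
    x$source, x$target, x$degree, x$n_pairs, mapping_error_nm(x)))
  invisible(x)
}
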