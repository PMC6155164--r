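# Per-nucleus cluster segmentation: Otsu threshold computed from the in-ROI
# pixel histogram only, followed by 8-connected component labeling. Every
# component is kept regardless of size - in SMLM a single bright pixel is a
# real detection, so no minimum-size filter is applied.

#' Otsu threshold of a sample of pixel values
#'
#' Maximizes the between-class variance over candidate thresholds. For
#' integer-valued data (count-mode renders) candidates are the observed
#' levels; continuous data are discretized into `n_bins` bins first.
#' Foreground is defined as strictly greater than the returned threshold.
#'
#' @param values Numeric vector (e.g. in-ROI pixel values).
#' @param n_bins Number of histogram bins for non-integer data.
#' @return The threshold (numeric scalar).
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values for Otsu threshold")
  if (length(unique(values)) < 2L)
    stop("Otsu threshold undefined: constant pixel values")
  integerish <- all(abs(values - round(values)) < 1e-9) &&
    diff(range(values)) <= 2 * n_bins
  if (integerish) {
    lev <- sort(unique(round(values)))
    cnt <- tabulate(match(round(values), lev))
  } else {
    br <- seq(min(values), max(values), length.out = n_bins + 1L)
    h <- graphics::hist(values, breaks = br, plot = FALSE)
    lev <- h$mids
    cnt <- h$counts
  }
  w <- cnt / sum(cnt)
  mu <- lev * w
  cw <- cumsum(w)          # P(class 0) at threshold = level k
  cmu <- cumsum(mu)
  mu_t <- cmu[length(cmu)]
  k <- seq_len(length(lev) - 1L)     # threshold between lev[k] and lev[k+1]
  sigma_b <- (mu_t * cw[k] - cmu[k])^2 / (cw[k] * (1 - cw[k]))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  best <- which.max(sigma_b)
  # threshold midway between the last background level and the next level
  (lev[best] + lev[best + 1L]) / 2
}

# 8-connected (default) component labeling of a logical matrix.
# Breadth-first flood fill over the foreground, vectorized per frontier.
label_components <- function(binary, connectivity = 8L) {
  stopifnot(is.matrix(binary), connectivity %in% c(4L, 8L))
  nx <- nrow(binary); ny <- ncol(binary)
  lab <- matrix(0L, nx, ny)
  fg <- which(binary)
  if (length(fg) == 0L) return(lab)
  if (connectivity == 8L) {
    di <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    dj <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  } else {
    di <- c(0L, -1L, 1L, 0L)
    dj <- c(-1L, 0L, 0L, 1L)
  }
  nextlab <- 0L
  for (seed in fg) {
    if (lab[seed] != 0L) next
    nextlab <- nextlab + 1L
    lab[seed] <- nextlab
    frontier <- seed
    while (length(frontier) > 0L) {
      i <- (frontier - 1L) %% nx + 1L
      j <- (frontier - 1L) %/% nx + 1L
      ni <- rep(i, times = length(di)) + rep(di, each = length(i))
      nj <- rep(j, times = length(dj)) + rep(dj, each = length(j))
      ok <- ni >= 1L & ni <= nx & nj >= 1L & nj <= ny
      cand <- unique((nj[ok] - 1L) * nx + ni[ok])
      cand <- cand[binary[cand] & lab[cand] == 0L]
      lab[cand] <- nextlab
      frontier <- cand
    }
  }
  lab
}

#' Segment one channel of a rendered nucleus into clusters
#'
#' The threshold is Otsu's, computed from the pixels inside the nucleus ROI
#' only; pixels outside the ROI never enter the histogram nor the mask.
#'
#' @param img A `rendered_image`.
#' @param roi A `nucleus_roi` on the same grid.
#' @param connectivity 8 (default) or 4.
#' @param weighted Use intensity-weighted centers of mass (default); if
#'   `FALSE`, binary-mask centroids.
#' @param mask Optional precomputed ROI mask (logical matrix) to avoid
#'   recomputing it for every channel of the same nucleus.
#' @return A `cluster_set`: list with `clusters` (data.frame: id, n_px,
#'   area_nm2, com_x_nm, com_y_nm), `pixels` (list of linear pixel indices
#'   per cluster), `threshold`, `channel`, `grid`, `roi_id`, `roi_area_nm2`.
#' @export
segment_channel <- function(img, roi, connectivity = 8L, weighted = TRUE,
                            mask = NULL) {
  stopifnot(inherits(img, "rendered_image"), inherits(roi, "nucleus_roi"))
  if (is.null(mask)) mask <- roi_mask(roi, img$grid)
  vals <- img$pixels[mask]
  if (length(vals) == 0L) stop("ROI '", roi$id, "' covers no pixels")
  if (length(unique(vals)) < 2L)
    stop("segmentation failed for nucleus '", roi$id,
         "': constant in-ROI image, Otsu threshold undefined")
  thr <- otsu_threshold(vals)
  binary <- (img$pixels > thr) & mask
  lab <- label_components(binary, connectivity = connectivity)
  new_cluster_set(lab, img, thr, roi, weighted = weighted)
}

# Build a cluster_set from a label matrix (shared by segmentation and the
# synthetic geometric cluster generator).
new_cluster_set <- function(lab, img, threshold, roi, weighted = TRUE) {
  grid <- img$grid
  fg <- which(lab > 0L)
  ids <- lab[fg]
  pix <- split(fg, ids)
  px2 <- grid$pixel_nm^2
  if (length(pix) > 0L) {
    wts <- if (weighted) img$pixels[fg] else rep(1, length(fg))
    wsplit <- split(wts, ids)
    p <- lin_to_px(grid, fg)
    ctr <- px_center_nm(grid, p$ix, p$iy)
    xs <- split(ctr$x, ids); ys <- split(ctr$y, ids)
    com <- t(mapply(function(x, y, w) {
      s <- sum(w); c(sum(x * w) / s, sum(y * w) / s)
    }, xs, ys, wsplit))
    clusters <- data.frame(
      id = as.integer(names(pix)),
      n_px = lengths(pix),
      area_nm2 = lengths(pix) * px2,
      com_x_nm = com[, 1],
      com_y_nm = com[, 2],
      row.names = NULL
    )
  } else {
    clusters <- data.frame(id = integer(0), n_px = integer(0),
                           area_nm2 = numeric(0), com_x_nm = numeric(0),
                           com_y_nm = numeric(0))
  }
  structure(list(clusters = clusters, pixels = unname(pix),
                 threshold = threshold, channel = img$channel,
                 grid = grid, roi_id = roi$id, roi_area_nm2 = roi$area_nm2),
            class = "cluster_set")
}

#' Number of clusters in a set
#' @param set A `cluster_set`.
#' @return Integer count.
#' @export
n_clusters <- function(set) nrow(set$clusters)

#' Per-cluster summary table
#'
#' One row per cluster: id, channel, nucleus, pixel count, area (nm^2) and
#' center of mass (nm). Feeds per-cell focus counting downstream.
#'
#' @param set A `cluster_set`.
#' @return A data.frame.
#' @export
cluster_summary <- function(set) {
  stopifnot(inherits(set, "cluster_set"))
  cl <- set$clusters
  if (nrow(cl) == 0L)
    return(data.frame(nucleus = character(0), channel = character(0),
                      id = integer(0), n_px = integer(0),
                      area_nm2 = numeric(0), com_x_nm = numeric(0),
                      com_y_nm = numeric(0)))
  data.frame(nucleus = set$roi_id, channel = set$channel, cl,
             row.names = NULL)
}

# union mask (logical vector over grid pixels) of a cluster set
set_union_mask <- function(set) {
  v <- logical(prod(set$grid$dim_px))
  v[unlist(set$pixels)] <- TRUE
  v
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf(
    "<cluster_set> channel '%s', nucleus '%s': %d clusters, threshold %.3g\n",
    x$channel, x$roi_id, n_clusters(x), x$threshold))
  invisible(x)
}
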