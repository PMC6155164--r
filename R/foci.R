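# Repair-focus analysis: a focus is a nascent-DNA cluster; a protein is
# present at a focus when one of its clusters intersects the naDNA cluster
# mask or has its center of mass within an association radius (250 nm
# default) of the naDNA center of mass. Foci with no protein present are
# counted but excluded from the records. Population fractions, intrafoci
# center-of-mass distances, and single/double Gaussian distance fits with
# proximal/distal classification follow.

#' Identify multi-channel repair foci
#'
#' @param nadna_set naDNA `cluster_set` (each cluster is one candidate
#'   focus).
#' @param protein_sets Named list of protein `cluster_set`s on the same
#'   grid.
#' @param association_radius_nm Center-of-mass association radius
#'   (default 250 nm).
#' @return A `focus_records` data.frame: nucleus, focus (naDNA cluster) id
#'   and center, one presence flag per protein, one associated-cluster id
#'   per protein (nearest by center of mass among qualifying clusters).
#'   Attribute `n_nadna_only` counts naDNA clusters with no protein.
#' @export
identify_foci <- function(nadna_set, protein_sets,
                          association_radius_nm = 250) {
  stopifnot(inherits(nadna_set, "cluster_set"), length(protein_sets) >= 1L,
            !is.null(names(protein_sets)))
  for (ps in protein_sets)
    if (!same_grid(nadna_set$grid, ps$grid))
      stop("protein cluster set not on the naDNA grid")
  nf <- n_clusters(nadna_set)
  proteins <- names(protein_sets)
  pres <- matrix(FALSE, nf, length(proteins),
                 dimnames = list(NULL, proteins))
  assoc <- matrix(NA_integer_, nf, length(proteins),
                  dimnames = list(NULL, paste0(proteins, "_cluster")))
  qual_ids <- matrix("", nf, length(proteins),
                     dimnames = list(NULL, paste0(proteins, "_clusters")))
  for (p in seq_along(proteins)) {
    ps <- protein_sets[[p]]
    if (n_clusters(ps) == 0L) next
    mask_p <- set_union_mask(ps)
    # map each in-mask pixel to its protein cluster id for intersection hits
    owner <- integer(length(mask_p))
    for (k in seq_along(ps$pixels)) owner[ps$pixels[[k]]] <- k
    for (i in seq_len(nf)) {
      dx <- ps$clusters$com_x_nm - nadna_set$clusters$com_x_nm[i]
      dy <- ps$clusters$com_y_nm - nadna_set$clusters$com_y_nm[i]
      d <- sqrt(dx^2 + dy^2)
      hit_px <- owner[nadna_set$pixels[[i]]]
      hit_ids <- unique(hit_px[hit_px > 0L])
      near_ids <- which(d <= association_radius_nm)
      qual <- union(hit_ids, near_ids)
      if (length(qual) > 0L) {
        pres[i, p] <- TRUE
        assoc[i, p] <- qual[which.min(d[qual])]
        qual_ids[i, p] <- paste(sort(qual), collapse = ",")
      }
    }
  }
  any_present <- rowSums(pres) > 0L
  rec <- data.frame(nucleus = nadna_set$roi_id,
                    focus_id = nadna_set$clusters$id,
                    com_x_nm = nadna_set$clusters$com_x_nm,
                    com_y_nm = nadna_set$clusters$com_y_nm)
  rec <- cbind(rec, as.data.frame(pres), as.data.frame(assoc),
               as.data.frame(qual_ids, stringsAsFactors = FALSE))
  rec <- rec[any_present, , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "n_nadna_only") <- sum(!any_present)
  attr(rec, "proteins") <- proteins
  class(rec) <- c("focus_records", class(rec))
  rec
}

#' Classify a focus population into fractions
#'
#' Fractions of foci positive only for the first protein, only for the
#' second, or for both, over all foci carrying at least one of the pair.
#' Also reports the pairwise interdependency descriptors: `prevalence`
#' (fraction both-positive), `dependence_a_on_b` / `dependence_b_on_a`
#' (fraction of one protein's foci also positive for the other), and an
#' `exclusion` flag set when the both-fraction falls below the product of
#' the marginals (the independence expectation).
#'
#' @param records A `focus_records` data.frame.
#' @param pair Length-2 character: the two protein columns to classify.
#' @return A `population_fractions` list: `fractions` (named, sums to 1),
#'   `n_foci`, `prevalence`, `dependence_a_on_b`, `dependence_b_on_a`,
#'   `exclusion`.
#' @export
classify_population <- function(records, pair) {
  stopifnot(length(pair) == 2L, all(pair %in% names(records)))
  a <- records[[pair[1]]]
  b <- records[[pair[2]]]
  keep <- a | b
  if (!any(keep)) stop("no foci carry either protein of the pair")
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  fr <- c(sum(a & !b), sum(!a & b), sum(a & b)) / n
  names(fr) <- c(paste0(pair[1], "-only"), paste0(pair[2], "-only"), "both")
  structure(list(
    fractions = fr, n_foci = n,
    prevalence = fr[["both"]],
    dependence_a_on_b = if (any(b)) sum(a & b) / sum(b) else NA_real_,
    dependence_b_on_a = if (any(a)) sum(a & b) / sum(a) else NA_real_,
    exclusion = fr[["both"]] < mean(a) * mean(b),
    pair = pair
  ), class = "population_fractions")
}

#' @export
print.population_fractions <- function(x, ...) {
  cat(sprintf("<population_fractions> %s / %s, n = %d foci\n",
              x$pair[1], x$pair[2], x$n_foci))
  for (nm in names(x$fractions))
    cat(sprintf("  %-14s %5.1f%%\n", nm, 100 * x$fractions[[nm]]))
  cat(sprintf("  prevalence %.3f | dependence(%s|%s) %.3f | exclusion %s\n",
              x$prevalence, x$pair[1], x$pair[2], x$dependence_a_on_b,
              x$exclusion))
  invisible(x)
}

#' Intrafoci center-of-mass distances for a protein pair
#'
#' One Euclidean distance (nm) per focus where both proteins are present:
#' the distance between the centers of mass of the two colors at the focus.
#' Each protein's center is computed over *all* of its qualifying clusters
#' (pixel-count weighted), so a cluster that the threshold fragments into
#' several components still contributes a single, unbiased center.
#'
#' @param records A `focus_records`.
#' @param protein_sets The named list of protein `cluster_set`s used to
#'   build the records.
#' @param pair Length-2 protein names.
#' @return Numeric vector of distances (nm); empty with a warning when no
#'   focus carries both proteins.
#' @export
intrafoci_distances <- function(records, protein_sets, pair) {
  stopifnot(length(pair) == 2L, all(pair %in% names(records)),
            all(pair %in% names(protein_sets)))
  both <- records[[pair[1]]] & records[[pair[2]]]
  if (!any(both)) {
    warning("no foci carry both ", pair[1], " and ", pair[2])
    return(numeric(0))
  }
  color_com <- function(protein, rows) {
    cl <- protein_sets[[protein]]$clusters
    ids_str <- records[[paste0(protein, "_clusters")]][rows]
    t(vapply(strsplit(ids_str, ","), function(ids) {
      ids <- as.integer(ids)
      w <- cl$n_px[ids]
      c(sum(cl$com_x_nm[ids] * w), sum(cl$com_y_nm[ids] * w)) / sum(w)
    }, numeric(2)))
  }
  rows <- which(both)
  ca <- color_com(pair[1], rows)
  cb <- color_com(pair[2], rows)
  sqrt((ca[, 1] - cb[, 1])^2 + (ca[, 2] - cb[, 2])^2)
}

# Single Gaussian least-squares fit to binned counts. Poisson weighting:
# an unweighted pass supplies predicted counts, then the fit is repeated
# with weights 1/max(prediction, 1) - the inverse of the Poisson variance,
# estimated from the model rather than the noisy observed counts.
fit_gauss_single <- function(mids, counts, start = NULL) {
  df <- data.frame(x = mids, y = counts)
  if (is.null(start)) {
    mu0 <- sum(mids * counts) / sum(counts)
    s0 <- sqrt(pmax(sum(counts * (mids - mu0)^2) / sum(counts), 1))
    start <- list(A = max(counts), mu = mu0, s = s0)
  }
  ctl <- minpack.lm::nls.lm.control(maxiter = 200)
  f0 <- minpack.lm::nlsLM(
    y ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df, start = start,
    lower = c(A = 0, mu = 0, s = 1), control = ctl)
  minpack.lm::nlsLM(
    y ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df,
    start = as.list(stats::coef(f0)),
    weights = 1 / pmax(stats::fitted(f0), 1),
    lower = c(A = 0, mu = 0, s = 1), control = ctl)
}

# double fit: component 1 fixed at the proximal reference (135 nm center,
# 75 nm FWHM), free amplitude; component 2 fully free
fit_gauss_double <- function(mids, counts, fixed_center = 135,
                             fixed_fwhm = 75) {
  df <- data.frame(x = mids, y = counts)
  s1 <- fwhm_to_sd(fixed_fwhm)
  # start the free component away from the fixed one, on the heavier side
  far <- mids > fixed_center + 2 * s1
  mu20 <- if (any(far) && sum(counts[far]) > 0)
    sum(mids[far] * counts[far]) / sum(counts[far]) else fixed_center + 150
  ctl <- minpack.lm::nls.lm.control(maxiter = 200)
  form <- y ~ A1 * exp(-(x - 135)^2 / (2 * s1sq)) +
    A2 * exp(-(x - mu2)^2 / (2 * s2^2))
  dat <- cbind(df, s1sq = s1^2)
  lo <- c(A1 = 0, A2 = 0, mu2 = 0, s2 = 5)
  f0 <- minpack.lm::nlsLM(
    form, data = dat,
    start = list(A1 = max(counts) / 2, A2 = max(counts) / 2,
                 mu2 = mu20, s2 = 50),
    lower = lo, control = ctl)
  minpack.lm::nlsLM(
    form, data = dat, start = as.list(stats::coef(f0)),
    weights = 1 / pmax(stats::fitted(f0), 1), lower = lo, control = ctl)
}

#' Fit an intrafoci distance histogram with one or two Gaussians
#'
#' Distances are binned (10 nm default) and the bin counts fitted by
#' weighted least squares. With `model = "auto"` a single Gaussian is tried
#' first and the double model (component 1 fixed at 135 nm center / 75 nm
#' FWHM with free amplitude; component 2 free) is adopted only when it cuts
#' the residual sum of squares by more than half and an F test at alpha =
#' 0.05 supports the extra parameters.
#'
#' Classification of the spatial relationship: a single-Gaussian center
#' within 135 +/- 37.5 nm is `proximal`; a center beyond 180 nm is
#' `distal`; accepted double fits are `mixed`; anything else (including
#' centers in the (172.5, 180] gap) is `indeterminate`.
#'
#' @param distances Numeric vector of intrafoci distances (nm).
#' @param bin_width_nm Histogram bin width (default 10 nm).
#' @param model `"auto"`, `"single"`, or `"double"`.
#' @return A `distance_fit`: `model`, `components` data.frame (center,
#'   fwhm, amplitude, fixed), `classification`, `rss`, `r_squared`,
#'   `n`, `histogram`.
#' @export
fit_distance_distribution <- function(distances, bin_width_nm = 10,
                                      model = c("auto", "single", "double")) {
  model <- match.arg(model)
  distances <- distances[is.finite(distances) & distances >= 0]
  n <- length(distances)
  if (n < 3L) stop("need at least 3 distances to fit")
  if (n < 50L)
    warning("only ", n, " distances; the fit may be unstable")
  br <- seq(0, max(distances) + bin_width_nm, by = bin_width_nm)
  h <- graphics::hist(distances, breaks = br, plot = FALSE)
  mids <- h$mids; counts <- h$counts
  rss <- function(fit) sum(stats::residuals(fit)^2)
  single <- tryCatch(fit_gauss_single(mids, counts), error = function(e) e)
  use <- model
  if (model == "auto") {
    if (inherits(single, "error")) use <- "double"
    else {
      dbl <- tryCatch(fit_gauss_double(mids, counts), error = function(e) e)
      if (!inherits(dbl, "error")) {
        rss1 <- rss(single); rss2 <- rss(dbl)
        df2 <- length(mids) - 4L
        fstat <- ((rss1 - rss2) / 1) / (rss2 / max(df2, 1))
        pf_ <- stats::pf(fstat, 1, max(df2, 1), lower.tail = FALSE)
        if (rss2 < 0.5 * rss1 && pf_ < 0.05) use <- "double"
        else use <- "single"
      } else use <- "single"
    }
  }
  if (use == "single") {
    if (inherits(single, "error"))
      stop("single-Gaussian fit failed: ", conditionMessage(single))
    cf <- stats::coef(single)
    comp <- data.frame(center_nm = cf[["mu"]],
                       fwhm_nm = sd_to_fwhm(cf[["s"]]),
                       amplitude = cf[["A"]], fixed = FALSE)
    cls <- classify_center(cf[["mu"]])
    fit <- single
  } else {
    fit <- tryCatch(fit_gauss_double(mids, counts), error = function(e)
      stop("double-Gaussian fit failed: ", conditionMessage(e)))
    cf <- stats::coef(fit)
    comp <- data.frame(
      center_nm = c(135, cf[["mu2"]]),
      fwhm_nm = c(75, sd_to_fwhm(cf[["s2"]])),
      amplitude = c(cf[["A1"]], cf[["A2"]]),
      fixed = c(TRUE, FALSE))
    cls <- "mixed"
  }
  tss <- sum((counts - mean(counts))^2)
  structure(list(model = use, components = comp, classification = cls,
                 rss = rss(fit), r_squared = 1 - rss(fit) / max(tss, 1e-12),
                 n = n,
                 histogram = data.frame(mid_nm = mids, count = counts)),
            class = "distance_fit")
}

#' Proximal/distal call for a single-Gaussian center
#'
#' `proximal` within [97.5, 172.5] nm (135 +/- 37.5), `distal` beyond
#' 180 nm, `indeterminate` otherwise (including the (172.5, 180] gap).
#'
#' @param center_nm Fitted center (nm).
#' @return Character classification.
#' @export
classify_center <- function(center_nm) {
  if (center_nm >= 97.5 && center_nm <= 172.5) "proximal"
  else if (center_nm > 180) "distal"
  else "indeterminate"
}

#' 2D likelihood intensity map of a distance fit
#'
#' Presentation artifact: each fitted component becomes a radial Gaussian
#' ridge (a ring at its center distance, radial profile from the fitted
#' Gaussian), amplitudes in the fitted ratio; the map is normalized to a
#' maximum of 1.
#'
#' @param fit A `distance_fit`.
#' @param extent_nm Half-width of the square map (default 1.5x the largest
#'   center + 3 s.d.).
#' @param pixel_nm Map pixel size (default 5 nm).
#' @return Matrix (x by y) with attributes `pixel_nm`, `extent_nm`.
#' @export
likelihood_map_2d <- function(fit, extent_nm = NULL, pixel_nm = 5) {
  stopifnot(inherits(fit, "distance_fit"))
  comp <- fit$components
  if (is.null(extent_nm))
    extent_nm <- max(comp$center_nm + 3 * fwhm_to_sd(comp$fwhm_nm)) * 1.2
  ax <- seq(-extent_nm, extent_nm, by = pixel_nm)
  r <- sqrt(outer(ax^2, ax^2, "+"))
  m <- matrix(0, length(ax), length(ax))
  for (k in seq_len(nrow(comp))) {
    s <- max(fwhm_to_sd(comp$fwhm_nm[k]), 1e-6)
    m <- m + comp$amplitude[k] * exp(-(r - comp$center_nm[k])^2 / (2 * s^2))
  }
  if (max(m) > 0) m <- m / max(m)
  structure(m, pixel_nm = pixel_nm, extent_nm = extent_nm)
}

#' @export
print.distance_fit <- function(x, ...) {
  cat(sprintf("<distance_fit> %s model, n = %d, classification: %s\n",
              x$model, x$n, x$classification))
  for (k in seq_len(nrow(x$components)))
    cat(sprintf("  component %d: center %.1f nm, FWHM %.1f nm, amplitude %.2f%s\n",
                k, x$components$center_nm[k], x$components$fwhm_nm[k],
                x$components$amplitude[k],
                if (x$components$fixed[k]) " (fixed)" else ""))
  cat(sprintf("  RSS %.3g, R^2 %.4f\n", x$rss, x$r_squared))
  invisible(x)
}
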