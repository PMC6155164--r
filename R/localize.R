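# Single-molecule localization from raw frames: per-frame background
# estimation on a 2 x 2 um window at the frame minimum, candidate detection
# as local maxima of a lightly smoothed frame above background mean +
# snr_min * s.d., and per-candidate 2D Gaussian least-squares fits. Fits are
# accepted only when the full width at half maximum stays at or below
# `fwhm_max_nm` (640 nm default) and the signal-to-noise ratio - fitted
# amplitude over the background s.d. - is better than `snr_min` (3).

#' Background mean and s.d. of one frame
#'
#' Computed over a `window_um` x `window_um` square centered on the minimum
#' intensity pixel of the frame; if the frame is smaller than the window,
#' the window is clipped to the frame (and noted in the result).
#'
#' @param frame Numeric matrix (photon counts; x by y).
#' @param pixel_nm Camera pixel size (nm).
#' @param window_um Window edge (default 2 um).
#' @return List with `mean`, `sd`, `clipped`.
#' @export
estimate_background <- function(frame, pixel_nm, window_um = 2) {
  stopifnot(is.matrix(frame), pixel_nm > 0)
  w <- max(2L, round(window_um * 1000 / pixel_nm))
  nx <- nrow(frame); ny <- ncol(frame)
  clipped <- w > nx || w > ny
  idx <- which.min(frame)
  ci <- (idx - 1L) %% nx + 1L
  cj <- (idx - 1L) %/% nx + 1L
  h <- w %/% 2L
  i0 <- max(1L, ci - h); i1 <- min(nx, ci + h)
  j0 <- max(1L, cj - h); j1 <- min(ny, cj + h)
  win <- frame[i0:i1, j0:j1]
  list(mean = mean(win), sd = stats::sd(as.numeric(win)), clipped = clipped)
}

# Gaussian blur by accumulating shifted copies (small separable kernel).
smooth_frame <- function(frame, sd_px = 1) {
  r <- max(1L, ceiling(2 * sd_px))
  k <- exp(-(-r:r)^2 / (2 * sd_px^2))
  k <- k / sum(k)
  nx <- nrow(frame); ny <- ncol(frame)
  pad <- function(m, di, dj) {
    si <- pmin(pmax(seq_len(nx) + di, 1L), nx)
    sj <- pmin(pmax(seq_len(ny) + dj, 1L), ny)
    m[si, sj, drop = FALSE]
  }
  out <- matrix(0, nx, ny)
  for (d in -r:r) out <- out + k[d + r + 1L] * pad(frame, d, 0L)
  out2 <- matrix(0, nx, ny)
  for (d in -r:r) out2 <- out2 + k[d + r + 1L] * pad(out, 0L, d)
  out2
}

# strict local maxima (8-neighborhood) above a threshold
find_peaks <- function(img, threshold) {
  nx <- nrow(img); ny <- ncol(img)
  if (nx < 3L || ny < 3L) return(integer(0))
  core <- img[2:(nx - 1), 2:(ny - 1)]
  is_max <- core > threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    is_max <- is_max & core >= img[2:(nx - 1) + di, 2:(ny - 1) + dj]
  }
  w <- which(is_max)
  i <- (w - 1L) %% (nx - 2L) + 2L
  j <- (w - 1L) %/% (nx - 2L) + 2L
  (j - 1L) * nx + i
}

# fit one candidate; returns NULL on failure
fit_spot <- function(sub, ci, cj, hw, pixel_nm) {
  nx <- nrow(sub); ny <- ncol(sub)
  i0 <- max(1L, ci - hw); i1 <- min(nx, ci + hw)
  j0 <- max(1L, cj - hw); j1 <- min(ny, cj + hw)
  win <- sub[i0:i1, j0:j1]
  df <- data.frame(
    x = rep((i0:i1) - 1, times = j1 - j0 + 1L),   # 0-based pixel coords
    y = rep((j0:j1) - 1, each = i1 - i0 + 1L),
    z = as.numeric(win))
  a0 <- max(win); if (a0 <= 0) return(NULL)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2)) + b,
      data = df,
      start = list(A = a0, x0 = ci - 1, y0 = cj - 1, s = 1.3, b = 0),
      lower = c(A = 0, x0 = i0 - 2, y0 = j0 - 2, s = 0.3, b = -a0),
      upper = c(A = Inf, x0 = i1, y0 = j1, s = 20, b = a0),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  list(A = cf[["A"]], x0 = cf[["x0"]], y0 = cf[["y0"]], s_px = cf[["s"]])
}

#' Localize single molecules in a frame stack
#'
#' @param stack A `frame_stack` (or 3D array x, y, frame of photon counts).
#' @param pixel_nm Camera pixel size in nm; defaults to the stack's
#'   `pixel_nm` attribute.
#' @param snr_min Minimum signal-to-noise ratio (fitted amplitude /
#'   background s.d.); fits at or below it are discarded.
#' @param fwhm_max_nm Maximum accepted PSF FWHM in nm.
#' @param channel Channel label for the output table.
#' @return Localization table: `x_nm`, `y_nm`, `frame`, `channel`,
#'   `intensity` (fitted amplitude), `fwhm_nm`, `snr`, `precision_nm`.
#'   Attribute `n_rejected` counts discarded fits (filters + crowded pairs).
#' @export
localize_stack <- function(stack, pixel_nm = NULL, snr_min = 3,
                           fwhm_max_nm = 640, channel = "unknown") {
  if (is.null(pixel_nm)) pixel_nm <- attr(stack, "pixel_nm")
  if (is.null(pixel_nm)) stop("pixel size unknown: pass pixel_nm")
  stopifnot(length(dim(stack)) == 3)
  hw <- max(3L, ceiling(2.5 * fwhm_to_sd(fwhm_max_nm) / pixel_nm))
  out <- list()
  n_rejected <- 0L
  for (f in seq_len(dim(stack)[3])) {
    frame <- stack[, , f]
    if (all(frame == 0)) next
    bg <- estimate_background(frame, pixel_nm)
    if (!is.finite(bg$sd) || bg$sd == 0) bg$sd <- 1e-6
    sub <- frame - bg$mean
    sm <- smooth_frame(sub)
    peaks <- find_peaks(sm, snr_min * bg$sd)
    if (length(peaks) == 0L) next
    nx <- nrow(frame)
    fits <- list()
    for (p in peaks) {
      ci <- (p - 1L) %% nx + 1L
      cj <- (p - 1L) %/% nx + 1L
      ft <- fit_spot(sub, ci, cj, hw, pixel_nm)
      if (is.null(ft)) { n_rejected <- n_rejected + 1L; next }
      ft$fwhm_nm <- sd_to_fwhm(ft$s_px) * pixel_nm
      ft$snr <- ft$A / bg$sd
      ok <- ft$snr > snr_min && ft$fwhm_nm <= fwhm_max_nm && ft$fwhm_nm > 0
      if (!ok) { n_rejected <- n_rejected + 1L; next }
      fits[[length(fits) + 1L]] <- ft
    }
    if (length(fits) == 0L) next
    # crowded emitters: accepted fits closer than 1 FWHM are both dropped
    if (length(fits) > 1L) {
      xs <- vapply(fits, `[[`, 0, "x0")
      ys <- vapply(fits, `[[`, 0, "y0")
      fw <- vapply(fits, `[[`, 0, "fwhm_nm")
      d_nm <- as.matrix(stats::dist(cbind(xs, ys))) * pixel_nm
      lim <- outer(fw, fw, pmax)
      bad <- apply(d_nm < lim & upper.tri(d_nm) | t(d_nm < lim & upper.tri(d_nm)),
                   1, any)
      n_rejected <- n_rejected + sum(bad)
      fits <- fits[!bad]
    }
    for (ft in fits) {
      n_photons <- max(1, 2 * pi * ft$A * ft$s_px^2)
      out[[length(out) + 1L]] <- data.frame(
        x_nm = (ft$x0 + 0.5) * pixel_nm,
        y_nm = (ft$y0 + 0.5) * pixel_nm,
        frame = f, channel = channel, intensity = ft$A,
        fwhm_nm = ft$fwhm_nm, snr = ft$snr,
        precision_nm = fwhm_to_sd(ft$fwhm_nm) / sqrt(n_photons))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    cbind(empty_locs(), data.frame(fwhm_nm = numeric(0), snr = numeric(0)))[
      , c("x_nm", "y_nm", "frame", "channel", "intensity", "fwhm_nm", "snr",
          "precision_nm")]
  rownames(res) <- NULL
  attr(res, "n_rejected") <- n_rejected
  res
}
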