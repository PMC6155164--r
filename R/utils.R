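# Shared numerical helpers used across the pipeline.

#' Conversion factor between Gaussian FWHM and standard deviation
#'
#' `FWHM = 2 * sqrt(2 * log(2)) * sd`. Used everywhere a width is stated as a
#' full width at half maximum (PSFs, displacement models, distance fits).
#'
#' @format A length-one numeric, `2 * sqrt(2 * log(2))` (about 2.3548).
#' @export
FWHM_PER_SD <- 2 * sqrt(2 * log(2))

#' Convert FWHM (nm) to Gaussian s.d. (nm)
#' @param fwhm Full width at half maximum.
#' @return Standard deviation in the same units.
#' @export
fwhm_to_sd <- function(fwhm) fwhm / FWHM_PER_SD

#' Convert Gaussian s.d. (nm) to FWHM (nm)
#' @param sd Standard deviation.
#' @return Full width at half maximum in the same units.
#' @export
sd_to_fwhm <- function(sd) sd * FWHM_PER_SD

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministic counter mixing: sub-seeds for internal simulation loops
#' (e.g. the 20 cluster randomizations of a colocalization run) are derived
#' from one master seed so a whole analysis replays bit-identically from a
#' single integer. Arithmetic is exact in doubles (all intermediates < 2^53)
#' and the result lies in [1, 2^31 - 2].
#'
#' @param seed Master seed (integer-valued scalar).
#' @param counter Non-negative integer distinguishing the consumer.
#' @return An integer seed usable with [set.seed()].
#' @export
derive_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(counter), length(counter) == 1L, counter >= 0)
  m <- 2147483647 # 2^31 - 1
  s <- (abs(seed) %% m) + 1
  # two rounds of multiply-add mixing keeps neighboring counters uncorrelated
  x <- (s * 48271) %% m
  x <- (x + (counter + 1) * 69621) %% m
  x <- (x * 16807) %% m
  as.integer(x %% (m - 1) + 1)
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Polygon area by the shoelace formula (nm^2); vertices as n x 2 matrix.
polygon_area <- function(verts) {
  x <- verts[, 1]; y <- verts[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Points-in-polygon via mgcv::in.out (C implementation).
points_in_polygon <- function(verts, pts) {
  bnd <- rbind(verts, verts[1, , drop = FALSE])
  mgcv::in.out(as.matrix(bnd), as.matrix(pts))
}

# Exponent table for a total-degree-d bivariate polynomial basis.
poly_exponents <- function(degree) {
  g <- expand.grid(i = 0:degree, j = 0:degree)
  g <- g[g$i + g$j <= degree, , drop = FALSE]
  g <- g[order(g$i + g$j, g$i), , drop = FALSE]
  rownames(g) <- NULL
  g
}

# Design matrix of monomials x^i y^j for the exponent table.
poly_design <- function(x, y, exponents) {
  mapply(function(i, j) x^i * y^j, exponents$i, exponents$j)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
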