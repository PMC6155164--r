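# Population-level aggregation of per-cell colocalization coefficients:
# group means with s.e.m., Welch two-sample t tests against a reference
# condition, significance stars, and the protein x timepoint heatmap matrix.

#' Summarize per-cell coefficients by condition and timepoint
#'
#' Cells whose coefficient is `NA` (flagged nuclei, e.g. zero simulated
#' overlap) are excluded from group statistics and counted in `n_excluded`.
#'
#' @param data data.frame with columns `condition`, `timepoint`,
#'   `coefficient`, and optionally `protein`.
#' @param reference Condition against which each group is t-tested
#'   (two-sample Welch). Groups are compared with the reference cells of the
#'   same protein (all reference cells if the reference lacks that
#'   timepoint structure).
#' @return A `population_summary` data.frame: one row per (protein,
#'   condition, timepoint) with `n`, `mean`, `sem`, `t`, `p`, `stars`,
#'   `flag`.
#' @export
summarize_population <- function(data, reference) {
  stopifnot(all(c("condition", "timepoint", "coefficient") %in% names(data)))
  if (!"protein" %in% names(data)) data$protein <- "protein"
  if (!reference %in% data$condition)
    stop("reference condition '", reference, "' not present")
  key <- interaction(data$protein, data$condition, data$timepoint, drop = TRUE)
  groups <- split(data, key)
  rows <- lapply(groups, function(g) {
    v <- g$coefficient
    n_excl <- sum(is.na(v))
    v <- v[!is.na(v)]
    ref <- data$coefficient[data$condition == reference &
                              data$protein == g$protein[1]]
    ref <- ref[!is.na(ref)]
    out <- data.frame(protein = g$protein[1], condition = g$condition[1],
                      timepoint = g$timepoint[1], n = length(v),
                      mean = mean(v), sem = NA_real_, t = NA_real_,
                      p = NA_real_, stars = "", flag = NA_character_,
                      n_excluded = n_excl)
    if (length(v) >= 2L) out$sem <- stats::sd(v) / sqrt(length(v))
    else out$flag <- "n<2"
    if (g$condition[1] != reference && length(v) >= 2L && length(ref) >= 2L) {
      tt <- welch_t(v, ref)
      out$t <- tt$t; out$p <- tt$p
      out$stars <- p_stars(tt$p)
      if (!is.na(tt$flag)) out$flag <- tt$flag
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res <- res[order(res$protein, res$condition, res$timepoint), ]
  class(res) <- c("population_summary", class(res))
  res
}

# Welch two-sample t with an epsilon-variance guard so degenerate
# zero-variance groups still yield a finite statistic (flagged).
welch_t <- function(a, b, eps = 1e-12) {
  va <- stats::var(a); vb <- stats::var(b)
  degenerate <- (va == 0 && vb == 0)
  if (!degenerate) {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    return(list(t = unname(tt$statistic), p = tt$p.value, flag = NA_character_))
  }
  se2 <- eps / length(a) + eps / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- length(a) + length(b) - 2
  p <- if (mean(a) == mean(b)) 1 else 2 * stats::pt(-abs(tstat), df)
  list(t = tstat, p = p, flag = "degenerate-variance")
}

# Significance stars following the usual convention.
p_stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}

#' Protein-by-timepoint heatmap matrix of mean coefficients
#'
#' Aggregates a population summary (one condition) into the matrix behind a
#' spatiotemporal arrival/departure heatmap. Missing (protein, timepoint)
#' cells are `NA`; duplicates are an error.
#'
#' @param summary A `population_summary` (or compatible data.frame with
#'   `protein`, `timepoint`, `mean`).
#' @return Numeric matrix, rows = proteins, columns = sorted timepoints.
#' @export
build_timecourse_heatmap <- function(summary) {
  stopifnot(all(c("protein", "timepoint", "mean") %in% names(summary)))
  if (nrow(summary) == 0L) {
    warning("empty population summary: returning empty heatmap")
    return(matrix(numeric(0), 0, 0))
  }
  if (anyDuplicated(summary[, c("protein", "timepoint")]))
    stop("duplicate (protein, timepoint) entries in summary")
  prot <- unique(summary$protein)
  tp <- sort(unique(summary$timepoint))
  m <- matrix(NA_real_, length(prot), length(tp),
              dimnames = list(prot, as.character(tp)))
  m[cbind(match(summary$protein, prot), match(summary$timepoint, tp))] <-
    summary$mean
  m
}
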