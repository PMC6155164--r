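# Readers and writers for the package's tabular formats. The native
# localization table is a headered CSV with columns x_nm, y_nm, frame,
# channel, intensity, precision_nm; a generic x/y/frame TSV dialect is also
# accepted. Coordinates are always nm internally.

LOC_COLUMNS <- c("x_nm", "y_nm", "frame", "channel", "intensity",
                 "precision_nm")

#' Write a localization table as headered CSV
#'
#' @param locs Localization table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path) {
  missing <- setdiff(LOC_COLUMNS, names(locs))
  if (length(missing))
    stop("localization table lacks column(s): ",
         paste(missing, collapse = ", "))
  utils::write.csv(locs[, union(LOC_COLUMNS, names(locs))], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a localization table
#'
#' @param path Input file.
#' @param dialect `"csv"` (native, headered) or `"tsv_xyframe"` (generic
#'   whitespace-separated x, y, frame with optional header).
#' @param units `"nm"` (default) or `"um"` (converted to nm on read).
#' @return A validated localization table (nm coordinates). Malformed
#'   numeric fields are an error naming the offending file line(s).
#' @export
read_localizations <- function(path, dialect = c("csv", "tsv_xyframe"),
                               units = c("nm", "um")) {
  dialect <- match.arg(dialect)
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "csv") {
    raw <- utils::read.csv(path, colClasses = "character",
                           check.names = FALSE)
    missing <- setdiff(LOC_COLUMNS, names(raw))
    if (length(missing))
      stop("format error in ", path, ": missing mandatory column(s): ",
           paste(missing, collapse = ", "))
    num_cols <- setdiff(LOC_COLUMNS, "channel")
  } else {
    raw <- utils::read.table(path, colClasses = "character",
                             col.names = c("x_nm", "y_nm", "frame"),
                             fill = FALSE)
    # a header row of labels is tolerated and dropped
    if (nrow(raw) > 0L && is.na(suppressWarnings(as.numeric(raw[1, 1]))))
      raw <- raw[-1, , drop = FALSE]
    raw$channel <- "unknown"
    raw$intensity <- "1"
    raw$precision_nm <- "10"
    num_cols <- c("x_nm", "y_nm", "frame")
  }
  out <- raw
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(v) & !(raw[[cc]] %in% c("NA", "")))
    if (length(bad))
      stop("format error in ", path, ": non-numeric '", cc, "' on line",
           if (length(bad) > 1) "s" else "", " ",
           paste(utils::head(bad + 1L, 5), collapse = ", "),
           " (1-based, counting the header)")
    out[[cc]] <- v
  }
  out$frame <- as.integer(out$frame)
  if (units == "um")
    for (cc in intersect(c("x_nm", "y_nm", "precision_nm"), names(out)))
      out[[cc]] <- out[[cc]] * 1000
  rownames(out) <- NULL
  out
}

#' Write a colocalization result as JSON
#'
#' @param result A `coloc_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coloc_json <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file.
#' @return The configuration list (validated by [run_pipeline()]).
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

# stable content hash of a configuration (md5 of its canonical YAML)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}
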