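# CSV schemas shared by the pipeline.  All three assessment methods use the
# same flat hole schema with a `source` column, so method comparisons are
# plain joins on net_id.
.truth_cols <- c("net_id", "side", "cx_cm", "cy_cm", "a_cm", "b_cm",
                 "orientation_deg", "area_cm2")
.hole_cols <- c("net_id", "side", "cx_cm", "cy_cm", "area_cm2",
                "perimeter_cm", "circularity", "aspect_ratio",
                "major_axis_cm", "minor_axis_cm", "source")
.assessment_cols <- c("net_id", "method", "hole_count", "cat1", "cat2",
                      "cat3", "cat4", "total_area_cm2", "serviceability")

# Write numerics at full double precision so read-back is lossless.
.write_csv_full <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_csv_schema <- function(path, required, numeric_cols) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad))
      stop("parse error in ", path, ", column ", col, ", row ", bad[1],
           ": non-numeric value '", df[[col]][bad[1]], "'")
    df[[col]] <- v
  }
  df
}

#' Read and write hole-inventory CSV files
#'
#' `write_ground_truth_csv()`/`read_ground_truth_csv()` handle the
#' generator's planted-hole schema (`net_id`, `side`, `cx_cm`, `cy_cm`,
#' `a_cm`, `b_cm`, `orientation_deg`, `area_cm2`); `write_hole_csv()`/
#' `read_hole_csv()` handle the measurement schema, which adds perimeter,
#' circularity, aspect ratio, axis lengths and a `source` column.  Numeric
#' fields round-trip at full double precision.
#'
#' @param x data frame to write.
#' @param path CSV file path.
#' @return The data frame (readers) or `path`, invisibly (writers).
#' @name hole_csv
NULL

#' @rdname hole_csv
#' @export
write_ground_truth_csv <- function(x, path) {
  missing <- setdiff(.truth_cols, names(x))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  .write_csv_full(x[, .truth_cols, drop = FALSE], path)
}

#' @rdname hole_csv
#' @export
read_ground_truth_csv <- function(path) {
  .read_csv_schema(path, .truth_cols, setdiff(.truth_cols, c("net_id", "side")))
}

#' @rdname hole_csv
#' @export
write_hole_csv <- function(x, path) {
  missing <- setdiff(.hole_cols, names(x))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  .write_csv_full(x[, .hole_cols, drop = FALSE], path)
}

#' @rdname hole_csv
#' @export
read_hole_csv <- function(path) {
  .read_csv_schema(path, .hole_cols,
                   setdiff(.hole_cols, c("net_id", "side", "source")))
}

#' Read and write per-net assessment CSV files
#'
#' Schema: `net_id`, `method`, `hole_count`, `cat1`..`cat4`,
#' `total_area_cm2`, `serviceability`.
#'
#' @param x assessment data frame from [assess_nets()].
#' @param path CSV file path.
#' @name assessment_csv
NULL

#' @rdname assessment_csv
#' @export
write_assessment_csv <- function(x, path) {
  missing <- setdiff(.assessment_cols, names(x))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  x$serviceability <- as.character(x$serviceability)
  .write_csv_full(x[, .assessment_cols, drop = FALSE], path)
}

#' @rdname assessment_csv
#' @export
read_assessment_csv <- function(path) {
  df <- .read_csv_schema(path, .assessment_cols,
                         c("hole_count", "cat1", "cat2", "cat3", "cat4",
                           "total_area_cm2"))
  df$serviceability <- factor(df$serviceability,
                              levels = c("good", "damaged", "too_torn"))
  df
}

#' Read or write a generator configuration as YAML
#'
#' @param path YAML file path.
#' @param config a [generator_config()].
#' @return `read_config()` returns a validated `generator_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(generator_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("configuration error: unknown field(s) ", paste(unknown, collapse = ", "))
  do.call(generator_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Write a net-side image as PNG
#'
#' @param x a `net_side_image` or numeric matrix in `[0, 1]`.
#' @param path PNG file path.
#' @export
write_net_image <- function(x, path) {
  if (inherits(x, "net_side_image")) x <- x$image
  png::writePNG(x, path)
  invisible(path)
}

#' Write a composite raster as a plain-text matrix CSV
#'
#' Cells are written bottom row first, matching the grid convention (row 1
#' = bottom of the panel).
#'
#' @param raster a `composite_raster`.
#' @param path CSV file path.
#' @export
write_raster_csv <- function(raster, path) {
  stopifnot(inherits(raster, "composite_raster"))
  write.table(raster$values, path, sep = ",",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write hotspot labels as CSV
#'
#' One row per cell: `cell_x`, `cell_y` (1-based from the left/bottom),
#' `z`, `p`, `label`.
#'
#' @param gi a labelled [gi_star()] grid.
#' @param path CSV file path.
#' @export
write_hotspot_csv <- function(gi, path) {
  stopifnot(inherits(gi, "gi_star_grid"))
  df <- data.frame(cell_x = rep(seq_len(ncol(gi$z)), each = nrow(gi$z)),
                   cell_y = rep(seq_len(nrow(gi$z)), ncol(gi$z)),
                   z = as.vector(gi$z), p = as.vector(gi$p),
                   label = as.vector(gi$label))
  .write_csv_full(df, path)
}

#' Write a pipeline run manifest as JSON
#'
#' The manifest records the configuration snapshot, the root seed and the
#' per-stage seeds derived from it, the conventions in force (cutoffs,
#' cell sizes, zero-difference handling) and an MD5 digest of every file
#' the run wrote, so a run can be reproduced bit-identically.
#'
#' @param manifest named list as assembled by [run_pipeline()].
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
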