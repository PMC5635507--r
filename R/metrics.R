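# WHOPES hole-size classes, by major-axis diameter (cm):
#   1: (0.5, 2]   "smaller than a thumb"
#   2: (2, 10]    "larger than a thumb, smaller than a fist"
#   3: (10, 25]   "larger than a fist, smaller than a head"
#   4: (25, Inf)  "head-sized or larger"
# Holes of diameter <= 0.5 cm are not counted (mosquitoes are assumed
# unable to pass).  Midpoint areas are circle areas at the class midpoint
# diameters 1.25, 6 and 17.5 cm; the open-ended top class is conventionally
# assigned 30 cm.  The areas are stored as the guideline constants.
.whopes_bounds <- c(0.5, 2, 10, 25)
.whopes_mid_diam <- c(1.25, 6, 17.5, 30)
.whopes_mid_area <- c(1.2, 28.3, 240.5, 706.9)

#' WHOPES size category of a hole
#'
#' Classifies a hole by its (major-axis) diameter into the four WHOPES
#' size classes; holes of 0.5 cm or less are not counted and map to `NA`.
#'
#' @param diameter_cm non-negative diameter(s) in cm.  For non-circular
#'   holes the major axis is used as the diameter proxy.
#' @return Integer vector of categories 1-4, `NA` for uncounted holes.
#' @examples
#' whopes_category(c(0.5, 2, 26))  # NA, 1, 4
#' @export
whopes_category <- function(diameter_cm) {
  if (any(diameter_cm < 0)) stop("diameter_cm must be >= 0")
  k <- findInterval(diameter_cm, .whopes_bounds, left.open = TRUE)
  k[k == 0L] <- NA_integer_
  as.integer(k)
}

#' Midpoint area of a WHOPES category
#'
#' The guideline area imputed to every hole in a WHOPES size class: the
#' area of a circle at the class midpoint diameter (1.25, 6, 17.5 cm, and
#' 30 cm by convention for the open-ended top class), rounded to one
#' decimal: 1.2, 28.3, 240.5 and 706.9 cm2.
#'
#' @param category integer category 1-4 (vectorized; `NA` passes through).
#' @return Midpoint area(s) in cm2.
#' @export
whopes_midpoint_area <- function(category) {
  ok <- is.na(category) | (category %in% 1:4)
  if (!all(ok)) stop("category must be 1, 2, 3 or 4")
  .whopes_mid_area[as.integer(category)]
}

#' @rdname whopes_midpoint_area
#' @export
whopes_midpoint_diameter <- function(category) {
  ok <- is.na(category) | (category %in% 1:4)
  if (!all(ok)) stop("category must be 1, 2, 3 or 4")
  .whopes_mid_diam[as.integer(category)]
}

#' Area of an elliptical hole from ruler measurements
#'
#' `A = pi * a * b` with `a` half the measured length (major axis) and `b`
#' half the measured width (minor axis).
#'
#' @param length_cm,width_cm full axis lengths in cm,
#'   `length_cm >= width_cm >= 0` (vectorized).
#' @return Area(s) in cm2.
#' @examples
#' ellipse_area(4, 2)  # 2*pi
#' @export
ellipse_area <- function(length_cm, width_cm) {
  if (any(width_cm < 0)) stop("width_cm must be >= 0")
  if (any(width_cm > length_cm)) stop("width_cm must not exceed length_cm")
  pi * (length_cm / 2) * (width_cm / 2)
}

#' Filter holes by major-axis cutoff
#'
#' Keeps holes whose major axis is at least `cutoff_cm`, preserving order.
#' The standard comparison cutoff is 0.5 cm; 0.4 cm probes the sensitivity
#' of results to the subjective field cutoff.
#'
#' @param holes hole-measurement data frame with a `major_axis_cm` column.
#' @param cutoff_cm non-negative cutoff in cm.
#' @return The filtered data frame.
#' @export
filter_by_major_axis <- function(holes, cutoff_cm = 0.5) {
  if (cutoff_cm < 0) stop("cutoff_cm must be >= 0")
  holes[holes$major_axis_cm >= cutoff_cm, , drop = FALSE]
}

#' Serviceability class of a net
#'
#' Net-level condition from total hole area: `good` below 80 cm2,
#' `damaged` from 80 up to (excluding) 790 cm2, `too_torn` at 790 cm2 and
#' above.  The published thresholds leave the gaps `[79, 80)` and
#' `[789, 790)` unassigned; the half-open convention used here is
#' exhaustive and order-preserving.
#'
#' @param total_area_cm2 non-negative total hole area(s) in cm2.
#' @return Factor with levels `good`, `damaged`, `too_torn`.
#' @export
serviceability <- function(total_area_cm2) {
  if (any(total_area_cm2 < 0)) stop("total_area_cm2 must be >= 0")
  cls <- ifelse(total_area_cm2 < 80, "good",
         ifelse(total_area_cm2 < 790, "damaged", "too_torn"))
  factor(cls, levels = c("good", "damaged", "too_torn"))
}

#' Per-net damage assessment
#'
#' Aggregates one net's holes under one of the three area models:
#' * `whopes`: each hole contributes the midpoint area of its WHOPES class
#'   (keyed on major-axis diameter); holes of 0.5 cm or less are not
#'   counted, following the field protocol's strict cutoff.
#' * `image`: each hole contributes its measured `area_cm2` (apply
#'   [filter_by_major_axis()] beforehand if a comparison cutoff is wanted).
#' * `ruler`: each hole contributes the ellipse area from its major and
#'   minor axes.
#'
#' Category counts (by major-axis diameter) and the serviceability class
#' are reported for every method.
#'
#' @param holes hole data frame for a single net (columns `net_id`,
#'   `major_axis_cm`, plus `area_cm2` for `image` and `minor_axis_cm` for
#'   `ruler`); may have zero rows.
#' @param method `"image"`, `"whopes"` or `"ruler"`.
#' @param net_id net identifier used when `holes` is empty.
#' @return One-row data frame: `net_id`, `method`, `hole_count`,
#'   `cat1`..`cat4`, `total_area_cm2`, `serviceability`.
#' @export
assess_net <- function(holes, method = c("image", "whopes", "ruler"),
                       net_id = NULL) {
  method <- match.arg(method)
  if (nrow(holes) > 0) {
    ids <- unique(holes$net_id)
    if (length(ids) > 1)
      stop("holes span several net_ids; assess_net scores a single net")
    net_id <- ids
  } else if (is.null(net_id)) net_id <- NA_character_

  if (nrow(holes) == 0) {
    cat_counts <- integer(4)
    total <- 0
    count <- 0L
  } else {
    category <- whopes_category(holes$major_axis_cm)
    cat_counts <- tabulate(category, 4L)
    if (method == "whopes") {
      keep <- !is.na(category)
      count <- sum(keep)
      total <- sum(whopes_midpoint_area(category[keep]))
    } else {
      count <- nrow(holes)
      total <- if (method == "image") sum(holes$area_cm2)
               else sum(ellipse_area(holes$major_axis_cm, holes$minor_axis_cm))
    }
  }
  data.frame(net_id = net_id, method = method, hole_count = count,
             cat1 = cat_counts[1], cat2 = cat_counts[2],
             cat3 = cat_counts[3], cat4 = cat_counts[4],
             total_area_cm2 = total,
             serviceability = serviceability(total),
             stringsAsFactors = FALSE)
}

#' Assess many nets at once
#'
#' Splits a hole inventory by `net_id` and applies [assess_net()] to each.
#' Net ids listed in `net_ids` but absent from `holes` get a zero-hole
#' assessment, so intact nets stay in paired comparisons.
#'
#' @inheritParams assess_net
#' @param net_ids optional character vector of all net ids to report.
#' @return Data frame with one row per net, ordered by `net_id`.
#' @export
assess_nets <- function(holes, method = c("image", "whopes", "ruler"),
                        net_ids = NULL) {
  method <- match.arg(method)
  if (is.null(net_ids)) net_ids <- sort(unique(holes$net_id))
  out <- lapply(net_ids, function(id)
    assess_net(holes[holes$net_id == id, , drop = FALSE], method, net_id = id))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Seven-number summary of a distribution
#'
#' Minimum, quartiles, median, mean, maximum and total, with quartiles by
#' the median-of-halves rule (the median is excluded from both halves when
#' the sample size is odd).
#'
#' @param values non-empty numeric vector.
#' @return Named list: `min`, `q1`, `median`, `mean`, `q3`, `max`, `sum`.
#' @examples
#' summarize_distribution(c(1, 2, 3, 4))  # q1 1.5, median 2.5, q3 3.5
#' @export
summarize_distribution <- function(values) {
  if (length(values) == 0) stop("values must be non-empty")
  if (any(!is.finite(values))) stop("values must be finite")
  x <- sort(values)
  n <- length(x)
  lower <- x[seq_len(floor(n / 2))]
  upper <- x[seq.int(ceiling(n / 2) + 1, n)]
  if (n == 1) lower <- upper <- x
  list(min = x[1], q1 = median(lower), median = median(x),
       mean = mean(x), q3 = median(upper), max = x[n], sum = sum(x))
}
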