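#' Scale calibration from a reference marker
#'
#' Converts between pixels and cm from an in-frame marker of known physical
#' length.  The factor applies multiplicatively to lengths and quadratically
#' to areas.
#'
#' @param marker_length_cm physical marker length (> 0).
#' @param marker_length_px its measured length in pixels (> 0).
#' @return Object of class `scale_calibration` with `cm_per_px`,
#'   `marker_length_cm` and `marker_length_px`.
#' @examples
#' calibrate_scale(10, 200)$cm_per_px  # 0.05
#' @export
calibrate_scale <- function(marker_length_cm, marker_length_px) {
  if (!is.numeric(marker_length_cm) || !is.numeric(marker_length_px) ||
      marker_length_cm <= 0 || marker_length_px <= 0)
    stop("marker_length_cm and marker_length_px must both be > 0")
  structure(list(cm_per_px = marker_length_cm / marker_length_px,
                 marker_length_cm = marker_length_cm,
                 marker_length_px = marker_length_px),
            class = "scale_calibration")
}

# Otsu's threshold on a 256-bin histogram; NA for a constant image.
.otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, edges, all.inside = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- w * (1 - w)
  sb <- ifelse(denom > 0, (mu_t * w - mu)^2 / denom, 0)
  edges[which.max(sb) + 1L]   # upper edge of the best split bin
}

#' Binarize a net-side image
#'
#' Foreground (`TRUE`) marks hole pixels, which are dark: a pixel is
#' foreground when its intensity is strictly below the threshold.  With
#' `method = "otsu"` the threshold maximizes between-class variance on a
#' 256-bin histogram; `method = "fixed"` uses the supplied `threshold`.
#'
#' @param image single-channel numeric matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold intensity cutoff, required for `method = "fixed"`.
#' @return Logical mask with attributes `method` and `threshold`.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(image), is.numeric(image))
  if (method == "otsu") {
    threshold <- .otsu_threshold(image)
    if (is.na(threshold)) {
      warning("constant image: Otsu threshold is degenerate, returning empty mask")
      mask <- matrix(FALSE, nrow(image), ncol(image))
      attr(mask, "method") <- "otsu"
      attr(mask, "threshold") <- NA_real_
      return(mask)
    }
  } else if (is.null(threshold)) {
    stop("method = 'fixed' requires a threshold")
  }
  mask <- image < threshold
  attr(mask, "method") <- method
  attr(mask, "threshold") <- threshold
  mask
}

#' Circularity of a shape
#'
#' `4 * pi * area / perimeter^2`: exactly 1 for a circle, approaching 0
#' with elongation.  Values are capped at 1, since digitization can push
#' the raw ratio above 1 for small pixelated shapes.
#'
#' @param area,perimeter shape area and perimeter in consistent units;
#'   `perimeter` must be > 0.
#' @return Circularity in `(0, 1]`.
#' @examples
#' circularity(pi, 2 * pi)  # unit circle: exactly 1
#' @export
circularity <- function(area, perimeter) {
  if (any(perimeter <= 0)) stop("perimeter must be > 0")
  pmin(1, 4 * pi * area / perimeter^2)
}

.empty_holes <- function() {
  data.frame(net_id = character(), side = character(),
             cx_cm = numeric(), cy_cm = numeric(), area_cm2 = numeric(),
             perimeter_cm = numeric(), circularity = numeric(),
             aspect_ratio = numeric(), major_axis_cm = numeric(),
             minor_axis_cm = numeric(), source = character(),
             stringsAsFactors = FALSE)
}

# Default particle floor: pixel area of a 0.2 cm-diameter disk at the
# run's resolution, and never below 1 pixel.
.default_min_area_px <- function(cm_per_px) {
  max(1L, as.integer(ceiling(pi * 0.1^2 / cm_per_px^2)))
}

#' Measure holes in a binary mask
#'
#' Particle analysis of a calibrated binary mask: 8-connected components of
#' at least `min_area_px` pixels become one hole record each.  Area is
#' pixel count times `cm_per_px^2`; the perimeter is the length of the
#' traced outer contour (diagonal steps weighted `sqrt(2)`); circularity is
#' `4*pi*area/perimeter^2` capped at 1; the major/minor axes and aspect
#' ratio come from the ellipse with matching second central moments (with
#' the 1/12 px^2 variance of the unit pixel added, so single-pixel-wide
#' components stay finite).  Centroids are reported in cm from the left and
#' bottom edges of the panel.
#'
#' @param mask logical matrix, `TRUE` = hole pixel; row 1 is the top of the
#'   panel.
#' @param cal a [calibrate_scale()] result.
#' @param min_area_px smallest component retained, in pixels (>= 1);
#'   default: area of a 0.2 cm-diameter disk at this resolution.
#' @param net_id,side identifiers copied into the records.
#' @return Data frame of hole measurements (`source = "image"`), possibly
#'   with zero rows.
#' @export
measure_holes <- function(mask, cal, min_area_px = NULL,
                          net_id = "net0001", side = "long1") {
  stopifnot(is.matrix(mask), inherits(cal, "scale_calibration"))
  cmpp <- cal$cm_per_px
  if (is.null(min_area_px)) min_area_px <- .default_min_area_px(cmpp)
  if (min_area_px < 1) stop("min_area_px must be >= 1")
  storage.mode(mask) <- "logical"
  lab <- cc_label_8(mask)
  n_lab <- attr(lab, "n_labels")
  if (n_lab == 0L) return(.empty_holes())

  idx <- which(lab > 0L)
  l <- lab[idx]
  nr <- nrow(lab)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  npix <- tabulate(l, n_lab)
  s <- rowsum(cbind(cc, rr, cc^2, rr^2, cc * rr), l)  # rows ordered by label
  mx <- s[, 1] / npix
  my <- s[, 2] / npix
  # second central moments with the unit-pixel 1/12 correction
  sxx <- s[, 3] / npix - mx^2 + 1 / 12
  syy <- s[, 4] / npix - my^2 + 1 / 12
  sxy <- s[, 5] / npix - mx * my
  tr2 <- (sxx + syy) / 2
  det2 <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
  l1 <- tr2 + det2
  l2 <- pmax(tr2 - det2, 1e-12)
  major_px <- 4 * sqrt(l1)
  minor_px <- 4 * sqrt(l2)
  perim_px <- cc_perimeter(lab, n_lab)

  keep <- npix >= min_area_px
  if (!any(keep)) return(.empty_holes())
  data.frame(
    net_id = net_id, side = side,
    cx_cm = (mx[keep] - 0.5) * cmpp,
    cy_cm = (nr - my[keep] + 0.5) * cmpp,
    area_cm2 = npix[keep] * cmpp^2,
    perimeter_cm = perim_px[keep] * cmpp,
    circularity = circularity(npix[keep], perim_px[keep]),
    aspect_ratio = major_px[keep] / minor_px[keep],
    major_axis_cm = major_px[keep] * cmpp,
    minor_axis_cm = minor_px[keep] * cmpp,
    source = "image",
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Detect and measure holes on a net-side image
#'
#' Full measurement chain for one panel: calibrate the scale from the
#' marker descriptor, binarize, mask out the marker region (padded by two
#' pixels), and measure the remaining particles.
#'
#' @param x a `net_side_image` (from [render_side_image()]) or a numeric
#'   image matrix.
#' @param marker marker descriptor (`length_cm`, `length_px`, `bbox_px`);
#'   taken from `x` when `x` is a `net_side_image`.
#' @param min_area_px particle floor in pixels; see [measure_holes()].
#' @param method,threshold binarization settings, see [binarize()].
#' @param net_id,side identifiers for the records; default to the values
#'   carried by `x` where available.
#' @return Data frame of hole measurements tagged `source = "image"`.
#' @export
detect_holes <- function(x, marker = NULL, min_area_px = NULL,
                         method = "otsu", threshold = NULL,
                         net_id = "net0001", side = NULL) {
  if (inherits(x, "net_side_image")) {
    if (is.null(marker)) marker <- x$marker
    if (is.null(side)) side <- x$side
    x <- x$image
  }
  if (is.null(side)) side <- "long1"
  if (is.null(marker) || is.null(marker$length_cm) || is.null(marker$length_px))
    stop("calibration error: no usable scale marker descriptor supplied")
  cal <- calibrate_scale(marker$length_cm, marker$length_px)
  mask <- binarize(x, method = method, threshold = threshold)
  if (!is.null(marker$bbox_px)) {
    b <- marker$bbox_px
    r0 <- max(1L, b[1] - 2L); r1 <- min(nrow(mask), b[2] + 2L)
    c0 <- max(1L, b[3] - 2L); c1 <- min(ncol(mask), b[4] + 2L)
    mask[r0:r1, c0:c1] <- FALSE
  }
  measure_holes(mask, cal, min_area_px = min_area_px,
                net_id = net_id, side = side)
}

#' Read a net photograph from disk
#'
#' Reads a PNG or TIFF image; RGB images are converted to a single channel
#' by Rec. 709 luminance.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return Numeric intensity matrix in `[0, 1]`.
#' @export
read_net_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "': ", path))
  if (length(dim(img)) == 3) {
    ch <- dim(img)[3]
    img <- if (ch >= 3)
      0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    else img[, , 1]
  }
  img
}
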