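#' Reconstruct ellipse axes from area and aspect ratio
#'
#' Inverts the (area, aspect ratio) pair of a measured hole into the
#' semi-axes of the perfect ellipse with that area and elongation:
#' `a = sqrt(area * ar / pi)`, `b = sqrt(area / (pi * ar))`, so that
#' `pi * a * b` recovers the area and `a / b` the aspect ratio.  Holes are
#' assumed to orient horizontally (no angular information is available
#' from the measurement chain).
#'
#' @param cx_cm,cy_cm centroid in cm from the left/bottom panel edges.
#' @param area_cm2 hole area(s), > 0.
#' @param ar aspect ratio(s), >= 1.
#' @return Data frame of ellipses: `cx_cm`, `cy_cm`, `a_cm`, `b_cm`,
#'   `orientation_deg` (all 0).
#' @examples
#' reconstruct_ellipse(0, 0, 4 * pi, 4)  # a = 4, b = 1
#' @export
reconstruct_ellipse <- function(cx_cm, cy_cm, area_cm2, ar) {
  if (any(area_cm2 <= 0)) stop("area_cm2 must be > 0")
  if (any(ar < 1)) stop("ar must be >= 1")
  data.frame(cx_cm = cx_cm, cy_cm = cy_cm,
             a_cm = sqrt(area_cm2 * ar / pi),
             b_cm = sqrt(area_cm2 / (pi * ar)),
             orientation_deg = 0)
}

.raster_dims <- function(side_type, cell_size_cm, geometry) {
  dims <- panel_size(side_type, geometry)
  c(h = ceiling(dims[["height_cm"]] / cell_size_cm),
    w = ceiling(dims[["width_cm"]] / cell_size_cm))
}

.new_raster <- function(values, side_type, cell_size_cm, n_nets) {
  structure(list(values = values, side_type = side_type,
                 cell_size_cm = cell_size_cm, n_nets = n_nets),
            class = "composite_raster")
}

#' @export
print.composite_raster <- function(x, ...) {
  cat(sprintf("composite_raster: %s side, %d x %d cells of %g cm (%d nets), total %g\n",
              x$side_type, nrow(x$values), ncol(x$values), x$cell_size_cm,
              x$n_nets, sum(x$values)))
  invisible(x)
}

#' Rasterize one net side's hole ellipses
#'
#' Converts a set of elliptical holes into a binary coverage grid for one
#' panel: a cell is marked 1 when its center lies inside any ellipse
#' (polygon-to-raster cell-center rule).  Row 1 of the grid is the bottom
#' of the panel; columns run from the left edge.
#'
#' @param ellipses data frame with `cx_cm`, `cy_cm`, `a_cm`, `b_cm` and
#'   optionally `orientation_deg` (degrees; default 0 = horizontal).
#' @param side_type `"long"`, `"short"` or `"roof"`.
#' @param cell_size_cm positive cell size in cm (default 1).
#' @param geometry a [net_geometry()].
#' @return A `composite_raster` with values in `{0, 1}`.
#' @export
rasterize_side <- function(ellipses, side_type = c("long", "short", "roof"),
                           cell_size_cm = 1, geometry = net_geometry()) {
  side_type <- match.arg(side_type)
  if (cell_size_cm <= 0) stop("cell_size_cm must be > 0")
  hw <- .raster_dims(side_type, cell_size_cm, geometry)
  vals <- matrix(0, nrow = hw["h"], ncol = hw["w"])
  dims <- panel_size(side_type, geometry)
  W <- dims[["width_cm"]]; H <- dims[["height_cm"]]
  for (i in seq_len(nrow(ellipses))) {
    cx <- ellipses$cx_cm[i]; cy <- ellipses$cy_cm[i]
    a <- ellipses$a_cm[i]; b <- ellipses$b_cm[i]
    th <- if ("orientation_deg" %in% names(ellipses))
      ellipses$orientation_deg[i] * pi / 180 else 0
    ct <- cos(th); st <- sin(th)
    ex <- sqrt((a * ct)^2 + (b * st)^2)
    ey <- sqrt((a * st)^2 + (b * ct)^2)
    if (cx + ex < 0 || cx - ex > W || cy + ey < 0 || cy - ey > H) {
      warning("ellipse ", i, " lies entirely outside the panel")
      next
    }
    jr <- max(1, floor((cx - ex) / cell_size_cm)):min(hw["w"], ceiling((cx + ex) / cell_size_cm))
    ir <- max(1, floor((cy - ey) / cell_size_cm)):min(hw["h"], ceiling((cy + ey) / cell_size_cm))
    xc <- (jr - 0.5) * cell_size_cm
    yc <- (ir - 0.5) * cell_size_cm
    dx <- outer(rep(1, length(ir)), xc - cx)
    dy <- outer(yc - cy, rep(1, length(jr)))
    u <- dx * ct + dy * st
    v <- -dx * st + dy * ct
    vals[ir, jr][(u / a)^2 + (v / b)^2 <= 1] <- 1
  }
  .new_raster(vals, side_type, cell_size_cm, n_nets = 1L)
}

#' Sum coverage rasters across nets
#'
#' Cellwise sum of per-net coverage layers of one side type, producing the
#' composite damage picture across nets.
#'
#' @param layers list of `composite_raster` objects with identical side
#'   type, cell size and dimensions.
#' @return A `composite_raster` whose total equals the sum of layer totals.
#' @export
composite_sum <- function(layers) {
  if (length(layers) == 0) stop("no layers")
  ref <- layers[[1]]
  for (l in layers[-1]) {
    if (!identical(dim(l$values), dim(ref$values)) ||
        l$side_type != ref$side_type ||
        l$cell_size_cm != ref$cell_size_cm)
      stop("layers differ in side type, cell size or dimensions")
  }
  vals <- Reduce(`+`, lapply(layers, `[[`, "values"))
  .new_raster(vals, ref$side_type, ref$cell_size_cm,
              n_nets = sum(vapply(layers, `[[`, numeric(1), "n_nets")))
}

#' Bin hole centroids into a count grid
#'
#' Counts hole centroids per grid cell for one side type, pooling all
#' sides of that type across nets (the input of hot spot analysis).
#' Centroids falling outside the panel are clamped to the boundary cell
#' with a warning.
#'
#' @param holes hole data frame with `side`, `cx_cm`, `cy_cm` (and
#'   optionally `net_id`).
#' @param side_type `"long"`, `"short"` or `"roof"`.
#' @param cell_size_cm positive cell size in cm (default 10).
#' @param geometry a [net_geometry()].
#' @return A `composite_raster` of counts; `sum(values)` equals the number
#'   of holes on that side type.
#' @export
bin_centroids <- function(holes, side_type = c("long", "short", "roof"),
                          cell_size_cm = 10, geometry = net_geometry()) {
  side_type <- match.arg(side_type)
  if (cell_size_cm <= 0) stop("cell_size_cm must be > 0")
  hw <- .raster_dims(side_type, cell_size_cm, geometry)
  h <- holes[sub("[0-9]+$", "", holes$side) == side_type, , drop = FALSE]
  vals <- matrix(0, nrow = hw["h"], ncol = hw["w"])
  n_nets <- if ("net_id" %in% names(h)) length(unique(h$net_id)) else 1L
  if (nrow(h) > 0) {
    i <- ceiling(h$cy_cm / cell_size_cm)
    j <- ceiling(h$cx_cm / cell_size_cm)
    out <- i < 1 | i > hw["h"] | j < 1 | j > hw["w"] |
      h$cx_cm < 0 | h$cy_cm < 0
    if (any(out)) warning(sum(out), " centroid(s) outside the panel; clamped")
    i <- pmin(pmax(i, 1), hw["h"])
    j <- pmin(pmax(j, 1), hw["w"])
    i[h$cy_cm == 0] <- 1  # bottom edge belongs to the first cell
    j[h$cx_cm == 0] <- 1
    for (k in seq_along(i)) vals[i[k], j[k]] <- vals[i[k], j[k]] + 1
  }
  .new_raster(vals, side_type, cell_size_cm, n_nets = n_nets)
}

#' Getis-Ord Gi* local hot spot statistic
#'
#' For each grid cell `i`, with binary weights `w_ij = 1` for all cells
#' whose centers lie within `neighborhood_radius_cm` (the cell itself
#' included, hence Gi* rather than Gi):
#' \deqn{G_i^* = \frac{\sum_j w_{ij} x_j - \bar{X} W_i}
#'   {S \sqrt{(n W_i - W_i^2)/(n-1)}}}
#' with \eqn{\bar{X}} the global mean, `S` the global (population) standard
#' deviation, and `W_i` the neighbourhood size.  Two-sided p-values come
#' from the standard normal.  A constant grid is degenerate: all z are 0.
#'
#' @param counts numeric matrix or `composite_raster` of cell counts.
#' @param neighborhood_radius_cm fixed-distance band radius (>= cell size).
#' @param cell_size_cm cell size; taken from `counts` when it is a
#'   `composite_raster`.
#' @return Object of class `gi_star_grid`: `z`, `p`, `label` (all `"none"`
#'   until [label_hotspots()] is applied), `neighborhood_radius_cm`,
#'   `cell_size_cm`, `degenerate`.
#' @export
gi_star <- function(counts, neighborhood_radius_cm = 20, cell_size_cm = NULL) {
  side_type <- NA_character_
  if (inherits(counts, "composite_raster")) {
    if (is.null(cell_size_cm)) cell_size_cm <- counts$cell_size_cm
    side_type <- counts$side_type
    counts <- counts$values
  }
  if (is.null(cell_size_cm)) stop("cell_size_cm required for a bare matrix")
  if (neighborhood_radius_cm < cell_size_cm)
    stop("neighborhood_radius_cm must be >= cell_size_cm")
  x <- counts
  n <- length(x)
  xbar <- mean(x)
  s <- sqrt(sum(x^2) / n - xbar^2)
  degenerate <- s == 0
  z <- matrix(0, nrow(x), ncol(x))
  if (!degenerate) {
    # binary-kernel neighbourhood sums via shifted accumulation
    kr <- floor(neighborhood_radius_cm / cell_size_cm)
    offs <- expand.grid(di = -kr:kr, dj = -kr:kr)
    offs <- offs[(offs$di^2 + offs$dj^2) * cell_size_cm^2 <=
                   neighborhood_radius_cm^2, ]
    a <- matrix(0, nrow(x), ncol(x))   # sum of x over neighbourhood
    w <- matrix(0, nrow(x), ncol(x))   # neighbourhood size W_i
    nr <- nrow(x); nc <- ncol(x)
    for (k in seq_len(nrow(offs))) {
      di <- offs$di[k]; dj <- offs$dj[k]
      ri <- max(1, 1 - di):min(nr, nr - di)
      cj <- max(1, 1 - dj):min(nc, nc - dj)
      a[ri, cj] <- a[ri, cj] + x[ri + di, cj + dj]
      w[ri, cj] <- w[ri, cj] + 1
    }
    denom <- s * sqrt((n * w - w^2) / (n - 1))
    z <- (a - xbar * w) / denom
    z[!is.finite(z)] <- 0   # W_i = n: neighbourhood covers the whole grid
  }
  structure(list(z = z, p = 2 * pnorm(-abs(z)),
                 label = matrix("none", nrow(x), ncol(x)),
                 side_type = side_type,
                 neighborhood_radius_cm = neighborhood_radius_cm,
                 cell_size_cm = cell_size_cm,
                 alpha = NA_real_, fdr_applied = FALSE,
                 degenerate = degenerate),
            class = "gi_star_grid")
}

#' Label hot and cold cells
#'
#' Thresholds a Gi* grid at significance level `alpha`, by default after
#' Benjamini-Hochberg false-discovery-rate adjustment of the two-sided
#' p-values across cells.  Cells with positive z below the threshold are
#' `hot`, negative-z cells `cold`, everything else `none`.
#'
#' @param gi a [gi_star()] result.
#' @param alpha significance level in (0, 1).
#' @param fdr apply Benjamini-Hochberg adjustment before thresholding.
#' @return The `gi_star_grid` with its `label` matrix filled in.
#' @export
label_hotspots <- function(gi, alpha = 0.05, fdr = TRUE) {
  stopifnot(inherits(gi, "gi_star_grid"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  lab <- matrix("none", nrow(gi$z), ncol(gi$z))
  if (!gi$degenerate) {
    padj <- if (fdr) matrix(p.adjust(gi$p, method = "BH"), nrow(gi$p))
            else gi$p
    lab[gi$z > 0 & padj <= alpha] <- "hot"
    lab[gi$z < 0 & padj <= alpha] <- "cold"
  }
  gi$label <- lab
  gi$alpha <- alpha
  gi$fdr_applied <- fdr
  gi
}

#' @export
print.gi_star_grid <- function(x, ...) {
  cat(sprintf("gi_star_grid: %d x %d cells of %g cm, band %g cm; %d hot, %d cold%s\n",
              nrow(x$z), ncol(x$z), x$cell_size_cm, x$neighborhood_radius_cm,
              sum(x$label == "hot"), sum(x$label == "cold"),
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}
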