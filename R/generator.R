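#' WHOPES hole-size category mixtures
#'
#' Two calibrated mixtures over the four WHOPES size classes are available:
#' `"image"`, the distribution observed when holes are sized objectively
#' from photographs (84% / 13% / 2% / 0.3%, normalized), and `"surveyor"`,
#' the distribution scored visually in the field (66% / 27% / 5% / 2%).
#' The image mixture is the generator default.
#'
#' @param preset `"image"` or `"surveyor"`.
#' @return Numeric probability 4-vector summing to 1.
#' @export
category_mix <- function(preset = c("image", "surveyor")) {
  preset <- match.arg(preset)
  p <- switch(preset,
    image    = c(0.84, 0.13, 0.02, 0.003),
    surveyor = c(0.66, 0.27, 0.05, 0.02))
  p / sum(p)
}

#' Configuration of the synthetic-net generator
#'
#' Bundles every tunable of the synthetic bed-net generator.  Defaults are
#' calibrated to the damage structure typical of polyethylene LLINs after
#' roughly one year of field use: a right-skewed hole count per net
#' (negative binomial, median 10, IQR about 4-22), a category mixture in
#' which 84% of holes are smaller than a thumb, log-normal aspect ratios
#' whose medians rise with hole size class (2.4, 3.5, 4.8, 5.5; overall
#' median about 2.6), and half of all side-panel holes concentrated in the
#' lowest quarter of the panel.
#'
#' @param holes_per_net either a single non-negative count (every net gets
#'   exactly that many holes) or a list `list(type = "nbinom", size=, mu=)`.
#' @param category_probs probability 4-vector over WHOPES size classes;
#'   must sum to 1 (tolerance 1e-9).
#' @param ar_logmean log-scale mean(s) of the aspect-ratio law; either a
#'   scalar or one value per size class.  Must be >= 0 (aspect ratios are
#'   never below 1 in the median).
#' @param ar_logsd log-scale standard deviation of the aspect-ratio law.
#' @param bottom_band_fraction probability that a side-panel hole falls in
#'   the lowest quarter of the panel height; `0.25` makes vertical
#'   placement uniform.  Roof holes are always placed uniformly.
#' @param resolution_px_per_cm rendering resolution, pixels per cm.
#' @param noise_sd additive Gaussian pixel-noise standard deviation, on the
#'   `[0, 1]` intensity scale.
#' @param seed default integer seed for sampling and rendering; `NULL`
#'   leaves the RNG stream untouched.
#' @return An object of class `generator_config`.
#' @seealso [sample_hole_inventory()], [render_side_image()]
#' @export
generator_config <- function(holes_per_net = list(type = "nbinom", size = 0.85, mu = 16),
                             category_probs = category_mix("image"),
                             ar_logmean = log(c(2.4, 3.5, 4.8, 5.5)),
                             ar_logsd = 0.45,
                             bottom_band_fraction = 0.5,
                             resolution_px_per_cm = 5,
                             noise_sd = 0.02,
                             seed = NULL) {
  if (is.numeric(holes_per_net)) {
    if (length(holes_per_net) != 1 || holes_per_net < 0)
      stop("configuration error: holes_per_net must be a single count >= 0")
  } else if (!is.list(holes_per_net) || !identical(holes_per_net$type, "nbinom") ||
             is.null(holes_per_net$size) || is.null(holes_per_net$mu)) {
    stop("configuration error: holes_per_net must be a count or list(type='nbinom', size=, mu=)")
  }
  if (length(category_probs) != 4 || any(category_probs < 0) ||
      abs(sum(category_probs) - 1) > 1e-9)
    stop("configuration error: category_probs must be 4 probabilities summing to 1")
  if (!length(ar_logmean) %in% c(1L, 4L) || any(ar_logmean < 0))
    stop("configuration error: ar_logmean must be a non-negative scalar or 4-vector")
  if (ar_logsd < 0) stop("configuration error: ar_logsd must be >= 0")
  if (bottom_band_fraction < 0 || bottom_band_fraction > 1)
    stop("configuration error: bottom_band_fraction must be in [0, 1]")
  if (resolution_px_per_cm <= 0)
    stop("configuration error: resolution_px_per_cm must be > 0")
  if (noise_sd < 0) stop("configuration error: noise_sd must be >= 0")
  structure(
    list(holes_per_net = holes_per_net, category_probs = category_probs,
         ar_logmean = ar_logmean, ar_logsd = ar_logsd,
         bottom_band_fraction = bottom_band_fraction,
         resolution_px_per_cm = resolution_px_per_cm,
         noise_sd = noise_sd, seed = seed),
    class = "generator_config")
}

# WHOPES major-axis diameter bounds (cm); the open-ended top class is
# truncated at 60 cm for sampling.
.cat_lo <- c(0.5, 2, 10, 25)
.cat_hi <- c(2, 10, 25, 60)

.sample_counts <- function(spec, n) {
  if (is.numeric(spec)) rep.int(as.integer(spec), n)
  else rnbinom(n, size = spec$size, mu = spec$mu)
}

# Log-normal aspect ratios with per-category location and a floor of 1,
# enforced by resampling.
.sample_ar <- function(category, ar_logmean, ar_logsd) {
  mu <- if (length(ar_logmean) == 1) rep(ar_logmean, 4) else ar_logmean
  ar <- rlnorm(length(category), mu[category], ar_logsd)
  while (any(bad <- ar < 1))
    ar[bad] <- rlnorm(sum(bad), mu[category[bad]], ar_logsd)
  ar
}

.empty_truth <- function() {
  data.frame(net_id = character(), side = character(),
             cx_cm = numeric(), cy_cm = numeric(),
             a_cm = numeric(), b_cm = numeric(),
             orientation_deg = numeric(), area_cm2 = numeric(),
             stringsAsFactors = FALSE)
}

#' Sample a ground-truth hole inventory
#'
#' Draws a full inventory of elliptical holes over `n_nets` synthetic nets.
#' Each hole carries a net id, a side, a centroid (cm from the left and
#' bottom panel edges), semi-axes `a_cm >= b_cm`, an orientation (0 degrees
#' by default: horizontal), and its exact area `pi * a * b`.  Sampling
#' scheme: holes are apportioned to sides proportionally to panel area; the
#' WHOPES size class is drawn from `category_probs`; the major-axis
#' diameter `2a` is log-uniform within the class bounds; the aspect ratio
#' `a/b` follows the configured log-normal law; the vertical position of
#' side-panel holes is a mixture placing `bottom_band_fraction` of the mass
#' uniformly in the lowest quarter of the panel.
#'
#' @param config a [generator_config()].
#' @param geometry a [net_geometry()].
#' @param n_nets number of nets to simulate (>= 1).
#' @param seed integer seed; defaults to `config$seed`.
#' @return A data frame of planted holes (columns `net_id`, `side`,
#'   `cx_cm`, `cy_cm`, `a_cm`, `b_cm`, `orientation_deg`, `area_cm2`), one
#'   row per hole; zero rows when every net has zero holes.
#' @examples
#' truth <- sample_hole_inventory(generator_config(seed = 1), n_nets = 3)
#' head(truth)
#' @export
sample_hole_inventory <- function(config, geometry = net_geometry(), n_nets,
                                  seed = config$seed) {
  stopifnot(inherits(config, "generator_config"), n_nets >= 1)
  .with_seed(seed, function() {
    counts <- .sample_counts(config$holes_per_net, n_nets)
    total <- sum(counts)
    if (total == 0) return(.empty_truth())
    net_id <- rep(sprintf("net%04d", seq_len(n_nets)), counts)
    areas <- .panel_areas(geometry)
    side <- sample(geometry$sides, total, replace = TRUE, prob = areas)
    category <- sample.int(4L, total, replace = TRUE, prob = config$category_probs)
    diam <- exp(runif(total, log(.cat_lo[category]), log(.cat_hi[category])))
    a <- diam / 2
    ar <- .sample_ar(category, config$ar_logmean, config$ar_logsd)
    b <- a / ar

    dims <- vapply(side, panel_size, numeric(2), geometry = geometry)
    w <- dims["width_cm", ]
    h <- dims["height_cm", ]
    cx <- runif(total, 0, w)
    on_roof <- side_type(side) == "roof"
    in_band <- !on_roof & runif(total) < config$bottom_band_fraction
    cy <- ifelse(in_band, runif(total, 0, 0.25 * h), runif(total, 0.25 * h, h))
    cy[on_roof] <- runif(sum(on_roof), 0, h[on_roof])

    data.frame(net_id = net_id, side = side, cx_cm = cx, cy_cm = cy,
               a_cm = a, b_cm = b, orientation_deg = 0,
               area_cm2 = pi * a * b,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Plant non-overlapping holes on a regular grid
#'
#' Places `n` elliptical holes at safely separated grid positions on one
#' panel type, for detector parameter-recovery studies where overlap must
#' not occur.  Spills onto additional synthetic nets when one panel cannot
#' hold all holes.
#'
#' @param n number of holes.
#' @param side side identifier the holes belong to.
#' @param diameter_range major-axis diameter range (cm); drawn log-uniformly.
#' @param ar_logmean,ar_logsd aspect-ratio law (see [generator_config()]).
#' @param geometry a [net_geometry()].
#' @param seed integer seed.
#' @return Ground-truth data frame as from [sample_hole_inventory()].
#' @export
plant_grid_holes <- function(n, side = "long1", diameter_range = c(1, 6),
                             ar_logmean = log(2.6), ar_logsd = 0.45,
                             geometry = net_geometry(), seed = NULL) {
  stopifnot(n >= 1, diameter_range[1] > 0, diameter_range[2] >= diameter_range[1])
  .with_seed(seed, function() {
    dims <- panel_size(side, geometry)
    cell <- diameter_range[2] + 2   # grid pitch leaves >= 2 cm clearance
    ncx <- floor(dims[["width_cm"]] / cell)
    ncy <- floor(dims[["height_cm"]] / cell)
    per_panel <- ncx * ncy
    if (per_panel < 1) stop("panel too small for the requested diameter range")
    idx <- seq_len(n) - 1L
    panel <- idx %/% per_panel
    pos <- idx %% per_panel
    cx <- ((pos %% ncx) + 0.5) * cell
    cy <- ((pos %/% ncx) + 0.5) * cell
    diam <- exp(runif(n, log(diameter_range[1]), log(diameter_range[2])))
    a <- diam / 2
    ar <- .sample_ar(rep(1L, n), ar_logmean, ar_logsd)
    b <- a / ar
    data.frame(net_id = sprintf("net%04d", panel + 1L), side = side,
               cx_cm = cx, cy_cm = cy, a_cm = a, b_cm = b,
               orientation_deg = 0, area_cm2 = pi * a * b,
               stringsAsFactors = FALSE)
  })
}

#' Render one net side as a raster image
#'
#' Paints the fabric of one panel as a bright field, each planted hole as a
#' hard-filled dark ellipse (no anti-aliasing, so pixel counts are exact up
#' to boundary digitization), and a dark rectangular scale marker of known
#' physical length near the top-left corner; additive Gaussian noise is
#' applied last.  Holes extending beyond the panel are clipped and flagged
#' in the returned descriptor.
#'
#' @param holes ground-truth rows, all on `side`.
#' @param side side identifier to render.
#' @param resolution_px_per_cm pixels per cm.
#' @param noise_sd Gaussian noise sd on the `[0, 1]` intensity scale.
#' @param seed integer seed for the noise field.
#' @param marker_length_cm physical length of the scale marker.
#' @param geometry a [net_geometry()].
#' @return An object of class `net_side_image`: list with `image` (numeric
#'   matrix in `[0, 1]`, row 1 = top of panel), `marker` (descriptor with
#'   `length_cm`, `length_px`, `bbox_px` = c(row1, row2, col1, col2)),
#'   `clipped` (row indices of clipped holes), `side`, and
#'   `resolution_px_per_cm`.
#' @export
render_side_image <- function(holes, side, resolution_px_per_cm = 5,
                              noise_sd = 0.02, seed = NULL,
                              marker_length_cm = 10, geometry = net_geometry()) {
  stopifnot(resolution_px_per_cm > 0)
  if (nrow(holes) > 0 && !all(holes$side == side))
    stop("all holes must belong to side '", side, "'")
  res <- resolution_px_per_cm
  dims <- panel_size(side, geometry)
  W <- dims[["width_cm"]]; H <- dims[["height_cm"]]
  npw <- round(W * res); nph <- round(H * res)
  fabric <- 0.8; dark <- 0.05
  img <- matrix(fabric, nrow = nph, ncol = npw)

  clipped <- integer(0)
  if (nrow(holes) > 0) {
    th <- holes$orientation_deg * pi / 180
    ct <- cos(th); st <- sin(th)
    ex <- sqrt((holes$a_cm * ct)^2 + (holes$b_cm * st)^2)  # half-extent in x
    ey <- sqrt((holes$a_cm * st)^2 + (holes$b_cm * ct)^2)
    clipped <- which(holes$cx_cm - ex < 0 | holes$cx_cm + ex > W |
                     holes$cy_cm - ey < 0 | holes$cy_cm + ey > H)
    for (i in seq_len(nrow(holes))) {
      c0 <- max(1L, floor((holes$cx_cm[i] - ex[i]) * res))
      c1 <- min(npw, ceiling((holes$cx_cm[i] + ex[i]) * res) + 1L)
      r1 <- max(1L, floor((H - holes$cy_cm[i] - ey[i]) * res))
      r0 <- min(nph, ceiling((H - holes$cy_cm[i] + ey[i]) * res) + 1L)
      if (c0 > c1 || r1 > r0) next
      cols <- c0:c1; rows <- r1:r0
      x <- (cols - 0.5) / res
      y <- (nph - rows + 0.5) / res
      dx <- outer(rep(1, length(rows)), x - holes$cx_cm[i])
      dy <- outer(y - holes$cy_cm[i], rep(1, length(cols)))
      u <- dx * ct[i] + dy * st[i]
      v <- -dx * st[i] + dy * ct[i]
      inside <- (u / holes$a_cm[i])^2 + (v / holes$b_cm[i])^2 <= 1
      img[rows, cols][inside] <- dark
    }
  }

  # scale marker: marker_length_cm x 2 cm rectangle, 2 cm in from top-left
  mr0 <- floor(2 * res) + 1L
  mr1 <- min(nph, mr0 + round(2 * res) - 1L)
  mc0 <- floor(2 * res) + 1L
  mc1 <- min(npw, mc0 + round(marker_length_cm * res) - 1L)
  img[mr0:mr1, mc0:mc1] <- dark
  marker <- list(length_cm = marker_length_cm,
                 length_px = mc1 - mc0 + 1L,
                 bbox_px = c(mr0, mr1, mc0, mc1))

  if (noise_sd > 0)
    img <- .with_seed(seed, function() {
      matrix(pmin(1, pmax(0, img + rnorm(length(img), 0, noise_sd))),
             nrow = nph)
    })

  structure(list(image = img, marker = marker, clipped = clipped,
                 side = side, resolution_px_per_cm = res),
            class = "net_side_image")
}
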