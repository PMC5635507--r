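#' Simulated WHOPES surveyor assessment of a ground-truth inventory
#'
#' Emulates the field protocol applied to known holes: the surveyor judges
#' each hole by its longest dimension (major-axis diameter `2a`) and
#' assigns the WHOPES class; holes of 0.5 cm or less are not counted at
#' scoring time.  The returned table uses the common hole schema with
#' `source = "whopes"` and the class midpoint area as `area_cm2`.
#'
#' @param truth ground-truth data frame from [sample_hole_inventory()].
#' @return Hole-measurement data frame, `source = "whopes"`.
#' @export
simulate_whopes_survey <- function(truth) {
  category <- whopes_category(2 * truth$a_cm)
  data.frame(net_id = truth$net_id, side = truth$side,
             cx_cm = truth$cx_cm, cy_cm = truth$cy_cm,
             area_cm2 = whopes_midpoint_area(category),
             perimeter_cm = rep(NA_real_, nrow(truth)),
             circularity = rep(NA_real_, nrow(truth)),
             aspect_ratio = truth$a_cm / truth$b_cm,
             major_axis_cm = 2 * truth$a_cm,
             minor_axis_cm = 2 * truth$b_cm,
             source = rep("whopes", nrow(truth)),
             stringsAsFactors = FALSE)
}

#' Simulated ruler measurement of a ground-truth inventory
#'
#' Emulates tape-measure assessment: hole length and width are read off
#' exactly, and areas follow the ellipse formula `pi * a * b`.
#'
#' @param truth ground-truth data frame from [sample_hole_inventory()].
#' @return Hole-measurement data frame, `source = "ruler"`.
#' @export
simulate_ruler_measurement <- function(truth) {
  data.frame(net_id = truth$net_id, side = truth$side,
             cx_cm = truth$cx_cm, cy_cm = truth$cy_cm,
             area_cm2 = pi * truth$a_cm * truth$b_cm,
             perimeter_cm = rep(NA_real_, nrow(truth)),
             circularity = rep(NA_real_, nrow(truth)),
             aspect_ratio = truth$a_cm / truth$b_cm,
             major_axis_cm = 2 * truth$a_cm,
             minor_axis_cm = 2 * truth$b_cm,
             source = rep("ruler", nrow(truth)),
             stringsAsFactors = FALSE)
}

# Per-stage seeds are derived from the root seed by fixed prime offsets,
# kept below 2^31; stage k of the rendering loop uses seed_render + k.
.stage_seeds <- function(seed) {
  if (is.null(seed)) return(list(generate = NULL, render = NULL))
  list(generate = seed %% 2147480000L,
       render = (seed + 7919L) %% 2147480000L)
}

#' Run the full damage-assessment pipeline on synthetic nets
#'
#' End-to-end composition of every stage: sample ground truth, render and
#' image-analyse every side of every net, simulate the WHOPES surveyor and
#' the ruler method from the ground truth, score all three methods per
#' net, compare them pairwise on hole counts and total areas, and map the
#' spatial distribution of holes (composite coverage rasters and Gi* hot
#' spot grids per side type).  Deterministic for a fixed seed.
#'
#' @param config a [generator_config()].
#' @param n_nets number of nets to simulate.
#' @param seed root integer seed; per-stage seeds are derived from it.
#' @param geometry a [net_geometry()].
#' @param cutoff_cm major-axis cutoff applied to image and ruler holes
#'   before scoring (the WHOPES rule excludes holes <= 0.5 cm on its own).
#' @param cell_size_cm Gi* counting-cell size (cm).
#' @param composite_cell_cm composite coverage raster cell size (cm).
#' @param radius_cm Gi* fixed-distance band (cm).
#' @param alpha,fdr hot spot significance settings, see [label_hotspots()].
#' @param out_dir optional directory; when given, all artifacts (ground
#'   truth, hole inventories, assessments, rasters, hotspot labels,
#'   manifest, optionally PNG images) are written there.
#' @param write_images also write every rendered side as PNG (slow).
#' @return List with `truth`, `holes` (all three sources), `assessments`
#'   (named by method), `comparisons` (pairwise, by count and area),
#'   `spatial` (per side type: counts, Gi* grid, composite raster) and
#'   `manifest`.
#' @export
run_pipeline <- function(config = generator_config(), n_nets = 10, seed = 1,
                         geometry = net_geometry(), cutoff_cm = 0.5,
                         cell_size_cm = 10, composite_cell_cm = 1,
                         radius_cm = 20, alpha = 0.05, fdr = TRUE,
                         out_dir = NULL, write_images = FALSE) {
  seeds <- .stage_seeds(seed)
  truth <- sample_hole_inventory(config, geometry, n_nets, seed = seeds$generate)
  net_ids <- sprintf("net%04d", seq_len(n_nets))

  # image-analysis arm: render + detect each side of each net
  image_holes <- list()
  k <- 0L
  for (net in net_ids) {
    for (side in geometry$sides) {
      k <- k + 1L
      th <- truth[truth$net_id == net & truth$side == side, , drop = FALSE]
      img <- render_side_image(th, side,
                               resolution_px_per_cm = config$resolution_px_per_cm,
                               noise_sd = config$noise_sd,
                               seed = if (is.null(seeds$render)) NULL
                                      else seeds$render + k,
                               geometry = geometry)
      if (write_images && !is.null(out_dir)) {
        dir.create(file.path(out_dir, "images"), showWarnings = FALSE,
                   recursive = TRUE)
        write_net_image(img, file.path(out_dir, "images",
                                       sprintf("%s_%s.png", net, side)))
      }
      image_holes[[k]] <- detect_holes(img, net_id = net, side = side)
    }
  }
  image_holes <- do.call(rbind, image_holes)
  whopes_holes <- simulate_whopes_survey(truth)
  ruler_holes <- simulate_ruler_measurement(truth)
  holes <- rbind(image_holes, whopes_holes, ruler_holes)

  assessments <- list(
    whopes = assess_nets(whopes_holes, "whopes", net_ids = net_ids),
    image  = assess_nets(filter_by_major_axis(image_holes, cutoff_cm),
                         "image", net_ids = net_ids),
    ruler  = assess_nets(filter_by_major_axis(ruler_holes, cutoff_cm),
                         "ruler", net_ids = net_ids))

  pairs <- if (n_nets >= 2)
    list(c("whopes", "image"), c("whopes", "ruler"), c("image", "ruler"))
  else list()
  comparisons <- list()
  for (pr in pairs) {
    nm <- paste(pr, collapse = "_vs_")
    comparisons[[nm]] <- list(
      count = compare_methods(assessments[[pr[1]]], assessments[[pr[2]]],
                              metric = "hole_count"),
      area = compare_methods(assessments[[pr[1]]], assessments[[pr[2]]],
                             metric = "total_area_cm2"))
  }

  # spatial arm from the image-analysis measurements (holes of all sizes)
  spatial <- list()
  for (st in c("long", "short", "roof")) {
    counts <- bin_centroids(image_holes, st, cell_size_cm, geometry)
    gi <- label_hotspots(gi_star(counts, radius_cm), alpha = alpha, fdr = fdr)
    onsides <- image_holes[sub("[0-9]+$", "", image_holes$side) == st, ,
                           drop = FALSE]
    layers <- lapply(split(onsides, paste(onsides$net_id, onsides$side)),
                     function(h) {
                       ell <- reconstruct_ellipse(h$cx_cm, h$cy_cm,
                                                  h$area_cm2, h$aspect_ratio)
                       rasterize_side(ell, st, composite_cell_cm, geometry)
                     })
    composite <- if (length(layers)) composite_sum(unname(layers))
                 else rasterize_side(data.frame(), st, composite_cell_cm,
                                     geometry)
    spatial[[st]] <- list(counts = counts, gi = gi, composite = composite)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("netdamage")),
    seed = seed, stage_seeds = seeds, n_nets = n_nets,
    config = unclass(config),
    conventions = list(cutoff_cm = cutoff_cm,
                       whopes_cutoff = "strict > 0.5 cm",
                       image_ruler_cutoff = ">= cutoff_cm",
                       wilcoxon_zero_method = "drop",
                       gi_cell_size_cm = cell_size_cm,
                       composite_cell_cm = composite_cell_cm,
                       gi_radius_cm = radius_cm, alpha = alpha, fdr = fdr),
    files = list())

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(ground_truth = file.path(out_dir, "ground_truth.csv"),
               holes = file.path(out_dir, "holes.csv"))
    write_ground_truth_csv(truth, paths["ground_truth"])
    write_hole_csv(holes, paths["holes"])
    for (m in names(assessments)) {
      p <- file.path(out_dir, sprintf("assessment_%s.csv", m))
      write_assessment_csv(assessments[[m]], p)
      paths[paste0("assessment_", m)] <- p
    }
    for (st in names(spatial)) {
      p1 <- file.path(out_dir, sprintf("composite_%s.csv", st))
      p2 <- file.path(out_dir, sprintf("hotspots_%s.csv", st))
      write_raster_csv(spatial[[st]]$composite, p1)
      write_hotspot_csv(spatial[[st]]$gi, p2)
      paths[paste0("composite_", st)] <- p1
      paths[paste0("hotspots_", st)] <- p2
    }
    manifest$files <- as.list(tools::md5sum(unname(paths)))
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
  }

  list(truth = truth, holes = holes, assessments = assessments,
       comparisons = comparisons, spatial = spatial, manifest = manifest)
}
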