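test_that("scale calibration is a guarded ratio", {
  expect_equal(calibrate_scale(10, 200)$cm_per_px, 0.05)
  expect_equal(calibrate_scale(10, 10)$cm_per_px, 1)
  # 400 px^2 at 0.05 cm/px -> 1 cm^2
  expect_equal(400 * calibrate_scale(10, 200)$cm_per_px^2, 1)
  expect_error(calibrate_scale(0, 10), "> 0")
  expect_error(calibrate_scale(10, -1), "> 0")
})

test_that("binarization handles degenerate and boundary cases", {
  img <- matrix(0.8, 50, 50)
  expect_warning(m <- binarize(img, "otsu"), "degenerate")
  expect_false(any(m))
  expect_false(any(binarize(img, "fixed", threshold = 0)))
  expect_error(binarize(img, "fixed"), "threshold")
})

test_that("otsu separates a rendered side to within 3% of the painted mask", {
  th <- truth_df(c(60, 120, 160), c(40, 80, 110), c(4, 2, 6), c(1.5, 2, 1))
  img <- render_side_image(th, "long1", resolution_px_per_cm = 10, noise_sd = 0)
  painted <- sum(img$image < 0.4)   # noiseless ground-truth dark count
  noisy <- render_side_image(th, "long1", resolution_px_per_cm = 10,
                             noise_sd = 0.02, seed = 4)
  m <- binarize(noisy$image, "otsu")
  expect_lt(abs(sum(m) - painted) / painted, 0.03)
  # an independent Otsu implementation yields the same segmentation (the
  # objective is near-flat across the inter-mode valley, so the thresholds
  # themselves may sit at different valley positions)
  thr_eb <- EBImage::otsu(noisy$image, range = range(noisy$image))
  expect_lt(abs(sum(noisy$image < thr_eb) - sum(m)) / sum(m), 0.01)
})

test_that("connected components are 8-connected", {
  m <- matrix(FALSE, 10, 10)
  m[cbind(1:6, 1:6)] <- TRUE          # diagonal chain
  cal <- calibrate_scale(1, 1)
  h <- measure_holes(m, cal, min_area_px = 1)
  expect_equal(nrow(h), 1)            # one hole under the ImageJ convention
  expect_equal(max(EBImage::bwlabel(m)), 6)  # 4-connectivity would split it
})

test_that("a digitized disk measures like a circle", {
  m <- ellipse_mask(120, 120, 60, 60, 50, 50)
  cal <- calibrate_scale(1, 50)       # 0.02 cm/px -> unit-radius circle
  h <- measure_holes(m, cal, min_area_px = 1)
  expect_equal(nrow(h), 1)
  expect_equal(h$area_cm2, pi, tolerance = 0.02)
  expect_gte(h$circularity, 0.85)
  expect_lte(h$circularity, 1)
  expect_equal(h$aspect_ratio, 1, tolerance = 0.05)
  expect_equal(h$major_axis_cm, 2, tolerance = 0.05)
})

test_that("moment-fitted ellipse recovers the aspect ratio", {
  m <- ellipse_mask(100, 300, 50, 150, 80, 20)
  h <- measure_holes(m, calibrate_scale(1, 20), min_area_px = 1)
  expect_equal(h$aspect_ratio, 4, tolerance = 0.05)
  expect_equal(h$major_axis_cm / h$minor_axis_cm, h$aspect_ratio,
               tolerance = 1e-6)
})

test_that("disjoint particles yield one record each and empty masks none", {
  m <- ellipse_mask(100, 300, 30, 50, 20, 10) |
       ellipse_mask(100, 300, 70, 150, 15, 15) |
       ellipse_mask(100, 300, 40, 250, 25, 8)
  h <- measure_holes(m, calibrate_scale(1, 10), min_area_px = 1)
  expect_equal(nrow(h), 3)
  expect_equal(nrow(measure_holes(matrix(FALSE, 20, 20),
                                  calibrate_scale(1, 10))), 0)
})

test_that("detect recovers every planted non-overlapping hole >= 1 cm", {
  th <- plant_grid_holes(40, side = "long1", diameter_range = c(1, 5), seed = 21)
  img <- render_side_image(th, "long1", resolution_px_per_cm = 20, seed = 22)
  h <- detect_holes(img)
  expect_equal(nrow(h), nrow(th))
  expect_true(all(h$source == "image"))
  # total measured area is bounded by the panel area
  dims <- panel_size("long1")
  expect_lt(sum(h$area_cm2), prod(dims))
})

test_that("overlapping ellipses merge into one union-area record", {
  th <- truth_df(c(95, 98), c(75, 75), c(4, 4), c(2, 2))
  img <- render_side_image(th, "long1", resolution_px_per_cm = 20, noise_sd = 0)
  union_px <- sum(img$image < 0.4) -
    with(as.list(img$marker), (bbox_px[2] - bbox_px[1] + 1) *
                              (bbox_px[4] - bbox_px[3] + 1))
  noisy <- render_side_image(th, "long1", resolution_px_per_cm = 20,
                             noise_sd = 0.02, seed = 5)
  h <- detect_holes(noisy)
  expect_equal(nrow(h), 1)
  expect_equal(h$area_cm2, union_px / 400, tolerance = 0.02)
})

test_that("detect requires a usable marker and excludes its region", {
  img <- render_side_image(empty_truth_df(), "short1",
                           resolution_px_per_cm = 5, seed = 1)
  expect_equal(nrow(detect_holes(img)), 0)   # marker itself is not a hole
  expect_error(detect_holes(img$image, marker = NULL), "calibration error")
})

test_that("area error shrinks and circularity is stable across resolution", {
  th <- truth_df(95, 75, 3, 1.5)
  res <- c(10, 20, 40)
  out <- lapply(res, function(r) {
    img <- render_side_image(th, "long1", resolution_px_per_cm = r,
                             noise_sd = 0.02, seed = 6)
    detect_holes(img)
  })
  err <- vapply(out, function(h) abs(h$area_cm2 - th$area_cm2) / th$area_cm2,
                numeric(1))
  expect_true(all(diff(err) < 0))
  circ <- vapply(out, `[[`, numeric(1), "circularity")
  expect_lt(abs(circ[1] - circ[3]), 0.05)
})

test_that("circularity decreases with aspect ratio across planted categories", {
  cfg <- generator_config(holes_per_net = 60, seed = 31)
  truth <- sample_hole_inventory(cfg, n_nets = 40)
  ar <- truth$a_cm / truth$b_cm
  category <- whopes_category(2 * truth$a_cm)
  keep <- !is.na(category) & category <= 3
  kw <- kruskal_wallis(split(ar[keep], category[keep]))
  expect_lt(kw$p, 0.05)
  med <- tapply(ar[keep], category[keep], median)
  expect_true(all(diff(med) > 0))   # AR rises with size class...
  circ_proxy <- tapply(1 / ar[keep], category[keep], median)
  expect_true(all(diff(circ_proxy) < 0))  # ...so roundness falls
})
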