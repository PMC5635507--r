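test_that("ellipse reconstruction inverts (area, AR) exactly", {
  e <- reconstruct_ellipse(0, 0, pi, 1)
  expect_equal(e$a_cm, 1)
  expect_equal(e$b_cm, 1)
  e2 <- reconstruct_ellipse(10, 20, 4 * pi, 4)
  expect_equal(e2$a_cm, 4)
  expect_equal(e2$b_cm, 1)
  expect_error(reconstruct_ellipse(0, 0, 1, 0.5), ">= 1")
  expect_error(reconstruct_ellipse(0, 0, 0, 2), "> 0")

  set.seed(5)
  a <- exp(runif(50, log(0.3), log(20)))
  b <- a / runif(50, 1, 6)
  r <- reconstruct_ellipse(0, 0, pi * a * b, a / b)
  expect_equal(r$a_cm, a, tolerance = 1e-9)
  expect_equal(r$b_cm, b, tolerance = 1e-9)
})

test_that("round trip render -> measure -> reconstruct recovers planted axes", {
  th <- truth_df(c(60, 120), c(60, 100), c(4, 6), c(2, 1.5))
  img <- render_side_image(th, "long1", resolution_px_per_cm = 20,
                           noise_sd = 0.02, seed = 12)
  h <- detect_holes(img)
  m <- match_to_truth(h, th)
  rec <- reconstruct_ellipse(h$cx_cm[m], h$cy_cm[m], h$area_cm2[m],
                             h$aspect_ratio[m])
  expect_equal(rec$a_cm, th$a_cm, tolerance = 0.05)
  expect_equal(rec$b_cm, th$b_cm, tolerance = 0.05)
})

test_that("rasterization marks cells by the center-in-ellipse rule", {
  zero <- rasterize_side(data.frame(), "long", cell_size_cm = 1)
  expect_equal(sum(zero$values), 0)
  expect_equal(dim(zero$values), c(150, 190))

  one <- rasterize_side(data.frame(cx_cm = 95, cy_cm = 75, a_cm = 4, b_cm = 1),
                        "long", cell_size_cm = 1)
  expect_equal(sum(one$values), 4 * pi, tolerance = 0.15)
  expect_lte(sum(one$values), length(one$values))

  expect_warning(out <- rasterize_side(
    data.frame(cx_cm = -30, cy_cm = 75, a_cm = 2, b_cm = 1), "long", 1),
    "outside")
  expect_equal(sum(out$values), 0)
})

test_that("composite summation is cellwise and conserves totals", {
  l1 <- rasterize_side(data.frame(cx_cm = 50, cy_cm = 40, a_cm = 5, b_cm = 2),
                       "short", 1)
  l2 <- rasterize_side(data.frame(cx_cm = 120, cy_cm = 90, a_cm = 3, b_cm = 3),
                       "short", 1)
  expect_equal(composite_sum(list(l1))$values, l1$values)
  k3 <- composite_sum(list(l1, l1, l1))
  expect_equal(k3$values, 3 * l1$values)
  both <- composite_sum(list(l1, l2))
  expect_equal(sum(both$values), sum(l1$values) + sum(l2$values))
  expect_equal(both$n_nets, 2)
  bad <- rasterize_side(data.frame(), "long", 1)
  expect_error(composite_sum(list(l1, bad)), "differ")
})

test_that("centroid binning conserves counts and clamps strays", {
  holes <- data.frame(net_id = "n1", side = c("long1", "long2", "long1", "short1"),
                      cx_cm = c(10, 180, 95, 20), cy_cm = c(5, 140, 75, 30))
  g <- bin_centroids(holes, "long", cell_size_cm = 10)
  expect_equal(sum(g$values), 3)   # the short-side hole is excluded
  center <- bin_centroids(data.frame(net_id = "n1", side = "long1",
                                     cx_cm = 95, cy_cm = 75), "long", 10)
  expect_equal(center$values[8, 10], 1)
  expect_equal(sum(center$values), 1)
  expect_warning(cl <- bin_centroids(data.frame(net_id = "n1", side = "long1",
                                                cx_cm = 500, cy_cm = 75),
                                     "long", 10), "clamped")
  expect_equal(sum(cl$values), 1)

  # conservation under different cell sizes
  set.seed(3)
  hs <- data.frame(net_id = "n1", side = "short1",
                   cx_cm = runif(40, 0, 180), cy_cm = runif(40, 0, 150))
  for (cs in c(5, 10, 30))
    expect_equal(sum(bin_centroids(hs, "short", cs)$values), 40)
})

test_that("gi* matches the literal formula and flags degenerate grids", {
  flat <- gi_star(matrix(2, 10, 10), 20, cell_size_cm = 10)
  expect_true(flat$degenerate)
  expect_true(all(flat$z == 0))
  lab <- label_hotspots(flat)
  expect_true(all(lab$label == "none"))

  x <- matrix(0, 20, 20)
  x[9:11, 9:11] <- 10
  gi <- gi_star(x, neighborhood_radius_cm = 15, cell_size_cm = 10)
  expect_equal(which.max(gi$z), which(row(x) == 10 & col(x) == 10))
  oracle <- gi_star_oracle(x, 15, 10)
  expect_equal(gi$z, oracle, tolerance = 1e-9)

  set.seed(31)
  for (k in 1:3) {
    g <- matrix(rpois(24 * 30, 1.5), 24, 30)
    gi <- gi_star(g, neighborhood_radius_cm = 25, cell_size_cm = 10)
    expect_equal(gi$z, gi_star_oracle(g, 25, 10), tolerance = 1e-9)
  }

  # permuted grid at the smallest band: z-field centered near zero
  g <- matrix(sample(rep(0:3, 25)), 10, 10)
  gi <- gi_star(g, neighborhood_radius_cm = 10, cell_size_cm = 10)
  expect_lt(abs(mean(gi$z)), 0.1)
})

test_that("hotspot labelling respects alpha, FDR monotonicity and sign", {
  set.seed(13)
  x <- matrix(rpois(200, 1), 10, 20)
  x[9:10, 1:6] <- x[9:10, 1:6] + 8
  gi <- gi_star(x, 20, cell_size_cm = 10)
  # alpha -> 0 removes all labels (checked on a null grid whose smallest
  # p-value is far above the threshold)
  null_gi <- gi_star(matrix(rpois(200, 1), 10, 20), 20, cell_size_cm = 10)
  strict <- label_hotspots(null_gi, alpha = 1e-12)
  expect_true(all(strict$label == "none"))

  raw <- label_hotspots(gi, alpha = 0.05, fdr = FALSE)
  adj <- label_hotspots(gi, alpha = 0.05, fdr = TRUE)
  expect_true(all(which(adj$label != "none") %in% which(raw$label != "none")))
  expect_true(all(gi$z[adj$label == "hot"] > 0))
  expect_true(all(gi$z[adj$label == "cold"] < 0))
  expect_error(label_hotspots(gi, alpha = 0), "alpha")
})
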