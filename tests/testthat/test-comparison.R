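test_that("wilcoxon handles degenerate and mirrored inputs", {
  x <- c(3, 1, 4, 1, 5)
  r <- wilcoxon_signed_rank(x, x)
  expect_true(r$degenerate)
  expect_equal(r$p, 1)

  y <- c(2, 2, 2, 4, 4)
  a <- wilcoxon_signed_rank(x, y)
  b <- wilcoxon_signed_rank(y, x)
  expect_equal(a$p, b$p)
  expect_equal(a$statistic + b$statistic, sum(rank(abs((x - y)[x != y]))))
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
})

test_that("exact wilcoxon equals full sign enumeration", {
  x <- c(1, 2, 3, 0, 5, 6) + 10
  y <- c(0, 0, 0, 4, 0, 0) + 10   # differences 1, 2, 3, -4, 5, 6
  r <- wilcoxon_signed_rank(x, y)
  expect_equal(r$method, "exact")
  expect_equal(r$p, wilcoxon_enum_oracle(x, y))
  expect_equal(wilcoxon_signed_rank(x, y, alternative = "greater")$p,
               wilcoxon_enum_oracle(x, y, "greater"))

  # random instances with heavy ties, n <= 10
  set.seed(42)
  for (k in 1:15) {
    n <- sample(4:10, 1)
    a <- sample(0:6, n, replace = TRUE)
    b <- sample(0:6, n, replace = TRUE)
    if (all(a == b)) next
    expect_equal(wilcoxon_signed_rank(a, b)$p, wilcoxon_enum_oracle(a, b),
                 info = paste("case", k))
  }
})

test_that("exact wilcoxon matches stats::wilcox.test on tie-free data", {
  set.seed(7)
  x <- rnorm(10)
  y <- rnorm(10)
  r <- wilcoxon_signed_rank(x, y)
  w <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(r$statistic, unname(w$statistic))
  expect_equal(r$p, w$p.value)
})

test_that("large-sample wilcoxon matches the tie-corrected normal approximation", {
  set.seed(9)
  x <- sample(1:8, 40, replace = TRUE)
  y <- sample(1:8, 40, replace = TRUE)
  keep <- x != y
  r <- wilcoxon_signed_rank(x, y)
  expect_equal(r$method, "normal")
  w <- suppressWarnings(wilcox.test(x[keep], y[keep], paired = TRUE,
                                    exact = FALSE, correct = TRUE))
  expect_equal(r$p, w$p.value, tolerance = 1e-10)
})

test_that("spearman is rank-based, tie-safe, and matches cor.test", {
  x <- c(1, 2, 5, 9, 12)
  expect_equal(spearman_rho(x, exp(x))$rho, 1)
  expect_equal(spearman_rho(x, -x^3)$rho, -1)

  a <- c(1, 2, 2, 3, 5, 5, 5, 8)
  b <- c(2, 1, 4, 4, 6, 5, 9, 9)
  r <- spearman_rho(a, b)
  expect_equal(r$rho, cor(rank(a), rank(b)), tolerance = 1e-12)
  ct <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
  expect_equal(r$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(r$p, ct$p.value, tolerance = 1e-10)

  expect_warning(z <- spearman_rho(rep(1, 5), 1:5), "rank variance")
  expect_true(z$degenerate)
})

test_that("linear fit is ordinary least squares with guarded degeneracy", {
  x <- c(0, 1, 2, 7, 9)
  f <- linear_fit(x, x)
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  g <- linear_fit(x, 2.6 * x + 295)
  expect_equal(g$slope, 2.6)
  expect_equal(g$intercept, 295)
  expect_error(linear_fit(c(2, 2), c(1, 3)), "constant")
})

test_that("kruskal-wallis matches the hand rank-sum formula", {
  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_lt(same$H, 1e-10)
  expect_gt(same$p, 0.99)

  kw <- kruskal_wallis(list(c(1, 2, 3), c(10, 11, 12)))
  # H = 12/(N(N+1)) * sum(R_g^2/n_g) - 3(N+1), N=6, R = 6 and 15
  expect_equal(kw$H, 12 / 42 * (36 / 3 + 225 / 3) - 21, tolerance = 1e-12)
  expect_equal(kw$df, 1)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
  expect_error(kruskal_wallis(list(1:3)), "at least 2")
})

test_that("bland-altman reports bias and 1.96-sd limits of agreement", {
  x <- c(2, 3, 4)
  same <- bland_altman(x, x)
  expect_equal(same$bias, 0)
  expect_equal(same$loa_low, 0)
  expect_equal(same$loa_high, 0)

  shifted <- bland_altman(x + 3, x)
  expect_equal(shifted$bias, 3)
  expect_equal(shifted$loa_low, 3)

  d <- bland_altman(c(0, 1, 2), c(1, 1, 1))   # differences -1, 0, 1
  expect_equal(d$bias, 0)
  expect_equal(d$loa_high, 1.96)
  expect_equal(d$loa_low, -1.96)

  expect_error(bland_altman(c(0, 1), c(1, 1), log_transform = TRUE), "> 0")
  lg <- bland_altman(c(2, 4), c(1, 2), log_transform = TRUE)
  expect_equal(lg$bias, log(2))
})

test_that("compare_methods assembles the full battery from assessments", {
  truth <- sample_hole_inventory(generator_config(seed = 23), n_nets = 25)
  wh <- assess_nets(simulate_whopes_survey(truth), "whopes")
  ru <- assess_nets(simulate_ruler_measurement(truth), "ruler")
  cmp <- compare_methods(wh, ru, metric = "total_area_cm2")
  expect_s3_class(cmp, "paired_comparison")
  expect_equal(cmp$method_a, "whopes")
  expect_true(cmp$spearman$rho >= -1 && cmp$spearman$rho <= 1)
  expect_true(cmp$bland_altman$loa_low <= cmp$bland_altman$bias)
  expect_true(cmp$bland_altman$bias <= cmp$bland_altman$loa_high)
  expect_output(print(cmp), "Paired comparison")
})
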