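test_that("relative difference is (sim-ther)/ther in percent, NA at zero", {
  expect_equal(round(relative_difference_pct(85.36, 67.55)), 26)
  expect_equal(relative_difference_pct(5, 5), 0)
  expect_true(is.na(relative_difference_pct(3, 0)))
  expect_equal(relative_difference_pct(c(2, 3), c(4, 0)),
               c(-50, NA))
})

test_that("Mann-Whitney exact p matches enumeration on the worked cases", {
  r1 <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r1$U, 0)
  expect_equal(r1$p, 2 / 6, tolerance = 1e-12)
  expect_false(r1$significant)
  r2 <- mann_whitney_u(1:5, 6:10)
  expect_equal(r2$p, 2 / 252, tolerance = 1e-12)
  expect_true(r2$significant)
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p, 0.9)
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("Mann-Whitney agrees with brute-force enumeration across sizes", {
  set.seed(31)
  for (m in 2:4) for (n in 2:4) {
    x <- rnorm(m); y <- rnorm(n, 0.5)
    expect_equal(mann_whitney_u(x, y)$p, oracle_mw_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("exact and normal-approximation p-values stay close for n >= 10", {
  set.seed(32)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8, 0.3)
    p_exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    p_approx <- stats::wilcox.test(x, y, exact = FALSE,
                                   correct = TRUE)$p.value
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("Pearson categories use half-open bands on |r|", {
  expect_equal(pearson_with_category(1:5, 2 * (1:5))$category, "very strong")
  expect_equal(pearson_with_category(1:5, 2 * (1:5))$r, 1)
  expect_equal(pearson_with_category(1:5, -(1:5))$category, "very strong")
  expect_equal(r_category(0.86), "strong")
  expect_equal(r_category(0.29999), "very weak")
  expect_equal(r_category(0.3), "weak")
  expect_equal(r_category(0.5), "moderate")
  expect_equal(r_category(0.7), "strong")
  expect_equal(r_category(0.9), "very strong")
  expect_equal(r_category(0), "very weak")
  expect_equal(r_category(1), "very strong")
  # exhaustive over a fine grid: every |r| in [0,1] gets exactly one band
  grid <- seq(0, 1, by = 0.001)
  cats <- vapply(grid, r_category, character(1))
  expect_true(all(cats %in% c("very weak", "weak", "moderate", "strong",
                              "very strong")))
  expect_error(pearson_with_category(rep(1, 5), 1:5), "constant")
})

test_that("OLS fit recovers exact lines and the hand-solved 3-point case", {
  x <- 0:4
  f <- linear_fit(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  f2 <- linear_fit(x, x)
  expect_equal(f2$slope, 1)
  expect_equal(f2$intercept, 0, tolerance = 1e-12)
  f3 <- linear_fit(c(0, 1, 2), c(0, 1, 0))
  expect_equal(f3$slope, 0, tolerance = 1e-12)
  expect_equal(f3$intercept, 1 / 3)
  expect_error(linear_fit(c(2, 2, 2), 1:3), "degenerate")
})

test_that("Bland-Altman bias and limits follow the 1.96 SD convention", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$lower, ba0$upper), c(0, 0))
  ba <- bland_altman(c(0, 0), c(-1, 1))
  expect_equal(ba$bias, 0)
  expect_equal(ba$upper, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$lower, -1.96 * sqrt(2), tolerance = 1e-12)
  # shifting therapy by c shifts the bias, not the width
  sim <- rnorm(20); ther <- sim + rnorm(20, 0, 0.3)
  b1 <- bland_altman(sim, ther)
  b2 <- bland_altman(sim, ther + 5)
  expect_equal(b2$bias, b1$bias + 5)
  expect_equal(b2$upper - b2$lower, b1$upper - b1$lower)
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("Kruskal-Wallis matches the rank formula and is rank-invariant", {
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(kw$H, oracle_kw_h(list(c(1, 2), c(3, 4), c(5, 6))))
  expect_equal(kw$H, 32 / 7)
  expect_equal(kw$df, 2)
  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$H, 0)
  # invariance under a strictly monotone transform
  g <- list(rnorm(6), rnorm(5, 1), rnorm(7, 2))
  expect_equal(kruskal_wallis(g)$H,
               kruskal_wallis(lapply(g, exp))$H)
  expect_error(kruskal_wallis(list(1:3)), "at least 2")
})

test_that("volume stratification is inclusive at the threshold", {
  s <- stratify_by_tumor_volume(c(150, 250))
  expect_equal(as.character(s), c("small", "large"))
  expect_equal(as.character(stratify_by_tumor_volume(200)), "small")
  all_large <- stratify_by_tumor_volume(c(300, 400))
  expect_equal(sum(all_large == "small"), 0)
  expect_true("small" %in% levels(all_large))  # empty stratum still reported
})

test_that("voxelwise joint histogram conserves mass and fits the right slopes", {
  g <- voxel_grid(c(10, 10, 10), c(4, 4, 4))
  set.seed(33)
  sim <- scalar_map(array(rexp(1000, 1 / 30), g$shape), g, "dose_Gy")
  mask <- sphere_mask(g, c(18, 18, 18), 16)
  ident <- voxelwise_joint(sim, sim, mask)
  expect_equal(ident$slope_ther_on_sim, 1, tolerance = 1e-9)
  expect_equal(sum(ident$counts), sum(mask))
  scaled <- scalar_map(0.63 * sim$values, g, "dose_Gy")
  vj <- voxelwise_joint(sim, scaled, mask)
  expect_equal(vj$slope_ther_on_sim, 0.63, tolerance = 1e-9)
  expect_equal(vj$slope_sim_on_ther, 1 / 0.63, tolerance = 1e-9)
  expect_error(voxelwise_joint(sim, sim, mask & FALSE), "empty")
})

test_that("Bland-Altman limits cover about 95% of normal differences", {
  set.seed(34)
  sim <- rnorm(10000)
  ther <- sim + rnorm(10000, 0.2, 1)
  ba <- bland_altman(sim, ther)
  d <- ther - sim
  coverage <- mean(d >= ba$lower & d <= ba$upper)
  expect_lt(abs(coverage - 0.95), 0.01)
})
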