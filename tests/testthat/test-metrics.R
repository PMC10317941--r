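test_that("mean absorbed dose is the arithmetic voxel mean", {
  fx <- dose_fixture(rep(40, 8))
  expect_equal(mean_absorbed_dose(fx$map, fx$mask), 40)
  fx2 <- dose_fixture(c(10, 30))
  expect_equal(mean_absorbed_dose(fx2$map, fx2$mask), 20)
  empty <- fx2$mask & FALSE
  expect_error(mean_absorbed_dose(fx2$map, empty), "empty")
})

test_that("cumulative DVH is an exact right-continuous step function", {
  fx <- dose_fixture(c(10, 30))
  dvh <- cumulative_dvh(fx$map, fx$mask)
  # F(0) = 100, F(20) = 50, F at max = fraction at max, F above max = 0
  expect_equal(volume_at_dose(fx$map, fx$mask, 0), 100)
  expect_equal(volume_at_dose(fx$map, fx$mask, 20), 50)
  expect_equal(volume_at_dose(fx$map, fx$mask, 30), 50)
  expect_equal(volume_at_dose(fx$map, fx$mask, 31), 0)
  curve <- as.data.frame(dvh, bin_Gy = 1)
  expect_equal(curve$volume_pct[curve$dose_Gy == 0], 100)
  expect_true(all(diff(curve$volume_pct) <= 0))
  # uniform dose: single step at D
  u <- dose_fixture(rep(50, 5))
  duvh <- cumulative_dvh(u$map, u$mask)
  expect_equal(duvh$dose, 50)
  expect_equal(duvh$frac_pct, 100)
})

test_that("Dx uses the sup definition on the step DVH, no interpolation", {
  fx <- dose_fixture(c(10, 30))
  expect_equal(dose_at_volume(fx$map, fx$mask, 50), 30)
  expect_equal(dose_at_volume(fx$map, fx$mask, 70), 10)
  expect_equal(dose_at_volume(fx$map, fx$mask, 100), 10)  # minimum voxel dose
  u <- dose_fixture(rep(50, 4))
  expect_equal(dose_at_volume(u$map, u$mask, 50), 50)
  expect_equal(dose_at_volume(u$map, u$mask, 95), 50)
  expect_error(dose_at_volume(fx$map, fx$mask, 0), "in \\(0, 100\\]")
  expect_error(dose_at_volume(fx$map, fx$mask, 101), "in \\(0, 100\\]")
})

test_that("Dx/Vx agree with the brute-force sorted-voxel oracle", {
  set.seed(21)
  for (i in 1:15) {
    n <- sample(5:400, 1)
    doses <- round(rexp(n, 1 / 60), sample(c(0, 1, 3), 1))  # ties likely
    fx <- dose_fixture(doses)
    for (x in c(1, 33, 50, 70, 95, 100))
      expect_identical(dose_at_volume(fx$map, fx$mask, x),
                       oracle_dx(doses, x))
    for (th in c(0, 20, 50, 90, 120, 205, max(doses)))
      expect_identical(volume_at_dose(fx$map, fx$mask, th),
                       oracle_vx(doses, th))
  }
})

test_that("MAD equals the integral of the step DVH", {
  set.seed(22)
  for (i in 1:10) {
    doses <- rexp(sample(10:200, 1), 1 / 40)
    fx <- dose_fixture(doses)
    dvh <- cumulative_dvh(fx$map, fx$mask)
    # F is constant on (u_k, u_{k+1}] with value frac_pct[k+1], and 100 on
    # [0, u_1]; integrate the step function exactly
    edges <- c(0, dvh$dose)
    f_seg <- c(100, dvh$frac_pct[-1])
    integral <- sum(f_seg * diff(edges)) / 100
    expect_equal(integral, mean(doses), tolerance = 1e-9)
  }
})

test_that("Dx and Vx are duality-consistent and permutation/scale covariant", {
  set.seed(23)
  doses <- rexp(100, 1 / 50)
  fx <- dose_fixture(doses)
  for (x in c(10, 50, 90)) {
    dx <- dose_at_volume(fx$map, fx$mask, x)
    expect_gte(volume_at_dose(fx$map, fx$mask, dx), x)
  }
  perm <- dose_fixture(sample(doses))
  expect_equal(dose_at_volume(perm$map, perm$mask, 50),
               dose_at_volume(fx$map, fx$mask, 50))
  scaled <- dose_fixture(3 * doses)
  expect_equal(dose_at_volume(scaled$map, scaled$mask, 70),
               3 * dose_at_volume(fx$map, fx$mask, 70))
})

test_that("TNR follows the specific-activity ratio and its invariances", {
  g <- voxel_grid(c(10, 1, 1), c(10, 10, 10))  # 1 ml voxels
  tl <- box_mask(g, 1:2, 1, 1)
  ntl <- box_mask(g, 3:10, 1, 1)
  # uniform specific activity -> TNR 1
  u <- scalar_map(array(5, g$shape), g, "activity_Bq")
  expect_equal(tnr(u, tl, ntl)$tnr, 1)
  # TL: 2 MBq in 2 voxels; NTL: 5 MBq in 8 voxels. At unit density the
  # masses are 2 g and 8 g equivalents: TNR = (2/2)/(5/8) = 1.6
  act <- array(0, g$shape)
  act[1:2] <- 1e6
  act[3:10] <- 5e6 / 8
  a <- scalar_map(act, g, "activity_Bq")
  res <- tnr(a, tl, ntl, density = 1)
  expect_equal(res$tnr, (2 / 2) / (5 / 8))
  expect_equal(res$A_TL, 2e6)
  expect_equal(res$M_NTL, 0.008)  # 8 ml at density 1
  # 2 MBq in 10 ml vs 5 MBq in 100 ml -> TNR = 4 (density cancels)
  gg <- voxel_grid(c(110, 1, 1), c(10, 10, 10))
  tl2 <- box_mask(gg, 1:10, 1, 1)
  ntl2 <- box_mask(gg, 11:110, 1, 1)
  act2v <- array(0, gg$shape)
  act2v[1:10] <- 2e6 / 10
  act2v[11:110] <- 5e6 / 100
  expect_equal(tnr(scalar_map(act2v, gg, "activity_Bq"), tl2, ntl2,
                   density = 1.05)$tnr, 4)
  # scale invariance
  a2 <- scalar_map(100 * act, g, "activity_Bq")
  expect_equal(tnr(a2, tl, ntl)$tnr, tnr(a, tl, ntl)$tnr)
  # empty TL activity -> ratio 0; zero NTL activity -> NA
  zero_tl <- scalar_map(array(c(0, 0, rep(1, 8)), g$shape), g, "activity_Bq")
  expect_equal(tnr(zero_tl, tl, ntl)$tnr, 0)
  zero_ntl <- scalar_map(array(c(1, 1, rep(0, 8)), g$shape), g, "activity_Bq")
  expect_true(is.na(tnr(zero_ntl, tl, ntl)$tnr))
})

test_that("metric panel covers the VOI families with the right thresholds", {
  g <- voxel_grid(c(12, 12, 12), c(10, 10, 10))
  liver <- box_mask(g, 1:12, 1:12, 1:12)
  lobe <- box_mask(g, 1:8, 1:12, 1:12)
  lesion <- box_mask(g, 2:4, 2:4, 2:4)
  vois <- derive_vois(liver, lobe, list(lesion), g)
  mk <- function(val_tl, val_rest) {
    v <- array(val_rest, g$shape)
    v[vois$masks$TL] <- val_tl
    scalar_map(v, g, "dose_Gy")
  }
  p100 <- metrics_panel(mk(100, 30), vois, A_net_GBq = 2)
  tlrow <- function(p, m) p[p$voi == "TL" & p$metric == m, ]
  expect_equal(tlrow(p100, "V120")$value, 0)
  expect_equal(tlrow(p100, "V205")$value, 0)
  expect_equal(tlrow(p100, "D95")$value, 100)
  expect_equal(tlrow(p100, "MAD")$value_norm, 50)   # 100 Gy / 2 GBq
  p210 <- metrics_panel(mk(210, 30), vois, 2)
  expect_equal(tlrow(p210, "V205")$value, 100)
  expect_setequal(p100$metric[p100$voi == "NTLt"],
                  c("MAD", "D50", "D70", "D95", "V20", "V50", "V90"))
  expect_setequal(p100$metric[p100$voi == "TL"],
                  c("MAD", "D50", "D70", "D95", "V120", "V205"))
  # Dx ordering invariant
  for (v in c("TL", "NTLt", "NTLw")) {
    d <- p100[p100$voi == v, ]
    expect_true(d$value[d$metric == "D50"] >= d$value[d$metric == "D70"])
    expect_true(d$value[d$metric == "D70"] >= d$value[d$metric == "D95"])
  }
})
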