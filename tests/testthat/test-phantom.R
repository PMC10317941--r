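test_that("phantom generation is deterministic under a fixed seed", {
  p <- small_phantom_params(seed = 5)
  a <- generate_case(p)
  b <- generate_case(p)
  expect_identical(a$sim_counts$values, b$sim_counts$values)
  expect_identical(a$ther_counts$values, b$ther_counts$values)
  expect_identical(a$masks$liver, b$masks$liver)
  # a different seed changes the counts
  c2 <- generate_case(small_phantom_params(seed = 6))
  expect_false(identical(a$sim_counts$values, c2$sim_counts$values))
})

test_that("noiseless phantom gives identical arms and exact TNR recovery", {
  cs <- generate_case(noiseless_params(seed = 9))
  expect_identical(cs$sim_counts$values, cs$ther_counts$values)
  res <- run_case(cs)
  r <- res$record
  sim <- r[r$arm == "sim", ]
  ther <- r[r$arm == "ther", ]
  expect_equal(sim$value, ther$value, tolerance = 1e-12)
  tnr_ther <- res$tnr$tnr_ntlt[res$tnr$arm == "ther"]
  expect_equal(tnr_ther, cs$ground_truth$params$tnr_true, tolerance = 1e-12)
  # pipeline metrics equal the ground-truth panel
  gt <- ground_truth_metrics(cs)
  merged <- merge(sim, gt$panel, by = c("voi", "metric"))
  expect_equal(merged$value.x, merged$value.y, tolerance = 1e-9)
})

test_that("expected-count mode conserves the count budget", {
  cs <- generate_case(small_phantom_params(poisson = FALSE, seed = 2))
  expect_equal(sum(cs$ther_counts$values), 3e6, tolerance = 1e-6)
  expect_equal(sum(cs$sim_counts$values), 3e6, tolerance = 1e-6)
})

test_that("tumour bias raises the TL dose difference monotonically", {
  reldiff_at <- function(b) {
    cs <- generate_case(small_phantom_params(bias_T = b, tau_n = 0, tau_t = 0,
                                             sigma_n = 0, sigma_t = 0,
                                             poisson = FALSE, seed = 3))
    r <- run_case(cs)$record
    s <- r[r$arm == "sim" & r$voi == "TL" & r$metric == "MAD", "value_norm"]
    t <- r[r$arm == "ther" & r$voi == "TL" & r$metric == "MAD", "value_norm"]
    relative_difference_pct(s, t)
  }
  d <- vapply(c(1, 1.15, 1.26, 1.4), reldiff_at, numeric(1))
  expect_true(all(diff(d) > 0))
  # in deterministic expected-count mode the bias is reproduced exactly
  expect_equal(d[1], 0, tolerance = 1e-9)
  expect_equal(d[3], 26, tolerance = 0.5)
})

test_that("stronger voxel discordance lowers the voxelwise correlation", {
  r_at <- function(tau) {
    cs <- generate_case(small_phantom_params(tau_n = tau, tau_t = tau,
                                             psf_fwhm_mm = 0, seed = 13))
    res <- run_case(cs, keep_maps = TRUE)
    cor(res$maps$sim_dose$values[res$vois$masks$liver],
        res$maps$ther_dose$values[res$vois$masks$liver])
  }
  rs <- vapply(c(0, 0.3, 0.8), r_at, numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("PSF blur pulls small-tumour dose below ground truth (spill-out)", {
  p <- small_phantom_params(tumors = list(list(center = c(40, 10, 0),
                                               radius_mm = 18)),
                            psf_fwhm_mm = 12, poisson = FALSE,
                            sigma_n = 0, sigma_t = 0, tau_n = 0, tau_t = 0,
                            seed = 4)
  cs <- generate_case(p)
  res <- run_case(cs)
  gt <- ground_truth_metrics(cs)
  mad_pipe <- res$record[res$record$arm == "ther" & res$record$voi == "TL" &
                           res$record$metric == "MAD", "value"]
  mad_true <- gt$panel[gt$panel$voi == "TL" & gt$panel$metric == "MAD",
                       "value"]
  expect_lt(mad_pipe, mad_true)
})

test_that("high-count therapy TNR estimates recover the truth", {
  ests <- vapply(1:8, function(s) {
    cs <- generate_case(small_phantom_params(psf_fwhm_mm = 0,
                                             count_scale = 1e7,
                                             tau_n = 0, tau_t = 0,
                                             seed = 100 + s))
    res <- run_case(cs)
    res$tnr$tnr_ntlt[res$tnr$arm == "ther"] /
      cs$ground_truth$tnr_ntlt
  }, numeric(1))
  # ratio of estimate to realized truth: mean within 3 MC SEs of 1
  se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 1), 3 * pmax(se, 1e-4))
})

test_that("tumours outside the liver are rejected", {
  expect_error(generate_case(small_phantom_params(
    tumors = list(list(center = c(95, 0, 0), radius_mm = 30)))),
    "outside the liver")
})

test_that("cohort generation is seeded, strata-spanning and validated", {
  expect_error(generate_cohort(0), ">= 1")
  a <- generate_cohort(3, seed = 77, base_params = small_phantom_params())
  b <- generate_cohort(3, seed = 77, base_params = small_phantom_params())
  expect_identical(lapply(a, function(x) x$sim_counts$values),
                   lapply(b, function(x) x$sim_counts$values))
  # default distributions populate both tumoral-volume strata
  big <- generate_cohort(30, seed = 19, base_params = small_phantom_params())
  vols <- vapply(big, function(cs) {
    tl <- Reduce(`|`, cs$masks$lesions)
    voi_volume_ml(tl, cs$sim_counts$grid)
  }, numeric(1))
  strat <- stratify_by_tumor_volume(vols)
  expect_gt(sum(strat == "small"), 0)
  expect_gt(sum(strat == "large"), 0)
})
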