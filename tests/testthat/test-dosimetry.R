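mk_dose <- function(vals, spacing = 4.42)
  voxel_grid(vals, spacing, unit = "Gy")
mk_mask <- function(vals, spacing = 4.42)
  voxel_grid(vals, spacing, unit = "mask")

test_that("mean dose matches a summed-loop oracle", {
  set.seed(3)
  d <- array(runif(8^3, 0, 120), rep(8, 3))
  m <- array(as.numeric(runif(8^3) > 0.6), rep(8, 3))
  got <- mean_dose(mk_dose(d), mk_mask(m))
  acc <- 0; n <- 0
  for (i in seq_along(d)) if (m[i] != 0) { acc <- acc + d[i]; n <- n + 1 }
  expect_equal(got, acc / n, tolerance = 1e-12)
  # half at 10 Gy, half at 30 Gy
  h <- array(c(10, 30), c(2, 1, 1))
  expect_equal(mean_dose(mk_dose(h), mk_mask(array(1, c(2, 1, 1)))), 20)
  expect_error(mean_dose(mk_dose(d), mk_mask(array(0, rep(8, 3)))),
               "empty mask")
})

test_that("V_x is the fraction at or above threshold, non-increasing", {
  d <- array(c(100, 100, 10, 10), c(4, 1, 1))
  m <- array(1, c(4, 1, 1))
  expect_equal(v_at_dose(mk_dose(d), mk_mask(m), 70), 50)
  expect_equal(v_at_dose(mk_dose(d), mk_mask(m), 0), 100)
  expect_equal(v_at_dose(mk_dose(d), mk_mask(m), 200), 0)
  set.seed(4)
  dr <- mk_dose(array(runif(6^3, 0, 250), rep(6, 3)))
  mr <- mk_mask(array(1, rep(6, 3)))
  vx <- vapply(seq(0, 250, by = 10),
               function(t) v_at_dose(dr, mr, t), numeric(1))
  expect_true(all(diff(vx) <= 0))
})

test_that("DVH bins are half-open, normalized and consistent with V_x", {
  # uniform 5.5 Gy: all volume in bin [5, 6)
  u <- mk_dose(array(5.5, rep(4, 3)))
  m <- mk_mask(array(1, rep(4, 3)))
  h <- dvh(u, m)
  expect_equal(length(h$differential_pct), 6)
  expect_equal(h$differential_pct[6], 100)
  expect_equal(h$cumulative_pct[1:6], c(100, 100, 100, 100, 100, 100))
  # a voxel exactly at a bin edge goes to the upper bin
  e <- dvh(mk_dose(array(3, c(1, 1, 1))), mk_mask(array(1, c(1, 1, 1))))
  expect_equal(e$differential_pct[4], 100)   # bin [3, 4)

  set.seed(5)
  d <- mk_dose(array(runif(8^3, 0, 130), rep(8, 3)))
  mm <- mk_mask(array(as.numeric(runif(8^3) > 0.4), rep(8, 3)))
  h2 <- dvh(d, mm)
  expect_equal(sum(h2$differential_pct), 100, tolerance = 1e-9)
  expect_true(all(diff(h2$cumulative_pct) <= 0))
  expect_equal(h2$cumulative_pct[1], 100)
  # cumulative at 70 Gy is exactly V_70Gy
  expect_equal(h2$cumulative_pct[71], v_at_dose(d, mm, 70),
               tolerance = 1e-12)
  expect_equal(h2$cumulative_pct,
               rev(cumsum(rev(h2$differential_pct))), tolerance = 1e-12)
})

test_that("DVH MAE reproduces hand-computed values and metric properties", {
  spike <- function(at, n) { v <- rep(0, n); v[at + 1] <- 100; v }
  ref <- dvh_from_differential(spike(10, 20))
  test <- dvh_from_differential(spike(11, 20))
  # spike shifted one bin: |100| + |100| over D_max = 20 bins
  expect_equal(mae_dvh(test, ref), 10)
  expect_equal(mae_dvh(ref, ref), 0)
  # symmetric on shared D_max
  expect_equal(mae_dvh(test, ref), mae_dvh(ref, test, d_max = 20))
  # triangle inequality on a shared D_max
  set.seed(6)
  rnd <- function() { v <- runif(20); dvh_from_differential(100 * v / sum(v)) }
  x <- rnd(); y <- rnd(); z <- rnd()
  expect_lte(mae_dvh(x, z), mae_dvh(x, y) + mae_dvh(y, z) + 1e-12)
  # shorter DVH is zero-padded
  short <- dvh_from_differential(spike(5, 10))
  long <- dvh_from_differential(spike(15, 20))
  expect_equal(mae_dvh(short, long), 10)
  expect_error(dvh_from_differential(c(50, 20)), "sum to 100")
})

test_that("percent difference is the absolute relative deviation", {
  expect_equal(percent_difference(103, 100), 3)
  expect_equal(percent_difference(100, 100), 0)
  expect_equal(percent_difference(27.80, 100), 72.20)
  expect_error(percent_difference(1, 0), "positive")
})

test_that("paired Wilcoxon with Bonferroni matches the exact null", {
  a <- 1:20 + 0.5
  shift <- seq(0.3, 2.2, by = 0.1)            # distinct, all positive
  res <- paired_wilcoxon_bonferroni(a + shift, a, n_comparisons = 1)
  # all 20 differences positive with distinct magnitudes: the signed-rank
  # statistic is at its maximum and the exact two-sided p is 2 / 2^20
  expect_equal(res$p_raw, 2 / 2^20, tolerance = 1e-12)
  expect_lt(res$p_adjusted, 1e-4)
  expect_true(res$significant)
  # Bonferroni multiplies and caps at 1
  res7 <- paired_wilcoxon_bonferroni(a + shift, a, n_comparisons = 7)
  expect_equal(res7$p_adjusted, min(1, res$p_raw * 7), tolerance = 1e-12)
  big <- paired_wilcoxon_bonferroni(a + shift, a, n_comparisons = 1e6)
  expect_equal(big$p_adjusted, 1)
  # identical samples: undefined test reported as p = 1 with a warning
  expect_warning(same <- paired_wilcoxon_bonferroni(a, a), "zero")
  expect_equal(same$p_adjusted, 1)
  expect_false(same$significant)
  expect_error(paired_wilcoxon_bonferroni(1:3, 1:3), "at least 5")
})

test_that("Bland-Altman limits follow mean +/- 1.96 SD of percent differences", {
  ref <- c(2, 4, 6, 8)
  same <- bland_altman(ref, ref)
  expect_equal(same$mean_diff_pct, 0)
  expect_equal(same$limits_pct, c(0, 0))
  # +1% and -1%: mean 0, sample SD sqrt(2)
  ba <- bland_altman(c(1.01, 0.99) * c(5, 5), c(5, 5))
  expect_equal(ba$mean_diff_pct, 0, tolerance = 1e-12)
  expect_equal(ba$sd_diff_pct, sqrt(2), tolerance = 1e-9)
  expect_equal(length(ba$diff_pct), 2)
  expect_error(bland_altman(c(1, 2), c(1, 0)), "zero reference")
})

test_that("dose report aggregates the standard dosimetrics", {
  case <- make_phantom(phantom_config(lsf_pct = 10, tnr = 5))
  kl <- cached_kernel(1.06, 4.42, 2)
  ku <- cached_kernel(0.26, 4.42, 10)
  d <- compute_dose_map(case, "LiCKLuKD", kl, ku)
  rep <- dose_report(d, case$masks)
  expect_named(rep$mean_gy, c("nl", "tumors", "lungs"))
  expect_equal(rep$vx_pct[["lungs_5gy"]],
               v_at_dose(d, case$masks$lungs, 5))
  expect_equal(rep$mean_gy[["tumors"]], mean_dose(d, case$masks$tumors))
  expect_gt(rep$mean_gy[["tumors"]], rep$mean_gy[["nl"]])
  expect_gt(rep$mean_gy[["nl"]], rep$mean_gy[["lungs"]])
})
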