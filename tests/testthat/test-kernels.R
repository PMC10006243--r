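eps <- y90_constants()$eps_j_per_gbqh

test_that("decay constants are internally consistent", {
  dc <- y90_constants()
  expect_equal(dc$lambda_per_h * dc$t_half_h, log(2), tolerance = 1e-15)
  expect_equal(dc$eps_j_per_gbqh * dc$tia_h_per_gbq, dc$e_total_j_per_gbq,
               tolerance = 1e-15)
})

test_that("LED kernel is the exact local-deposition limit", {
  k <- build_led_kernel(1.06, 4.42)
  mass <- 1.06 * 4.42^3 * 1e-6                   # 9.153e-5 kg
  expect_equal(mass, 9.153194e-5, tolerance = 1e-6)
  expect_equal(k$values[1, 1, 1], eps / mass, tolerance = 1e-14)
  expect_equal(k$values[1, 1, 1], 5873.5, tolerance = 1e-4)
  expect_equal(capture_fraction(k), 1, tolerance = 1e-14)
  # dose per TIA is inversely proportional to voxel mass
  k2 <- build_led_kernel(2.12, 4.42)
  expect_equal(k2$values[1, 1, 1], k$values[1, 1, 1] / 2,
               tolerance = 1e-14)
  expect_error(build_led_kernel(0, 4.42), "positive")
})

test_that("generated kernels capture their energy and are symmetric", {
  kl <- cached_kernel(1.06, 4.8, 2)
  ku <- cached_kernel(0.26, 4.8, 10)
  expect_gte(kl$capture_fraction, 0.99)
  expect_gte(ku$capture_fraction, 0.99)
  expect_lte(kl$capture_fraction, 1)
  expect_lte(ku$capture_fraction, 1)
  # energy accounting: sum(K) * M == capture * eps by construction
  for (k in list(kl, ku)) {
    mass <- k$medium_density * prod(k$spacing) * 1e-6
    expect_equal(sum(k$values) * mass, k$capture_fraction * eps,
                 tolerance = 1e-10)
  }
  # exact point symmetry (indeed full octant symmetry)
  expect_identical(kl$values, kl$values[5:1, 5:1, 5:1])
  expect_identical(ku$values, ku$values[21:1, 21:1, 21:1])
  # kernel values decrease away from the center along an axis
  expect_true(all(diff(kl$values[3:5, 3, 3]) < 0))
})

test_that("capture fraction grows with support and medium density", {
  caps <- vapply(1:3, function(h) cached_kernel(1.06, 4.42, h)$capture_fraction,
                 numeric(1))
  expect_true(all(diff(caps) > 0))
  # denser medium, shorter beta range, more energy inside a fixed support
  expect_gt(cached_kernel(1.06, 4.42, 1)$capture_fraction,
            generate_vsv_kernel(0.5, 4.42, 1)$capture_fraction)
  # truncating an extended kernel to its center voxel: the self-dose share
  k <- cached_kernel(1.06, 4.42, 2)
  ctr_only <- dose_kernel(k$values[3, 3, 3, drop = FALSE] * array(1, c(1, 1, 1)),
                          k$spacing, k$medium_density)
  self_share <- capture_fraction(ctr_only)
  expect_lt(self_share, 1)
  expect_equal(self_share,
               k$values[3, 3, 3] * 1.06 * 4.42^3 * 1e-6 / eps,
               tolerance = 1e-12)
})

test_that("half_size 0 degenerates to the all-energy-local kernel", {
  k0 <- generate_vsv_kernel(1.06, 4.8, 0)
  led <- build_led_kernel(1.06, 4.8)
  expect_equal(k0$values, led$values, tolerance = 1e-14)
  expect_equal(k0$capture_fraction, 1)
})

test_that("kernels obey the density scaling law", {
  # K_rho at spacing h equals (rho/rho_w)^2 K_water at spacing h*rho/rho_w
  beta <- 0.26
  ku <- cached_kernel(0.26, 4.8, 10)
  kw <- generate_vsv_kernel(1.00, 4.8 * beta, 10)
  rel <- max(abs(ku$values - beta^2 * kw$values)) / max(ku$values)
  expect_lt(rel, 0.01)
})

test_that("kernel save/load round trip is lossless and validated", {
  k <- cached_kernel(1.06, 4.8, 2)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  save_kernel(k, f)
  k2 <- load_kernel(f)
  expect_identical(k2$values, k$values)
  expect_equal(k2$medium_density, k$medium_density)
  expect_equal(k2$capture_fraction, k$capture_fraction, tolerance = 1e-9)

  # sidecar with a missing field is rejected, naming the field
  meta <- jsonlite::read_json(paste0(f, ".json"))
  meta$medium_density <- NULL
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  file.copy(f, f2)
  jsonlite::write_json(meta, paste0(f2, ".json"), auto_unbox = TRUE)
  expect_error(load_kernel(f2), "medium_density")
  # missing sidecar altogether
  f3 <- withr::local_tempfile(fileext = ".nii.gz")
  file.copy(f, f3)
  expect_error(load_kernel(f3), "sidecar")

  # an imported kernel summing to more than the released energy is rejected
  inflated <- k
  inflated$values <- k$values * (1.02 / k$capture_fraction)
  f4 <- withr::local_tempfile(fileext = ".nii.gz")
  save_map(voxel_grid(inflated$values, k$spacing, unit = "S"), f4)
  jsonlite::write_json(list(medium_density = 1.06, spacing_mm = k$spacing,
                            units = "Gy/(GBq.h)"),
                       paste0(f4, ".json"), auto_unbox = TRUE, digits = NA)
  expect_error(load_kernel(f4), "over-conserves")

  # asymmetric (stochastic-looking) kernels are flagged, not rejected;
  # scaled down so the perturbed kernel still conserves < 100% of energy
  noisy <- k$values * 0.9
  noisy[1, 1, 1] <- noisy[1, 1, 1] + 0.1 * max(noisy)
  f5 <- withr::local_tempfile(fileext = ".nii.gz")
  save_map(voxel_grid(noisy, k$spacing, unit = "S"), f5)
  jsonlite::write_json(list(medium_density = 1.06, spacing_mm = k$spacing,
                            units = "Gy/(GBq.h)", generator = "mc"),
                       paste0(f5, ".json"), auto_unbox = TRUE, digits = NA)
  expect_warning(k5 <- load_kernel(f5), "asymmetric")
  expect_s3_class(k5, "dose_kernel")
})

test_that("kernel constructor rejects malformed kernels", {
  expect_error(dose_kernel(array(1, c(4, 5, 5)), 4.8, 1.06), "odd")
  expect_error(dose_kernel(array(-1, c(3, 3, 3)), 4.8, 1.06),
               "non-negative")
  expect_error(generate_vsv_kernel(-1, 4.8, 2), "positive")
})
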