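# Shared fixtures: kernels are cached per session since generation is the
# only expensive step, and several tests reuse the same media/support.

.fixture_env <- new.env(parent = emptyenv())

cached_kernel <- function(density, spacing, half_size) {
  key <- paste0("k_", density, "_", spacing, "_", half_size)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_vsv_kernel(density, spacing, half_size)
  .fixture_env[[key]]
}

# Compact phantom fully embedded in soft tissue with every kernel support
# inside the field of view: used for exact energy-bookkeeping checks.
compact_phantom_config <- function(...) {
  phantom_config(
    shape = c(64L, 64L, 64L), spacing = 4.42,
    liver_center = c(141, 120, 80), liver_semiaxes = c(45, 40, 35),
    lung_centers = list(c(100, 141, 160), c(183, 141, 160)),
    lung_semiaxes = c(28, 30, 32),
    tumors = list(list(center = c(150, 120, 80), radius_mm = 15,
                       uptake = 1)),
    torso_semiaxes = NULL, background_density = 1.00,
    ...)
}

# A small all-uniform case: constant density, activity confined to a box
# "liver"; a single far-corner voxel serves as the (activity-free) lungs
# mask that the case container requires.
uniform_box_case <- function(n = 12L, spacing = 4.42, density = 1.06,
                             activity_total = 1, liver_all = FALSE) {
  sh <- rep(n, 3L)
  li <- array(0, sh)
  if (liver_all) li[] <- 1 else li[4:(n - 3), 4:(n - 3), 4:(n - 3)] <- 1
  li[1, 1, 1] <- 0
  lu <- array(0, sh); lu[1, 1, 1] <- 1
  masks <- derive_masks(voxel_grid(li, spacing, unit = "mask"),
                        voxel_grid(lu, spacing, unit = "mask"))
  act <- array(0, sh)
  act[masks$liver$values != 0] <- activity_total / sum(masks$liver$values)
  patient_case(voxel_grid(act, spacing, unit = "GBq"),
               voxel_grid(array(density, sh), spacing, unit = "g/cm3"),
               masks, ia_maa_gbq = activity_total)
}

# Independent brute-force linear convolution oracle: per-target triple
# loop over kernel offsets, no shared code with the package backends.
naive_conv3 <- function(a, k) {
  da <- dim(a); dk <- dim(k); half <- (dk - 1L) %/% 2L
  out <- array(0, da)
  for (z in seq_len(da[3])) for (y in seq_len(da[2])) for (x in seq_len(da[1])) {
    acc <- 0
    for (p in seq_len(dk[3])) for (n in seq_len(dk[2])) for (m in seq_len(dk[1])) {
      sx <- x - (m - half[1] - 1L); sy <- y - (n - half[2] - 1L)
      sz <- z - (p - half[3] - 1L)
      if (sx >= 1 && sx <= da[1] && sy >= 1 && sy <= da[2] &&
          sz >= 1 && sz <= da[3])
        acc <- acc + a[sx, sy, sz] * k[m, n, p]
    }
    out[x, y, z] <- acc
  }
  out
}

random_kernel <- function(n, spacing = 4.42) {
  vals <- array(stats::runif(n^3), rep(n, 3L))
  eps <- y90_constants()$eps_j_per_gbqh
  # scale so total energy is below the released energy (valid kernel)
  mass <- 1.06 * spacing^3 * 1e-6
  vals <- vals * (0.5 * eps / (sum(vals) * mass))
  dose_kernel(vals, spacing, 1.06)
}
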