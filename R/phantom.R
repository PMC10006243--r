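#' Digital phantom configuration
#'
#' Parameters of the synthetic SPECT/CT-like digital phantom: a torso of
#' soft tissue containing an ellipsoidal liver with embedded spherical
#' tumors and two ellipsoidal lungs of heterogeneous low density,
#' surrounded by air. Activity is distributed by compartment so that the
#' configured lung shunt fraction (LSF) and tumor-to-normal-liver ratio
#' (TNR) are recovered exactly by [compute_lsf()] and [compute_tnr()] on
#' the noiseless phantom.
#'
#' The default geometry (4.42 mm isotropic voxels, 64 x 64 x 72 grid)
#' yields a normal-liver volume of ~1040 mL and a lung volume of ~2070 mL,
#' inside the ranges spanned by clinical Y-90 radioembolization cohorts
#' (NL roughly 480-1900 mL, lungs roughly 1960-3550 mL). Default LSF 5%
#' and TNR 4 sit near the middle of clinically reported ranges
#' (LSF 1.5-21.2%, TNR 1.2-38.9); the default injected MAA activity is
#' 0.111 GBq.
#'
#' @param shape Grid dimensions (voxels).
#' @param spacing Voxel spacing in mm (scalar or length 3); 4.42 and 4.8
#'   are typical SPECT reconstruction voxel sizes.
#' @param liver_center,liver_semiaxes Liver ellipsoid center and semi-axes
#'   in mm (world coordinates).
#' @param lung_centers List of two lung ellipsoid centers (mm).
#' @param lung_semiaxes Lung ellipsoid semi-axes (mm), shared by both.
#' @param lung_density_mean Mean lung density, g/cm^3.
#' @param lung_density_sd Per-voxel Gaussian density jitter SD, g/cm^3.
#' @param tumors List of tumors, each `list(center = mm, radius_mm = r,
#'   uptake = multiplier)`; `uptake` scales that tumor's concentration
#'   relative to the TNR-determined tumor concentration.
#' @param torso_center,torso_semiaxes Torso ellipsoid (mm); soft tissue of
#'   `background_density` inside, air outside. `torso_semiaxes = NULL`
#'   fills the whole grid with soft tissue.
#' @param background_density Soft-tissue density inside the torso, g/cm^3.
#' @param lsf_pct Target lung shunt fraction, percent, in [0, 100).
#' @param tnr Target tumor-to-normal-liver activity concentration ratio
#'   (> 0).
#' @param ia_maa_gbq Injected Tc-99m-MAA activity, GBq.
#' @param blur_fwhm_mm SPECT-like Gaussian blur FWHM (0 = none).
#' @param noise Logical; apply Poisson noise on the counts scale.
#' @param total_counts Total SPECT counts used for the Poisson noise scale.
#' @param seed Integer seed for density jitter and noise.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(64L, 64L, 72L),
                           spacing = 4.42,
                           liver_center = c(150, 130, 85),
                           liver_semiaxes = c(80, 60, 55),
                           lung_centers = list(c(82, 140, 220),
                                               c(201, 140, 220)),
                           lung_semiaxes = c(52, 63, 76),
                           lung_density_mean = 0.26,
                           lung_density_sd = 0.05,
                           tumors = list(list(center = c(165, 140, 95),
                                              radius_mm = 25,
                                              uptake = 1)),
                           torso_center = c(141.5, 141.5, 159),
                           torso_semiaxes = c(139, 139, 159),
                           background_density = 1.00,
                           lsf_pct = 5, tnr = 4,
                           ia_maa_gbq = 0.111,
                           blur_fwhm_mm = 0, noise = FALSE,
                           total_counts = 5e6,
                           seed = 20230310L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (lsf_pct < 0 || lsf_pct >= 100) stop("LSF must be in [0, 100)")
  if (tnr <= 0) stop("TNR must be > 0")
  for (tm in tumors) {
    u <- (tm$center - liver_center) / liver_semiaxes
    if (sqrt(sum(u^2)) + tm$radius_mm / min(liver_semiaxes) > 1)
      stop("tumor at (", paste(tm$center, collapse = ", "),
           ") is not fully inside the liver ellipsoid")
  }
  structure(list(shape = as.integer(shape), spacing = spacing,
                 liver_center = liver_center,
                 liver_semiaxes = liver_semiaxes,
                 lung_centers = lung_centers, lung_semiaxes = lung_semiaxes,
                 lung_density_mean = lung_density_mean,
                 lung_density_sd = lung_density_sd,
                 tumors = tumors, torso_center = torso_center,
                 torso_semiaxes = torso_semiaxes,
                 background_density = background_density,
                 lsf_pct = lsf_pct, tnr = tnr, ia_maa_gbq = ia_maa_gbq,
                 blur_fwhm_mm = blur_fwhm_mm, noise = noise,
                 total_counts = total_counts, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Bundle maps and masks into a patient case
#'
#' @param activity Activity `voxel_grid` (GBq).
#' @param density Density `voxel_grid` (g/cm^3).
#' @param masks A `voi_masks` set aligned with the maps.
#' @param ia_maa_gbq Injected MAA activity in GBq.
#' @param truth Optional list of ground-truth values (phantoms only).
#' @return A `patient_case`.
#' @export
patient_case <- function(activity, density, masks, ia_maa_gbq,
                         truth = NULL) {
  stopifnot(inherits(activity, "voxel_grid"), activity$unit == "GBq",
            inherits(density, "voxel_grid"), density$unit == "g/cm3",
            inherits(masks, "voi_masks"))
  .assert_aligned(activity, density, "activity and density maps")
  .assert_aligned(activity, masks$liver, "activity map and masks")
  structure(list(activity = activity, density = density, masks = masks,
                 ia_maa_gbq = ia_maa_gbq, truth = truth),
            class = "patient_case")
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("<patient_case> IA_MAA %.4g GBq, total activity %.6g GBq\n",
              x$ia_maa_gbq, sum(x$activity$values)))
  print(x$masks)
  invisible(x)
}

# Ellipsoid / sphere occupancy on the voxel-center lattice
.ellipsoid_mask <- function(shape, spacing, center, semiaxes) {
  cx <- (seq_len(shape[1]) - 0.5) * spacing[1]
  cy <- (seq_len(shape[2]) - 0.5) * spacing[2]
  cz <- (seq_len(shape[3]) - 0.5) * spacing[3]
  dx2 <- ((cx - center[1]) / semiaxes[1])^2
  dy2 <- ((cy - center[2]) / semiaxes[2])^2
  dz2 <- ((cz - center[3]) / semiaxes[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

#' Generate a synthetic patient case from a phantom configuration
#'
#' Builds masks, the density map and the activity map. Activity is
#' assigned per compartment: the lungs receive `IA * LSF/100` at uniform
#' concentration and the remainder is split between tumors and normal
#' liver so that the activity-concentration ratio equals the configured
#' TNR (both at nominal density 1.06 g/cm^3, so the per-voxel activity
#' ratio is also TNR). Optional SPECT-like blur and Poisson noise are then
#' applied via [degrade_spect()].
#'
#' @param cfg A [phantom_config()].
#' @return A `patient_case`; `$truth` holds the configured LSF, TNR,
#'   volumes and seed.
#' @examples
#' case <- make_phantom(phantom_config(lsf_pct = 10, tnr = 5))
#' compute_lsf(case)  # 10
#' @export
make_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  sh <- cfg$shape; sp <- cfg$spacing
  li <- .ellipsoid_mask(sh, sp, cfg$liver_center, cfg$liver_semiaxes)
  lu <- .ellipsoid_mask(sh, sp, cfg$lung_centers[[1]], cfg$lung_semiaxes) |
        .ellipsoid_mask(sh, sp, cfg$lung_centers[[2]], cfg$lung_semiaxes)
  tu <- array(FALSE, sh)
  tumor_of <- array(0L, sh)
  for (ti in seq_along(cfg$tumors)) {
    tm <- cfg$tumors[[ti]]
    m <- .ellipsoid_mask(sh, sp, tm$center, rep(tm$radius_mm, 3))
    tu <- tu | m
    tumor_of[m] <- ti
  }
  as_mask <- function(x) voxel_grid(array(as.numeric(x), sh), sp, unit = "mask")
  masks <- derive_masks(as_mask(li), as_mask(lu), as_mask(tu))

  # density: air outside torso, soft tissue inside, organs override
  dens <- array(RHO_AIR, sh)
  if (!is.null(cfg$torso_semiaxes)) {
    torso <- .ellipsoid_mask(sh, sp, cfg$torso_center, cfg$torso_semiaxes)
    dens[torso] <- cfg$background_density
  } else dens[] <- cfg$background_density
  dens[masks$liver$values != 0] <- RHO_LIVER
  lung_idx <- which(masks$lungs$values != 0)
  jitter <- .with_seed(cfg$seed, stats::rnorm(length(lung_idx), 0,
                                              cfg$lung_density_sd))
  dens[lung_idx] <- pmax(cfg$lung_density_mean + jitter, RHO_FLOOR)

  # compartment activity assignment
  act <- array(0, sh)
  ia <- cfg$ia_maa_gbq
  a_lungs <- ia * cfg$lsf_pct / 100
  n_lung <- length(lung_idx)
  if (n_lung > 0 && a_lungs > 0) act[lung_idx] <- a_lungs / n_lung
  nl_idx <- which(masks$nl$values != 0)
  tu_idx <- which(masks$tumors$values != 0)
  uptake <- vapply(cfg$tumors, function(t) t$uptake %||% 1, numeric(1))
  w_tu <- if (length(tu_idx)) cfg$tnr * uptake[tumor_of[tu_idx]] else numeric(0)
  a_liver <- ia - a_lungs
  a_per_nl <- a_liver / (length(nl_idx) + sum(w_tu))
  act[nl_idx] <- a_per_nl
  if (length(tu_idx)) act[tu_idx] <- a_per_nl * w_tu

  case <- patient_case(
    voxel_grid(act, sp, unit = "GBq"),
    voxel_grid(dens, sp, unit = "g/cm3"),
    masks, ia,
    truth = list(lsf_pct = cfg$lsf_pct, tnr = cfg$tnr,
                 volumes_ml = mask_volumes_ml(masks), seed = cfg$seed))
  if (cfg$blur_fwhm_mm > 0 || cfg$noise)
    case <- degrade_spect(case, cfg$blur_fwhm_mm, cfg$noise,
                          seed = cfg$seed, total_counts = cfg$total_counts)
  case
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr with a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Apply SPECT-like degradation to a patient case
#'
#' Gaussian blur of the activity map (reflective boundaries, so total
#' activity is conserved) followed by optional Poisson noise applied on a
#' counts scale and recalibrated so the total activity equals the
#' original injected activity. The density map and masks are untouched:
#' CT resolution is much finer than SPECT.
#'
#' @param case A `patient_case`.
#' @param fwhm_mm Gaussian blur FWHM in mm (0 = no blur).
#' @param noise Logical; apply Poisson noise.
#' @param seed Integer seed making the noise reproducible.
#' @param total_counts Counts scale for the Poisson stage.
#' @return A degraded `patient_case`.
#' @export
degrade_spect <- function(case, fwhm_mm, noise = FALSE, seed = 1L,
                          total_counts = 5e6) {
  stopifnot(inherits(case, "patient_case"))
  if (fwhm_mm < 0) stop("blur FWHM must be >= 0")
  act <- case$activity$values
  if (fwhm_mm > 0)
    act <- .gaussian_blur3d(act, fwhm_mm / 2.354820045,
                            case$activity$spacing)
  if (noise) {
    total <- sum(act)
    if (total <= 0) stop("cannot apply noise to an all-zero activity map")
    k <- total_counts / total
    counts <- .with_seed(seed, stats::rpois(length(act), act * k))
    act <- array(counts / k, dim(act))
    if (sum(act) > 0) act <- act * (total / sum(act))
  }
  out <- case
  out$activity <- voxel_grid(act, case$activity$spacing,
                             case$activity$origin, unit = "GBq")
  out
}

# Separable Gaussian blur with reflective (half-sample) boundary handling;
# each 1D operator has unit column sums, so mass is conserved exactly.
.gaussian_blur3d <- function(vals, sigma_mm, spacing) {
  d <- dim(vals)
  for (ax in 1:3) {
    sig <- sigma_mm / spacing[ax]
    if (sig <= 0) next
    w <- max(1L, ceiling(4 * sig))
    g <- stats::dnorm(seq(-w, w), sd = sig)
    g <- g / sum(g)
    n <- d[ax]
    b <- matrix(0, n, n)
    for (j in seq_len(n)) {
      i_ext <- j + seq(-w, w)
      i_fold <- ifelse(i_ext < 1L, 1L - i_ext,
                       ifelse(i_ext > n, 2L * n + 1L - i_ext, i_ext))
      # guard against pathological n < w: clamp after one reflection
      i_fold <- pmin(pmax(i_fold, 1L), n)
      for (t in seq_along(i_ext)) b[i_fold[t], j] <- b[i_fold[t], j] + g[t]
    }
    perm <- c(ax, setdiff(1:3, ax))
    v <- aperm(vals, perm)
    dv <- dim(v)
    v <- b %*% matrix(v, nrow = dv[1])
    dim(v) <- dv
    vals <- aperm(v, order(perm))
  }
  vals
}

#' Point-source test case on a uniform grid
#'
#' All activity in the central voxel of an odd-sized uniform-density grid;
#' the standard fixture for kernel and convolution checks (a convolution
#' of this case reproduces the kernel itself).
#'
#' @param shape Odd grid dimensions.
#' @param spacing Voxel spacing in mm.
#' @param density Uniform density, g/cm^3.
#' @param activity_gbq Activity placed in the center voxel.
#' @return A `patient_case` whose liver mask is the center voxel and whose
#'   lungs mask is the 6-neighborhood (masks are needed by downstream
#'   code; they carry no anatomical meaning here).
#' @export
make_delta_case <- function(shape, spacing, density, activity_gbq) {
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  if (any(shape %% 2L == 0L))
    stop("delta case requires odd grid dimensions so a center voxel exists")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  ctr <- (shape + 1L) %/% 2L
  act <- array(0, shape)
  act[ctr[1], ctr[2], ctr[3]] <- activity_gbq
  li <- array(0, shape); li[ctr[1], ctr[2], ctr[3]] <- 1
  lu <- array(0, shape)
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1)))
    lu[ctr[1] + off[1], ctr[2] + off[2], ctr[3] + off[3]] <- 1
  masks <- derive_masks(voxel_grid(li, spacing, unit = "mask"),
                        voxel_grid(lu, spacing, unit = "mask"))
  patient_case(voxel_grid(act, spacing, unit = "GBq"),
               voxel_grid(array(density, shape), spacing, unit = "g/cm3"),
               masks, ia_maa_gbq = max(activity_gbq, 1e-12))
}
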