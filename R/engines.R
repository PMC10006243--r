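#' Calibrate a counts map to absolute activity
#'
#' Applies the self-calibration factor
#' (total injected activity) / (total counts over the field of view) so
#' that the calibrated map sums exactly to the injected activity.
#'
#' @param counts A `voxel_grid` of SPECT counts.
#' @param ia_gbq Total injected activity in GBq.
#' @return An activity `voxel_grid` (GBq) together with the factor in
#'   attribute `"calibration_factor"` (GBq per count).
#' @export
calibrate_activity <- function(counts, ia_gbq) {
  stopifnot(inherits(counts, "voxel_grid"))
  total <- sum(counts$values)
  if (total <= 0) stop("all-zero counts map: calibration undefined")
  if (ia_gbq <= 0) stop("injected activity must be positive")
  factor <- ia_gbq / total
  out <- voxel_grid(counts$values * factor, counts$spacing, counts$origin,
                    unit = "GBq")
  attr(out, "calibration_factor") <- factor
  out
}

#' Time-integrated activity map
#'
#' Converts an activity map (GBq) to time-integrated activity (GBq h)
#' assuming trapping with physical decay only:
#' \eqn{\tilde A = A / \lambda = A \cdot T_{1/2}/\ln 2}. For Y-90 this is
#' 92.390 GBq h per GBq.
#'
#' @param activity An activity `voxel_grid` (GBq).
#' @return A TIA `voxel_grid` (GBq h).
#' @export
compute_tia <- function(activity) {
  stopifnot(inherits(activity, "voxel_grid"))
  if (activity$unit != "GBq") stop("compute_tia expects a 'GBq' grid")
  voxel_grid(activity$values * y90_constants()$tia_h_per_gbq,
             activity$spacing, activity$origin, unit = "GBq.h")
}

#' Split a TIA map into liver and lung components
#'
#' TIA inside the liver mask (tumors included) goes to the liver map, TIA
#' inside the lungs to the lung map. TIA outside both compartments is
#' assigned to the liver map under `outside_policy = "liver"` (soft tissue
#' is closer to liver than lung in density) or discarded under `"drop"`.
#'
#' @param tia A TIA `voxel_grid` (GBq h).
#' @param masks A `voi_masks` aligned with `tia`.
#' @param outside_policy `"liver"` or `"drop"`.
#' @return List with `liver` and `lungs` TIA grids.
#' @export
split_tia <- function(tia, masks, outside_policy = c("liver", "drop")) {
  outside_policy <- match.arg(outside_policy)
  stopifnot(inherits(tia, "voxel_grid"), inherits(masks, "voi_masks"))
  .assert_aligned(tia, masks$liver, "TIA map and masks")
  in_liver <- masks$liver$values != 0
  in_lungs <- masks$lungs$values != 0
  keep_liver <- if (outside_policy == "liver") !in_lungs else in_liver
  mk <- function(keep)
    voxel_grid(tia$values * keep, tia$spacing, tia$origin, unit = "GBq.h")
  list(liver = mk(keep_liver), lungs = mk(in_lungs))
}

#' Convolve a TIA map with a dose kernel
#'
#' Stationary 3D convolution with zero padding outside the field of view
#' (activity is zero outside the body). The `"direct"` backend accumulates
#' the spatial-domain sum over kernel offsets; the `"fft"` backend
#' computes the same linear convolution by zero-padded FFT. Both agree to
#' near machine precision.
#'
#' @param tia A TIA `voxel_grid` (GBq h).
#' @param kernel A `dose_kernel` whose spacing matches the grid spacing
#'   within 1e-6 mm.
#' @param backend `"fft"` or `"direct"`.
#' @return A dose `voxel_grid` (Gy).
#' @export
convolve_dose <- function(tia, kernel, backend = c("fft", "direct")) {
  backend <- match.arg(backend)
  stopifnot(inherits(tia, "voxel_grid"), inherits(kernel, "dose_kernel"))
  if (any(abs(tia$spacing - kernel$spacing) > 1e-6))
    stop(sprintf("kernel spacing (%s mm) does not match grid spacing (%s mm)",
                 paste(signif(kernel$spacing, 6), collapse = "x"),
                 paste(signif(tia$spacing, 6), collapse = "x")))
  out <- if (backend == "direct")
    .conv3_direct(tia$values, kernel$values)
  else
    .conv3_fft(tia$values, kernel$values)
  out[out < 0] <- 0  # clip FFT round-off; true values are non-negative
  voxel_grid(out, tia$spacing, tia$origin, unit = "Gy")
}

# Direct spatial sum: D(v) = sum_s A(s) K(v - s), zero-padded boundaries.
.conv3_direct <- function(a, k) {
  da <- dim(a); dk <- dim(k)
  half <- (dk - 1L) %/% 2L
  out <- array(0, da)
  for (p in seq_len(dk[3])) for (n in seq_len(dk[2])) for (m in seq_len(dk[1])) {
    kv <- k[m, n, p]
    if (kv == 0) next
    off <- c(m, n, p) - half - 1L   # target = source + off
    sx <- max(1L, 1L - off[1]):min(da[1], da[1] - off[1])
    sy <- max(1L, 1L - off[2]):min(da[2], da[2] - off[2])
    sz <- max(1L, 1L - off[3]):min(da[3], da[3] - off[3])
    if (!length(sx) || !length(sy) || !length(sz)) next
    out[sx + off[1], sy + off[2], sz + off[3]] <-
      out[sx + off[1], sy + off[2], sz + off[3]] + kv * a[sx, sy, sz]
  }
  out
}

# Zero-padded FFT linear convolution cropped to the input geometry.
.conv3_fft <- function(a, k) {
  da <- dim(a); dk <- dim(k)
  half <- (dk - 1L) %/% 2L
  dp <- da + dk - 1L
  pa <- array(0, dp); pa[seq_len(da[1]), seq_len(da[2]), seq_len(da[3])] <- a
  pk <- array(0, dp); pk[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- k
  full <- Re(stats::fft(stats::fft(pa) * stats::fft(pk), inverse = TRUE)) /
    prod(dp)
  full[half[1] + seq_len(da[1]), half[2] + seq_len(da[2]),
       half[3] + seq_len(da[3])]
}

#' The seven VSV dose-conversion methods
#'
#' @return Character vector of method names.
#' @export
vsv_methods <- function() {
  c("LED", "LiK", "LiLuK", "LiKD", "LiCK", "LiLuKD", "LiCKLuKD")
}

#' Compute a 3D absorbed dose map by a VSV method
#'
#' Converts the case's activity map to TIA and applies one of the seven
#' voxel-level dose-conversion methods. Writing \eqn{\otimes} for
#' stationary convolution, \eqn{\rho_L, \rho_{Lu}} for the kernel media
#' densities and \eqn{\rho(v)} for the local density map:
#' \describe{
#'   \item{LED}{\eqn{D(v) = \tilde A(v)\,\epsilon / M(v)}: local energy
#'     deposition, all energy absorbed in the emitting voxel.}
#'   \item{LiK}{\eqn{D = \tilde A \otimes K_{Liver}}: whole-body TIA with
#'     the liver kernel.}
#'   \item{LiLuK}{\eqn{D = \tilde A_{Liver} \otimes K_{Liver} +
#'     \tilde A_{Lungs} \otimes K_{Lung}}: tissue-specific kernels.}
#'   \item{LiKD}{\eqn{D(v) = [\tilde A \otimes K_{Liver}](v)\,
#'     \rho_L/\rho(v)}: density correction at the dose-deposition
#'     (target) voxel.}
#'   \item{LiCK}{\eqn{D = [\tilde A\, \rho_L/\rho] \otimes K_{Liver}}:
#'     center-voxel scaling, the density ratio applied at the emission
#'     (source) voxel before convolution.}
#'   \item{LiLuKD}{tissue-specific kernels, each density-corrected at the
#'     target voxel.}
#'   \item{LiCKLuKD}{liver component with center-voxel scaling, lung
#'     component with target-voxel density correction.}
#' }
#' Densities are clamped below at 0.05 g/cm^3 before any division so that
#' near-air CT voxels cannot produce unbounded dose; a voxel with exactly
#' zero density but non-zero TIA is an error.
#'
#' @param case A `patient_case`.
#' @param method One of [vsv_methods()] (case-insensitive).
#' @param liver_kernel,lung_kernel `dose_kernel`s matching the grid
#'   spacing. `lung_kernel` is only required by the two-kernel methods.
#' @param backend Convolution backend, `"fft"` or `"direct"`.
#' @param outside_policy Policy for TIA outside liver and lungs in
#'   two-kernel methods (see [split_tia()]).
#' @return A dose `voxel_grid` (Gy).
#' @export
compute_dose_map <- function(case, method, liver_kernel = NULL,
                             lung_kernel = NULL,
                             backend = c("fft", "direct"),
                             outside_policy = c("liver", "drop")) {
  backend <- match.arg(backend)
  outside_policy <- match.arg(outside_policy)
  stopifnot(inherits(case, "patient_case"))
  method <- match.arg(toupper(method), toupper(vsv_methods()))
  method <- vsv_methods()[toupper(vsv_methods()) == method]

  tia <- compute_tia(case$activity)
  rho <- case$density$values
  bad <- which(rho == 0 & tia$values > 0)
  if (length(bad)) {
    idx <- arrayInd(bad[seq_len(min(5, length(bad)))], dim(rho)) - 1L
    stop("zero density at voxel(s) carrying TIA: ",
         paste(apply(idx, 1, function(r)
           sprintf("(%d,%d,%d)", r[1], r[2], r[3])), collapse = " "),
         if (length(bad) > 5) sprintf(" and %d more", length(bad) - 5))
  }
  rho_safe <- pmax(rho, RHO_FLOOR); dim(rho_safe) <- dim(rho)

  if (method == "LED") {
    eps <- y90_constants()$eps_j_per_gbqh
    mass <- rho * prod(case$density$spacing) * 1e-6  # kg
    d <- ifelse(tia$values > 0, tia$values * eps / pmax(mass, .Machine$double.xmin),
                0)
    dim(d) <- dim(rho)
    return(voxel_grid(d, tia$spacing, tia$origin, unit = "Gy"))
  }

  if (is.null(liver_kernel)) stop("method ", method, " needs a liver kernel")
  two_kernel <- method %in% c("LiLuK", "LiLuKD", "LiCKLuKD")
  if (two_kernel && is.null(lung_kernel))
    stop("method ", method, " needs a lung kernel")
  rho_l <- liver_kernel$medium_density

  scale_grid <- function(g, fac) {
    v <- g$values * fac; dim(v) <- dim(g$values)
    voxel_grid(v, g$spacing, g$origin, unit = g$unit)
  }

  if (!two_kernel) {
    src <- switch(method,
      LiK = tia,
      LiKD = tia,
      LiCK = scale_grid(tia, rho_l / rho_safe))
    d <- convolve_dose(src, liver_kernel, backend)
    if (method == "LiKD") d <- scale_grid(d, rho_l / rho_safe)
    return(d)
  }

  rho_lu <- lung_kernel$medium_density
  parts <- split_tia(tia, case$masks, outside_policy)
  liver_src <- if (method == "LiCKLuKD")
    scale_grid(parts$liver, rho_l / rho_safe) else parts$liver
  d_liver <- convolve_dose(liver_src, liver_kernel, backend)
  if (method == "LiLuKD") d_liver <- scale_grid(d_liver, rho_l / rho_safe)
  d_lung <- convolve_dose(parts$lungs, lung_kernel, backend)
  if (method %in% c("LiLuKD", "LiCKLuKD"))
    d_lung <- scale_grid(d_lung, rho_lu / rho_safe)
  v <- d_liver$values + d_lung$values
  voxel_grid(v, tia$spacing, tia$origin, unit = "Gy")
}
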