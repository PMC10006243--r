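#' Construct a voxel-S-value dose kernel
#'
#' A `dose_kernel` is an odd-sized 3D array giving the absorbed dose (Gy)
#' delivered to each voxel per unit time-integrated activity (GBq h) in the
#' central source voxel, for an infinite uniform medium of the stated
#' density. The energy-capture fraction is the fraction of the total
#' released energy per unit TIA contained within the kernel support.
#'
#' @param values Odd-sized non-negative 3D array, Gy per (GBq h).
#' @param spacing Voxel spacing in mm (scalar or length 3).
#' @param medium_density Medium density in g/cm^3.
#' @param capture_fraction Energy-capture fraction in (0, 1]. If `NULL` it
#'   is computed from the values.
#' @param generator Free-text provenance tag.
#' @return An object of class `dose_kernel`.
#' @export
dose_kernel <- function(values, spacing, medium_density,
                        capture_fraction = NULL, generator = "unknown") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("kernel values must be a 3D array")
  if (any(dim(values) %% 2L == 0L))
    stop("all kernel dimensions must be odd, got ",
         paste(dim(values), collapse = "x"))
  if (any(!is.finite(values)) || any(values < 0))
    stop("kernel values must be finite and non-negative")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (medium_density <= 0) stop("medium density must be positive")
  k <- structure(list(values = values, spacing = as.numeric(spacing),
                      medium_density = medium_density,
                      capture_fraction = NA_real_, generator = generator),
                 class = "dose_kernel")
  cf <- if (is.null(capture_fraction)) {
    sum(values) * .kernel_voxel_mass_kg(k) / y90_constants()$eps_j_per_gbqh
  } else capture_fraction
  if (cf <= 0 || cf > 1 + 1e-9)
    stop(sprintf("capture fraction %.6f outside (0, 1]", cf))
  k$capture_fraction <- min(cf, 1)
  k
}

#' @export
print.dose_kernel <- function(x, ...) {
  cat(sprintf(
    "<dose_kernel> %s voxels, %s mm, medium %.3g g/cm3, capture %.5f\n",
    paste(dim(x$values), collapse = "x"),
    paste(signif(x$spacing, 4), collapse = "x"),
    x$medium_density, x$capture_fraction))
  cat(sprintf("  center S-value %.6g Gy/(GBq.h)\n",
              x$values[(dim(x$values)[1] + 1) / 2,
                       (dim(x$values)[2] + 1) / 2,
                       (dim(x$values)[3] + 1) / 2]))
  invisible(x)
}

# Voxel mass (kg) of a kernel voxel: density g/cm3 * volume mm3 * 1e-6
.kernel_voxel_mass_kg <- function(kernel) {
  kernel$medium_density * prod(kernel$spacing) * 1e-6
}

#' Energy-capture fraction of a kernel
#'
#' Fraction of the total released energy per unit TIA
#' (\eqn{\epsilon = 49.67 \ln 2 / 64.04} J per GBq h) deposited within the
#' kernel support: `sum(K) * voxel_mass / eps`.
#'
#' @param kernel A `dose_kernel`.
#' @return Fraction in (0, 1].
#' @export
capture_fraction <- function(kernel) {
  stopifnot(inherits(kernel, "dose_kernel"))
  eps <- y90_constants()$eps_j_per_gbqh
  sum(kernel$values) * .kernel_voxel_mass_kg(kernel) / eps
}

#' Local-energy-deposition (LED) kernel
#'
#' The degenerate single-voxel kernel in which all emitted energy is
#' absorbed in the source voxel: value `eps / M` with `M` the voxel mass.
#' Its capture fraction is 1 by definition.
#'
#' @param density Medium density in g/cm^3.
#' @param spacing Voxel spacing in mm (scalar or length 3).
#' @return A 1x1x1 `dose_kernel`.
#' @examples
#' k <- build_led_kernel(1.06, 4.42)
#' k$values[1, 1, 1]  # eps / (9.153e-5 kg)
#' @export
build_led_kernel <- function(density, spacing) {
  if (density <= 0) stop("medium density must be positive")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  eps <- y90_constants()$eps_j_per_gbqh
  mass <- density * prod(spacing) * 1e-6
  dose_kernel(array(eps / mass, c(1L, 1L, 1L)), spacing, density,
              capture_fraction = 1, generator = "led")
}

#' Generate a voxel-S-value kernel for a uniform medium
#'
#' Integrates the embedded Y-90 beta dose-point kernel over voxel pairs to
#' produce the VSV kernel for a uniform medium. The voxel-pair average is
#' computed exactly in radial-shell form: the difference vector between a
#' point in the source voxel and a point in the target voxel follows a
#' separable triangular density, so the kernel value is
#' \deqn{K(d) = \int j(r)\, r^2 A_d(r)\, dr,\qquad
#'       A_d(r) = \int_{S^2} T_d(r\omega)\, d\omega,}
#' where the \eqn{1/r^2} singularity of the dose-point kernel cancels
#' against the shell factor, leaving a bounded smooth integrand (the
#' central self-dose voxel needs no special casing). Because the
#' triangular densities of all lattice offsets form a partition of unity,
#' the kernel values sum to exactly the released energy when the support
#' is unbounded; a truncated support strictly loses energy, so the
#' capture fraction is guaranteed to lie in (0, 1]. Truncated kernels are
#' reported as-is, never renormalized.
#'
#' `half_size = 0` returns the degenerate all-energy-local kernel,
#' identical to [build_led_kernel()].
#'
#' @param medium_density Medium density in g/cm^3 (1.06 liver, 0.26 lung).
#' @param spacing Voxel spacing in mm (scalar or length 3).
#' @param half_size Half support in voxels; the kernel is
#'   `(2*half_size+1)^3`.
#' @param n_theta,n_phi Angular quadrature orders (Gauss-Legendre in
#'   cos(theta), uniform in phi).
#' @param dr Radial step in mm; default `min(spacing)/32`.
#' @return A `dose_kernel`.
#' @examples
#' \donttest{
#' k <- generate_vsv_kernel(1.06, 4.8, half_size = 2)
#' k$capture_fraction  # > 0.99
#' }
#' @export
generate_vsv_kernel <- function(medium_density, spacing, half_size,
                                n_theta = 16L, n_phi = 32L, dr = NULL) {
  if (medium_density <= 0) stop("medium density must be positive")
  if (half_size < 0) stop("half_size must be >= 0")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (half_size == 0L) {
    k <- build_led_kernel(medium_density, spacing)
    k$generator <- "dpk-quadrature (degenerate local)"
    return(k)
  }
  eps <- y90_constants()$eps_j_per_gbqh
  r_e <- .R_E_WATER_MM / medium_density        # scaled CSDA range, mm
  r_max <- .dpk_range_mm(medium_density)       # end of DPK support, mm
  if (is.null(dr)) dr <- min(spacing) / 32

  # global midpoint radial grid; shared by all voxels so that the
  # partition-of-unity energy accounting is exact
  r <- seq(dr / 2, r_max + dr, by = dr)
  f_r <- .dpk_shape(r / r_e)
  i_f <- sum(f_r) * dr / r_e                   # radial normalization of F

  # angular quadrature: Gauss-Legendre in mu = cos(theta), uniform phi
  gl <- .gauss_legendre(n_theta)
  mu <- gl$nodes; w_mu <- gl$weights           # on [-1, 1]
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  st <- sqrt(pmax(0, 1 - mu^2))
  omega <- cbind(as.vector(outer(st, cos(phi))),
                 as.vector(outer(st, sin(phi))),
                 rep(mu, times = n_phi))
  w_ang <- rep(w_mu, times = n_phi) * (2 * pi / n_phi)  # sums to 4*pi

  rho_kg_mm3 <- medium_density * 1e-6
  coef <- eps / (4 * pi * rho_kg_mm3 * r_e * i_f)
  h <- spacing                                  # per-axis triangular half-width

  iso <- isTRUE(all.equal(spacing[1], spacing[2])) &&
         isTRUE(all.equal(spacing[1], spacing[3]))
  n <- 2L * half_size + 1L
  kern <- array(0, c(n, n, n))
  idx <- 0:half_size
  reps <- if (iso) {
    g <- expand.grid(i = idx, j = idx, k = idx)
    g[g$i >= g$j & g$j >= g$k, ]
  } else expand.grid(i = idx, j = idx, k = idx)

  hat <- function(t, hh) pmax(hh - abs(t), 0) / hh^2  # first arg keeps dim
  vals <- numeric(nrow(reps))
  for (q in seq_len(nrow(reps))) {
    d <- c(reps$i[q], reps$j[q], reps$k[q]) * spacing
    r_lo <- sqrt(sum(pmax(0, d - h)^2))
    r_hi <- sqrt(sum((d + h)^2))
    sel <- which(r >= r_lo - dr & r <= min(r_hi, r_max) + dr)
    if (!length(sel)) next
    rs <- r[sel]
    ux <- outer(rs, omega[, 1])                 # n_r x n_ang
    uy <- outer(rs, omega[, 2])
    uz <- outer(rs, omega[, 3])
    t_d <- hat(ux - d[1], h[1]) * hat(uy - d[2], h[2]) * hat(uz - d[3], h[3])
    a_d <- as.vector(t_d %*% w_ang)
    vals[q] <- coef * sum(f_r[sel] * a_d) * dr
  }

  ctr <- half_size + 1L
  for (q in seq_len(nrow(reps))) {
    trip <- c(reps$i[q], reps$j[q], reps$k[q])
    perms <- if (iso) unique(.permutations3(trip)) else list(trip)
    for (p in perms) {
      sx <- unique(c(p[1], -p[1])); sy <- unique(c(p[2], -p[2]))
      sz <- unique(c(p[3], -p[3]))
      kern[ctr + sx, ctr + sy, ctr + sz] <- vals[q]
    }
  }
  dose_kernel(kern, spacing, medium_density, generator = "dpk-quadrature")
}

.gauss_legendre <- function(n) {
  # Golub-Welsch: eigen-decomposition of the Jacobi matrix on [-1, 1]
  if (n == 1L) return(list(nodes = 0, weights = 2))
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  jac <- matrix(0, n, n)
  jac[cbind(i, i + 1L)] <- b
  jac[cbind(i + 1L, i)] <- b
  e <- eigen(jac, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

.permutations3 <- function(x) {
  list(x[c(1, 2, 3)], x[c(1, 3, 2)], x[c(2, 1, 3)],
       x[c(2, 3, 1)], x[c(3, 1, 2)], x[c(3, 2, 1)])
}

#' Save a dose kernel to a NIfTI file with a JSON sidecar
#'
#' The kernel array is written as float64 NIfTI and the metadata
#' (`medium_density`, `spacing_mm`, `units`, `capture_fraction`,
#' `generator`) as a JSON sidecar at `<path>.json`, so kernels simulated
#' externally (e.g. by Monte Carlo) can be exchanged with the generator's
#' output.
#'
#' @param kernel A `dose_kernel`.
#' @param path Output NIfTI path.
#' @return `path`, invisibly.
#' @export
save_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "dose_kernel"))
  g <- voxel_grid(kernel$values, kernel$spacing, unit = "S")
  save_map(g, path)
  meta <- list(medium_density = kernel$medium_density,
               spacing_mm = kernel$spacing,
               units = "Gy/(GBq.h)",
               capture_fraction = kernel$capture_fraction,
               generator = kernel$generator)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a dose kernel saved by [save_kernel()] or produced externally
#'
#' Validates the imported kernel: metadata fields must be present, the
#' summed kernel energy must not exceed the released energy (imported
#' kernels that over-conserve are rejected), and point symmetry about the
#' center is checked. Asymmetry beyond `sym_tol` (relative, intended for
#' stochastic Monte Carlo kernels) is flagged with a warning, not
#' rejected.
#'
#' @param path NIfTI path; the sidecar is expected at `<path>.json`.
#' @param sym_tol Relative tolerance for the point-symmetry check.
#' @return A `dose_kernel`.
#' @export
load_kernel <- function(path, sym_tol = 0.05) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing kernel metadata sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("medium_density", "spacing_mm", "units"))
    if (is.null(meta[[field]]))
      stop("kernel sidecar is missing required field '", field, "'")
  if (!identical(meta$units, "Gy/(GBq.h)"))
    stop("kernel unit mismatch: expected 'Gy/(GBq.h)', got '",
         meta$units, "'")
  g <- load_map(path, expected_unit = "S")
  vals <- g$values
  probe <- structure(list(values = vals, spacing = as.numeric(meta$spacing_mm),
                          medium_density = meta$medium_density),
                     class = "dose_kernel")
  cf <- capture_fraction(probe)
  if (cf > 1 + 1e-6)
    stop(sprintf(
      "imported kernel over-conserves energy: summed energy = %.4f x released",
      cf))
  flipped <- vals[rev(seq_len(dim(vals)[1])), rev(seq_len(dim(vals)[2])),
                  rev(seq_len(dim(vals)[3]))]
  asym <- max(abs(vals - flipped)) / max(vals)
  if (asym > sym_tol)
    warning(sprintf(
      "imported kernel asymmetric: max relative asymmetry %.3f (kept as-is)",
      asym))
  dose_kernel(vals, as.numeric(meta$spacing_mm), meta$medium_density,
              capture_fraction = min(cf, 1),
              generator = if (!is.null(meta$generator)) meta$generator
                          else "imported")
}
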