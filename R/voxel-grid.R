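#' Construct a 3D voxel grid
#'
#' The core container of the package: a 3D scalar field with voxel spacing
#' (mm), a world-space origin (mm) and a semantic unit tag. Activity,
#' time-integrated activity, density, HU and absorbed-dose maps are all
#' `voxel_grid` objects. The world position of the center of voxel
#' `(i, j, k)` (0-based) is `origin + (index + 0.5) * spacing`.
#'
#' @param values Numeric 3D array. Must be finite; non-negative unless
#'   `unit` is `"HU"`.
#' @param spacing Numeric length-3 vector of strictly positive voxel
#'   spacings in mm (a scalar is recycled).
#' @param origin Numeric length-3 world-space origin in mm.
#' @param unit One of `"counts"`, `"GBq"`, `"GBq.h"`, `"g/cm3"`, `"HU"`,
#'   `"Gy"`, `"mask"`, `"S"`.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(array(1, dim = c(4, 4, 4)), spacing = 4.42, unit = "GBq")
#' voxel_volume_ml(g)
#' @export
voxel_grid <- function(values, spacing, origin = c(0, 0, 0),
                       unit = c("counts", "GBq", "GBq.h", "g/cm3", "HU",
                                "Gy", "mask", "S")) {
  unit <- match.arg(unit)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("expected 3D volume, got ", length(dim(values)), " dimensions")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values (mm)")
  bad <- which(!is.finite(values))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(values)) - 1L
    stop(sprintf("non-finite voxel value at index (%d, %d, %d)",
                 idx[1], idx[2], idx[3]))
  }
  if (unit != "HU" && any(values < 0)) {
    idx <- arrayInd(which(values < 0)[1L], dim(values)) - 1L
    stop(sprintf("negative value in '%s' grid at index (%d, %d, %d)",
                 unit, idx[1], idx[2], idx[3]))
  }
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin), unit = unit),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s  dim %s  spacing %s mm  origin (%s) mm\n",
              x$unit, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  range [%.4g, %.4g], sum %.6g\n",
              min(x$values), max(x$values), sum(x$values)))
  invisible(x)
}

#' Voxel volume of a grid in mL
#' @param grid A `voxel_grid` (or `dose_kernel`).
#' @return Voxel volume in mL (cm^3).
#' @export
voxel_volume_ml <- function(grid) prod(grid$spacing) / 1000

#' Voxel mass map in kg
#'
#' @param density A density `voxel_grid` in g/cm^3.
#' @return Numeric array of per-voxel masses in kg.
#' @export
voxel_mass_kg <- function(density) {
  stopifnot(inherits(density, "voxel_grid"), density$unit == "g/cm3")
  density$values * voxel_volume_ml(density) / 1000
}

#' Test whether two grids share shape, spacing and origin
#'
#' @param a,b `voxel_grid` objects.
#' @param tol Alignment tolerance in mm.
#' @return Logical.
#' @export
grids_aligned <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

.assert_aligned <- function(a, b, what = "grids") {
  if (!grids_aligned(a, b)) stop(what, " are not aligned (shape/spacing/origin)")
  invisible(TRUE)
}

#' Read a 3D map from a NIfTI file
#'
#' Loads a 3D NIfTI volume, taking spacing and origin from the header
#' (the translation column of the stored affine minus half a voxel, per the
#' package coordinate convention) and attaching the expected unit tag.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param expected_unit Unit tag to attach (see [voxel_grid()]).
#' @return A `voxel_grid`.
#' @export
load_map <- function(path, expected_unit = "Gy") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected 3D volume, got ", length(d), " dimensions in ", path)
  spacing <- RNifti::pixdim(img)[1:3]
  aff <- RNifti::xform(img)
  origin <- as.numeric(aff[1:3, 4]) - 0.5 * spacing
  voxel_grid(array(as.numeric(img), dim = d), spacing = spacing,
             origin = origin, unit = expected_unit)
}

#' Write a voxel grid to a NIfTI file
#'
#' Maps are written as float64 so that load/save round trips are lossless;
#' `"mask"` grids are written as uint8.
#'
#' @param grid A `voxel_grid`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_map <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$spacing
  aff <- diag(c(grid$spacing, 1))
  aff[1:3, 4] <- grid$origin + 0.5 * grid$spacing
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  dtype <- if (grid$unit == "mask") "uint8" else "double"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Resample a grid onto the geometry of a target grid
#'
#' Nearest-neighbour or trilinear resampling in world space, used to bring
#' CT-resolution maps down to the SPECT dosimetry grid. Sampling outside
#' the source field of view returns 0. Binary masks must use
#' `method = "nearest"` so they stay binary.
#'
#' @param src Source `voxel_grid`.
#' @param target `voxel_grid` whose shape/spacing/origin define the output
#'   geometry (its values are ignored).
#' @param method `"nearest"` or `"trilinear"`.
#' @return A `voxel_grid` aligned with `target`, carrying `src$unit`.
#' @export
resample_to_grid <- function(src, target, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(src, "voxel_grid"), inherits(target, "voxel_grid"))
  td <- dim(target$values)
  if (any(td == 0L)) stop("degenerate target grid with zero extent")
  if (src$unit == "mask" && method != "nearest")
    stop("binary masks must be resampled with method = 'nearest'")

  # world coords of target voxel centers, converted to fractional src index
  wx <- target$origin[1] + (seq_len(td[1]) - 0.5) * target$spacing[1]
  wy <- target$origin[2] + (seq_len(td[2]) - 0.5) * target$spacing[2]
  wz <- target$origin[3] + (seq_len(td[3]) - 0.5) * target$spacing[3]
  fx <- (wx - src$origin[1]) / src$spacing[1] + 0.5  # 1-based fractional index
  fy <- (wy - src$origin[2]) / src$spacing[2] + 0.5
  fz <- (wz - src$origin[3]) / src$spacing[3] + 0.5
  sd <- dim(src$values)

  if (method == "nearest") {
    ix <- round(fx); iy <- round(fy); iz <- round(fz)
    okx <- ix >= 1 & ix <= sd[1]; oky <- iy >= 1 & iy <= sd[2]
    okz <- iz >= 1 & iz <= sd[3]
    ix <- pmin(pmax(ix, 1), sd[1]); iy <- pmin(pmax(iy, 1), sd[2])
    iz <- pmin(pmax(iz, 1), sd[3])
    out <- src$values[ix, iy, iz, drop = FALSE]
    out <- out * outer(outer(as.numeric(okx), as.numeric(oky)), as.numeric(okz))
    dim(out) <- td
  } else {
    out <- .trilinear_sample(src$values, fx, fy, fz)
  }
  voxel_grid(out, spacing = target$spacing, origin = target$origin,
             unit = src$unit)
}

# Separable trilinear sampling at the tensor grid fx x fy x fz of 1-based
# fractional indices; zero outside the source volume.
.trilinear_sample <- function(vals, fx, fy, fz) {
  sd <- dim(vals)
  lo <- function(f, n) pmin(pmax(floor(f), 1), n)
  x0 <- lo(fx, sd[1] - 1L); y0 <- lo(fy, sd[2] - 1L); z0 <- lo(fz, sd[3] - 1L)
  tx <- fx - x0; ty <- fy - y0; tz <- fz - z0
  inx <- fx >= 1 & fx <= sd[1]; iny <- fy >= 1 & fy <= sd[2]
  inz <- fz >= 1 & fz <= sd[3]
  out <- array(0, dim = c(length(fx), length(fy), length(fz)))
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    w <- outer(outer(if (cx == 1) tx else 1 - tx,
                     if (cy == 1) ty else 1 - ty),
               if (cz == 1) tz else 1 - tz)
    out <- out + w * vals[x0 + cx, y0 + cy, z0 + cz, drop = FALSE]
  }
  out * outer(outer(as.numeric(inx), as.numeric(iny)), as.numeric(inz))
}

#' Convert a CT HU map to a mass-density map
#'
#' Piecewise-linear CT calibration: `rho = 1 + HU/1000` for HU <= 0 and
#' `rho = 1 + 0.6 * HU/1000` for HU > 0 (g/cm^3), clipped to
#' `[0.00126, 3.0]`. The two slopes are configurable to match a scanner
#' calibration.
#'
#' @param hu A `voxel_grid` with unit `"HU"`.
#' @param slope_neg,slope_pos Slopes (g/cm^3 per 1000 HU) below and above
#'   water.
#' @param clip Length-2 clipping range in g/cm^3.
#' @return A density `voxel_grid` (g/cm^3).
#' @examples
#' hu <- voxel_grid(array(c(-1000, -740, 0, 60), c(4, 1, 1)),
#'                  spacing = 4.8, unit = "HU")
#' hu_to_density(hu)$values[, 1, 1]  # 0.00126 0.26 1.00 1.036
#' @export
hu_to_density <- function(hu, slope_neg = 1.0, slope_pos = 0.6,
                          clip = c(0.00126, 3.0)) {
  stopifnot(inherits(hu, "voxel_grid"))
  if (hu$unit != "HU") stop("hu_to_density expects a grid with unit 'HU'")
  v <- hu$values
  rho <- ifelse(v <= 0, 1 + slope_neg * v / 1000, 1 + slope_pos * v / 1000)
  rho <- pmin(pmax(rho, clip[1]), clip[2])
  dim(rho) <- dim(v)
  voxel_grid(rho, spacing = hu$spacing, origin = hu$origin, unit = "g/cm3")
}
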