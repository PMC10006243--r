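#' Build a consistent VOI mask set from liver, lungs and tumor masks
#'
#' Enforces the compartment rules used throughout the package: tumors are
#' clipped to the liver, the liver takes precedence over the lungs on any
#' overlap, and normal liver (NL) is defined as liver minus tumors. Counts
#' of reassigned voxels are recorded and reported as warnings.
#'
#' @param liver,lungs,tumors Binary `voxel_grid`s (unit `"mask"`) on a
#'   common grid. `tumors` may be `NULL` for a tumor-free case.
#' @return An object of class `voi_masks` with elements `liver`, `lungs`,
#'   `tumors`, `nl` (all `voxel_grid`s) and `reassigned`, a named count
#'   vector (`tumor_outside_liver`, `lung_overlap_liver`).
#' @examples
#' z <- array(0, c(6, 6, 6))
#' li <- z; li[2:5, 2:5, 2:4] <- 1
#' lu <- z; lu[2:5, 2:5, 5:6] <- 1
#' tu <- z; tu[3:4, 3:4, 3] <- 1
#' mk <- function(v) voxel_grid(v, 4.8, unit = "mask")
#' m <- derive_masks(mk(li), mk(lu), mk(tu))
#' sum(m$nl$values)  # liver voxels minus tumor voxels
#' @export
derive_masks <- function(liver, lungs, tumors = NULL) {
  stopifnot(inherits(liver, "voxel_grid"), inherits(lungs, "voxel_grid"))
  .assert_aligned(liver, lungs, "liver and lungs masks")
  if (is.null(tumors))
    tumors <- voxel_grid(array(0, dim(liver$values)), liver$spacing,
                         liver$origin, unit = "mask")
  .assert_aligned(liver, tumors, "liver and tumors masks")
  for (m in list(liver, lungs, tumors))
    if (!all(m$values %in% c(0, 1))) stop("masks must be binary {0,1}")

  li <- liver$values != 0
  lu <- lungs$values != 0
  tu <- tumors$values != 0
  if (!any(li)) stop("empty liver mask: dosimetry undefined")
  if (!any(lu)) stop("empty lungs mask: dosimetry undefined")

  n_overlap <- sum(li & lu)
  if (n_overlap > 0) {
    warning(n_overlap, " liver/lung overlap voxel(s) assigned to liver")
    lu <- lu & !li
  }
  n_outside <- sum(tu & !li)
  if (n_outside > 0) {
    warning(n_outside, " tumor voxel(s) outside liver dropped from tumors")
    tu <- tu & li
  }
  nl <- li & !tu

  as_mask <- function(x)
    voxel_grid(array(as.numeric(x), dim(liver$values)), liver$spacing,
               liver$origin, unit = "mask")
  structure(list(liver = as_mask(li), lungs = as_mask(lu),
                 tumors = as_mask(tu), nl = as_mask(nl),
                 reassigned = c(tumor_outside_liver = n_outside,
                                lung_overlap_liver = n_overlap)),
            class = "voi_masks")
}

#' @export
print.voi_masks <- function(x, ...) {
  n <- vapply(x[c("liver", "lungs", "tumors", "nl")],
              function(m) sum(m$values), numeric(1))
  vol <- n * voxel_volume_ml(x$liver)
  cat("<voi_masks> voxel counts (volume mL):\n")
  for (k in names(n))
    cat(sprintf("  %-7s %8d (%9.1f mL)\n", k, as.integer(n[k]), vol[k]))
  invisible(x)
}

#' VOI volumes in mL
#' @param masks A `voi_masks` object.
#' @return Named numeric vector of volumes (mL) for liver, lungs, tumors, nl.
#' @export
mask_volumes_ml <- function(masks) {
  stopifnot(inherits(masks, "voi_masks"))
  v <- voxel_volume_ml(masks$liver)
  vapply(masks[c("liver", "lungs", "tumors", "nl")],
         function(m) sum(m$values) * v, numeric(1))
}
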