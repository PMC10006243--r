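#' Mean absorbed dose over a VOI
#'
#' @param dose A dose `voxel_grid` (Gy).
#' @param mask A binary `voxel_grid` aligned with `dose`.
#' @return Mean dose in Gy over the mask voxels.
#' @export
mean_dose <- function(dose, mask) {
  stopifnot(inherits(dose, "voxel_grid"), inherits(mask, "voxel_grid"))
  .assert_aligned(dose, mask, "dose map and mask")
  sel <- mask$values != 0
  if (!any(sel)) stop("empty mask: mean dose undefined")
  mean(dose$values[sel])
}

#' Volume fraction receiving at least a threshold dose
#'
#' The V_x metric: percentage of VOI voxels with dose >= `threshold_gy`
#' (e.g. V_70Gy of normal liver, V_200Gy of tumors, V_5Gy / V_13Gy of
#' lungs).
#'
#' @param dose A dose `voxel_grid` (Gy).
#' @param mask A binary `voxel_grid`.
#' @param threshold_gy Dose threshold in Gy (>= 0).
#' @return Percentage in [0, 100].
#' @export
v_at_dose <- function(dose, mask, threshold_gy) {
  stopifnot(threshold_gy >= 0)
  .assert_aligned(dose, mask, "dose map and mask")
  sel <- mask$values != 0
  if (!any(sel)) stop("empty mask: V_x undefined")
  100 * sum(dose$values[sel] >= threshold_gy) / sum(sel)
}

#' Dose-volume histogram on 1-Gy bins
#'
#' Differential DVH: percent of VOI volume per half-open 1-Gy bin
#' `[k, k+1)` for `k = 0 .. Dmax-1` (a voxel exactly at a bin edge goes
#' to the upper bin). Cumulative DVH: percent of volume receiving at
#' least the bin lower edge; by construction `cumulative[k+1]` equals
#' [v_at_dose()] at `k` Gy.
#'
#' @param dose A dose `voxel_grid` (Gy).
#' @param mask A binary `voxel_grid`.
#' @return A `dvh` object: list with `edges_gy` (lower bin edges),
#'   `differential_pct`, `cumulative_pct`.
#' @export
dvh <- function(dose, mask) {
  .assert_aligned(dose, mask, "dose map and mask")
  sel <- mask$values != 0
  if (!any(sel)) stop("empty mask: DVH undefined")
  d <- dose$values[sel]
  n_bins <- max(1L, as.integer(ceiling(max(d) + 1e-12)))
  counts <- tabulate(pmin(floor(d), n_bins - 1L) + 1L, nbins = n_bins)
  dvh_from_differential(100 * counts / length(d))
}

#' Build a DVH object from a differential vector
#'
#' Mainly for constructing reference DVHs in tests and comparisons.
#'
#' @param differential_pct Percent of volume per 1-Gy bin, starting at
#'   the `[0, 1)` Gy bin; must sum to 100 (within 1e-9) unless
#'   `check = FALSE`.
#' @param check Verify normalization.
#' @return A `dvh` object.
#' @export
dvh_from_differential <- function(differential_pct, check = TRUE) {
  if (check && abs(sum(differential_pct) - 100) > 1e-9)
    stop("differential DVH must sum to 100%")
  structure(list(edges_gy = seq_along(differential_pct) - 1,
                 differential_pct = as.numeric(differential_pct),
                 cumulative_pct = rev(cumsum(rev(differential_pct)))),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> %d bins of 1 Gy, D_max bin [%d, %d) Gy\n",
              length(x$edges_gy), max(x$edges_gy), max(x$edges_gy) + 1))
  invisible(x)
}

#' Mean absolute error between two differential DVHs
#'
#' \deqn{MAE = \frac{1}{D_{max}} \sum_{k=1}^{D_{max}}
#'   |V^{test}_k - V^{ref}_k|}
#' with 1-Gy bins, V in percent of VOI volume per bin, and `D_max` the
#' number of bins of the reference DVH (the maximum absorbed dose of the
#' reference map, in Gy, rounded up). The shorter DVH is zero-padded to
#' the longer, so dose deposited by the test method beyond the reference
#' range still counts as error.
#'
#' @param dvh_test,dvh_ref `dvh` objects on 1-Gy bins.
#' @param d_max Normalizing bin count; defaults to the reference DVH
#'   length.
#' @return The MAE (percent per bin, averaged over reference bins).
#' @export
mae_dvh <- function(dvh_test, dvh_ref, d_max = NULL) {
  stopifnot(inherits(dvh_test, "dvh"), inherits(dvh_ref, "dvh"))
  if (is.null(d_max)) d_max <- length(dvh_ref$differential_pct)
  if (d_max < 1) stop("empty reference DVH")
  n <- max(length(dvh_test$differential_pct),
           length(dvh_ref$differential_pct))
  pad <- function(v) c(v, rep(0, n - length(v)))
  sum(abs(pad(dvh_test$differential_pct) -
            pad(dvh_ref$differential_pct))) / d_max
}

#' Absolute percent difference against a reference value
#'
#' @param value_test,value_ref Scalars; `value_ref` must be positive.
#' @return `100 * |test - ref| / ref`.
#' @export
percent_difference <- function(value_test, value_ref) {
  if (any(value_ref <= 0)) stop("reference value must be positive")
  100 * abs(value_test - value_ref) / value_ref
}

#' Paired two-tailed Wilcoxon signed-rank test with Bonferroni correction
#'
#' The method-comparison test used for per-patient dosimetric indices:
#' two-tailed paired Wilcoxon signed-rank p-value multiplied by the
#' number of comparisons, capped at 1.
#'
#' @param samples_a,samples_b Paired numeric vectors (length >= 5).
#' @param n_comparisons Bonferroni multiplier (>= 1).
#' @param alpha Significance level for the returned flag.
#' @return List with `p_raw`, `p_adjusted`, `significant`.
#' @export
paired_wilcoxon_bonferroni <- function(samples_a, samples_b,
                                       n_comparisons = 1L, alpha = 0.05) {
  if (length(samples_a) != length(samples_b))
    stop("paired samples must have equal length")
  if (length(samples_a) < 5) stop("need at least 5 pairs")
  if (n_comparisons < 1) stop("n_comparisons must be >= 1")
  diffs <- samples_a - samples_b
  if (all(diffs == 0)) {
    warning("all paired differences are zero; test undefined, p = 1")
    p <- 1
  } else {
    p <- stats::wilcox.test(samples_a, samples_b, paired = TRUE,
                            alternative = "two.sided", exact = NULL)$p.value
  }
  p_adj <- min(1, p * n_comparisons)
  list(p_raw = p, p_adjusted = p_adj, significant = p_adj <= alpha)
}

#' Bland-Altman comparison of MIA estimates
#'
#' Per-pair differences expressed as percent of the reference, with the
#' mean difference and 95% limits of agreement (mean +/- 1.96 SD).
#'
#' @param mia_test,mia_ref Numeric vectors (equal length >= 2) in GBq;
#'   `mia_ref` entries must be non-zero.
#' @return List with `diff_pct` (per pair), `mean_pct` (reference-scale
#'   means, the Bland-Altman x-axis), `mean_diff_pct`, `sd_diff_pct`,
#'   `limits_pct` (length 2).
#' @export
bland_altman <- function(mia_test, mia_ref) {
  if (length(mia_test) != length(mia_ref))
    stop("test and reference lists must have equal length")
  if (length(mia_ref) < 2) stop("need at least 2 pairs")
  if (any(mia_ref == 0)) stop("zero reference entries")
  diff_pct <- 100 * (mia_test - mia_ref) / mia_ref
  m <- mean(diff_pct)
  s <- if (length(diff_pct) > 1) stats::sd(diff_pct) else 0
  list(diff_pct = diff_pct,
       mean_pct = (mia_test + mia_ref) / 2,
       mean_diff_pct = m, sd_diff_pct = s,
       limits_pct = c(m - 1.96 * s, m + 1.96 * s))
}

#' Per-VOI dose report for one dose map
#'
#' Convenience summary: mean doses and the standard V_x metrics for NL,
#' tumors and lungs, plus the three DVHs.
#'
#' @param dose A dose `voxel_grid` (Gy).
#' @param masks A `voi_masks`.
#' @return A `dose_report` list with `mean_gy`, `vx_pct`, `dvhs`.
#' @export
dose_report <- function(dose, masks) {
  stopifnot(inherits(masks, "voi_masks"))
  vois <- list(nl = masks$nl, tumors = masks$tumors, lungs = masks$lungs)
  vois <- vois[vapply(vois, function(m) any(m$values != 0), logical(1))]
  mean_gy <- vapply(vois, function(m) mean_dose(dose, m), numeric(1))
  vx <- c(
    nl_70gy = if (!is.null(vois$nl)) v_at_dose(dose, vois$nl, 70) else NA_real_,
    tumors_200gy = if (!is.null(vois$tumors))
      v_at_dose(dose, vois$tumors, 200) else NA_real_,
    lungs_5gy = if (!is.null(vois$lungs))
      v_at_dose(dose, vois$lungs, 5) else NA_real_,
    lungs_13gy = if (!is.null(vois$lungs))
      v_at_dose(dose, vois$lungs, 13) else NA_real_)
  structure(list(mean_gy = mean_gy, vx_pct = vx,
                 dvhs = lapply(vois, function(m) dvh(dose, m))),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat("<dose_report>\n  mean dose (Gy): ",
      paste(sprintf("%s %.2f", names(x$mean_gy), x$mean_gy),
            collapse = ", "), "\n", sep = "")
  vx <- x$vx_pct[!is.na(x$vx_pct)]
  cat("  V_x (%): ",
      paste(sprintf("%s %.1f", names(vx), vx), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
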