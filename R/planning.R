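#' Planning dose limits
#'
#' Upper mean-dose limits used for maximum-injected-activity planning:
#' 70 Gy for normal liver and 30 Gy for lungs by convention. An LSF above
#' 20% triggers an advisory warning in [compartment_summary()] — high
#' lung shunt is a traditional exclusion criterion, although lung mean
#' dose is the physically meaningful quantity.
#'
#' @param d_nl_max_gy,d_lungs_max_gy Dose limits in Gy.
#' @param lsf_warn_pct Advisory LSF threshold in percent.
#' @return A `planning_limits` list.
#' @export
planning_limits <- function(d_nl_max_gy = 70, d_lungs_max_gy = 30,
                            lsf_warn_pct = 20) {
  stopifnot(d_nl_max_gy > 0, d_lungs_max_gy > 0, lsf_warn_pct > 0)
  structure(list(d_nl_max_gy = d_nl_max_gy, d_lungs_max_gy = d_lungs_max_gy,
                 lsf_warn_pct = lsf_warn_pct), class = "planning_limits")
}

#' Compartment masses at nominal densities
#'
#' Masses for the partition model: voxel count times voxel volume times
#' the nominal density of the tissue (1.06 g/cm^3 for tumors and normal
#' liver, 0.26 g/cm^3 for lungs), as used clinically when only
#' CT-segmented volumes are available.
#'
#' @param masks A `voi_masks`.
#' @return Named vector (kg): `tumors`, `nl`, `lungs`.
#' @export
compartment_masses <- function(masks) {
  stopifnot(inherits(masks, "voi_masks"))
  v_ml <- voxel_volume_ml(masks$liver)
  n <- vapply(masks[c("tumors", "nl", "lungs")],
              function(m) sum(m$values), numeric(1))
  if (n[["nl"]] == 0) stop("empty normal-liver mask")
  if (n[["lungs"]] == 0) stop("empty lungs mask")
  c(tumors = n[["tumors"]] * v_ml * RHO_LIVER / 1000,
    nl = n[["nl"]] * v_ml * RHO_LIVER / 1000,
    lungs = n[["lungs"]] * v_ml * RHO_LUNG / 1000)
}

#' Lung shunt fraction of a case
#'
#' \eqn{LSF = 100 \cdot A_{Lungs} / (A_{Lungs} + A_{Liver})} with
#' \eqn{A_{Liver}} the whole-liver activity (tumors included).
#'
#' @param case A `patient_case`.
#' @return LSF in percent.
#' @export
compute_lsf <- function(case) {
  stopifnot(inherits(case, "patient_case"))
  a <- case$activity$values
  a_lungs <- sum(a[case$masks$lungs$values != 0])
  a_liver <- sum(a[case$masks$liver$values != 0])
  if (a_lungs + a_liver <= 0)
    stop("no activity in liver or lungs: LSF undefined")
  100 * a_lungs / (a_lungs + a_liver)
}

#' Tumor-to-normal-liver ratio of a case
#'
#' \eqn{TNR = (A_{Tumors}/M_{Tumors}) / (A_{NL}/M_{NL})} with masses at
#' nominal densities from [compartment_masses()].
#'
#' @param case A `patient_case`.
#' @return TNR (dimensionless).
#' @export
compute_tnr <- function(case) {
  stopifnot(inherits(case, "patient_case"))
  a <- case$activity$values
  m <- compartment_masses(case$masks)
  if (m[["tumors"]] == 0) stop("empty tumors mask: TNR undefined")
  a_tum <- sum(a[case$masks$tumors$values != 0])
  a_nl <- sum(a[case$masks$nl$values != 0])
  if (a_nl <= 0) stop("zero normal-liver activity concentration")
  (a_tum / m[["tumors"]]) / (a_nl / m[["nl"]])
}

#' Compartment summary of a case
#'
#' Activities, nominal-density masses, volumes, LSF and TNR of the three
#' planning compartments.
#'
#' @param case A `patient_case`.
#' @param warn_lsf Emit the advisory warning when LSF exceeds the
#'   [planning_limits()] threshold.
#' @param limits A `planning_limits` (for the advisory threshold only).
#' @return A `compartment_summary` list.
#' @export
compartment_summary <- function(case, warn_lsf = TRUE,
                                limits = planning_limits()) {
  stopifnot(inherits(case, "patient_case"))
  a <- case$activity$values
  masks <- case$masks
  act <- c(lungs = sum(a[masks$lungs$values != 0]),
           liver = sum(a[masks$liver$values != 0]),
           tumors = sum(a[masks$tumors$values != 0]),
           nl = sum(a[masks$nl$values != 0]))
  m <- compartment_masses(masks)
  lsf <- compute_lsf(case)
  tnr <- if (m[["tumors"]] > 0 && act[["nl"]] > 0) compute_tnr(case) else NA_real_
  if (warn_lsf && lsf > limits$lsf_warn_pct)
    warning(sprintf(
      "LSF %.1f%% exceeds the advisory %.0f%% threshold (reported, not excluded)",
      lsf, limits$lsf_warn_pct))
  structure(list(activity_gbq = act, mass_kg = m,
                 volumes_ml = mask_volumes_ml(masks),
                 lsf_pct = lsf, tnr = tnr),
            class = "compartment_summary")
}

#' Maximum injected activity by the partition model
#'
#' \deqn{MIA_{PM} = \min\!\left[
#'   \frac{(M_{Tumors} TNR + M_{NL})\, D^{max}_{NL}}{49.67\,(1 - LSF/100)},\;
#'   \frac{M_{Lungs}\, D^{max}_{Lungs}}{49.67\, LSF/100}\right]}
#' with masses in kg, doses in Gy and 49.67 J/GBq the constant converting
#' administered activity to released energy. At LSF = 0 the lung term is
#' infinite and the normal-liver limit binds.
#'
#' @param tnr Tumor-to-normal-liver ratio.
#' @param lsf_pct Lung shunt fraction, percent.
#' @param masses_kg Named vector with `tumors`, `nl`, `lungs` (kg), e.g.
#'   from [compartment_masses()].
#' @param limits A [planning_limits()].
#' @return List with `mia_gbq`, `binding` (`"nl"` or `"lungs"`),
#'   `nl_term_gbq`, `lung_term_gbq`.
#' @examples
#' m <- c(tumors = 20.6 * 1.06e-3, nl = 1372.8 * 1.06e-3,
#'        lungs = 3591.2 * 0.26e-3)
#' mia_partition(tnr = 1.3, lsf_pct = 1.5, masses_kg = m)$mia_gbq  # 2.123
#' @export
mia_partition <- function(tnr, lsf_pct, masses_kg,
                          limits = planning_limits()) {
  stopifnot(tnr > 0, lsf_pct >= 0, lsf_pct < 100,
            all(c("tumors", "nl", "lungs") %in% names(masses_kg)))
  e_total <- y90_constants()$e_total_j_per_gbq
  nl_term <- (masses_kg[["tumors"]] * tnr + masses_kg[["nl"]]) *
    limits$d_nl_max_gy / (e_total * (1 - lsf_pct / 100))
  lung_term <- if (lsf_pct > 0)
    masses_kg[["lungs"]] * limits$d_lungs_max_gy / (e_total * lsf_pct / 100)
  else Inf
  list(mia_gbq = min(nl_term, lung_term),
       binding = if (nl_term <= lung_term) "nl" else "lungs",
       nl_term_gbq = nl_term, lung_term_gbq = lung_term)
}

#' Maximum injected activity from a 3D dose map
#'
#' Scales the per-GBq mean doses measured on the MAA study up to the dose
#' limits:
#' \deqn{MIA_{3D} = \min\!\left[\frac{D^{max}_{NL}}
#'   {D^{mean}_{NL}/IA_{MAA}},\;
#'   \frac{D^{max}_{Lungs}}{D^{mean}_{Lungs}/IA_{MAA}}\right].}
#'
#' @param mean_dose_nl_gy,mean_dose_lungs_gy Mean VOI doses (Gy) of the
#'   dose map computed at the MAA activity.
#' @param ia_maa_gbq The injected MAA activity (GBq) the dose map was
#'   computed for.
#' @param limits A [planning_limits()].
#' @return List with `mia_gbq`, `binding`, `nl_term_gbq`,
#'   `lung_term_gbq`.
#' @export
mia_3d <- function(mean_dose_nl_gy, mean_dose_lungs_gy, ia_maa_gbq,
                   limits = planning_limits()) {
  stopifnot(ia_maa_gbq > 0, mean_dose_nl_gy >= 0, mean_dose_lungs_gy >= 0)
  if (mean_dose_nl_gy == 0 && mean_dose_lungs_gy == 0)
    stop("both mean doses are zero: MIA undefined")
  nl_term <- if (mean_dose_nl_gy > 0)
    limits$d_nl_max_gy / (mean_dose_nl_gy / ia_maa_gbq) else Inf
  lung_term <- if (mean_dose_lungs_gy > 0)
    limits$d_lungs_max_gy / (mean_dose_lungs_gy / ia_maa_gbq) else Inf
  list(mia_gbq = min(nl_term, lung_term),
       binding = if (nl_term <= lung_term) "nl" else "lungs",
       nl_term_gbq = nl_term, lung_term_gbq = lung_term)
}
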