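#' Physical constants for yttrium-90 liver dosimetry
#'
#' Defaults: Y-90 physical half-life 64.1 h; mean energy released per decay
#' 0.93 MeV (beta spectrum mean, locally absorbed); liver density
#' 1.05 g/cm3; the CODATA MeV-to-joule conversion.
#'
#' @param T_half_h Half-life in hours.
#' @param E_mean_MeV Mean energy per decay in MeV.
#' @param density Tissue density in g/ml.
#' @param joules_per_MeV Conversion constant.
#' @return A `physics_constants` list.
#' @export
physics_constants <- function(T_half_h = 64.1, E_mean_MeV = 0.93,
                              density = 1.05,
                              joules_per_MeV = 1.602176634e-13) {
  stopifnot(T_half_h > 0, E_mean_MeV > 0, density > 0, joules_per_MeV > 0)
  structure(list(T_half_h = T_half_h, E_mean_MeV = E_mean_MeV,
                 density = density, joules_per_MeV = joules_per_MeV),
            class = "physics_constants")
}

#' Net administered activity
#'
#' The activity actually delivered to the liver: injected minus the residual
#' measured in the vial, optionally reduced by the lung shunt fraction.
#' Under the no-extrahepatic-shunt assumption the LSF correction is off by
#' default.
#'
#' @param A_injected Injected activity in GBq.
#' @param A_residual Residual activity left in the vial, GBq.
#' @param lsf Lung shunt fraction in `[0, 1)`.
#' @param apply_lsf Apply the `(1 - lsf)` correction?
#' @param use_residual Subtract the residual? (TRUE in routine practice.)
#' @return Net activity `A_net` in GBq.
#' @examples
#' net_activity(2.60, 0.10)                       # 2.50
#' net_activity(2.60, 0, lsf = 0.08, apply_lsf = TRUE)  # 2.392
#' @export
net_activity <- function(A_injected, A_residual = 0, lsf = 0,
                         apply_lsf = FALSE, use_residual = TRUE) {
  stopifnot(A_injected > 0, A_residual >= 0, lsf >= 0, lsf < 1)
  if (A_residual >= A_injected)
    stop("residual activity must be smaller than injected activity")
  a <- A_injected - if (use_residual) A_residual else 0
  if (apply_lsf) a <- a * (1 - lsf)
  a
}

#' Self-calibrate a count map to a known activity
#'
#' Scales the SPECT count map so that the summed activity over the
#' calibration region (normally the whole liver, per the
#' no-extrahepatic-shunt assumption) equals the net administered activity.
#' Voxels outside the region get zero activity.
#'
#' @param counts A [scalar_map] of kind `"counts"`.
#' @param region Logical mask, the calibration region.
#' @param A_net_GBq Net activity in GBq.
#' @return A [scalar_map] of kind `"activity_Bq"` whose sum over `region`
#'   equals `A_net_GBq * 1e9`.
#' @export
self_calibrate <- function(counts, region, A_net_GBq) {
  stopifnot(inherits(counts, "scalar_map"), is.logical(region))
  if (!all(dim(region) == counts$grid$shape))
    stop("region mask does not match the count-map grid")
  total <- sum(counts$values[region])
  if (total <= 0) stop("zero total counts in the calibration region")
  act <- array(0, dim(counts$values))
  act[region] <- counts$values[region] / total * (A_net_GBq * 1e9)
  scalar_map(act, counts$grid, kind = "activity_Bq")
}

#' Local-deposition dose conversion factor
#'
#' Closed form of the local deposition method (LDM) for a permanently
#' trapped source decaying physically: energy per unit administered
#' activity, `(T_half/ln 2) * E_mean * J_per_MeV * 1e9` in Gy.kg/GBq.
#' About 49.61 Gy.kg/GBq for Y-90 defaults: the mean dose to a region of
#' mass M kg receiving A GBq is `dose_factor * A / M` Gy regardless of the
#' spatial distribution.
#'
#' @param constants A [physics_constants] list.
#' @return Scalar, Gy.kg per GBq.
#' @export
dose_factor <- function(constants = physics_constants()) {
  (constants$T_half_h * 3600 / log(2)) * constants$E_mean_MeV *
    constants$joules_per_MeV * 1e9
}

#' Absorbed-dose map by the local deposition method
#'
#' Assumes permanent microsphere trapping (time-integrated activity
#' `A * T_half / ln 2`) and no energy cross-talk between voxels: each
#' voxel's decay energy is absorbed in its own mass.
#'
#' @param activity A [scalar_map] of kind `"activity_Bq"`.
#' @param constants A [physics_constants] list.
#' @return A [scalar_map] of kind `"dose_Gy"`.
#' @export
ldm_dose_map <- function(activity, constants = physics_constants()) {
  stopifnot(inherits(activity, "scalar_map"))
  mass_kg <- voxel_volume_ml(activity$grid) * constants$density / 1000
  tia <- activity$values * constants$T_half_h * 3600 / log(2)  # decays
  dose <- tia * constants$E_mean_MeV * constants$joules_per_MeV / mass_kg
  scalar_map(dose, activity$grid, kind = "dose_Gy")
}

#' Build paired simulation and therapy dose maps
#'
#' Both arms are calibrated to the same Y-90 net activity and converted with
#' Y-90 constants: the Tc-99m-MAA (simulation) image serves purely as a
#' spatial surrogate for the microsphere distribution, so simulation
#' dosimetry is Y-90 dosimetry computed on the MAA count distribution.
#'
#' @param sim_counts,ther_counts Count maps ([scalar_map]) on the reference
#'   grid.
#' @param region Calibration-region mask (normally the whole liver).
#' @param A_net_GBq Net Y-90 activity, GBq.
#' @param constants A [physics_constants] list.
#' @return List with `sim_activity`, `ther_activity`, `sim_dose`,
#'   `ther_dose` ([scalar_map]s) and `A_net_GBq`.
#' @export
build_dose_maps <- function(sim_counts, ther_counts, region, A_net_GBq,
                            constants = physics_constants()) {
  sim_act <- self_calibrate(sim_counts, region, A_net_GBq)
  ther_act <- self_calibrate(ther_counts, region, A_net_GBq)
  list(sim_activity = sim_act,
       ther_activity = ther_act,
       sim_dose = ldm_dose_map(sim_act, constants),
       ther_dose = ldm_dose_map(ther_act, constants),
       A_net_GBq = A_net_GBq)
}
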