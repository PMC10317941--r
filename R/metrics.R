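#' Mean absorbed dose over a VOI
#'
#' @param dose_map A [scalar_map] of kind `"dose_Gy"`.
#' @param mask Non-empty logical mask on the same grid.
#' @return Mean dose in Gy.
#' @export
mean_absorbed_dose <- function(dose_map, mask) {
  stopifnot(inherits(dose_map, "scalar_map"), is.logical(mask))
  if (!any(mask)) stop("empty mask")
  mean(dose_map$values[mask])
}

#' Cumulative dose-volume histogram
#'
#' The exact step function `F(d)` = percentage of the VOI volume receiving
#' at least `d` Gy, built from the unbinned voxel doses (uniform voxel
#' volume). `F(0) = 100`, non-increasing, right-continuous.
#'
#' @param dose_map A [scalar_map] of kind `"dose_Gy"`.
#' @param mask Non-empty logical mask.
#' @return A `dvh` object: sorted unique doses, `F` at each, voxel count.
#'   Evaluate anywhere with `volume_at_dose`; export a binned curve with
#'   `as.data.frame`.
#' @export
cumulative_dvh <- function(dose_map, mask) {
  stopifnot(inherits(dose_map, "scalar_map"), is.logical(mask))
  if (!any(mask)) stop("empty mask")
  d <- sort(dose_map$values[mask])
  n <- length(d)
  u <- unique(d)
  # fraction with dose >= u[i]; d is sorted so this is exact
  frac <- 100 * vapply(u, function(x) sum(d >= x), numeric(1)) / n
  structure(list(dose = u, frac_pct = frac, n_voxels = n,
                 voxel_ml = voxel_volume_ml(dose_map$grid)),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> %d voxels (%.1f ml), dose range [%.3g, %.3g] Gy\n",
              x$n_voxels, x$n_voxels * x$voxel_ml,
              min(x$dose), max(x$dose)))
  invisible(x)
}

#' @export
#' @param row.names,optional,bin_Gy Standard `as.data.frame` arguments plus
#'   the export bin width in Gy.
#' @rdname cumulative_dvh
as.data.frame.dvh <- function(x, row.names = NULL, optional = FALSE,
                              bin_Gy = 1, ...) {
  grid <- seq(0, max(x$dose) + bin_Gy, by = bin_Gy)
  f <- vapply(grid, function(g) step_frac(x, g), numeric(1))
  data.frame(dose_Gy = grid, volume_pct = f)
}

# F(g) on the step DVH: % of voxels with dose >= g
step_frac <- function(dvh, g) {
  if (g <= dvh$dose[1]) return(100)
  i <- findInterval(g, dvh$dose)
  if (dvh$dose[i] == g) dvh$frac_pct[i]
  else if (i == length(dvh$dose)) 0
  else dvh$frac_pct[i + 1]
}

#' @export
plot.dvh <- function(x, ..., xlab = "Absorbed dose (Gy)",
                     ylab = "Volume (%)", type = "s") {
  graphics::plot(c(0, x$dose), c(100, x$frac_pct), type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Dose-volume metrics Dx and Vx
#'
#' `dose_at_volume` returns Dx, the minimum dose received by the hottest
#' `x`% of the VOI volume, evaluated on the exact step DVH with no
#' interpolation: the `ceiling(x * N / 100)`-th largest voxel dose
#' (equivalently `max{d : F(d) >= x}`). `volume_at_dose` returns Vx, the
#' percentage of the VOI volume receiving at least `x` Gy. An interpolated
#' Dx variant (linear on the sorted-dose quantile) is available for plot
#' parity but is never used for reported metrics.
#'
#' @param dose_map A [scalar_map] of kind `"dose_Gy"`.
#' @param mask Non-empty logical mask.
#' @param x Volume percentage (Dx, `0 < x <= 100`) or dose threshold in Gy
#'   (Vx, `x >= 0`).
#' @param interpolate Use linear interpolation between sorted voxel doses.
#' @return Dx in Gy / Vx in percent.
#' @export
dose_at_volume <- function(dose_map, mask, x, interpolate = FALSE) {
  stopifnot(inherits(dose_map, "scalar_map"), is.logical(mask))
  if (!any(mask)) stop("empty mask")
  if (x <= 0 || x > 100) stop("x must be in (0, 100]")
  d <- sort(dose_map$values[mask], decreasing = TRUE)
  if (interpolate)
    return(unname(stats::quantile(d, probs = 1 - x / 100, type = 7)))
  d[ceiling(x * length(d) / 100)]
}

#' @rdname dose_at_volume
#' @export
volume_at_dose <- function(dose_map, mask, x) {
  stopifnot(inherits(dose_map, "scalar_map"), is.logical(mask))
  if (!any(mask)) stop("empty mask")
  if (x < 0) stop("dose threshold must be >= 0")
  100 * sum(dose_map$values[mask] >= x) / sum(mask)
}

#' Tumour-to-normal ratio of specific activity
#'
#' `TNR = (A_TL / M_TL) / (A_NTL / M_NTL)` with activities summed from the
#' activity map over each VOI and masses from voxel counting at uniform
#' density. Invariant to any global rescaling of the activity map, so a
#' simulation TNR needs no Y-90 calibration.
#'
#' @param activity_map A [scalar_map] (activity or counts).
#' @param tl,ntl Logical masks for tumoral and non-tumoral liver.
#' @param density Tissue density in g/ml.
#' @return List with `tnr`, `A_TL`, `A_NTL` (map units), `M_TL`, `M_NTL`
#'   (kg). `tnr` is `NA` when the NTL activity is zero (undefined).
#' @export
tnr <- function(activity_map, tl, ntl, density = 1.05) {
  stopifnot(inherits(activity_map, "scalar_map"))
  if (!any(tl) || !any(ntl)) stop("both masks must be non-empty")
  grid <- activity_map$grid
  A_TL <- sum(activity_map$values[tl])
  A_NTL <- sum(activity_map$values[ntl])
  M_TL <- voi_mass_kg(tl, grid, density)
  M_NTL <- voi_mass_kg(ntl, grid, density)
  ratio <- if (A_NTL <= 0) NA_real_ else (A_TL / M_TL) / (A_NTL / M_NTL)
  list(tnr = ratio, A_TL = A_TL, A_NTL = A_NTL, M_TL = M_TL, M_NTL = M_NTL)
}

# metric panels per VOI family: Dx in Gy/GBq columns, Vx in % on absolute Gy
tl_vx_levels <- c(120, 205)
ntl_vx_levels <- c(20, 50, 90)
dx_levels <- c(50, 70, 95)

#' Per-VOI dose-metric panel
#'
#' Computes the reporting panel for one dose map: for `TL`
#' `{MAD, D50, D70, D95, V120, V205}`; for `NTLt` and `NTLw`
#' `{MAD, D50, D70, D95, V20, V50, V90}`. Dose metrics are reported both in
#' absolute Gy and normalized Gy per GBq of net activity; Vx thresholds are
#' absolute Gy and Vx values are % of the VOI volume.
#'
#' @param dose_map A [scalar_map] of kind `"dose_Gy"`.
#' @param vois A `voi_set` from [derive_vois()].
#' @param A_net_GBq Net activity used for normalization.
#' @param interpolate_dx Passed to [dose_at_volume()].
#' @return Long data.frame: `voi`, `metric`, `unit` (`"Gy"` or `"pct"`),
#'   `value` (Gy or %), `value_norm` (Gy/GBq; `NA` for Vx rows),
#'   `volume_ml`.
#' @export
metrics_panel <- function(dose_map, vois, A_net_GBq,
                          interpolate_dx = FALSE) {
  stopifnot(inherits(vois, "voi_set"))
  rows <- list()
  for (voi in c("TL", "NTLt", "NTLw")) {
    mask <- vois$masks[[voi]]
    vol <- voi_volume_ml(mask, vois$grid)
    if (!any(mask)) next  # e.g. all lesions excluded: TL panel absent
    vx <- if (voi == "TL") tl_vx_levels else ntl_vx_levels
    mad <- mean_absorbed_dose(dose_map, mask)
    dx <- vapply(dx_levels, function(x)
      dose_at_volume(dose_map, mask, x, interpolate = interpolate_dx),
      numeric(1))
    vxv <- vapply(vx, function(x) volume_at_dose(dose_map, mask, x),
                  numeric(1))
    rows[[voi]] <- data.frame(
      voi = voi,
      metric = c("MAD", paste0("D", dx_levels), paste0("V", vx)),
      unit = c(rep("Gy", 1 + length(dx_levels)), rep("pct", length(vx))),
      value = c(mad, dx, vxv),
      value_norm = c(c(mad, dx) / A_net_GBq, rep(NA_real_, length(vx))),
      volume_ml = vol)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert a normalized dose to an absolute dose
#'
#' @param value_per_GBq Dose in Gy/GBq.
#' @param A_GBq Activity in GBq.
#' @return Dose in Gy.
#' @export
denormalize_dose <- function(value_per_GBq, A_GBq) value_per_GBq * A_GBq
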