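#' Pipeline configuration
#'
#' @param min_lesion_ml Lesion exclusion threshold (ml, strict `<`).
#' @param calibration_region `"liver"` (default, no-extrahepatic-shunt
#'   assumption) or `"fov"` (whole field of view).
#' @param apply_lsf,use_residual Passed to [net_activity()].
#' @param constants A [physics_constants()] list.
#' @param interpolate_dx Use interpolated Dx (plot parity only).
#' @param strata_threshold_ml Tumoral-volume stratum boundary.
#' @param paired_test Use the paired signed-rank variant in cohort tables
#'   instead of the unpaired Mann-Whitney protocol.
#' @return A `sirt_config` list.
#' @export
sirt_config <- function(min_lesion_ml = 4, calibration_region = c("liver", "fov"),
                        apply_lsf = FALSE, use_residual = TRUE,
                        constants = physics_constants(),
                        interpolate_dx = FALSE,
                        strata_threshold_ml = 200,
                        paired_test = FALSE) {
  structure(list(min_lesion_ml = min_lesion_ml,
                 calibration_region = match.arg(calibration_region),
                 apply_lsf = apply_lsf, use_residual = use_residual,
                 constants = constants, interpolate_dx = interpolate_dx,
                 strata_threshold_ml = strata_threshold_ml,
                 paired_test = paired_test),
            class = "sirt_config")
}

#' Run the dosimetry pipeline on one case
#'
#' Load/resample to the reference grid (the simulation grid), apply the
#' small-lesion filter, derive VOIs, self-calibrate both arms to the same
#' net Y-90 activity, convert to dose by the local deposition method, and
#' compute the metric panel and TNRs for both arms.
#'
#' @param case A `patient_case` (from [generate_case()] or [read_case()]).
#' @param config A [sirt_config()].
#' @param keep_maps Keep the activity/dose maps in the result (memory!).
#' @return A `case_result`: `record` (long data.frame: case_id, arm, voi,
#'   metric, unit, value, value_norm, volume_ml), `tnr` (data.frame), the
#'   applied `A_net_GBq`, per-case metadata, `excluded_lesions`, and flags.
#' @export
run_case <- function(case, config = sirt_config(), keep_maps = FALSE) {
  stopifnot(inherits(case, "patient_case"))
  ref_grid <- case$sim_counts$grid
  ther <- resample_to_reference(case$ther_counts, ref_grid, "trilinear")
  liver <- resample_to_reference(case$masks$liver, ref_grid, "nearest")
  lobe <- resample_to_reference(case$masks$lobe, ref_grid, "nearest")
  lesions <- lapply(case$masks$lesions, resample_to_reference,
                    ref_grid = ref_grid, mode = "nearest")

  retained <- exclude_small_lesions(lesions, grid = ref_grid,
                                    min_ml = config$min_lesion_ml,
                                    quiet = TRUE)
  vois <- derive_vois(liver, lobe, retained, grid = ref_grid)
  A_net <- net_activity(case$meta$A_injected, case$meta$A_residual,
                        case$meta$lsf, apply_lsf = config$apply_lsf,
                        use_residual = config$use_residual)
  region <- if (config$calibration_region == "liver") vois$masks$liver else {
    m <- array(TRUE, ref_grid$shape); attr(m, "grid") <- ref_grid; m
  }
  maps <- build_dose_maps(case$sim_counts, ther, region, A_net,
                          config$constants)

  rec <- rbind(
    cbind(arm = "sim", metrics_panel(maps$sim_dose, vois, A_net,
                                     config$interpolate_dx)),
    cbind(arm = "ther", metrics_panel(maps$ther_dose, vois, A_net,
                                      config$interpolate_dx)))
  rec <- cbind(case_id = case$meta$case_id, rec)

  has_tl <- any(vois$masks$TL)
  tnr_df <- if (has_tl) {
    rows <- lapply(c("sim", "ther"), function(arm) {
      act <- maps[[paste0(arm, "_activity")]]
      data.frame(case_id = case$meta$case_id, arm = arm,
                 tnr_ntlt = tnr(act, vois$masks$TL, vois$masks$NTLt,
                                config$constants$density)$tnr,
                 tnr_ntlw = tnr(act, vois$masks$TL, vois$masks$NTLw,
                                config$constants$density)$tnr)
    })
    do.call(rbind, rows)
  } else data.frame(case_id = character(), arm = character(),
                    tnr_ntlt = numeric(), tnr_ntlw = numeric())

  structure(list(
    case_id = case$meta$case_id,
    record = rec, tnr = tnr_df, A_net_GBq = A_net,
    tl_volume_ml = if (has_tl) voi_volume_ml(vois$masks$TL, ref_grid) else 0,
    meta = case$meta,
    volumes_ml = vapply(vois$masks, voi_volume_ml, numeric(1),
                        grid = ref_grid),
    excluded_lesions = attr(retained, "excluded"),
    all_lesions_excluded = !has_tl && length(case$masks$lesions) > 0,
    maps = if (keep_maps) maps else NULL,
    vois = if (keep_maps) vois else NULL),
    class = "case_result")
}

#' @export
print.case_result <- function(x, ...) {
  cat(sprintf("<case_result> %s: A_net %.3f GBq, TL %.1f ml%s\n",
              x$case_id, x$A_net_GBq, x$tl_volume_ml,
              if (x$all_lesions_excluded) " [all lesions excluded]" else ""))
  if (nrow(x$excluded_lesions))
    cat(sprintf("  excluded %d lesion(s) under the volume threshold\n",
                nrow(x$excluded_lesions)))
  invisible(x)
}

#' Run the pipeline over a cohort
#'
#' Executes [run_case()] per case with failure isolation (one corrupt case
#' is logged and skipped, never aborts the cohort) and assembles the cohort
#' comparison tables.
#'
#' @param cases List of `patient_case` objects, or a directory-manifest
#'   data.frame with a `path` column of case directories for [read_case()].
#' @param config A [sirt_config()].
#' @return A `sirt_cohort`: `results` (per-case `case_result`s), `tables`
#'   (see [cohort_tables()]), `failures` (named character of error
#'   messages), `config`.
#' @export
run_cohort <- function(cases, config = sirt_config()) {
  if (is.data.frame(cases)) {
    paths <- cases$path
    cases <- lapply(paths, function(p) tryCatch(read_case(p),
                                                error = function(e) e))
  }
  results <- list(); failures <- character()
  for (i in seq_along(cases)) {
    out <- if (inherits(cases[[i]], "error")) cases[[i]] else
      tryCatch(run_case(cases[[i]], config), error = function(e) e)
    if (inherits(out, "error")) {
      id <- if (inherits(cases[[i]], "patient_case"))
        cases[[i]]$meta$case_id else sprintf("case_%d", i)
      failures[id] <- conditionMessage(out)
    } else results[[out$case_id]] <- out
  }
  if (length(results) < 2)
    stop("fewer than 2 cases succeeded (",
         length(failures), " failed)")
  structure(list(results = results,
                 tables = cohort_tables(results, config),
                 failures = failures, config = config),
            class = "sirt_cohort")
}

#' @export
print.sirt_cohort <- function(x, ...) {
  cat(sprintf("<sirt_cohort> %d case(s) analysed, %d failed\n",
              length(x$results), length(x$failures)))
  cat("\nMetric comparison (normalized, simulation vs therapy):\n")
  print(x$tables$metrics, digits = 3)
  cat("\nTNR comparison:\n")
  print(x$tables$tnr, digits = 3)
  invisible(x)
}

#' @export
summary.sirt_cohort <- function(object, ...) {
  cat("Cohort summary\n")
  print(object$tables$cohort, digits = 4)
  cat("\nVolume-stratified tumour metrics:\n")
  print(object$tables$strata, digits = 3)
  invisible(object$tables)
}
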