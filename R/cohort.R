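#' Cohort comparison tables
#'
#' Aggregates per-case pipeline records into the four reporting tables of
#' the agreement protocol:
#'
#' * `cohort`: demographic/volume summary, median `[range]` per variable;
#' * `metrics`: per VOI and metric, mean +/- SD for simulation and therapy
#'   (normalized Gy/GBq for dose metrics, % for Vx), two-sided Mann-Whitney
#'   p with significance flag, Pearson r with p and strength category,
#'   therapy-on-simulation OLS slope/intercept (and the reverse
#'   orientation), and the mean `[min-max]` per-case relative difference
#'   (dash-flagged whenever any case has a zero therapy denominator);
#' * `strata`: the tumour metrics `MAD`, `D50`, `D70`, `V120` per tumoral
#'   volume stratum (<= / > threshold);
#' * `tnr`: TNR rows (overall and per stratum, both NTL references) with
#'   Mann-Whitney p, Pearson r and Bland-Altman bias `[95% limits]`
#'   (therapy minus simulation).
#'
#' Statistics for dose metrics are computed on the normalized (Gy/GBq)
#' scale; Vx on its natural % scale.
#'
#' @param results List of `case_result` objects (see [run_case()]).
#' @param config A [sirt_config()].
#' @return A list of data.frames (class `sirt_tables`).
#' @export
cohort_tables <- function(results, config = sirt_config()) {
  if (length(results) < 2) stop("need at least 2 cases")
  rec <- do.call(rbind, lapply(results, `[[`, "record"))
  tnr_rec <- do.call(rbind, lapply(results, `[[`, "tnr"))
  tl_vol <- vapply(results, `[[`, numeric(1), "tl_volume_ml")
  strat <- stratify_by_tumor_volume(tl_vol, config$strata_threshold_ml)
  names(strat) <- names(tl_vol) <- vapply(results, `[[`, character(1),
                                          "case_id")

  metrics_tab <- metric_table(rec, config)
  strata_tab <- do.call(rbind, lapply(levels(strat), function(lv) {
    ids <- names(strat)[strat == lv]
    sub <- rec[rec$case_id %in% ids & rec$voi == "TL" &
                 rec$metric %in% c("MAD", "D50", "D70", "V120"), ]
    if (length(ids) < 2 || nrow(sub) == 0) {
      # empty or single-case stratum: report n with an NA-filled row of the
      # same shape as a populated stratum
      template <- cbind(data.frame(voi = "TL", metric = NA_character_,
                                   scale = NA_character_),
                        compare_paired(c(0, 1, 2), c(0, 1, 2), config))
      template[1, ] <- NA
      return(cbind(stratum = lv, n = length(ids), template))
    }
    cbind(stratum = lv, n = length(ids), metric_table(sub, config))
  }))

  structure(list(cohort = cohort_summary(results),
                 metrics = metrics_tab,
                 strata = strata_tab,
                 tnr = tnr_table(tnr_rec, strat, config)),
            class = "sirt_tables")
}

# pivot a long record into per-(voi, metric) paired samples and compare
metric_table <- function(rec, config) {
  keys <- unique(rec[, c("voi", "metric", "unit")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- rec[rec$voi == k$voi & rec$metric == k$metric, ]
    val <- if (k$unit == "Gy") "value_norm" else "value"
    sim <- sub[sub$arm == "sim", ]
    ther <- sub[sub$arm == "ther", ]
    ids <- intersect(sim$case_id, ther$case_id)
    s <- sim[[val]][match(ids, sim$case_id)]
    t <- ther[[val]][match(ids, ther$case_id)]
    ok <- is.finite(s) & is.finite(t)
    s <- s[ok]; t <- t[ok]
    cmp <- compare_paired(s, t, config)
    cbind(data.frame(voi = k$voi, metric = k$metric,
                     scale = if (k$unit == "Gy") "Gy/GBq" else "%"),
          cmp)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

compare_paired <- function(s, t, config) {
  n <- length(s)
  mw <- mann_whitney_u(s, t, paired = config$paired_test)
  pe <- if (n >= 3 && stats::sd(s) > 0 && stats::sd(t) > 0)
    pearson_with_category(s, t) else list(r = NA, p = NA, category = NA)
  fit <- if (n >= 2 && stats::sd(s) > 0) linear_fit(s, t) else
    list(slope = NA, intercept = NA)
  fit_rev <- if (n >= 2 && stats::sd(t) > 0) linear_fit(t, s) else
    list(slope = NA, intercept = NA)
  rd <- relative_difference_pct(s, t)
  any_undef <- anyNA(rd)
  rdv <- rd[!is.na(rd)]
  data.frame(
    sim_mean = mean(s), sim_sd = stats::sd(s),
    ther_mean = mean(t), ther_sd = stats::sd(t),
    wilcoxon_p = mw$p, significant = mw$significant,
    pearson_r = pe$r, pearson_p = pe$p, r_category = pe$category,
    slope_ther_on_sim = fit$slope, intercept_ther_on_sim = fit$intercept,
    slope_sim_on_ther = fit_rev$slope,
    rel_diff_mean = if (length(rdv)) mean(rdv) else NA_real_,
    rel_diff_min = if (length(rdv)) min(rdv) else NA_real_,
    rel_diff_max = if (length(rdv)) max(rdv) else NA_real_,
    rel_diff_undefined = any_undef,
    n_valid = n)
}

tnr_table <- function(tnr_rec, strat, config) {
  if (nrow(tnr_rec) == 0) return(data.frame())
  groups <- c(list(all = names(strat)),
              split(names(strat), strat))
  rows <- list()
  for (g in names(groups)) {
    ids <- groups[[g]]
    sub <- tnr_rec[tnr_rec$case_id %in% ids, ]
    for (ref in c("tnr_ntlt", "tnr_ntlw")) {
      sim <- sub[sub$arm == "sim", ]
      ther <- sub[sub$arm == "ther", ]
      cids <- intersect(sim$case_id, ther$case_id)
      s <- sim[[ref]][match(cids, sim$case_id)]
      t <- ther[[ref]][match(cids, ther$case_id)]
      ok <- is.finite(s) & is.finite(t)
      s <- s[ok]; t <- t[ok]
      if (length(s) < 2) {
        rows[[paste(g, ref)]] <- data.frame(
          stratum = g, reference = sub("tnr_", "", ref), n = length(s),
          sim_mean = NA, sim_sd = NA, ther_mean = NA, ther_sd = NA,
          wilcoxon_p = NA, significant = NA, pearson_r = NA, pearson_p = NA,
          ba_bias = NA, ba_lower = NA, ba_upper = NA)
        next
      }
      mw <- mann_whitney_u(s, t, paired = config$paired_test)
      pe <- if (length(s) >= 3 && stats::sd(s) > 0 && stats::sd(t) > 0)
        pearson_with_category(s, t) else list(r = NA, p = NA)
      ba <- bland_altman(s, t)
      rows[[paste(g, ref)]] <- data.frame(
        stratum = g, reference = sub("tnr_", "", ref), n = length(s),
        sim_mean = mean(s), sim_sd = stats::sd(s),
        ther_mean = mean(t), ther_sd = stats::sd(t),
        wilcoxon_p = mw$p, significant = mw$significant,
        pearson_r = pe$r, pearson_p = pe$p,
        ba_bias = ba$bias, ba_lower = ba$lower, ba_upper = ba$upper)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

cohort_summary <- function(results) {
  med_range <- function(x) sprintf("%.2f [%.2f-%.2f]", stats::median(x),
                                   min(x), max(x))
  a_inj <- vapply(results, function(r) r$meta$A_injected, numeric(1))
  lsf <- vapply(results, function(r) r$meta$lsf, numeric(1))
  days <- vapply(results, function(r) r$meta$waiting_days, numeric(1))
  lobes <- vapply(results, function(r) r$meta$treated_lobe, character(1))
  vols <- do.call(rbind, lapply(results, `[[`, "volumes_ml"))
  nles <- vapply(results, function(r)
    nrow(r$excluded_lesions) + (r$tl_volume_ml > 0), numeric(1))
  data.frame(
    variable = c("n cases", "Y-90 injected activity (GBq)", "LSF (%)",
                 "waiting period (d)", "treated lobe right, n (%)",
                 "TL (ml)", "NTLt (ml)", "NTLw (ml)", "whole liver (ml)"),
    value = c(sprintf("%d", length(results)),
              med_range(a_inj), med_range(100 * lsf), med_range(days),
              sprintf("%d (%.1f%%)", sum(lobes == "right"),
                      100 * mean(lobes == "right")),
              med_range(vols[, "TL"]), med_range(vols[, "NTLt"]),
              med_range(vols[, "NTLw"]), med_range(vols[, "liver"])))
}

#' @export
print.sirt_tables <- function(x, ...) {
  cat("== Cohort summary ==\n"); print(x$cohort)
  cat("\n== Simulation vs therapy metrics ==\n")
  print(x$metrics, digits = 3)
  cat("\n== Tumoral-volume strata ==\n"); print(x$strata, digits = 3)
  cat("\n== TNR ==\n"); print(x$tnr, digits = 3)
  invisible(x)
}

#' Write cohort tables to CSV
#'
#' @param tables A `sirt_tables` list (or a `sirt_cohort`).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_tables <- function(tables, dir) {
  if (inherits(tables, "sirt_cohort")) tables <- tables$tables
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in c("cohort", "metrics", "strata", "tnr")) {
    p <- file.path(dir, paste0("table_", nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths[nm] <- p
  }
  invisible(paths)
}
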