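#' Per-case relative difference (%)
#'
#' `100 * (sim - ther) / ther`, with a zero therapy value giving `NA`
#' (undefined, excluded from cohort means and flagged in the tables).
#'
#' @param sim,ther Numeric vectors of per-case values.
#' @return Numeric vector of percentages with `NA` where `ther == 0`.
#' @export
relative_difference_pct <- function(sim, ther) {
  stopifnot(length(sim) == length(ther))
  out <- 100 * (sim - ther) / ther
  out[ther == 0] <- NA_real_
  out
}

#' Mann-Whitney U test (two-sided)
#'
#' Unpaired rank-sum comparison of simulation and therapy metric samples via
#' [stats::wilcox.test()]: exact for small tie-free samples, otherwise the
#' normal approximation with tie and continuity corrections. A paired
#' Wilcoxon signed-rank variant is available behind `paired = TRUE` for
#' paired designs; the unpaired test is the primary protocol.
#'
#' @param x,y Numeric samples.
#' @param paired Use the signed-rank test instead.
#' @param alpha Significance level for the flag.
#' @return List: `U` (rank-sum statistic), `p`, `significant`.
#' @export
mann_whitney_u <- function(x, y, paired = FALSE, alpha = 0.05) {
  if (length(x) < 1 || length(y) < 1) stop("empty sample")
  res <- suppressWarnings(stats::wilcox.test(x, y, paired = paired,
                                             correct = TRUE))
  list(U = unname(res$statistic), p = res$p.value,
       significant = res$p.value < alpha)
}

#' Pearson correlation with strength category
#'
#' Sample Pearson `r` with the conventional strength bands on `|r|`:
#' `[0, 0.3)` very weak, `[0.3, 0.5)` weak, `[0.5, 0.7)` moderate,
#' `[0.7, 0.9)` strong, `[0.9, 1]` very strong.
#'
#' @param x,y Numeric vectors (`n >= 3`, non-constant).
#' @return List: `r`, `p`, `category`.
#' @export
pearson_with_category <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  res <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(res$estimate), p = res$p.value,
       category = r_category(unname(res$estimate)))
}

#' @rdname pearson_with_category
#' @param r Correlation coefficient.
#' @export
r_category <- function(r) {
  a <- abs(r)
  if (a > 1) stop("|r| must be <= 1")
  bands <- c("very weak", "weak", "moderate", "strong", "very strong")
  # half-open bands [0,0.3), [0.3,0.5), [0.5,0.7), [0.7,0.9), [0.9,1]
  bands[min(findInterval(a, c(0, 0.3, 0.5, 0.7, 0.9)), 5L)]
}

#' Ordinary least-squares line
#'
#' Fits `y ~ x` with intercept. Cohort regressions orient therapy on
#' simulation by default; both orientations are reported where the
#' direction matters.
#'
#' @param x,y Numeric vectors, `n >= 2`, `x` non-constant.
#' @return List: `slope`, `intercept`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) < 2) stop("need at least 2 points")
  if (stats::sd(x) == 0) stop("degenerate x: zero variance")
  co <- stats::coef(stats::lm(y ~ x))
  list(slope = unname(co[2]), intercept = unname(co[1]))
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Differences are oriented therapy minus simulation, so a negative bias
#' means the simulation overestimates. Limits are `bias +/- 1.96 * SD` with
#' the sample (n-1) standard deviation.
#'
#' @param sim,ther Numeric vectors, `n >= 2`.
#' @return List: `bias`, `lower`, `upper`, `sd`.
#' @export
bland_altman <- function(sim, ther) {
  stopifnot(length(sim) == length(ther))
  if (length(sim) < 2) stop("need at least 2 pairs")
  d <- ther - sim
  s <- stats::sd(d)
  list(bias = mean(d), lower = mean(d) - 1.96 * s,
       upper = mean(d) + 1.96 * s, sd = s)
}

#' Kruskal-Wallis test across groups
#'
#' Tie-corrected H with a chi-squared p on k-1 degrees of freedom, via
#' [stats::kruskal.test()]. Used to probe discrete covariates (sex, treated
#' lobe, lesion count, volume stratum) against per-case metric differences.
#'
#' @param groups List of numeric vectors (>= 2 non-empty groups).
#' @return List: `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("need at least 2 non-empty groups")
  res <- stats::kruskal.test(groups)
  list(H = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter))
}

#' Stratify cases by tumoral-liver volume
#'
#' Two strata at the threshold (inclusive on the small side):
#' `small` = TL volume <= threshold, `large` = TL volume > threshold.
#'
#' @param tl_volume_ml Numeric vector of per-case TL volumes.
#' @param threshold_ml Stratum boundary in ml.
#' @return Factor with levels `small`, `large`.
#' @export
stratify_by_tumor_volume <- function(tl_volume_ml, threshold_ml = 200) {
  stopifnot(threshold_ml > 0)
  factor(ifelse(tl_volume_ml <= threshold_ml, "small", "large"),
         levels = c("small", "large"))
}

#' Voxel-wise joint histogram and fitted line
#'
#' 2-D histogram of paired (simulation dose, therapy dose) voxel values over
#' a mask, with OLS lines fitted on the raw voxel pairs in both
#' orientations: `slope_ther_on_sim` (therapy regressed on simulation; below
#' one when the simulation overestimates) and `slope_sim_on_ther` (the
#' converse; above one under simulation overestimation).
#'
#' @param sim_map,ther_map Dose maps ([scalar_map]) on a common grid.
#' @param mask Non-empty logical mask.
#' @param n_bins Histogram bins per axis.
#' @return List: `counts` (n_bins x n_bins matrix), `sim_breaks`,
#'   `ther_breaks`, `slope_ther_on_sim`, `slope_sim_on_ther`,
#'   `intercept_ther_on_sim`, `n_voxels`.
#' @export
voxelwise_joint <- function(sim_map, ther_map, mask, n_bins = 64) {
  stopifnot(inherits(sim_map, "scalar_map"), inherits(ther_map, "scalar_map"))
  if (!any(mask)) stop("empty mask")
  s <- sim_map$values[mask]
  t <- ther_map$values[mask]
  lim <- range(c(s, t))
  if (diff(lim) == 0) lim <- lim + c(0, 1)
  br <- seq(lim[1], lim[2], length.out = n_bins + 1)
  bi <- findInterval(s, br, rightmost.closed = TRUE, all.inside = TRUE)
  bj <- findInterval(t, br, rightmost.closed = TRUE, all.inside = TRUE)
  tab <- table(factor(bi, levels = 1:n_bins), factor(bj, levels = 1:n_bins))
  counts <- matrix(as.integer(tab), n_bins, n_bins)
  f1 <- linear_fit(s, t)
  f2 <- linear_fit(t, s)
  list(counts = counts, sim_breaks = br, ther_breaks = br,
       slope_ther_on_sim = f1$slope, intercept_ther_on_sim = f1$intercept,
       slope_sim_on_ther = f2$slope, n_voxels = length(s))
}
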