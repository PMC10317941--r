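#' Parameters for a synthetic paired-SPECT phantom case
#'
#' Defines the study conditions for one simulated treatment: an ellipsoidal
#' liver split into two lobes by a sagittal plane, spherical lesions inside
#' the treated lobe, a latent specific-uptake field with multiplicative
#' lognormal heterogeneity, Gaussian PSF blur, Poisson counting noise, and
#' a controlled simulation-versus-therapy discordance.
#'
#' The latent uptake is 1 (mean-corrected lognormal, `sdlog = sigma_n`) in
#' non-tumoral liver and `tnr_true` times a mean-corrected lognormal
#' (`sdlog = sigma_t`) in tumoral liver, so `tnr_true` is the expected
#' specific-uptake ratio. The simulation arm multiplies the therapy latent
#' field by a voxel-wise mean-corrected lognormal discordance (`tau_t` in
#' tumour, `tau_n` elsewhere) and by a tumour uptake bias. `bias_T`
#' parameterizes the observable post-calibration tumour dose bias: because
#' self-calibration fixes the total liver activity and the PSF spills
#' tumour counts outwards, the generator solves the linear forward model
#' (blur included) for the pre-calibration tumour factor that makes the
#' expected calibrated tumour dose ratio simulation/therapy equal `bias_T`
#' independent of tumour burden and resolution; without blur this reduces
#' to `f = bias_T (1 - s) / (1 - bias_T s)` with `s` the tumour uptake
#' share.
#'
#' @param shape,spacing Grid shape and voxel spacing (mm); default 64^3 at
#'   4 mm.
#' @param liver_semiaxes Ellipsoid semi-axes in mm (default gives ~1.84 l).
#' @param lobe_plane_frac Sagittal split plane as a fraction of the first
#'   semi-axis, measured from the liver centre; the treated (right) lobe is
#'   `x >= centre + frac * a` (default -0.25, right lobe ~ 2/3 of liver).
#' @param tumors List of `list(center = mm offsets from liver centre,
#'   radius_mm)` spheres; must lie inside the liver.
#' @param tnr_true Expected tumour-to-normal specific-uptake ratio.
#' @param sigma_n,sigma_t Lognormal heterogeneity sdlog for normal/tumour
#'   tissue.
#' @param tau_n,tau_t Voxel-wise lognormal simulation-therapy discordance
#'   sdlog for normal/tumour tissue.
#' @param bias_T Post-calibration tumour dose bias of the simulation arm
#'   (1 = unbiased; 1.26 reproduces a 26% tumour overestimation).
#' @param psf_fwhm_mm Isotropic Gaussian PSF FWHM in mm applied to expected
#'   counts before Poisson sampling (0 disables). `psf_fwhm_ther_mm` lets
#'   the therapy arm use a wider PSF (bremsstrahlung imaging has poorer
#'   resolution); defaults to `psf_fwhm_mm`.
#' @param psf_fwhm_ther_mm Therapy-arm PSF FWHM in mm.
#' @param count_scale Expected total counts per map.
#' @param poisson Draw Poisson counts (`FALSE` = expected-count mode).
#' @param A_injected_GBq,residual_fraction,lsf,treated_lobe,waiting_days
#'   Metadata for the activity record.
#' @param seed Integer seed; the whole case is reproducible from it.
#' @return A validated `phantom_params` list.
#' @export
phantom_params <- function(shape = c(64, 64, 64), spacing = c(4, 4, 4),
                           liver_semiaxes = c(100, 80, 55),
                           lobe_plane_frac = -0.25,
                           tumors = list(list(center = c(35, 12, 0),
                                              radius_mm = 35)),
                           tnr_true = 2.3,
                           sigma_n = 0.3, sigma_t = 0.5,
                           tau_n = 0.15, tau_t = 0.4,
                           bias_T = 1,
                           psf_fwhm_mm = 12, psf_fwhm_ther_mm = NULL,
                           count_scale = 3e6, poisson = TRUE,
                           A_injected_GBq = 2.6, residual_fraction = 0.02,
                           lsf = 0.08, treated_lobe = "right",
                           waiting_days = 20, seed = 1L) {
  if (is.null(psf_fwhm_ther_mm)) psf_fwhm_ther_mm <- psf_fwhm_mm
  p <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
            liver_semiaxes = liver_semiaxes,
            lobe_plane_frac = lobe_plane_frac, tumors = tumors,
            tnr_true = tnr_true, sigma_n = sigma_n, sigma_t = sigma_t,
            tau_n = tau_n, tau_t = tau_t, bias_T = bias_T,
            psf_fwhm_mm = psf_fwhm_mm, psf_fwhm_ther_mm = psf_fwhm_ther_mm,
            count_scale = count_scale, poisson = isTRUE(poisson),
            A_injected_GBq = A_injected_GBq,
            residual_fraction = residual_fraction, lsf = lsf,
            treated_lobe = treated_lobe, waiting_days = waiting_days,
            seed = as.integer(seed))
  stopifnot(p$tnr_true > 0, p$sigma_n >= 0, p$sigma_t >= 0,
            p$tau_n >= 0, p$tau_t >= 0, p$bias_T > 0, p$count_scale > 0,
            p$A_injected_GBq > 0, p$residual_fraction >= 0,
            p$residual_fraction < 1, all(p$liver_semiaxes > 0),
            p$psf_fwhm_mm >= 0, p$psf_fwhm_ther_mm >= 0)
  structure(p, class = "phantom_params")
}

# Separable Gaussian blur on a 3-D array; fwhm in mm, zero-padded edges.
gaussian_blur <- function(arr, fwhm_mm, spacing) {
  if (fwhm_mm <= 0) return(arr)
  d <- dim(arr)
  for (ax in 1:3) {
    sd_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing[ax]
    r <- ceiling(3 * sd_vox)
    k <- stats::dnorm(-r:r, sd = sd_vox)
    k <- k / sum(k)
    n <- d[ax]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- k[ok]
    }
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(arr, perm)
    dm <- dim(m)
    dim(m) <- c(dm[1], dm[2] * dm[3])
    m <- K %*% m
    dim(m) <- dm
    arr <- aperm(m, order(perm))
  }
  arr
}

# Pre-calibration tumour uptake factor f achieving an expected
# post-calibration, post-blur tumour dose bias of bias_T. Blur is linear,
# so with S_T = sum_TL blur(u), C = sum_TL blur(u 1_TL), L = sum_liv blur(u)
# and C_L = sum_liv blur(u 1_TL) (sim-arm PSF; therapy-arm sums analogous),
# the expected calibrated TL bias is
#   [S_T + (f-1) C] / [L + (f-1) C_L]  :  [S_T' / L']
# which is linear in f. Reduces to f = b(1-s)/(1-bs) without blur.
solve_tumor_factor <- function(u, TL, liver, bias_T, fwhm_sim, fwhm_ther,
                               spacing) {
  if (bias_T == 1) return(1)
  uT <- u
  uT[!TL] <- 0
  bs_u <- gaussian_blur(u, fwhm_sim, spacing)
  bs_uT <- gaussian_blur(uT, fwhm_sim, spacing)
  bt_u <- if (fwhm_ther == fwhm_sim) bs_u else
    gaussian_blur(u, fwhm_ther, spacing)
  S_T <- sum(bs_u[TL]); C <- sum(bs_uT[TL])
  L <- sum(bs_u[liver]); C_L <- sum(bs_uT[liver])
  beta <- bias_T * sum(bt_u[TL]) / sum(bt_u[liver])
  denom <- C - beta * C_L
  if (denom <= 0)
    stop("bias_T too large for this tumour burden and PSF")
  f <- 1 + (beta * L - S_T) / denom
  if (f <= 0) stop("bias_T infeasible for this geometry")
  f
}

ellipsoid_mask <- function(grid, center_mm, semiaxes_mm) {
  cx <- axis_coords(grid, 1); cy <- axis_coords(grid, 2)
  cz <- axis_coords(grid, 3)
  sh <- grid$shape
  X <- rep((cx - center_mm[1]) / semiaxes_mm[1], times = sh[2] * sh[3])
  Y <- rep(rep((cy - center_mm[2]) / semiaxes_mm[2], each = sh[1]),
           times = sh[3])
  Z <- rep((cz - center_mm[3]) / semiaxes_mm[3], each = sh[1] * sh[2])
  m <- array(X^2 + Y^2 + Z^2 <= 1, sh)
  attr(m, "grid") <- grid
  m
}

#' Generate one synthetic paired simulation/therapy case
#'
#' Builds masks (ellipsoidal liver, half-space lobe, spherical lesions),
#' draws the latent uptake and discordance fields, blurs, normalizes to the
#' expected total counts and Poisson-samples both arms. Deterministic under
#' `params$seed`.
#'
#' @param params A [phantom_params()] list.
#' @return A `patient_case` with `sim_counts`, `ther_counts`, `masks`
#'   (`liver`, `lobe`, `lesions`), `meta`, and a `ground_truth` element
#'   holding the noiseless latent uptake map, the applied tumour factor,
#'   and the realized specific-uptake TNRs.
#' @export
generate_case <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  set.seed(p$seed)
  grid <- voxel_grid(p$shape, p$spacing)
  center <- p$origin_center <- (p$shape - 1) * p$spacing / 2
  liver <- ellipsoid_mask(grid, center, p$liver_semiaxes)
  if (!any(liver)) stop("degenerate geometry: empty liver")

  cx <- axis_coords(grid, 1)
  plane <- center[1] + p$lobe_plane_frac * p$liver_semiaxes[1]
  right <- array(rep(cx >= plane, times = p$shape[2] * p$shape[3]), p$shape)
  lobe <- if (identical(p$treated_lobe, "right")) right else (!right)
  lobe <- lobe & liver  # lobe contour clipped to liver in the phantom
  attr(lobe, "grid") <- grid

  lesions <- lapply(p$tumors, function(tu) {
    ctr <- center + tu$center
    # containment check against the shrunken ellipsoid
    shr <- p$liver_semiaxes - tu$radius_mm
    if (any(shr <= 0) || sum((tu$center / shr)^2) > 1)
      stop("tumour sphere extends outside the liver")
    ellipsoid_mask(grid, ctr, rep(tu$radius_mm, 3))
  })
  TL <- array(FALSE, p$shape)
  for (m in lesions) TL <- TL | m
  if (any(TL & !liver)) stop("tumour voxels outside the liver mask")

  ntl <- liver & !TL
  # latent specific uptake (therapy truth), mean-corrected lognormal
  u <- array(0, p$shape)
  u[ntl] <- stats::rlnorm(sum(ntl), -p$sigma_n^2 / 2, p$sigma_n)
  u[TL] <- p$tnr_true * stats::rlnorm(sum(TL), -p$sigma_t^2 / 2, p$sigma_t)

  # simulation arm: voxelwise discordance + tumour bias chosen so the
  # post-calibration tumour dose ratio is bias_T in expectation
  disc <- array(1, p$shape)
  disc[ntl] <- stats::rlnorm(sum(ntl), -p$tau_n^2 / 2, p$tau_n)
  disc[TL] <- stats::rlnorm(sum(TL), -p$tau_t^2 / 2, p$tau_t)
  s <- sum(u[TL]) / sum(u[liver])
  f <- solve_tumor_factor(u, TL, liver, p$bias_T,
                          p$psf_fwhm_mm, p$psf_fwhm_ther_mm, p$spacing)
  u_sim <- u * disc
  u_sim[TL] <- u_sim[TL] * f

  expected_counts <- function(lat, fwhm) {
    ec <- gaussian_blur(lat, fwhm, p$spacing)
    ec[ec < 0] <- 0
    ec * (p$count_scale / sum(ec))
  }
  ec_ther <- expected_counts(u, p$psf_fwhm_ther_mm)
  ec_sim <- expected_counts(u_sim, p$psf_fwhm_mm)
  draw <- function(ec) {
    v <- if (p$poisson) array(stats::rpois(length(ec), ec), dim(ec)) else ec
    scalar_map(v, grid, kind = "counts")
  }
  sim_counts <- draw(ec_sim)
  ther_counts <- draw(ec_ther)

  gt_tnr <- function(lat) {
    (mean(lat[TL])) / (mean(lat[ntl]))
  }
  gt <- list(latent = scalar_map(u, grid, kind = "other"),
             latent_sim = scalar_map(u_sim, grid, kind = "other"),
             tumor_factor = f, tumor_share = s,
             tnr_ntlw = gt_tnr(u),
             tnr_ntlt = mean(u[TL]) / mean(u[lobe & liver & !TL]),
             params = p)

  structure(list(
    sim_counts = sim_counts, ther_counts = ther_counts,
    masks = list(liver = liver, lobe = lobe, lesions = lesions),
    meta = list(case_id = sprintf("phantom_%06d", p$seed),
                A_injected = p$A_injected_GBq,
                A_residual = p$A_injected_GBq * p$residual_fraction,
                lsf = p$lsf, treated_lobe = p$treated_lobe,
                waiting_days = p$waiting_days),
    ground_truth = gt),
    class = "patient_case")
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("<patient_case> %s: %d lesion(s), A_injected %.2f GBq, lobe %s\n",
              x$meta$case_id, length(x$masks$lesions), x$meta$A_injected,
              x$meta$treated_lobe))
  invisible(x)
}

#' Ground-truth metric panel for a synthetic case
#'
#' Recomputes the per-VOI panel and TNRs from the noiseless latent uptake
#' field under exact calibration (no blur, no Poisson noise): the recovery
#' target for pipeline validation.
#'
#' @param case A `patient_case` from [generate_case()].
#' @param config A [sirt_config()]; controls constants and activity options.
#' @return List: `panel` (as [metrics_panel()]), `tnr_ntlt`, `tnr_ntlw`,
#'   `A_net_GBq`.
#' @export
ground_truth_metrics <- function(case, config = sirt_config()) {
  if (is.null(case$ground_truth))
    stop("case carries no ground truth (not generated by this package)")
  lat <- case$ground_truth$latent
  lat <- scalar_map(lat$values, lat$grid, kind = "counts")
  lesions <- exclude_small_lesions(case$masks$lesions,
                                   grid = lat$grid,
                                   min_ml = config$min_lesion_ml,
                                   quiet = TRUE)
  vois <- derive_vois(case$masks$liver, case$masks$lobe, lesions,
                      grid = lat$grid)
  A_net <- net_activity(case$meta$A_injected, case$meta$A_residual,
                        case$meta$lsf, apply_lsf = config$apply_lsf,
                        use_residual = config$use_residual)
  act <- self_calibrate(lat, vois$masks$liver, A_net)
  dose <- ldm_dose_map(act, config$constants)
  panel <- metrics_panel(dose, vois, A_net)
  tt <- if (any(vois$masks$TL)) {
    list(t = tnr(act, vois$masks$TL, vois$masks$NTLt,
                 config$constants$density)$tnr,
         w = tnr(act, vois$masks$TL, vois$masks$NTLw,
                 config$constants$density)$tnr)
  } else list(t = NA_real_, w = NA_real_)
  list(panel = panel, tnr_ntlt = tt$t, tnr_ntlw = tt$w, A_net_GBq = A_net)
}

#' Generate a synthetic cohort of paired cases
#'
#' Per-case parameters are drawn once from cohort distributions emulating a
#' retrospective glass-microsphere series: injected activity lognormal
#' around 2.6 GBq, single dominant lesion (sometimes 2-3), tumoral volumes
#' lognormal around 180 ml spanning both volume strata, expected TNR
#' lognormal around 2.3, treated lobe mostly right, and a per-case tumour
#' bias drawn as a mean-corrected lognormal around `bias_T_mean`
#' (`sdlog = sigma_bias`) representing case-level catheter/flow
#' discordance. Reproducible from `seed`.
#'
#' @param n Number of cases (>= 1).
#' @param seed Integer seed.
#' @param bias_T_mean Expected post-calibration tumour dose bias of the
#'   simulation arm.
#' @param sigma_bias sdlog of the per-case tumour bias.
#' @param base_params A [phantom_params()] supplying every parameter not
#'   drawn per case (grid, PSF, heterogeneity, count scale, ...).
#' @return List of `patient_case` objects (class `phantom_cohort`).
#' @export
generate_cohort <- function(n, seed = 1L, bias_T_mean = 1.26,
                            sigma_bias = 0.18,
                            base_params = phantom_params()) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  a_inj <- pmin(pmax(stats::rlnorm(n, log(2.6), 0.45), 0.7), 6)
  resid <- stats::runif(n, 0.005, 0.04)
  lsf <- stats::runif(n, 0.01, 0.15)
  days <- pmin(pmax(round(stats::rnorm(n, 21, 7)), 9), 47)
  side <- sample(c("right", "left"), n, replace = TRUE, prob = c(0.75, 0.25))
  liver_scale <- stats::rlnorm(n, 0, 0.12)  # liver volume spread ~ x0.5-x2
  v_tl <- pmin(pmax(stats::rlnorm(n, log(180), 0.6), 8), 450)
  tnr_t <- pmin(pmax(stats::rlnorm(n, log(2.3), 0.5), 1.2), 8)
  nles <- sample(1:3, n, replace = TRUE, prob = c(0.77, 0.15, 0.08))
  bias <- pmin(bias_T_mean * stats::rlnorm(n, -sigma_bias^2 / 2, sigma_bias),
               2.2)
  seeds <- sample.int(.Machine$integer.max - 1L, n)

  lapply(seq_len(n), function(i) {
    ax <- base_params$liver_semiaxes * liver_scale[i]
    liver_ml <- 4 / 3 * pi * prod(ax) / 1000
    # large tumours have lower uptake ratios, and a tumour-dominated count
    # budget leaves no headroom for a post-calibration overestimation bias:
    # cap the tumour volume, and cap the uptake share s = TNR V_T / (TNR V_T
    # + V_N) so that bias_i * s <= 0.6 stays feasible under PSF spill-out
    v_i <- min(v_tl[i], 0.35 * liver_ml)
    s_max <- 0.6 / max(bias[i], 1)
    ratio_max <- s_max / (1 - s_max)
    tnr_i <- max(1.2, min(tnr_t[i], ratio_max * (liver_ml - v_i) / v_i))
    splits <- list(1, c(0.8, 0.2), c(0.7, 0.2, 0.1))[[nles[i]]]
    vols <- v_i * splits
    radii <- pmin((3 * vols * 1000 / (4 * pi))^(1 / 3), 0.8 * min(ax))
    sgn <- if (side[i] == "right") 1 else -1
    offs <- list(c(0.35, 0.15, 0), c(0.38, -0.35, 0.1), c(0.30, 0.45, -0.2))
    tumors <- lapply(seq_along(radii), function(k) {
      ctr <- offs[[k]] * ax
      ctr[1] <- sgn * abs(ctr[1])
      # pull the centre inwards until the sphere fits in the liver
      shr <- ax - radii[k]
      q <- sqrt(sum((ctr / shr)^2))
      if (q > 0.95) ctr <- ctr * (0.95 / q)
      list(center = ctr, radius_mm = radii[k])
    })
    p <- base_params
    p$liver_semiaxes <- ax
    p$tumors <- tumors
    p$tnr_true <- tnr_i
    p$bias_T <- bias[i]
    p$A_injected_GBq <- a_inj[i]
    p$residual_fraction <- resid[i]
    p$lsf <- lsf[i]
    p$treated_lobe <- side[i]
    p$waiting_days <- days[i]
    p$seed <- seeds[i]
    case <- generate_case(p)
    case$meta$case_id <- sprintf("case_%03d", i)
    case
  }) -> cases
  structure(cases, class = c("phantom_cohort", "list"))
}
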