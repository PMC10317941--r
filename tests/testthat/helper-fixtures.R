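# In-code fixtures shared across test files.

# small grid/map builders -----------------------------------------------

tiny_grid <- function(shape = c(4, 4, 4), spacing = c(2, 2, 2),
                      origin = c(0, 0, 0)) {
  voxel_grid(shape, spacing, origin)
}

const_map <- function(value, grid = tiny_grid(), kind = "counts") {
  scalar_map(array(value, grid$shape), grid, kind = kind)
}

# a dose map holding the given voxel doses (padded with zeros) and a mask
# selecting exactly those voxels
dose_fixture <- function(doses, spacing = c(10, 10, 10)) {
  n <- length(doses)
  shape <- c(n, 1, 1)
  g <- voxel_grid(shape, spacing)
  map <- scalar_map(array(doses, shape), g, kind = "dose_Gy")
  mask <- array(TRUE, shape)
  attr(mask, "grid") <- g
  list(map = map, mask = mask, grid = g)
}

# axis-aligned box mask [i1..i2, j1..j2, k1..k2] on a grid
box_mask <- function(grid, i, j, k) {
  m <- array(FALSE, grid$shape)
  m[i, j, k] <- TRUE
  attr(m, "grid") <- grid
  m
}

# sphere mask of given radius (mm) centred at centre (mm)
sphere_mask <- function(grid, center_mm, radius_mm) {
  cx <- grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1]
  cy <- grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2]
  cz <- grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3]
  sh <- grid$shape
  X <- rep(cx - center_mm[1], times = sh[2] * sh[3])
  Y <- rep(rep(cy - center_mm[2], each = sh[1]), times = sh[3])
  Z <- rep(cz - center_mm[3], each = sh[1] * sh[2])
  m <- array(X^2 + Y^2 + Z^2 <= radius_mm^2, sh)
  attr(m, "grid") <- grid
  m
}

# small phantom parameters for fast unit tests (32^3 at 8 mm keeps the
# 256 mm field of view of the default geometry)
small_phantom_params <- function(...) {
  phantom_params(shape = c(32, 32, 32), spacing = c(8, 8, 8), ...)
}

noiseless_params <- function(...) {
  small_phantom_params(sigma_n = 0, sigma_t = 0, tau_n = 0, tau_t = 0,
                       bias_T = 1, psf_fwhm_mm = 0, poisson = FALSE, ...)
}
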