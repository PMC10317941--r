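#' Resample a map or mask onto a reference grid
#'
#' Maps every voxel centre of `ref_grid` into the input volume's continuous
#' index space through world (mm) coordinates and interpolates. Continuous
#' maps should use trilinear interpolation, binary masks nearest-neighbour
#' (preserves binarity). Voxels of the reference grid falling outside the
#' input extent become 0 (FALSE for masks).
#'
#' @param map A [scalar_map], or a logical mask array with a `grid`
#'   attribute.
#' @param ref_grid Target [voxel_grid].
#' @param mode `"trilinear"` or `"nearest"`. Defaults to `"nearest"` for
#'   masks and `"trilinear"` otherwise.
#' @return A [scalar_map] on `ref_grid` (or a logical mask with `grid`
#'   attribute if the input was a mask).
#' @export
resample_to_reference <- function(map, ref_grid, mode = NULL) {
  is_mask <- is.logical(map)
  if (is_mask) {
    grid <- attr(map, "grid")
    stopifnot(inherits(grid, "voxel_grid"))
    src <- scalar_map(array(as.numeric(map), dim(map)), grid, kind = "other")
  } else {
    stopifnot(inherits(map, "scalar_map"))
    src <- map
  }
  if (is.null(mode)) mode <- if (is_mask) "nearest" else "trilinear"
  mode <- match.arg(mode, c("nearest", "trilinear"))
  stopifnot(inherits(ref_grid, "voxel_grid"))

  if (same_grid(src$grid, ref_grid)) {
    out <- src$values
  } else {
    check_overlap(src$grid, ref_grid)
    # continuous (1-based) index of each reference voxel centre in src space
    ci <- lapply(1:3, function(ax)
      (axis_coords(ref_grid, ax) - src$grid$origin[ax]) /
        src$grid$spacing[ax] + 1)
    sh <- ref_grid$shape
    ix <- rep(ci[[1]], times = sh[2] * sh[3])
    iy <- rep(rep(ci[[2]], each = sh[1]), times = sh[3])
    iz <- rep(ci[[3]], each = sh[1] * sh[2])
    out <- if (mode == "nearest") {
      gather_nearest(src$values, ix, iy, iz)
    } else {
      gather_trilinear(src$values, ix, iy, iz)
    }
    dim(out) <- sh
  }
  if (is_mask) {
    m <- out > 0.5
    attr(m, "grid") <- ref_grid
    m
  } else {
    scalar_map(out, ref_grid, kind = src$kind)
  }
}

check_overlap <- function(a, b) {
  for (ax in 1:3) {
    alo <- a$origin[ax] - a$spacing[ax] / 2
    ahi <- a$origin[ax] + (a$shape[ax] - 0.5) * a$spacing[ax]
    blo <- b$origin[ax] - b$spacing[ax] / 2
    bhi <- b$origin[ax] + (b$shape[ax] - 0.5) * b$spacing[ax]
    if (ahi < blo || bhi < alo)
      stop("input and reference grids have disjoint spatial extents")
  }
  invisible(TRUE)
}

gather_nearest <- function(vals, ix, iy, iz) {
  d <- dim(vals)
  rx <- round(ix); ry <- round(iy); rz <- round(iz)
  ok <- rx >= 1 & rx <= d[1] & ry >= 1 & ry <= d[2] & rz >= 1 & rz <= d[3]
  out <- numeric(length(ix))
  lin <- (rz[ok] - 1) * d[1] * d[2] + (ry[ok] - 1) * d[1] + rx[ok]
  out[ok] <- vals[lin]
  out
}

gather_trilinear <- function(vals, ix, iy, iz) {
  d <- dim(vals)
  x0 <- floor(ix); y0 <- floor(iy); z0 <- floor(iz)
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  out <- numeric(length(ix))
  # fetch with out-of-range corners contributing 0
  corner <- function(cx, cy, cz) {
    ok <- cx >= 1 & cx <= d[1] & cy >= 1 & cy <= d[2] & cz >= 1 & cz <= d[3]
    v <- numeric(length(cx))
    lin <- (cz[ok] - 1) * d[1] * d[2] + (cy[ok] - 1) * d[1] + cx[ok]
    v[ok] <- vals[lin]
    v
  }
  out <- out + corner(x0,     y0,     z0)     * (1 - fx) * (1 - fy) * (1 - fz)
  out <- out + corner(x0 + 1, y0,     z0)     * fx       * (1 - fy) * (1 - fz)
  out <- out + corner(x0,     y0 + 1, z0)     * (1 - fx) * fy       * (1 - fz)
  out <- out + corner(x0 + 1, y0 + 1, z0)     * fx       * fy       * (1 - fz)
  out <- out + corner(x0,     y0,     z0 + 1) * (1 - fx) * (1 - fy) * fz
  out <- out + corner(x0 + 1, y0,     z0 + 1) * fx       * (1 - fy) * fz
  out <- out + corner(x0,     y0 + 1, z0 + 1) * (1 - fx) * fy       * fz
  out <- out + corner(x0 + 1, y0 + 1, z0 + 1) * fx       * fy       * fz
  out
}
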