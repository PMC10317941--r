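#' Rectilinear voxel grid
#'
#' Geometry of a 3-D image: array shape, voxel spacing (mm), world origin of
#' the first voxel centre (mm), and direction cosines. Only axis-aligned
#' grids (identity direction matrix) are supported.
#'
#' @param shape Integer vector of length 3, array dimensions (all >= 1).
#' @param spacing Numeric vector of length 3, voxel edge lengths in mm (> 0).
#' @param origin Numeric vector of length 3, world coordinate (mm) of the
#'   centre of voxel (1,1,1).
#' @param direction 3x3 direction-cosine matrix; must be the identity.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(64, 64, 64), spacing = c(4, 4, 4))
#' voxel_volume_ml(g)
#' @export
voxel_grid <- function(shape, spacing, origin = c(0, 0, 0),
                       direction = diag(3)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(shape) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(shape < 1L)) stop("grid shape components must be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel spacings must be finite and > 0")
  if (any(!is.finite(origin))) stop("grid origin must be finite")
  direction <- as.matrix(direction)
  if (!isTRUE(all.equal(direction, diag(3), tolerance = 1e-6)))
    stop("only axis-aligned grids (identity direction matrix) are supported")
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 direction = diag(3)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d, spacing %.4g x %.4g x %.4g mm, origin (%.4g, %.4g, %.4g)\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Voxel volume in millilitres
#'
#' @param grid A [voxel_grid].
#' @return Volume of one voxel in ml (`prod(spacing)/1000`).
#' @export
voxel_volume_ml <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  prod(grid$spacing) / 1000
}

#' @rdname voxel_grid
#' @param a,b Two `voxel_grid` objects.
#' @export
same_grid <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-6))
}

#' Per-voxel scalar volume
#'
#' A 3-D array of per-voxel values on a [voxel_grid], tagged with a physical
#' kind. Counts, activity and dose are physically non-negative: negative
#' values (e.g. reconstruction ringing) are clamped to zero; non-finite
#' values are an error.
#'
#' @param values 3-D numeric array matching `grid$shape`.
#' @param grid A [voxel_grid].
#' @param kind One of `"counts"`, `"activity_Bq"`, `"dose_Gy"`, `"other"`.
#' @return An object of class `scalar_map` with fields `values`, `grid`,
#'   `kind`.
#' @export
scalar_map <- function(values, grid, kind = c("counts", "activity_Bq",
                                              "dose_Gy", "other")) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "voxel_grid"))
  values <- as.array(values)
  if (length(dim(values)) != 3L || !all(dim(values) == grid$shape))
    stop("values must be a 3-D array matching the grid shape")
  if (any(!is.finite(values))) stop("scalar map contains non-finite values")
  if (kind != "other" && any(values < 0)) values[values < 0] <- 0
  structure(list(values = values, grid = grid, kind = kind),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  cat(sprintf("<scalar_map:%s> ", x$kind))
  print(x$grid)
  v <- x$values
  cat(sprintf("  values: min %.4g, mean %.4g, max %.4g, sum %.6g\n",
              min(v), mean(v), max(v), sum(v)))
  invisible(x)
}

# World coordinates (mm) of voxel centres along one axis.
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}
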