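#' Read and write 3-D volumes as NIfTI
#'
#' Thin wrappers around RNifti preserving the grid geometry (spacing via
#' pixdim, origin via the sform). Grids must be axis-aligned.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param kind Physical kind of the values, as in [scalar_map()]. Counts,
#'   activity and dose maps have negative voxels clamped to zero at load.
#' @return `load_map` returns a [scalar_map]; `load_mask` returns a logical
#'   3-D array with attribute `grid`.
#' @seealso [write_map()]
#' @export
load_map <- function(path, kind = "counts") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- array(as.vector(arr), dim(arr))  # drop RNifti attributes
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D volume, got ", length(dim(arr)), " dimensions: ", path)
  if (any(!is.finite(arr)))
    stop("volume contains non-finite values: ", path)
  grid <- grid_from_nifti(img, dim(arr))
  scalar_map(arr, grid, kind = kind)
}

#' @rdname load_map
#' @export
load_mask <- function(path) {
  m <- load_map(path, kind = "other")
  mask <- m$values > 0.5
  attr(mask, "grid") <- m$grid
  mask
}

#' @rdname load_map
#' @param map A [scalar_map] (or a logical mask array with a `grid`
#'   attribute, which is written as 0/1).
#' @export
write_map <- function(map, path) {
  if (is.logical(map)) {
    grid <- attr(map, "grid")
    stopifnot(inherits(grid, "voxel_grid"))
    map <- scalar_map(array(as.numeric(map), dim(map)), grid, kind = "other")
  }
  stopifnot(inherits(map, "scalar_map"))
  arr <- map$values
  attr(arr, "pixdim") <- map$grid$spacing
  img <- RNifti::asNifti(arr, datatype = "double")
  m <- diag(c(map$grid$spacing, 1))
  m[1:3, 4] <- map$grid$origin
  sf <- structure(m, code = 2L)
  img <- RNifti::`sform<-`(img, sf)
  img <- RNifti::`qform<-`(img, sf)
  RNifti::writeNifti(img, path)
  invisible(path)
}

grid_from_nifti <- function(img, shape) {
  x <- RNifti::xform(img)
  sp <- RNifti::pixdim(img)[1:3]
  rot <- x[1:3, 1:3]
  dircos <- sweep(rot, 2, sp, "/")
  if (!isTRUE(all.equal(abs(dircos), diag(3), tolerance = 1e-4)))
    stop("only axis-aligned volumes are supported")
  # Tolerate the LPS/RAS sign flip NIfTI writers introduce: geometry is kept
  # axis-aligned with the stored origin.
  voxel_grid(shape, spacing = sp, origin = x[1:3, 4])
}

#' Read or write a patient case on disk
#'
#' A case directory holds `sim.nii.gz` and `ther.nii.gz` count maps,
#' `mask_liver.nii.gz`, `mask_lobe.nii.gz`, `mask_lesion_<i>.nii.gz`, and a
#' `meta.csv` with the activity record (case_id, A_injected_GBq,
#' A_residual_GBq, LSF_percent, treated_lobe, waiting_days).
#'
#' @param case A `patient_case` (see [generate_case()]).
#' @param dir Directory to write into (created if missing).
#' @return `write_case` returns `dir`; `read_case` returns a `patient_case`.
#' @export
write_case <- function(case, dir) {
  stopifnot(inherits(case, "patient_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_map(case$sim_counts, file.path(dir, "sim.nii.gz"))
  write_map(case$ther_counts, file.path(dir, "ther.nii.gz"))
  write_map(case$masks$liver, file.path(dir, "mask_liver.nii.gz"))
  write_map(case$masks$lobe, file.path(dir, "mask_lobe.nii.gz"))
  for (i in seq_along(case$masks$lesions))
    write_map(case$masks$lesions[[i]],
              file.path(dir, sprintf("mask_lesion_%d.nii.gz", i)))
  meta <- case$meta
  utils::write.csv(data.frame(case_id = meta$case_id,
                              A_injected_GBq = meta$A_injected,
                              A_residual_GBq = meta$A_residual,
                              LSF_percent = 100 * meta$lsf,
                              treated_lobe = meta$treated_lobe,
                              waiting_days = meta$waiting_days,
                              n_lesions = length(case$masks$lesions)),
                   file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_case
#' @export
read_case <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "meta.csv"))
  sim <- load_map(file.path(dir, "sim.nii.gz"), kind = "counts")
  ther <- load_map(file.path(dir, "ther.nii.gz"), kind = "counts")
  liver <- load_mask(file.path(dir, "mask_liver.nii.gz"))
  lobe <- load_mask(file.path(dir, "mask_lobe.nii.gz"))
  lesions <- list()
  i <- 1L
  repeat {
    p <- file.path(dir, sprintf("mask_lesion_%d.nii.gz", i))
    if (!file.exists(p)) break
    lesions[[i]] <- load_mask(p)
    i <- i + 1L
  }
  structure(list(
    sim_counts = sim, ther_counts = ther,
    masks = list(liver = liver, lobe = lobe, lesions = lesions),
    meta = list(case_id = as.character(meta$case_id),
                A_injected = meta$A_injected_GBq,
                A_residual = meta$A_residual_GBq,
                lsf = meta$LSF_percent / 100,
                treated_lobe = as.character(meta$treated_lobe),
                waiting_days = meta$waiting_days)),
    class = "patient_case")
}
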