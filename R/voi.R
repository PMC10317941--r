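#' Volume and mass of a voxel mask
#'
#' Volume is voxel counting times the voxel volume; mass assumes a uniform
#' soft-tissue density (liver default 1.05 g/cm3).
#'
#' @param mask Logical 3-D array with a `grid` attribute (or on `grid`).
#' @param grid A [voxel_grid]; taken from the mask attribute if missing.
#' @param density Tissue density in g/ml.
#' @return Volume in ml / mass in kg.
#' @export
voi_volume_ml <- function(mask, grid = attr(mask, "grid")) {
  stopifnot(is.logical(mask), inherits(grid, "voxel_grid"))
  sum(mask) * voxel_volume_ml(grid)
}

#' @rdname voi_volume_ml
#' @export
voi_mass_kg <- function(mask, grid = attr(mask, "grid"), density = 1.05) {
  voi_volume_ml(mask, grid) * density / 1000
}

#' Drop lesions below a minimum volume
#'
#' Small lesions (default under 4 ml, roughly a 2-cm sphere) are unreliable
#' on SPECT because of partial-volume effects and registration sensitivity,
#' and are excluded from analysis. The threshold is strict: a lesion of
#' exactly `min_ml` is retained.
#'
#' @param lesion_masks List of logical masks on a common grid.
#' @param grid The shared [voxel_grid].
#' @param min_ml Exclusion threshold in ml.
#' @param quiet Suppress the per-lesion exclusion message.
#' @return The retained sublist, with attribute `excluded` (a data.frame of
#'   dropped lesion indices and their volumes).
#' @export
exclude_small_lesions <- function(lesion_masks, grid = NULL, min_ml = 4,
                                  quiet = FALSE) {
  if (length(lesion_masks) == 0) {
    out <- list()
    attr(out, "excluded") <- data.frame(lesion = integer(), volume_ml = numeric())
    return(out)
  }
  if (is.null(grid)) grid <- attr(lesion_masks[[1]], "grid")
  vols <- vapply(lesion_masks, voi_volume_ml, numeric(1), grid = grid)
  keep <- vols >= min_ml
  if (!quiet && any(!keep))
    message(sprintf("excluding %d lesion(s) under %g ml: %s",
                    sum(!keep), min_ml,
                    paste(sprintf("#%d (%.2f ml)", which(!keep), vols[!keep]),
                          collapse = ", ")))
  out <- lesion_masks[keep]
  attr(out, "excluded") <- data.frame(lesion = which(!keep),
                                      volume_ml = vols[!keep])
  out
}

#' Derive analysis volumes of interest
#'
#' From the whole-liver mask, the targeted-lobe mask and the retained lesion
#' masks, builds the three dosimetry VOIs: tumoral liver `TL` (union of
#' lesions), non-tumoral whole liver `NTLw = liver \ TL`, and non-tumoral
#' target `NTLt = (lobe intersect liver) \ TL`. Lobe contours drawn on CT
#' may spill outside the liver contour, so NTLt intersects with the liver
#' first.
#'
#' @param liver,lobe Logical masks on a common grid.
#' @param retained_lesions List of logical lesion masks (after
#'   [exclude_small_lesions()]).
#' @param grid The shared [voxel_grid].
#' @return A `voi_set`: list of logical masks `liver`, `lobe`, `TL`, `NTLt`,
#'   `NTLw` sharing `grid`.
#' @export
derive_vois <- function(liver, lobe, retained_lesions,
                        grid = attr(liver, "grid")) {
  stopifnot(inherits(grid, "voxel_grid"), is.logical(liver), is.logical(lobe))
  if (!any(liver)) stop("liver mask is empty")
  TL <- array(FALSE, dim(liver))
  for (m in retained_lesions) TL <- TL | m
  NTLw <- liver & !TL
  NTLt <- lobe & liver & !TL
  vois <- list(liver = liver, lobe = lobe, TL = TL, NTLt = NTLt, NTLw = NTLw)
  vois <- lapply(vois, function(m) { attr(m, "grid") <- grid; m })
  structure(list(grid = grid, masks = vois), class = "voi_set")
}

#' @export
print.voi_set <- function(x, ...) {
  vv <- voxel_volume_ml(x$grid)
  cat("<voi_set>\n")
  for (nm in names(x$masks))
    cat(sprintf("  %-6s %8.1f ml (%d voxels)\n", nm,
                sum(x$masks[[nm]]) * vv, sum(x$masks[[nm]])))
  invisible(x)
}
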