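#' Construct the LA wall from an endocardial segmentation
#'
#' The wall is defined as the metric dilation of the endocardial mask by
#' `dilation_mm` (a Euclidean ball in world mm, valid for anisotropic
#' voxels) minus the endocardial mask itself. A voxel belongs to the wall
#' when its centroid lies within `dilation_mm` of some endocardial voxel
#' centroid and is not itself endocardial.
#'
#' @param endo binary 3D array (or [label_volume]) marking the endocardial
#'   blood pool; must be non-empty.
#' @param spacing per-axis voxel size in mm.
#' @param dilation_mm dilation radius in mm (default 2).
#' @return object of class `wall_model`: `endo_mask`, `wall_mask` (logical
#'   arrays), `dilation_mm`, `spacing`, `wall_volume_mm3`.
#' @examples
#' endo <- array(FALSE, c(9, 9, 9)); endo[5, 5, 5] <- TRUE
#' w <- build_wall_mask(endo, spacing = c(1, 1, 1), dilation_mm = 2)
#' sum(w$wall_mask)  # 32 lattice points within 2 mm, center excluded
#' @export
build_wall_mask <- function(endo, spacing, dilation_mm = 2) {
  if (inherits(endo, "image_volume")) {
    spacing <- endo$spacing
    endo <- as_mask(endo)
  }
  endo <- as_mask(endo)
  if (!any(endo))
    stop("endocardial mask is empty", call. = FALSE)
  if (dilation_mm < 0)
    stop("dilation_mm must be >= 0", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (dilation_mm > 0 && dilation_mm < min(spacing))
    warning("dilation_mm (", dilation_mm, ") is smaller than the smallest ",
            "voxel dimension (", min(spacing), " mm); the wall may be ",
            "empty along some axes")
  dil <- dilate_mask(endo, spacing, dilation_mm)
  wall <- dil & !endo
  structure(list(endo_mask = endo, wall_mask = wall,
                 dilation_mm = dilation_mm, spacing = spacing,
                 wall_volume_mm3 = sum(wall) * voxel_volume_mm3(spacing)),
            class = "wall_model")
}

#' @export
print.wall_model <- function(x, ...) {
  cat(sprintf("<wall_model> %d wall voxels (%.1f mm3), dilation %.2f mm\n",
              sum(x$wall_mask), x$wall_volume_mm3, x$dilation_mm))
  invisible(x)
}

#' Quantify fibrosis within the LA wall by intensity thresholding
#'
#' Wall voxels whose LGE intensity exceeds `mu + threshold_k * sigma` are
#' labeled fibrotic, where `mu` and `sigma` describe the non-enhanced wall
#' signal. The reference statistics start from the median and 1.4826 x MAD
#' over all wall voxels and are then refined by iterative sigma clipping:
#' voxels above `mu + 3 sigma` are excluded and the statistics recomputed
#' until stable. The plain median/MAD pair breaks down when the enhanced
#' fraction approaches 30% (the contaminated MAD inflates the threshold
#' past the enhanced intensities); the clipped reference keeps the
#' recovery unbiased up to roughly 40% enhancement. The internal clip
#' multiplier is fixed at 3 regardless of `threshold_k`, so the reference
#' depends only on the data and the reported percentage is non-increasing
#' in `threshold_k`. Fibrosis burden is reported as a percentage of the
#' wall volume. The rule is scale-equivariant: rescaling all intensities
#' by a positive constant leaves the fibrotic mask unchanged.
#'
#' @param lge [intensity_volume] (or 3D numeric array) on the same grid as
#'   the wall.
#' @param wall a [build_wall_mask()] result, or a binary wall array.
#' @param threshold_k SD multiplier above the reference mean (default 3).
#' @param refine_iterations maximal sigma-clipping refinements of the
#'   reference statistics (default 20; 0 reproduces plain median/MAD).
#' @return object of class `fibrosis_result`: `fibrotic_mask` (logical
#'   array restricted to wall voxels), `fibrosis_percent`,
#'   `threshold_value`, `threshold_k`, `wall_voxels`, plus the robust
#'   reference statistics `mu` and `sigma`.
#' @export
quantify_fibrosis <- function(lge, wall, threshold_k = 3,
                              refine_iterations = 20L) {
  img <- if (inherits(lge, "image_volume")) lge$data else lge
  wall_mask <- if (inherits(wall, "wall_model")) wall$wall_mask else
    as_mask(wall)
  stop_if_grid_mismatch(img, wall_mask, "LGE and wall")
  if (!any(wall_mask))
    stop("wall mask is empty", call. = FALSE)
  vals <- img[wall_mask]
  if (anyNA(vals) || any(is.nan(vals)))
    stop("LGE volume contains NA/NaN intensities within the wall",
         call. = FALSE)
  mu <- median(vals)
  sigma <- mad(vals)  # 1.4826 * MAD
  for (it in seq_len(refine_iterations)) {
    ref <- vals[vals <= mu + 3 * sigma]
    if (length(ref) < 30L) break
    mu2 <- median(ref)
    sigma2 <- mad(ref)
    converged <- abs(mu2 - mu) <= 1e-10 * max(1, abs(mu)) &&
      abs(sigma2 - sigma) <= 1e-10 * max(1, sigma)
    mu <- mu2
    sigma <- sigma2
    if (converged) break
  }
  if (sigma == 0 && threshold_k > 0)
    warning("zero intensity variance within the wall; no voxel exceeds ",
            "the threshold")
  thr <- mu + threshold_k * sigma
  fibrotic <- wall_mask & (img > thr)
  structure(list(fibrotic_mask = fibrotic,
                 fibrosis_percent = 100 * sum(fibrotic) / sum(wall_mask),
                 threshold_value = thr,
                 threshold_k = threshold_k,
                 mu = mu, sigma = sigma,
                 wall_voxels = sum(wall_mask)),
            class = "fibrosis_result")
}

#' @export
print.fibrosis_result <- function(x, ...) {
  cat(sprintf(paste0("<fibrosis_result> %.2f%% of %d wall voxels fibrotic ",
                     "(threshold %.3f = mu + %.2g sigma)\n"),
              x$fibrosis_percent, x$wall_voxels, x$threshold_value,
              x$threshold_k))
  invisible(x)
}
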