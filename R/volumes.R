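#' Image volume containers
#'
#' A volume couples a 3D array with per-axis voxel spacing (mm) and a world
#' origin. World coordinates are right-handed millimetres with the origin at
#' the grid corner, so the centroid of voxel `(i, j, k)` (1-based) sits at
#' `origin + (c(i, j, k) - 0.5) * spacing`. All geometric operations in the
#' package work in world mm, never in raw voxel indices.
#'
#' `label_volume()` holds an integer label map (e.g. blood pool / wall /
#' EAT / pericardium); `intensity_volume()` holds a floating-point signal
#' such as an LGE acquisition on the same grid.
#'
#' @param data 3D array. Coerced to integer for labels, double for
#'   intensities.
#' @param spacing numeric length-3, voxel size in mm per axis (> 0).
#' @param origin numeric length-3, world position of the grid corner (mm).
#' @return An object of class `label_volume` or `intensity_volume`
#'   (both inherit from `image_volume`) with fields `data`, `spacing`,
#'   `origin`.
#' @examples
#' lab <- label_volume(array(0L, c(4, 4, 4)), spacing = c(1, 1, 1))
#' dim(lab$data)
#' @export
label_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  v <- new_volume(data, spacing, origin, "label_volume")
  storage.mode(v$data) <- "integer"
  v
}

#' @rdname label_volume
#' @export
intensity_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  v <- new_volume(data, spacing, origin, "intensity_volume")
  storage.mode(v$data) <- "double"
  v
}

new_volume <- function(data, spacing, origin, cls) {
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ", length(dim(data)),
         " dimensions", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive voxel sizes in mm", call. = FALSE)
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("origin must have length 3", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = c(cls, "image_volume"))
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin (%s) mm\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

# millimetre volume of one voxel
voxel_volume_mm3 <- function(spacing) prod(spacing)

# world coordinates (mm) of the centroids of TRUE voxels, rows ordered by
# ascending linear voxel index (the package-wide tie-break order)
voxel_centroids <- function(mask, spacing, origin = c(0, 0, 0)) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), 0, 3))
  sweep(sweep(idx - 0.5, 2, spacing, `*`), 2, origin, `+`)
}

# exact Euclidean distance (mm) from every voxel centroid to the nearest
# TRUE voxel centroid; anisotropic spacing supported
distance_to_mask <- function(mask, spacing) {
  stopifnot(is.logical(mask) || is.integer(mask))
  d2 <- cpp_edt_sq(as.logical(mask), dim(mask), as.numeric(spacing))
  array(sqrt(d2), dim(mask))
}

# metric dilation: voxels whose centroid lies within radius_mm of a TRUE
# voxel centroid (includes the original set)
dilate_mask <- function(mask, spacing, radius_mm) {
  distance_to_mask(mask, spacing) <= radius_mm
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  da <- if (inherits(a, "image_volume")) dim(a$data) else dim(a)
  db <- if (inherits(b, "image_volume")) dim(b$data) else dim(b)
  if (!identical(da, db))
    stop(what, " are on different grids: ", paste(da, collapse = "x"),
         " vs ", paste(db, collapse = "x"), call. = FALSE)
  invisible(TRUE)
}

as_mask <- function(x) {
  if (inherits(x, "image_volume")) x <- x$data
  if (is.logical(x)) x else x != 0
}
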