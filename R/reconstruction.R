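#' Triangulated surface with per-vertex attributes
#'
#' @param vertices N x 3 matrix of world-mm coordinates.
#' @param triangles M x 3 integer matrix of 1-based vertex indices.
#' @param attrs named list of per-vertex attribute vectors.
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, attrs = list()) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L || ncol(triangles) != 3L)
    stop("vertices and triangles must have 3 columns", call. = FALSE)
  if (nrow(triangles) && (min(triangles) < 1L ||
                          max(triangles) > nrow(vertices)))
    stop("triangle vertex indices out of range", call. = FALSE)
  for (a in attrs)
    if (length(a) != nrow(vertices))
      stop("attribute length must equal vertex count", call. = FALSE)
  structure(list(vertices = vertices, triangles = triangles, attrs = attrs),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles; attributes: %s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (length(x$attrs)) paste(names(x$attrs), collapse = ", ")
              else "none"))
  invisible(x)
}

#' Extract an iso-surface from a binary mask
#'
#' Marches the 0.5 level set of the voxel occupancy field with marching
#' tetrahedra on the Freudenthal lattice decomposition, which yields a
#' closed, consistently oriented triangle mesh for any blob interior to the
#' grid. The occupancy field is first smoothed with a small Gaussian
#' (`smooth_sigma_vox` voxels, default 1): marching the raw binary field
#' places every vertex on a staircase that overestimates surface area by
#' ~9%, while the mildly smoothed field recovers analytic areas and volumes
#' of digitized spheres to well under 1%. Set `smooth_sigma_vox = 0` for
#' the raw binary behaviour.
#'
#' @param mask binary 3D array (or [image_volume]); must be non-empty and
#'   must not touch the grid boundary.
#' @param spacing per-axis voxel size (mm); taken from `mask` when it is an
#'   [image_volume].
#' @param smooth_sigma_vox Gaussian smoothing of the occupancy field, in
#'   voxels.
#' @param origin world position of the grid corner (mm).
#' @return a [surface_mesh()] in world mm.
#' @examples
#' m <- array(FALSE, c(24, 24, 24))
#' ctr <- c(12.2, 12.4, 12.3)
#' idx <- which(!m, arr.ind = TRUE)
#' m[idx[rowSums(sweep(idx, 2, ctr)^2) <= 64, ]] <- TRUE
#' mesh <- extract_surface(m, spacing = c(1, 1, 1))
#' abs(mesh_area(mesh) / (4 * pi * 64) - 1) < 0.05
#' @export
extract_surface <- function(mask, spacing = NULL, smooth_sigma_vox = 1,
                            origin = c(0, 0, 0)) {
  if (inherits(mask, "image_volume")) {
    spacing <- mask$spacing
    origin <- mask$origin
    mask <- as_mask(mask)
  }
  mask <- as_mask(mask)
  if (!any(mask)) stop("mask is empty: no surface to extract", call. = FALSE)
  dims <- dim(mask)
  if (any(mask[1, , ]) || any(mask[dims[1], , ]) ||
      any(mask[, 1, ]) || any(mask[, dims[2], ]) ||
      any(mask[, , 1]) || any(mask[, , dims[3]]))
    stop("mask touches the grid boundary; pad the volume before surface ",
         "extraction", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing), 3L)
  field <- as.double(mask)
  if (smooth_sigma_vox > 0)
    field <- cpp_smooth3(field, dims, smooth_sigma_vox)
  res <- cpp_marching_tets(field, dims, 0.5)
  # lattice point (0-based) m corresponds to voxel m+1, centroid at
  # origin + (m + 0.5) * spacing
  verts <- sweep(sweep(res$vertices + 0.5, 2, spacing, `*`), 2, origin, `+`)
  surface_mesh(verts, res$triangles)
}

#' Mesh surface area, enclosed volume and connectivity
#'
#' `mesh_area()` sums triangle areas (mm^2); `mesh_volume()` uses the
#' divergence theorem over the oriented triangles and returns the absolute
#' enclosed volume (mm^3; meaningful for closed meshes);
#' `mesh_components()` counts connected components of the vertex graph;
#' `mesh_is_closed()` checks that every edge is shared by exactly two
#' triangles.
#'
#' @param mesh a [surface_mesh()].
#' @return scalar (area, volume, component count) or logical.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$triangles
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sum(sqrt(cx^2 + cy^2 + cz^2))
}

#' @rdname mesh_area
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$triangles
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  det3 <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
    p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
    p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  abs(sum(det3)) / 6
}

#' @rdname mesh_area
#' @export
mesh_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  f <- mesh$triangles
  for (e in list(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
                 cbind(f[, 3], f[, 1]))) {
    for (r in seq_len(nrow(e))) {
      ra <- find(e[r, 1]); rb <- find(e[r, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' @rdname mesh_area
#' @export
mesh_is_closed <- function(mesh) {
  f <- mesh$triangles
  edges <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
                 cbind(f[, 3], f[, 1]))
  key <- paste(pmin(edges[, 1], edges[, 2]),
               pmax(edges[, 1], edges[, 2]))
  all(table(key) == 2L)
}

#' Fat volume model (volume-weighted sample points)
#'
#' @param points K x 3 matrix of world-mm sample coordinates.
#' @param volumes length-K positive volume weights (mm^3).
#' @param total_volume total fat volume in mm^3 (defaults to
#'   `sum(volumes)`).
#' @return object of class `fat_model`.
#' @export
fat_model <- function(points, volumes,
                      total_volume = sum(volumes)) {
  points <- as.matrix(points)
  if (nrow(points) != length(volumes))
    stop("one volume weight per sample point required", call. = FALSE)
  if (length(volumes) && any(volumes <= 0))
    stop("all volume weights must be positive", call. = FALSE)
  structure(list(points = points, volumes = as.numeric(volumes),
                 total_volume = as.numeric(total_volume)),
            class = "fat_model")
}

#' @export
print.fat_model <- function(x, ...) {
  cat(sprintf("<fat_model> %d samples, total volume %.1f mm3 (%.2f mL)\n",
              nrow(x$points), x$total_volume, x$total_volume / 1000))
  invisible(x)
}

#' Convert a fat label mask into a volumetric sample model
#'
#' Each fat voxel is subdivided into an integer grid of sub-cells so the
#' sample spacing does not exceed `target_spacing_mm` along any axis
#' (default 1 mm, the working resolution of the colocalization metrics);
#' every sample carries its sub-cell volume. The model's total volume is
#' exactly voxel count x voxel volume regardless of subdivision.
#'
#' @param fat_mask binary 3D array (or [label_volume] interpreted as
#'   non-zero = fat).
#' @param spacing per-axis voxel size (mm).
#' @param target_spacing_mm maximal sample spacing (mm), > 0.
#' @param origin world position of the grid corner (mm).
#' @return a [fat_model()]; empty masks give a model with 0 samples and
#'   total volume 0.
#' @export
volumetrize_fat <- function(fat_mask, spacing = NULL, target_spacing_mm = 1,
                            origin = c(0, 0, 0)) {
  if (inherits(fat_mask, "image_volume")) {
    spacing <- fat_mask$spacing
    origin <- fat_mask$origin
    fat_mask <- as_mask(fat_mask)
  }
  fat_mask <- as_mask(fat_mask)
  if (target_spacing_mm <= 0)
    stop("target_spacing_mm must be > 0", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing), 3L)
  centroids <- voxel_centroids(fat_mask, spacing, origin)
  nvox <- nrow(centroids)
  if (nvox == 0L)
    return(fat_model(matrix(numeric(0), 0, 3), numeric(0), 0))
  nsub <- pmax(1L, ceiling(spacing / target_spacing_mm))
  # sub-cell center offsets within one voxel, per axis
  offs <- lapply(1:3, function(ax)
    ((seq_len(nsub[ax]) - 0.5) / nsub[ax] - 0.5) * spacing[ax])
  grid <- as.matrix(expand.grid(offs[[1]], offs[[2]], offs[[3]]))
  nper <- nrow(grid)
  pts <- centroids[rep(seq_len(nvox), each = nper), , drop = FALSE] +
    grid[rep(seq_len(nper), times = nvox), , drop = FALSE]
  subvol <- voxel_volume_mm3(spacing) / nper
  fat_model(pts, rep(subvol, nvox * nper),
            total_volume = nvox * voxel_volume_mm3(spacing))
}

#' Transfer fibrosis labels from wall voxels to surface vertices
#'
#' Every vertex inherits the fibrotic/non-fibrotic label of the nearest
#' wall-voxel centroid (ties broken by lowest linear voxel index). Vertices
#' whose nearest wall voxel is farther than `max_assign_mm` are labeled
#' non-fibrotic and counted in a warning.
#'
#' @param mesh [surface_mesh()] in the same world frame as the masks.
#' @param fibrotic_mask binary array of fibrotic wall voxels.
#' @param wall_mask binary array of all wall voxels (non-empty).
#' @param spacing per-axis voxel size (mm).
#' @param max_assign_mm assignment distance cut-off (mm, default 3).
#' @param origin world position of the grid corner (mm).
#' @return the mesh with an integer (0/1) per-vertex attribute `fibrotic`.
#' @export
map_fibrosis_to_surface <- function(mesh, fibrotic_mask, wall_mask, spacing,
                                    max_assign_mm = 3,
                                    origin = c(0, 0, 0)) {
  stopifnot(inherits(mesh, "surface_mesh"))
  fibrotic_mask <- as_mask(fibrotic_mask)
  wall_mask <- as_mask(wall_mask)
  stop_if_grid_mismatch(fibrotic_mask, wall_mask, "fibrosis and wall masks")
  if (!any(wall_mask))
    stop("wall mask is empty: cannot assign fibrosis labels", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing), 3L)
  W <- voxel_centroids(wall_mask, spacing, origin)
  wall_fib <- fibrotic_mask[wall_mask]  # linear-index order, as W
  nn <- cpp_grid_nn(W, mesh$vertices)
  lab <- wall_fib[nn$index]
  too_far <- sqrt(nn$d2) > max_assign_mm
  if (any(too_far)) {
    warning(sum(too_far), " surface vertices beyond ", max_assign_mm,
            " mm of any wall voxel; labeled non-fibrotic")
    lab[too_far] <- FALSE
  }
  mesh$attrs$fibrotic <- as.integer(lab)
  mesh
}
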