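#' Read and write volumes as NIfTI
#'
#' `read_volume()` loads a 3D NIfTI file and dispatches on the stored
#' values: integer-valued data become a [label_volume], anything else an
#' [intensity_volume]. The affine is reduced to per-axis spacing and a grid
#' corner origin (the package's world convention); `write_volume()` emits
#' the matching diagonal sform so files round-trip losslessly.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return [label_volume] or [intensity_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("cannot read volume: no such file '", path, "'", call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), "D in '", path, "'",
         call. = FALSE)
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  origin <- xf[1:3, 4] - 0.5 * sp
  arr <- array(as.vector(img), d)
  hdr <- RNifti::niftiHeader(img)
  integer_dtype <- hdr$datatype %in% c(2L, 4L, 8L, 256L, 512L, 768L)
  if (integer_dtype || all(arr == round(arr)))
    label_volume(arr, sp, origin)
  else
    intensity_volume(arr, sp, origin)
}

#' @rdname read_volume
#' @param vol a [label_volume] or [intensity_volume].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin + 0.5 * vol$spacing
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  datatype <- if (inherits(vol, "label_volume")) "int16" else "float"
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Landmark CSV I/O
#'
#' Plain CSV with columns `name, x, y, z` in world mm.
#'
#' @param path file path.
#' @return `read_landmarks()` returns a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns name,x,y,z", call. = FALSE)
  landmark_set(df$name, as.matrix(df[, c("x", "y", "z")]))
}

#' @rdname read_landmarks
#' @param landmarks a [landmark_set()].
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  df <- data.frame(name = landmarks$names,
                   x = landmarks$coords[, 1],
                   y = landmarks$coords[, 2],
                   z = landmarks$coords[, 3])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a rigid transform as JSON
#'
#' Row-major rotation, translation and fit RMS.
#'
#' @param transform a [rigid_transform()].
#' @param path file path.
#' @export
write_transform_json <- function(transform, path) {
  stopifnot(inherits(transform, "rigid_transform"))
  obj <- list(rotation_row_major = as.vector(t(transform$rotation)),
              translation_mm = transform$translation,
              rms_mm = transform$rms)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(obj$rotation_row_major, 3, 3, byrow = TRUE),
                  obj$translation_mm,
                  rms = if (is.null(obj$rms_mm)) NA_real_ else obj$rms_mm)
}

#' Write a surface mesh as legacy ASCII VTK polydata
#'
#' Per-vertex attributes are written as named `POINT_DATA` scalar arrays
#' (e.g. `fibrotic`, `d_eat_mm`, `v_eat_mm3`). Numbers are formatted with
#' `%.9g`, so identical meshes produce byte-identical files.
#'
#' @param mesh a [surface_mesh()].
#' @param path output path (conventionally `.vtk`).
#' @export
write_vtk_polydata <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices)
  nt <- nrow(mesh$triangles)
  writeLines(c("# vtk DataFile Version 3.0",
               "eatcoloc surface", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nv)), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nt, 4L * nt), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L),
             con)
  if (length(mesh$attrs)) {
    writeLines(sprintf("POINT_DATA %d", nv), con)
    for (nm in names(mesh$attrs)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", as.numeric(mesh$attrs[[nm]])), con)
    }
  }
  invisible(path)
}

#' Write a fat model as CSV
#'
#' Columns `x, y, z, volume_mm3` (world mm / mm^3).
#'
#' @param fat a [fat_model()].
#' @param path output path.
#' @export
write_fat_csv <- function(fat, path) {
  stopifnot(inherits(fat, "fat_model"))
  df <- data.frame(x = fat$points[, 1], y = fat$points[, 2],
                   z = fat$points[, 3], volume_mm3 = fat$volumes)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# deterministic polynomial hash of a string, hex; used to stamp outputs
# with the configuration they came from
config_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
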