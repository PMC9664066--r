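#' Named anatomical landmarks
#'
#' An ordered set of corresponding fiducial points (pulmonary vein, mitral
#' annulus and appendage analogs) used to align the fat ("Dixon") frame
#' with the fibrosis ("LGE") frame.
#'
#' @param names character vector of landmark labels.
#' @param coords L x 3 matrix of world coordinates (mm).
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(names, coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) != length(names) || ncol(coords) != 3L)
    stop("coords must be length(names) x 3", call. = FALSE)
  dimnames(coords) <- list(names, c("x", "y", "z"))
  structure(list(names = as.character(names), coords = coords),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set>\n")
  print(round(x$coords, 3))
  invisible(x)
}

#' Rigid (rotation + translation) transform
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation length-3 vector (mm).
#' @param rms optional post-fit RMS landmark residual (mm).
#' @return object of class `rigid_transform`. Maps `x -> R x + t`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            rms = NA_real_) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rotation must be 3x3 and translation length 3", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation matrix is not orthonormal", call. = FALSE)
  if (det(rotation) < 0)
    stop("rotation matrix has negative determinant (reflection)",
         call. = FALSE)
  structure(list(rotation = rotation, translation = translation, rms = rms),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> translation (mm):",
      paste(sprintf("%.3f", x$translation), collapse = ", "),
      if (!is.na(x$rms)) sprintf("| fit rms %.4g mm", x$rms) else "", "\n")
  print(round(x$rotation, 6))
  invisible(x)
}

#' Rotation matrix from Euler angles
#'
#' Intrinsic rotations about the fixed x, y, z axes in degrees, composed as
#' `Rz %*% Ry %*% Rx`.
#'
#' @param angles_deg length-3 numeric, degrees about x, y, z.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_from_euler <- function(angles_deg) {
  r <- angles_deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Least-squares rigid landmark registration
#'
#' Closed-form optimal rotation and translation mapping `moving` onto
#' `fixed` (cross-covariance SVD with reflection correction, i.e. the
#' Kabsch/Umeyama solution without scaling). Landmark correspondence is by
#' name and order; at least 3 non-collinear landmarks are required.
#'
#' @param moving,fixed [landmark_set()]s with identical names in identical
#'   order.
#' @return [rigid_transform()] with the post-fit RMS residual (mm) in
#'   `$rms`.
#' @examples
#' lm <- landmark_set(c("a", "b", "c", "d"),
#'                    rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0),
#'                          c(0, 0, 10)))
#' fit_rigid(lm, lm)$rms
#' @export
fit_rigid <- function(moving, fixed) {
  stopifnot(inherits(moving, "landmark_set"), inherits(fixed, "landmark_set"))
  if (!identical(moving$names, fixed$names))
    stop("landmark names/order differ between moving and fixed sets",
         call. = FALSE)
  P <- moving$coords
  Q <- fixed$coords
  L <- nrow(P)
  if (L < 3L)
    stop("need at least 3 landmarks for a unique rigid fit", call. = FALSE)
  pbar <- colMeans(P)
  qbar <- colMeans(Q)
  Pc <- sweep(P, 2, pbar)
  Qc <- sweep(Q, 2, qbar)
  sv <- svd(Pc)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12))
    stop("landmarks are collinear or coincident: rigid fit is degenerate",
         call. = FALSE)
  H <- crossprod(Pc, Qc)          # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))  # reflection correction
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- qbar - as.numeric(R %*% pbar)
  resid <- sweep(P %*% t(R), 2, tr, `+`) - Q
  rms <- sqrt(mean(rowSums(resid^2)))
  rigid_transform(R, tr, rms = rms)
}

#' Apply a rigid transform
#'
#' Maps coordinates `x -> R x + t`; per-vertex attributes and volume
#' weights are untouched (rigid motion is an isometry and preserves
#' volumes).
#'
#' @param transform a [rigid_transform()].
#' @param object a [landmark_set()], [surface_mesh], [fat_model] or plain
#'   N x 3 coordinate matrix.
#' @return object of the same type with transformed coordinates.
#' @export
apply_rigid <- function(transform, object) {
  stopifnot(inherits(transform, "rigid_transform"))
  UseMethod("apply_rigid", object)
}

rigid_points <- function(transform, xyz) {
  sweep(xyz %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' @export
apply_rigid.matrix <- function(transform, object) {
  rigid_points(transform, object)
}

#' @export
apply_rigid.landmark_set <- function(transform, object) {
  landmark_set(object$names, rigid_points(transform, object$coords))
}

#' @export
apply_rigid.surface_mesh <- function(transform, object) {
  object$vertices <- rigid_points(transform, object$vertices)
  object
}

#' @export
apply_rigid.fat_model <- function(transform, object) {
  if (nrow(object$points) > 0L)
    object$points <- rigid_points(transform, object$points)
  object
}

#' Compose and invert rigid transforms
#'
#' `compose_rigid(t2, t1)` is the transform applying `t1` first, then `t2`;
#' `invert_rigid(t)` undoes `t`.
#'
#' @param t1,t2,transform [rigid_transform()]s.
#' @return a [rigid_transform()].
#' @export
compose_rigid <- function(t2, t1) {
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.numeric(t2$rotation %*% t1$translation) +
                    t2$translation)
}

#' @rdname compose_rigid
#' @export
invert_rigid <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}
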