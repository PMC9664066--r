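#' Label codes used by the phantom generator
#'
#' Integer codes of the tissue classes in phantom label volumes:
#' background 0, LA blood pool 1, LA wall 2, LA-adjacent EAT 3, pericardial
#' shell 4, ventricular EAT analog 5. Classes are disjoint by construction.
#'
#' @export
phantom_labels <- c(background = 0L, blood_pool = 1L, wall = 2L,
                    eat = 3L, pericardium = 4L, ventricular_eat = 5L)

#' Configuration of the synthetic LA phantom
#'
#' Describes one synthetic case: an ellipsoidal LA blood pool wrapped by a
#' thin wall, a pericardial shell at a fixed gap, spherical fat depots in
#' the wall-pericardium band, contiguous fibrotic angular caps on the wall
#' with elevated LGE signal, and a known rigid misalignment between the
#' fibrosis ("LGE") and fat ("Dixon") acquisition frames.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_size_mm numeric length-3 (or scalar), voxel spacing in mm.
#' @param la_semiaxes_mm ellipsoid semi-axes of the LA blood pool (mm).
#' @param wall_thickness_mm nominal LA wall thickness (mm); the wall is the
#'   metric dilation of the blood pool by this amount, minus the blood pool.
#' @param pericardium_offset_mm gap between the epicardial surface and the
#'   pericardial shell (mm); fat depots live in this band.
#' @param pericardium_thickness_mm thickness of the pericardial shell label.
#' @param n_fat_depots number of spherical fat depots.
#' @param fat_depot_radius_mm radius of each depot sphere (mm).
#' @param fat_offset_mm signed radial offset of depot centers from the
#'   epicardial surface (mm).
#' @param fibrosis_fraction target fraction of wall voxels fibrotic (0-1).
#' @param fibrosis_patch_count number of fibrotic angular caps.
#' @param lge_baseline_mean,lge_baseline_sd Gaussian LGE baseline intensity
#'   (arbitrary units).
#' @param lge_fibrosis_delta additive LGE intensity shift of fibrotic wall
#'   voxels (same units).
#' @param coloc_mode depot placement relative to fibrotic caps: `"near"`
#'   (inside caps), `"far"` (away from every cap), or `"random"`.
#' @param rigid_misalignment list with `angles_deg` (rotations about x, y, z
#'   in degrees) and `translation_mm` mapping the LGE frame into the Dixon
#'   frame.
#' @param ventricular_fat logical; add a ventricular EAT analog slab below
#'   the pericardium (label 5), enabling the total-vs-LA EAT distinction.
#' @param ventricular_fat_thickness_mm thickness of that slab (mm).
#' @param seed RNG seed; identical config and seed give bit-identical cases.
#' @return A validated list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(96L, 96L, 96L),
                           voxel_size_mm = c(1, 1, 1),
                           la_semiaxes_mm = c(25, 22, 20),
                           wall_thickness_mm = 2,
                           pericardium_offset_mm = 6,
                           pericardium_thickness_mm = 1.5,
                           n_fat_depots = 8L,
                           fat_depot_radius_mm = 5,
                           fat_offset_mm = 2.5,
                           fibrosis_fraction = 0.2,
                           fibrosis_patch_count = 3L,
                           lge_baseline_mean = 40,
                           lge_baseline_sd = 6,
                           lge_fibrosis_delta = 36,
                           coloc_mode = c("random", "near", "far"),
                           rigid_misalignment = list(
                             angles_deg = c(5, -3, 8),
                             translation_mm = c(4, -2, 3)),
                           ventricular_fat = TRUE,
                           ventricular_fat_thickness_mm = 4,
                           seed = 1L) {
  coloc_mode <- match.arg(coloc_mode)
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = rep_len(as.numeric(voxel_size_mm), 3L),
              la_semiaxes_mm = rep_len(as.numeric(la_semiaxes_mm), 3L),
              wall_thickness_mm = wall_thickness_mm,
              pericardium_offset_mm = pericardium_offset_mm,
              pericardium_thickness_mm = pericardium_thickness_mm,
              n_fat_depots = as.integer(n_fat_depots),
              fat_depot_radius_mm = fat_depot_radius_mm,
              fat_offset_mm = fat_offset_mm,
              fibrosis_fraction = fibrosis_fraction,
              fibrosis_patch_count = as.integer(fibrosis_patch_count),
              lge_baseline_mean = lge_baseline_mean,
              lge_baseline_sd = lge_baseline_sd,
              lge_fibrosis_delta = lge_fibrosis_delta,
              coloc_mode = coloc_mode,
              rigid_misalignment = rigid_misalignment,
              ventricular_fat = isTRUE(ventricular_fat),
              ventricular_fat_thickness_mm = ventricular_fat_thickness_mm,
              seed = as.integer(seed))
  lengths_pos <- c("voxel_size_mm", "la_semiaxes_mm", "wall_thickness_mm",
                   "pericardium_offset_mm", "pericardium_thickness_mm",
                   "fat_depot_radius_mm", "ventricular_fat_thickness_mm")
  for (f in lengths_pos)
    if (any(!is.finite(cfg[[f]])) || any(cfg[[f]] <= 0))
      stop("phantom_config: '", f, "' must be positive", call. = FALSE)
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 4L))
    stop("phantom_config: grid_shape must be 3 integers >= 4", call. = FALSE)
  if (cfg$fibrosis_fraction < 0 || cfg$fibrosis_fraction > 1)
    stop("phantom_config: fibrosis_fraction must lie in [0, 1]",
         call. = FALSE)
  if (cfg$n_fat_depots < 0L)
    stop("phantom_config: n_fat_depots must be >= 0", call. = FALSE)
  if (cfg$fibrosis_fraction > 0 && cfg$fibrosis_patch_count < 1L)
    stop("phantom_config: fibrosis_fraction ", cfg$fibrosis_fraction,
         " is unreachable with fibrosis_patch_count ",
         cfg$fibrosis_patch_count, call. = FALSE)
  rm <- cfg$rigid_misalignment
  if (!is.list(rm) || length(rm$angles_deg) != 3L ||
      length(rm$translation_mm) != 3L)
    stop("phantom_config: rigid_misalignment needs angles_deg and ",
         "translation_mm, each length 3", call. = FALSE)
  structure(cfg, class = "phantom_config")
}

#' Generate one synthetic LA case
#'
#' Builds the label volume (see [phantom_labels]), the LGE intensity volume
#' (Gaussian baseline, fibrotic wall voxels shifted by
#' `lge_fibrosis_delta`), four anatomical landmark analogs (two pulmonary
#' veins, mitral annulus, appendage) in both acquisition frames, and a
#' ground-truth record. Fibrotic tissue forms contiguous angular caps whose
#' common angular radius is chosen so the achieved fibrotic fraction of
#' wall voxels matches the request (within voxelization ties).
#'
#' @param config a [phantom_config()].
#' @return A list of class `phantom_case` with elements `labels`
#'   ([label_volume]), `lge` ([intensity_volume]), `landmarks_lge`,
#'   `landmarks_dixon` ([landmark_set]), `truth` (achieved fibrosis
#'   fraction, cap geometry, depot centers, true rigid transform, fibrotic
#'   wall mask), and `config`.
#' @examples
#' cfg <- phantom_config(grid_shape = c(56, 56, 56),
#'                       la_semiaxes_mm = c(15, 13, 12),
#'                       pericardium_offset_mm = 4, fat_depot_radius_mm = 4,
#'                       seed = 7)
#' case <- make_la_phantom(cfg)
#' table(case$labels$data)[["1"]] > 0
#' @export
make_la_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  sp <- config$voxel_size_mm
  dims <- config$grid_shape
  extent <- dims * sp
  # off-lattice center avoids lattice-symmetric degeneracies in meshing
  center <- extent / 2 + 0.37 * sp

  a <- config$la_semiaxes_mm
  t_wall <- config$wall_thickness_mm
  off <- config$pericardium_offset_mm
  pth <- config$pericardium_thickness_mm
  outer_reach <- a + t_wall + off + pth
  margin <- 2 * sp
  lo_reach <- outer_reach +
    if (config$ventricular_fat)
      c(0, 0, config$ventricular_fat_thickness_mm) else c(0, 0, 0)
  for (ax in 1:3) {
    if (center[ax] - lo_reach[ax] < margin[ax] ||
        center[ax] + outer_reach[ax] > extent[ax] - margin[ax])
      stop("phantom geometry overflows the grid on axis ", ax,
           ": pericardium", if (config$ventricular_fat && ax == 3L)
             " / ventricular fat slab" else "",
           " needs >= 2 voxels margin; enlarge grid_shape or shrink ",
           "la_semiaxes_mm / pericardium_offset_mm", call. = FALSE)
  }

  set.seed(config$seed)

  # voxel centroid coordinates relative to the LA center
  cx <- (seq_len(dims[1]) - 0.5) * sp[1] - center[1]
  cy <- (seq_len(dims[2]) - 0.5) * sp[2] - center[2]
  cz <- (seq_len(dims[3]) - 0.5) * sp[3] - center[3]
  X <- array(cx, dims)
  Y <- array(rep(cy, each = dims[1]), dims)
  Z <- array(rep(cz, each = dims[1] * dims[2]), dims)

  rho2 <- (X / a[1])^2 + (Y / a[2])^2 + (Z / a[3])^2
  bp <- rho2 <= 1

  d <- distance_to_mask(bp, sp)
  wall <- d > 0 & d <= t_wall
  band <- d > t_wall & d <= t_wall + off
  peri <- d > t_wall + off & d <= t_wall + off + pth

  # ---- fibrotic angular caps on the wall -------------------------------
  wall_idx <- which(wall)
  wall_dirs <- cbind(X[wall_idx], Y[wall_idx], Z[wall_idx])
  wall_dirs <- wall_dirs / sqrt(rowSums(wall_dirs^2))

  fib_frac <- config$fibrosis_fraction
  if (fib_frac > 0) {
    caps <- sample_cap_centers(config$fibrosis_patch_count,
                               min_sep_rad = 40 * pi / 180)
    min_ang <- min_angle_to_caps(wall_dirs, caps)
    n_target <- ceiling(fib_frac * length(wall_idx))
    cap_angle <- sort(min_ang)[n_target]
    fibrotic_wall_idx <- wall_idx[min_ang <= cap_angle]
  } else {
    caps <- matrix(numeric(0), 0, 3)
    cap_angle <- 0
    fibrotic_wall_idx <- integer(0)
  }
  fibrotic <- array(FALSE, dims)
  fibrotic[fibrotic_wall_idx] <- TRUE
  achieved <- length(fibrotic_wall_idx) / length(wall_idx)

  # ---- fat depots -------------------------------------------------------
  nd <- config$n_fat_depots
  eat <- array(FALSE, dims)
  depot_centers <- matrix(numeric(0), 0, 3)
  if (nd > 0L) {
    dirs <- sample_depot_directions(nd, config$coloc_mode, caps, cap_angle)
    s <- 1 / sqrt((dirs[, 1] / a[1])^2 + (dirs[, 2] / a[2])^2 +
                    (dirs[, 3] / a[3])^2)
    radial <- s + t_wall + config$fat_offset_mm
    depot_centers <- dirs * radial  # relative to LA center
    band_idx <- which(band)
    bc <- cbind(X[band_idx], Y[band_idx], Z[band_idx])
    in_depot <- rep(FALSE, length(band_idx))
    for (k in seq_len(nd)) {
      dk2 <- (bc[, 1] - depot_centers[k, 1])^2 +
        (bc[, 2] - depot_centers[k, 2])^2 +
        (bc[, 3] - depot_centers[k, 3])^2
      in_depot <- in_depot | dk2 <= config$fat_depot_radius_mm^2
    }
    eat[band_idx[in_depot]] <- TRUE
  }

  # ---- ventricular fat analog ------------------------------------------
  vent <- array(FALSE, dims)
  if (config$ventricular_fat) {
    z_top <- -(a[3] + t_wall + off + pth)
    z_bot <- z_top - config$ventricular_fat_thickness_mm
    lat <- sqrt(X^2 + Y^2)
    vent <- Z > z_bot & Z <= z_top & lat <= max(a[1], a[2]) + t_wall + off &
      d > t_wall + off + pth
  }

  labels <- array(phantom_labels[["background"]], dims)
  labels[bp] <- phantom_labels[["blood_pool"]]
  labels[wall] <- phantom_labels[["wall"]]
  labels[eat] <- phantom_labels[["eat"]]
  labels[peri] <- phantom_labels[["pericardium"]]
  labels[vent] <- phantom_labels[["ventricular_eat"]]

  lge <- array(rnorm(prod(dims), config$lge_baseline_mean,
                     config$lge_baseline_sd), dims)
  lge[fibrotic] <- lge[fibrotic] + config$lge_fibrosis_delta

  # ---- landmarks and frame misalignment --------------------------------
  lm_dirs <- rbind(RSPV = c(0.50, 0.45, 0.74),
                   LIPV = c(-0.55, -0.30, 0.78),
                   MV   = c(0.05, -0.08, -0.99),
                   LAA  = c(0.90, -0.42, 0.11))
  lm_dirs <- lm_dirs / sqrt(rowSums(lm_dirs^2))
  s_lm <- 1 / sqrt((lm_dirs[, 1] / a[1])^2 + (lm_dirs[, 2] / a[2])^2 +
                     (lm_dirs[, 3] / a[3])^2)
  lm_xyz <- sweep(lm_dirs * s_lm, 2, center, `+`)
  landmarks_lge <- landmark_set(rownames(lm_dirs), lm_xyz)
  truth_tf <- rigid_transform(
    rotation = rotation_from_euler(config$rigid_misalignment$angles_deg),
    translation = config$rigid_misalignment$translation_mm)
  landmarks_dixon <- apply_rigid(truth_tf, landmarks_lge)

  truth <- list(fibrosis_fraction_target = fib_frac,
                fibrosis_fraction_achieved = achieved,
                cap_centers = caps,
                cap_angle_rad = cap_angle,
                depot_centers_mm = if (nrow(depot_centers))
                  sweep(depot_centers, 2, center, `+`) else depot_centers,
                depot_directions = if (nd > 0L && nrow(depot_centers))
                  depot_centers / sqrt(rowSums(depot_centers^2)) else
                    matrix(numeric(0), 0, 3),
                depot_radius_mm = config$fat_depot_radius_mm,
                coloc_mode = config$coloc_mode,
                transform = truth_tf,
                fibrotic_wall = fibrotic,
                la_center_mm = center,
                seed = config$seed)

  structure(list(labels = label_volume(labels, sp),
                 lge = intensity_volume(lge, sp),
                 landmarks_lge = landmarks_lge,
                 landmarks_dixon = landmarks_dixon,
                 truth = truth,
                 config = config),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf(paste0("<phantom_case> %s grid, fibrosis %.1f%% (target ",
                     "%.1f%%), %d fat depots, mode '%s', seed %d\n"),
              paste(dim(x$labels$data), collapse = "x"),
              100 * x$truth$fibrosis_fraction_achieved,
              100 * x$truth$fibrosis_fraction_target,
              nrow(x$truth$depot_centers_mm), x$truth$coloc_mode,
              x$config$seed))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Derives per-case seeds deterministically from a master seed and applies
#' a mild per-case anatomical jitter (semi-axes scaled by up to +/-8%) so
#' cases differ in size as patients do. Depot placement follows
#' `coloc_mode`: `"near"` puts depot centers inside fibrotic caps, `"far"`
#' keeps them at angular separation beyond every cap radius, `"random"`
#' places them uniformly.
#'
#' @param n_cases number of cases (>= 1).
#' @param base_config shared [phantom_config()]; per-case seed and jitter
#'   are applied on top.
#' @param coloc_mode optional override of `base_config$coloc_mode`.
#' @param seed master seed (defaults to `base_config$seed`).
#' @return list of [make_la_phantom()] cases, class `phantom_cohort`.
#' @export
make_cohort <- function(n_cases, base_config, coloc_mode = NULL,
                        seed = base_config$seed) {
  stopifnot(inherits(base_config, "phantom_config"))
  if (!is.numeric(n_cases) || length(n_cases) != 1L || n_cases < 1)
    stop("n_cases must be a positive integer", call. = FALSE)
  n_cases <- as.integer(n_cases)
  set.seed(as.integer(seed))
  case_seeds <- sample.int(.Machine$integer.max - 1L, n_cases)
  jitter <- matrix(runif(3L * n_cases, 0.92, 1.08), n_cases, 3L)
  cases <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    cfg_i <- unclass(base_config)
    cfg_i$seed <- case_seeds[i]
    cfg_i$la_semiaxes_mm <- base_config$la_semiaxes_mm * jitter[i, ]
    if (!is.null(coloc_mode)) cfg_i$coloc_mode <- coloc_mode
    cases[[i]] <- make_la_phantom(do.call(phantom_config, cfg_i))
  }
  structure(cases, class = "phantom_cohort")
}

# ---- internal geometry helpers ----------------------------------------

runit_vector <- function(n) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# cap centers with a minimum pairwise angular separation (best effort)
sample_cap_centers <- function(k, min_sep_rad, max_tries = 500L) {
  centers <- runit_vector(1)
  tries <- 0L
  while (nrow(centers) < k && tries < max_tries) {
    cand <- runit_vector(1)
    ang <- acos(pmin(1, pmax(-1, centers %*% t(cand))))
    if (all(ang >= min_sep_rad)) centers <- rbind(centers, cand)
    tries <- tries + 1L
  }
  while (nrow(centers) < k) centers <- rbind(centers, runit_vector(1))
  centers
}

min_angle_to_caps <- function(dirs, caps) {
  cosang <- dirs %*% t(caps)
  acos(pmin(1, pmax(-1, apply(cosang, 1, max))))
}

# rotate the cap center by `ang` towards a random azimuth
perturb_direction <- function(u, ang) {
  # orthonormal basis around u
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  phi <- runif(1, 0, 2 * pi)
  cos(ang) * u + sin(ang) * (cos(phi) * e1 + sin(phi) * e2)
}

sample_depot_directions <- function(nd, mode, caps, cap_angle) {
  if (mode != "random" && nrow(caps) == 0L)
    stop("coloc_mode '", mode, "' needs fibrotic caps ",
         "(fibrosis_fraction > 0)", call. = FALSE)
  dirs <- matrix(NA_real_, nd, 3)
  margin <- 10 * pi / 180
  for (k in seq_len(nd)) {
    if (mode == "random") {
      dirs[k, ] <- runit_vector(1)
    } else if (mode == "near") {
      cap <- caps[sample.int(nrow(caps), 1L), ]
      dirs[k, ] <- perturb_direction(cap, runif(1, 0, 0.8 * cap_angle))
    } else { # far: antipodal to a cap, rejected if near any cap
      ok <- FALSE
      for (try in seq_len(2000L)) {
        cap <- caps[sample.int(nrow(caps), 1L), ]
        cand <- perturb_direction(-cap, runif(1, 0, 25 * pi / 180))
        if (min_angle_to_caps(matrix(cand, 1), caps) > cap_angle + margin) {
          dirs[k, ] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("cannot place far-mode fat depots: fibrotic caps cover too ",
             "much of the sphere (cap angle ",
             sprintf("%.1f", cap_angle * 180 / pi), " deg)", call. = FALSE)
    }
  }
  dirs
}
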