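# digitized solid sphere: voxel centroid within `radius` of `center`
# (center and radius in voxel-index units unless spacing applied by caller)
make_sphere_mask <- function(dims, center, radius, spacing = c(1, 1, 1)) {
  m <- array(FALSE, dims)
  idx <- which(!m, arr.ind = TRUE)
  xyz <- sweep(idx - 0.5, 2, spacing, `*`)
  d2 <- (xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
    (xyz[, 3] - center[3])^2
  m[idx[d2 <= radius^2, , drop = FALSE]] <- TRUE
  m
}

make_shell_mask <- function(dims, center, r_in, r_out, spacing = c(1, 1, 1)) {
  m <- array(FALSE, dims)
  idx <- which(!m, arr.ind = TRUE)
  xyz <- sweep(idx - 0.5, 2, spacing, `*`)
  d2 <- (xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
    (xyz[, 3] - center[3])^2
  m[idx[d2 > r_in^2 & d2 <= r_out^2, , drop = FALSE]] <- TRUE
  m
}

# small phantom configuration used throughout the tests (fast to generate)
small_phantom_config <- function(...) {
  phantom_config(grid_shape = c(72L, 72L, 72L),
                 la_semiaxes_mm = c(20, 18, 16),
                 pericardium_offset_mm = 5,
                 fat_depot_radius_mm = 4.5,
                 fat_offset_mm = 2,
                 ...)
}

random_unit_quaternion_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}
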