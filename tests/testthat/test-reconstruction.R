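test_that("sphere surface area and enclosed volume match analytic values", {
  m <- make_sphere_mask(c(40, 40, 40), c(19.6, 20.3, 19.9), 15)
  mesh <- extract_surface(m, c(1, 1, 1))
  expect_lt(abs(mesh_area(mesh) / (4 * pi * 15^2) - 1), 0.05)
  expect_lt(abs(mesh_volume(mesh) / (4 / 3 * pi * 15^3) - 1), 0.05)
  expect_true(mesh_is_closed(mesh))
  # triangles are non-degenerate
  v <- mesh$vertices; f <- mesh$triangles
  a <- v[f[, 2], ] - v[f[, 1], ]; b <- v[f[, 3], ] - v[f[, 1], ]
  areas <- 0.5 * sqrt((a[, 2] * b[, 3] - a[, 3] * b[, 2])^2 +
                        (a[, 3] * b[, 1] - a[, 1] * b[, 3])^2 +
                        (a[, 1] * b[, 2] - a[, 2] * b[, 1])^2)
  expect_true(all(areas > 0))
})

test_that("mesh error against analytic values shrinks with voxel size", {
  err <- vapply(c(1, 0.5), function(h) {
    n <- ceiling(24 / h + 6)
    m <- make_sphere_mask(rep(n, 3), rep(n * h / 2 + 0.13, 3), 10,
                          spacing = rep(h, 3))
    mesh <- extract_surface(m, rep(h, 3))
    abs(mesh_volume(mesh) / (4 / 3 * pi * 1000) - 1)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("two disjoint blobs give a two-component surface", {
  m <- array(FALSE, c(40, 20, 20))
  m <- m | make_sphere_mask(c(40, 20, 20), c(10.2, 10.1, 9.9), 4)
  m <- m | make_sphere_mask(c(40, 20, 20), c(30.3, 10.2, 10.1), 4)
  mesh <- extract_surface(m, c(1, 1, 1))
  expect_identical(mesh_components(mesh), 2L)
})

test_that("surface extraction rejects empty and boundary-touching masks", {
  expect_error(extract_surface(array(FALSE, c(8, 8, 8)), c(1, 1, 1)),
               "empty")
  m <- array(FALSE, c(8, 8, 8)); m[1:4, 4, 4] <- TRUE
  expect_error(extract_surface(m, c(1, 1, 1)), "pad")
})

test_that("fat volumetrization conserves volume exactly", {
  set.seed(21)
  m <- array(FALSE, c(8, 8, 8))
  m[cbind(sample(2:7, 10, TRUE), sample(2:7, 10, TRUE),
          sample(2:7, 10, TRUE))] <- TRUE
  m[3, 3, 3] <- TRUE  # ensure >= 1
  nvox <- sum(m)
  fm1 <- volumetrize_fat(m, c(1, 1, 1.5), target_spacing_mm = 2)
  expect_identical(nrow(fm1$points), nvox)
  expect_identical(fm1$total_volume, nvox * 1.5)
  # subdivision multiplies the sample count, not the volume
  fm2 <- volumetrize_fat(m, c(1, 1, 1.5), target_spacing_mm = 0.5)
  expect_identical(nrow(fm2$points), nvox * 2L * 2L * 3L)
  expect_identical(fm2$total_volume, fm1$total_volume)
  expect_lt(abs(sum(fm2$volumes) - fm2$total_volume) /
              fm2$total_volume, 1e-9)
  # samples lie inside fat voxels
  idx <- ceiling(sweep(fm2$points, 2, c(1, 1, 1.5), `/`) - 1e-12)
  expect_true(all(m[idx]))
})

test_that("ten unit fat voxels of 1.5 mm slices hold 15 mm^3", {
  m <- array(FALSE, c(8, 8, 8))
  m[2:6, 3, c(2, 4)] <- TRUE  # 10 voxels
  fm <- volumetrize_fat(m, c(1, 1, 1.5), target_spacing_mm = 2)
  expect_identical(fm$total_volume, 15)
})

test_that("empty fat mask gives an empty model, not an error", {
  fm <- volumetrize_fat(array(FALSE, c(5, 5, 5)), c(1, 1, 1))
  expect_identical(nrow(fm$points), 0L)
  expect_identical(fm$total_volume, 0)
})

test_that("fibrosis label transfer is complete, constant-safe and stable", {
  m <- make_sphere_mask(c(32, 32, 32), c(16.2, 16.1, 15.9), 9)
  wall <- build_wall_mask(m, c(1, 1, 1), 2)$wall_mask
  mesh <- extract_surface(m | wall, c(1, 1, 1))
  all_fib <- map_fibrosis_to_surface(mesh, wall, wall, c(1, 1, 1))
  expect_true(all(all_fib$attrs$fibrotic == 1L))
  none <- map_fibrosis_to_surface(mesh, array(FALSE, dim(wall)), wall,
                                  c(1, 1, 1))
  expect_true(all(none$attrs$fibrotic == 0L))
  again <- map_fibrosis_to_surface(mesh, wall, wall, c(1, 1, 1))
  expect_identical(all_fib$attrs$fibrotic, again$attrs$fibrotic)
  expect_error(map_fibrosis_to_surface(mesh, wall, array(FALSE, dim(wall)),
                                       c(1, 1, 1)), "empty")
})

test_that("a hemispheric fibrotic cap labels half the sphere surface", {
  ctr <- c(16.2, 16.1, 15.9)
  m <- make_sphere_mask(c(32, 32, 32), ctr, 9)
  wall <- build_wall_mask(m, c(1, 1, 1), 2)$wall_mask
  # fibrotic: wall voxels with centroid above the equatorial plane
  fib <- wall
  zc <- (slice.index(wall, 3) - 0.5) * 1
  fib[zc <= ctr[3]] <- FALSE
  mesh <- extract_surface(m | wall, c(1, 1, 1))
  mesh <- map_fibrosis_to_surface(mesh, fib, wall, c(1, 1, 1))
  expect_lt(abs(mean(mesh$attrs$fibrotic) - 0.5), 0.05)
})
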