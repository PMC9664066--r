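random_instance <- function(n, k, seed) {
  set.seed(seed)
  list(mesh = surface_mesh(matrix(runif(3 * n, 0, 60), n, 3),
                           matrix(integer(0), 0, 3)),
       fat = fat_model(matrix(runif(3 * k, 0, 60), k, 3),
                       runif(k, 0.1, 2)))
}

test_that("a vertex sitting on a fat sample has zero distance", {
  P <- rbind(c(10, 10, 10), c(20, 5, 8))
  fat <- fat_model(P, c(1, 1))
  mesh <- surface_mesh(rbind(c(10, 10, 10), c(0, 0, 0)),
                       matrix(integer(0), 0, 3))
  d <- compute_deat_map(mesh, fat)
  expect_identical(d[1], 0)
  expect_equal(d[2], sqrt(300))
})

test_that("a single distant depot gives the analytic distance range", {
  m <- make_sphere_mask(c(52, 52, 52), c(26.2, 26.1, 25.9), 20)
  mesh <- extract_surface(m, c(1, 1, 1))
  fat <- fat_model(matrix(c(26.2, 26.1, 25.9) + c(30, 0, 0), 1, 3),
                   1)
  d <- compute_deat_map(mesh, fat)
  tol <- 1.5  # mesh vertices sit within a voxel of the ideal sphere
  expect_lt(abs(min(d) - 10), tol)
  expect_lt(abs(max(d) - 50), tol)
})

test_that("indexed maps equal the brute-force scans exactly", {
  for (seed in 1:6) {
    inst <- random_instance(400, 800, seed)
    expect_identical(compute_deat_map(inst$mesh, inst$fat, method = "grid"),
                     compute_deat_map(inst$mesh, inst$fat,
                                      method = "brute"))
    expect_identical(
      compute_veat_map(inst$mesh, inst$fat, 5, method = "grid"),
      compute_veat_map(inst$mesh, inst$fat, 5, method = "brute"))
  }
})

test_that("V_EAT sums all fat when everything lies within the radius", {
  set.seed(41)
  P <- matrix(rnorm(300, 0, 1), 100, 3)
  vols <- runif(100, 0.2, 1.3)
  fat <- fat_model(P, vols)
  mesh <- surface_mesh(rbind(c(0, 0, 0), c(100, 100, 100)),
                       matrix(integer(0), 0, 3))
  v <- compute_veat_map(mesh, fat, radius_mm = 50)
  expect_identical(v[1], sum(vols))   # completeness at the near vertex
  expect_identical(v[2], 0)           # nothing within reach of the far one
})

test_that("V_EAT is non-decreasing in the radius", {
  inst <- random_instance(150, 400, 9)
  radii <- c(1, 2, 5, 8, 12)
  V <- vapply(radii, function(r) compute_veat_map(inst$mesh, inst$fat, r),
              numeric(150))
  expect_true(all(apply(V, 1, function(row) all(diff(row) >= 0))))
})

test_that("maps are invariant under a common rigid motion", {
  inst <- random_instance(200, 500, 12)
  tf <- rigid_transform(rotation_from_euler(c(15, -30, 55)), c(7, -4, 12))
  mesh2 <- apply_rigid(tf, inst$mesh)
  fat2 <- apply_rigid(tf, inst$fat)
  expect_lt(max(abs(compute_deat_map(mesh2, fat2) -
                      compute_deat_map(inst$mesh, inst$fat))), 1e-9)
  expect_lt(max(abs(compute_veat_map(mesh2, fat2, 5) -
                      compute_veat_map(inst$mesh, inst$fat, 5))), 1e-9)
})

test_that("coverage, d_EAT and V_EAT are mutually consistent", {
  inst <- random_instance(300, 600, 15)
  maps <- compute_coloc_maps(inst$mesh, inst$fat, radius_mm = 5)
  expect_true(all(maps$d_eat >= 0))
  expect_identical(maps$coverage == 1L, maps$d_eat <= 5)
  expect_identical(maps$coverage == 1L, maps$v_eat > 0)
  expect_true(all(maps$v_eat <= inst$fat$total_volume + 1e-9))
})

test_that("an empty fat model is an error for d_EAT, zeros for V_EAT", {
  mesh <- surface_mesh(matrix(runif(30), 10, 3), matrix(integer(0), 0, 3))
  none <- fat_model(matrix(numeric(0), 0, 3), numeric(0))
  expect_error(compute_deat_map(mesh, none), "no EAT")
  expect_identical(compute_veat_map(mesh, none, 5), numeric(10))
})

test_that("stratification partitions vertices and flags empty groups", {
  mesh <- surface_mesh(matrix(runif(30), 10, 3), matrix(integer(0), 0, 3))
  fat <- fat_model(matrix(runif(9, 0, 1), 3, 3), rep(1, 3))
  maps <- compute_coloc_maps(mesh, fat, radius_mm = 5)
  expect_error(stratify_by_fibrosis(maps, mesh), "fibrotic")
  mesh$attrs$fibrotic <- rep(c(1L, 0L), 5)
  s <- stratify_by_fibrosis(maps, mesh)
  expect_identical(length(s$fibrotic$d_eat), 5L)
  expect_identical(length(s$non_fibrotic$d_eat), 5L)
  expect_null(s$empty_group)
  mesh$attrs$fibrotic <- rep(1L, 10)
  s2 <- stratify_by_fibrosis(maps, mesh)
  expect_identical(s2$empty_group, "non_fibrotic")
  expect_identical(length(s2$fibrotic$d_eat), 10L)
})

test_that("coverage fractions count covered vertices per group", {
  # hand-built: 4 fibrotic vertices (3 covered), 2 non-fibrotic (1 covered)
  maps <- structure(list(d_eat = c(1, 2, 3, 9, 1, 9),
                         v_eat = c(5, 5, 5, 0, 5, 0),
                         coverage = c(1L, 1L, 1L, 0L, 1L, 0L),
                         radius_mm = 5), class = "coloc_maps")
  mesh <- surface_mesh(matrix(0, 6, 3), matrix(integer(0), 0, 3),
                       attrs = list(fibrotic = c(1L, 1L, 1L, 1L, 0L, 0L)))
  s <- stratify_by_fibrosis(maps, mesh)
  cov <- coverage_fraction(s)
  expect_equal(cov[["fibrotic"]], 75)
  expect_equal(cov[["non_fibrotic"]], 50)
})

test_that("the sphere-shell phantom brackets d_EAT analytically", {
  # LA sphere R = 15, fat shell gap D = 3, thickness 2, 1 mm voxels
  ctr <- c(22.2, 22.1, 21.9)
  la <- make_sphere_mask(c(44, 44, 44), ctr, 15)
  shell <- make_shell_mask(c(44, 44, 44), ctr, 18, 20)
  mesh <- extract_surface(la, c(1, 1, 1))
  fat <- volumetrize_fat(shell, c(1, 1, 1), target_spacing_mm = 1)
  d <- compute_deat_map(mesh, fat)
  delta <- sqrt(3)  # sample-spacing diagonal
  expect_true(all(d >= 3 - delta))
  expect_true(all(d <= 3 + 2 + delta))
})
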