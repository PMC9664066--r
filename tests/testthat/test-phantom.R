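test_that("spherical blood pool volume matches the analytic sphere", {
  cfg <- phantom_config(grid_shape = c(64L, 64L, 64L),
                        la_semiaxes_mm = c(20, 20, 20),
                        pericardium_offset_mm = 4,
                        fat_depot_radius_mm = 4,
                        ventricular_fat = FALSE, seed = 1)
  case <- make_la_phantom(cfg)
  vol <- sum(case$labels$data == phantom_labels[["blood_pool"]]) *
    prod(case$labels$spacing)
  expect_lt(abs(vol / (4 / 3 * pi * 20^3) - 1), 0.05)
})

test_that("zero fat depots give an empty EAT class and a zero fat model", {
  case <- make_la_phantom(small_phantom_config(n_fat_depots = 0L, seed = 2))
  eat <- case$labels$data == phantom_labels[["eat"]]
  expect_false(any(eat))
  fm <- volumetrize_fat(eat, case$labels$spacing)
  expect_identical(nrow(fm$points), 0L)
  expect_identical(fm$total_volume, 0)
})

test_that("identical config and seed give bit-identical cases", {
  a <- make_la_phantom(small_phantom_config(seed = 42))
  b <- make_la_phantom(small_phantom_config(seed = 42))
  expect_identical(a$labels$data, b$labels$data)
  expect_identical(a$lge$data, b$lge$data)
  expect_identical(a$landmarks_dixon$coords, b$landmarks_dixon$coords)
})

test_that("EAT voxels lie strictly between wall exterior and pericardium", {
  case <- make_la_phantom(small_phantom_config(seed = 3))
  labs <- case$labels$data
  bp <- labs == phantom_labels[["blood_pool"]]
  d <- eatcoloc:::distance_to_mask(bp, case$labels$spacing)
  eat_d <- d[labs == phantom_labels[["eat"]]]
  cfg <- case$config
  expect_true(all(eat_d > cfg$wall_thickness_mm))
  expect_true(all(eat_d <= cfg$wall_thickness_mm + cfg$pericardium_offset_mm))
  # one label per voxel is structural; classes partition the grid
  expect_true(all(labs %in% phantom_labels))
})

test_that("achieved fibrosis fraction tracks the request across seeds", {
  cohort <- make_cohort(20, small_phantom_config(fibrosis_fraction = 0.2),
                        seed = 11)
  achieved <- vapply(cohort, function(cs)
    cs$truth$fibrosis_fraction_achieved, numeric(1))
  expect_lt(mean(abs(achieved - 0.2)), 0.03)
})

test_that("LGE contrast between fibrotic and normal wall recovers delta", {
  cfg <- small_phantom_config(seed = 5, lge_fibrosis_delta = 30,
                              lge_baseline_sd = 6)
  case <- make_la_phantom(cfg)
  wall <- case$labels$data == phantom_labels[["wall"]]
  fib <- case$truth$fibrotic_wall
  v_f <- case$lge$data[wall & fib]
  v_n <- case$lge$data[wall & !fib]
  se <- sqrt(var(v_f) / length(v_f) + var(v_n) / length(v_n))
  expect_lt(abs((mean(v_f) - mean(v_n)) - 30), 3 * se)
})

test_that("Dixon landmarks are the true transform applied to LGE ones", {
  case <- make_la_phantom(small_phantom_config(seed = 6))
  moved <- apply_rigid(case$truth$transform, case$landmarks_lge)
  expect_lt(max(abs(moved$coords - case$landmarks_dixon$coords)), 1e-9)
})

test_that("cohort depot placement honours the colocalization mode", {
  near <- make_cohort(3, small_phantom_config(), coloc_mode = "near",
                      seed = 7)
  for (cs in near) {
    ang <- eatcoloc:::min_angle_to_caps(cs$truth$depot_directions,
                                        cs$truth$cap_centers)
    expect_true(all(ang <= cs$truth$cap_angle_rad))
  }
  far <- make_cohort(3, small_phantom_config(), coloc_mode = "far",
                     seed = 7)
  for (cs in far) {
    ang <- eatcoloc:::min_angle_to_caps(cs$truth$depot_directions,
                                        cs$truth$cap_centers)
    expect_true(all(ang > cs$truth$cap_angle_rad))
  }
  # random mode: distinct depot centers, reproducible
  r1 <- make_cohort(3, small_phantom_config(), coloc_mode = "random",
                    seed = 7)
  r2 <- make_cohort(3, small_phantom_config(), coloc_mode = "random",
                    seed = 7)
  centers <- lapply(r1, function(cs) cs$truth$depot_centers_mm)
  expect_gt(nrow(unique(do.call(rbind, centers))), nrow(centers[[1]]))
  expect_identical(centers, lapply(r2, function(cs)
    cs$truth$depot_centers_mm))
})

test_that("invalid phantom parameters fail early with a clear message", {
  expect_error(make_la_phantom(phantom_config(grid_shape = c(40L, 40L, 40L),
                                              la_semiaxes_mm = c(25, 22, 20))),
               "overflow")
  expect_error(phantom_config(fibrosis_fraction = 0.2,
                              fibrosis_patch_count = 0L), "unreachable")
  expect_error(phantom_config(fibrosis_fraction = 1.2), "0, 1")
  expect_error(phantom_config(wall_thickness_mm = -1), "positive")
  expect_error(make_cohort(0, small_phantom_config()), "positive")
})
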