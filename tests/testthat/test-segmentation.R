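test_that("wall from a single voxel is the 2 mm lattice ball minus center", {
  endo <- array(FALSE, c(9, 9, 9))
  endo[5, 5, 5] <- TRUE
  w <- build_wall_mask(endo, c(1, 1, 1), dilation_mm = 2)
  # 33 integer offsets with Euclidean norm <= 2, minus the center voxel
  expect_identical(sum(w$wall_mask), 32L)
  expect_false(any(w$wall_mask & endo))
})

test_that("zero dilation gives an empty wall", {
  endo <- make_sphere_mask(c(16, 16, 16), c(8.2, 8.1, 7.9), 4)
  w <- build_wall_mask(endo, c(1, 1, 1), dilation_mm = 0)
  expect_identical(sum(w$wall_mask), 0L)
})

test_that("spherical shell wall volume matches the analytic value", {
  sp <- c(0.5, 0.5, 0.5)
  endo <- make_sphere_mask(c(56, 56, 56), c(14.1, 14.2, 13.9), 10,
                           spacing = sp)
  w <- build_wall_mask(endo, sp, dilation_mm = 2)
  shell <- 4 / 3 * pi * (12^3 - 10^3)
  expect_lt(abs(w$wall_volume_mm3 / shell - 1), 0.10)
})

test_that("anisotropic dilation uses a metric ball", {
  endo <- array(FALSE, c(9, 9, 9))
  endo[5, 5, 5] <- TRUE
  w <- build_wall_mask(endo, c(1, 1, 2), dilation_mm = 2)
  # offsets (i,j,k) with i^2 + j^2 + 4 k^2 <= 4: k=0 ring of 12 + k=+-1
  # single voxels + center = 15 lattice points, minus the center
  expect_identical(sum(w$wall_mask), 14L)
})

test_that("uniform wall intensity yields zero fibrosis with a warning", {
  endo <- make_sphere_mask(c(24, 24, 24), c(12.2, 12.1, 11.9), 6)
  w <- build_wall_mask(endo, c(1, 1, 1), 2)
  lge <- array(7, c(24, 24, 24))
  expect_warning(f <- quantify_fibrosis(lge, w, 3), "zero intensity")
  expect_identical(f$fibrosis_percent, 0)
})

test_that("planted enhancement is recovered at the default threshold", {
  set.seed(31)
  endo <- make_sphere_mask(c(40, 40, 40), c(20.2, 20.1, 19.9), 12)
  w <- build_wall_mask(endo, c(1, 1, 1), 2)
  lge <- array(rnorm(40^3, 40, 6), c(40, 40, 40))
  wall_idx <- which(w$wall_mask)
  planted <- wall_idx[seq_len(floor(0.2 * length(wall_idx)))]
  lge[planted] <- lge[planted] + 36  # +6 sigma
  f <- quantify_fibrosis(lge, w, 3)
  expect_lt(abs(f$fibrosis_percent - 20), 3)
  expect_true(all(which(f$fibrotic_mask) %in% wall_idx))
})

test_that("a threshold below the minimum labels the whole wall", {
  set.seed(32)
  endo <- make_sphere_mask(c(24, 24, 24), c(12.2, 12.1, 11.9), 6)
  w <- build_wall_mask(endo, c(1, 1, 1), 2)
  lge <- array(rnorm(24^3, 40, 6), c(24, 24, 24))
  f <- quantify_fibrosis(lge, w, threshold_k = -50)
  expect_identical(f$fibrosis_percent, 100)
})

test_that("fibrosis percent is non-increasing in threshold_k", {
  set.seed(33)
  endo <- make_sphere_mask(c(28, 28, 28), c(14.2, 14.1, 13.9), 8)
  w <- build_wall_mask(endo, c(1, 1, 1), 2)
  lge <- array(rnorm(28^3, 40, 6), c(28, 28, 28))
  pct <- vapply(c(-2, 0, 1, 2, 3, 4, 6),
                function(k) quantify_fibrosis(lge, w, k)$fibrosis_percent,
                numeric(1))
  expect_true(all(diff(pct) <= 0))
})

test_that("the fibrotic mask is scale equivariant", {
  set.seed(34)
  endo <- make_sphere_mask(c(28, 28, 28), c(14.2, 14.1, 13.9), 8)
  w <- build_wall_mask(endo, c(1, 1, 1), 2)
  lge <- array(rnorm(28^3, 40, 6), c(28, 28, 28))
  wall_idx <- which(w$wall_mask)
  lge[wall_idx[1:200]] <- lge[wall_idx[1:200]] + 36
  f1 <- quantify_fibrosis(lge, w, 3)
  f2 <- quantify_fibrosis(lge * 3.7, w, 3)
  expect_identical(f1$fibrotic_mask, f2$fibrotic_mask)
})

test_that("degenerate segmentation inputs raise errors", {
  expect_error(build_wall_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1), 2),
               "empty")
  endo <- array(FALSE, c(6, 6, 6)); endo[3, 3, 3] <- TRUE
  expect_warning(build_wall_mask(endo, c(1, 1, 1), 0.4), "smaller")
  w <- build_wall_mask(endo, c(1, 1, 1), 2)
  lge <- array(1, c(6, 6, 6)); lge[2, 3, 3] <- NaN
  expect_error(quantify_fibrosis(lge, w, 3), "NaN")
  expect_error(quantify_fibrosis(array(1, c(5, 5, 5)), w, 3),
               "different grids")
})
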