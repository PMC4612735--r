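test_that("image_volume validates spacing, origin and finiteness", {
  expect_error(image_volume(array(1, c(2, 2)), c(1, 1, 1)), "3D")
  expect_error(image_volume(array(1, c(2, 2, 2)), c(1, -1, 1)), "positive")
  a <- array(1, c(2, 2, 2)); a[1] <- NA
  expect_error(image_volume(a), "finite")
})

test_that("trilinear sampling interpolates and flags out-of-bounds queries", {
  v <- image_volume(array(seq_len(8), c(2, 2, 2)), spacing = c(2, 2, 2))
  # voxel centers reproduce exact values
  s <- sample_trilinear(v, rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 2)))
  expect_equal(s$values, c(1, 2, 7))
  expect_true(all(s$in_bounds))
  # midpoint of the cell averages all eight corners
  m <- sample_trilinear(v, rbind(c(1, 1, 1)))
  expect_equal(m$values, mean(1:8))
  # outside the voxel-center hull: flagged, clamped value still finite
  o <- sample_trilinear(v, rbind(c(-1, 0, 0), c(5, 2, 2)))
  expect_identical(o$in_bounds, c(FALSE, FALSE))
  expect_true(all(is.finite(o$values)))
})

test_that("seed conversion honours the frame and rejects outside seeds", {
  v <- uniform_volume(40, dim = c(10, 10, 10), spacing = c(2, 2, 2))
  expect_equal(seed_to_world(seed_point(c(3, 4, 5), "voxel"), v),
               c(6, 8, 10))
  expect_equal(seed_to_world(seed_point(c(6, 8, 10)), v), c(6, 8, 10))
  expect_error(seed_to_world(seed_point(c(100, 0, 0)), v), "out-of-bounds")
})

test_that("reference value: constant field, two-level mean, needle-robust median", {
  v <- uniform_volume(40, dim = c(21, 21, 21), spacing = c(2, 2, 2))
  ctr <- c(20, 20, 20)
  expect_equal(estimate_reference_value(v, ctr), 40)

  # half 40 / half 60 -> mean 50: 1 cm^3 at 2 mm spacing is a 5^3 cube;
  # make the plane split give exactly half along a 10-voxel stretch
  a <- array(40, c(20, 21, 21))
  a[12:20, , ] <- 60  # the 10-voxel window at the seed straddles 5 of each
  v2 <- image_volume(a, spacing = c(1, 2, 2))
  # cube spans x indices centered on the 40/60 interface
  ref <- estimate_reference_value(v2, seed_point(c(10, 10, 10), "voxel"),
                                  mode = "mean")
  expect_equal(ref, 50)

  # 124 voxels at 40 plus one bright needle voxel: median unaffected
  b <- array(40, c(5, 5, 5))
  b[3, 3, 3] <- 1000
  v3 <- image_volume(b, spacing = c(2, 2, 2))
  expect_equal(estimate_reference_value(v3, c(4, 4, 4), mode = "median"), 40)
})

test_that("reference value is translation invariant and outlier-bounded", {
  set.seed(11)
  base <- array(rnorm(13^3, 100, 5), c(13, 13, 13))
  v <- image_volume(base, spacing = c(1, 1, 1))
  r1 <- estimate_reference_value(v, seed_point(c(4, 4, 4), "voxel"))
  shifted <- array(0, c(13, 13, 13))
  shifted[3:13, 3:13, 3:13] <- base[1:11, 1:11, 1:11]
  v2 <- image_volume(shifted, spacing = c(1, 1, 1))
  r2 <- estimate_reference_value(v2, seed_point(c(6, 6, 6), "voxel"))
  expect_equal(r1, r2)

  # <= 10% outliers: median unchanged, mean shift bounded
  cube <- array(40, c(10, 10, 10))
  v3 <- image_volume(cube, spacing = c(1, 1, 1))
  n_out <- 100  # 10% of the 1000-voxel cube
  cube_out <- cube
  cube_out[seq_len(n_out)] <- 1000
  v4 <- image_volume(cube_out, spacing = c(1, 1, 1))
  seed <- seed_point(c(4.5, 4.5, 4.5), "voxel")
  expect_equal(estimate_reference_value(v4, seed, mode = "median"), 40)
  mean_shift <- estimate_reference_value(v4, seed, mode = "mean") - 40
  expect_lte(mean_shift, 0.1 * (1000 - 40) + 1e-9)
})

test_that("degenerate averaging regions are reported", {
  v <- uniform_volume(1, dim = c(3, 3, 3), spacing = c(0.5, 0.5, 0.5))
  expect_error(estimate_reference_value(v, c(10, 0, 0)), "out-of-bounds")
  expect_error(
    estimate_reference_value(v, c(0.5, 0.5, 0.5), region_volume_mm3 = -5),
    "positive")
})
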