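test_that("noise-free phantom without rim or needle is two-valued", {
  ph <- generate_phantom(phantom_spec(lesion_radii = c(8, 8, 8),
                                      spacing = c(1, 1, 1)))
  expect_identical(sort(unique(as.vector(ph$volume$values))), c(40, 110))
  expect_identical(ph$truth$grid, ph$volume$values == 40)
})

test_that("ground-truth volume matches the analytic ellipsoid within 3%", {
  radii <- c(15, 12, 18)
  ph <- generate_phantom(phantom_spec(lesion_radii = radii,
                                      spacing = c(0.7, 0.7, 1)))
  analytic <- 4 / 3 * pi * prod(radii)
  expect_lt(abs(ph$truth$volume_mm3 - analytic) / analytic, 0.03)
})

test_that("phantoms are bit-identical for a fixed spec and leave the RNG alone", {
  spec <- phantom_spec(lesion_radii = c(8, 8, 8), rim_thickness = 2,
                       needle = TRUE, noise_sigma = 10, rng_seed = 33)
  set.seed(1); x1 <- runif(1)
  a <- generate_phantom(spec)
  x2 <- runif(1)
  b <- generate_phantom(spec)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$truth$grid, b$truth$grid)
  set.seed(1)
  expect_identical(c(x1, x2), runif(2))  # caller RNG stream undisturbed
})

test_that("structures are painted in order and the needle never belongs to truth", {
  spec <- phantom_spec(lesion_radii = c(10, 10, 10), rim_thickness = 2,
                       needle = TRUE)
  ph <- generate_phantom(spec)
  vals <- ph$volume$values
  expect_setequal(unique(as.vector(vals)), c(40, 110, 160, 1000))
  needle <- vals == 1000
  expect_gt(sum(needle), 0)
  expect_true(!any(ph$truth$grid & needle))
  # the rim is a shell: bright voxels adjacent to the lesion, none inside
  expect_true(!any(ph$truth$grid & vals == 160))
})

test_that("intensity-ordering violations are rejected", {
  expect_error(phantom_spec(lesion_intensity = 120, background = 110),
               "ordering")
  expect_error(phantom_spec(rim_thickness = 2, rim_intensity = 100),
               "ordering")
  expect_error(phantom_spec(needle = TRUE, needle_intensity = 50),
               "brightest")
  expect_error(phantom_spec(lesion_radii = c(50, 50, 50),
                            shape = c(20, 20, 20)), "fit")
})

test_that("the case suite spans clinically typical volume and spacing ranges", {
  specs <- phantom_case_suite(12, rng_seed = 4)
  expect_length(specs, 12)
  expect_identical(sum(vapply(specs, function(s) s$needle, logical(1))), 6L)
  vols <- vapply(specs, function(s)
    4 / 3 * pi * prod(s$lesion_radii) / 1000, numeric(1))
  expect_true(all(vols >= 6.25 & vols <= 122.62))
  for (s in specs) {
    expect_true(all(s$spacing[1:2] >= 0.679 & s$spacing[1:2] <= 0.777))
    expect_true(s$spacing[3] >= 1 && s$spacing[3] <= 3)
  }
  # reproducible for a fixed seed
  specs2 <- phantom_case_suite(12, rng_seed = 4)
  expect_identical(specs, specs2)
})

test_that("phantom specs round-trip through YAML", {
  spec <- phantom_spec(lesion_radii = c(9, 8, 10), rim_thickness = 1.5,
                       needle = TRUE, noise_sigma = 5, rng_seed = 77)
  path <- tempfile(fileext = ".yaml")
  write_phantom_spec(spec, path)
  back <- read_phantom_spec(path)
  expect_equal(back$lesion_radii, spec$lesion_radii)
  expect_equal(back$rim_thickness, spec$rim_thickness)
  expect_identical(back$rng_seed, spec$rng_seed)
  expect_identical(generate_phantom(back)$volume$values,
                   generate_phantom(spec)$volume$values)
})
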