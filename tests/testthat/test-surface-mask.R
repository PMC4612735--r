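test_that("a delta_r = 0 cut yields the template sphere scaled to the cut radius", {
  tpl <- ray_template(2)
  v <- uniform_volume(100, dim = c(41, 41, 41))
  ctr <- c(20, 20, 20)
  p <- graph_cut_params(delta_r = 0, nodes_per_ray = 10, max_radius_mm = 10,
                        template_level = 2)
  g <- sample_node_grid(v, ctr, tpl, p, reference_value = 100)
  net <- build_flow_network(g, tpl, p)
  cst <- boundary_constraint(ctr + 5 * tpl$directions[3, ])
  cut <- solve_min_cut(apply_boundary_constraints(net, g, list(cst)))
  mesh <- cut_to_surface(cut, tpl)
  radii <- sqrt(rowSums(sweep(mesh$vertices, 2, ctr)^2))
  expect_equal(radii, rep(5, nrow(tpl$directions)))
  expect_true(all(radii <= p$max_radius_mm))
  # Euler characteristic of the closed surface (faces = template faces)
  expect_identical(nrow(mesh$vertices) - nrow(tpl$adjacency) +
                     nrow(mesh$faces), 2L)
})

test_that("voxelized sphere volume approximates the analytic ball", {
  tpl <- ray_template(3)
  mesh <- template_mesh(tpl)
  mesh$vertices <- mesh$vertices * 15  # radius 15 mm sphere
  ref <- uniform_volume(0, dim = c(41, 41, 41), spacing = c(1, 1, 1))
  mesh$vertices <- sweep(mesh$vertices, 2, c(20, 20, 20), "+")
  mask <- voxelize_surface(mesh, ref)
  analytic <- 4 / 3 * pi * 15^3
  expect_lt(abs(mask$volume_mm3 - analytic) / analytic, 0.05)
})

test_that("voxelization error shrinks with finer spacing", {
  tpl <- ray_template(3)
  err <- vapply(c(1, 0.5), function(s) {
    n <- round(24 / s) + 1
    ref <- uniform_volume(0, dim = rep(n, 3), spacing = rep(s, 3))
    ctr <- rep((n - 1) * s / 2, 3)
    mesh <- template_mesh(tpl)
    mesh$vertices <- sweep(mesh$vertices * 9, 2, ctr, "+")
    m <- voxelize_surface(mesh, ref)
    abs(m$volume_mm3 - 4 / 3 * pi * 9^3)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("meshes outside the grid give an empty mask with a warning", {
  tpl <- ray_template(1)
  mesh <- template_mesh(tpl)
  mesh$vertices <- sweep(mesh$vertices * 2, 2, c(100, 100, 100), "+")
  ref <- uniform_volume(0, dim = c(10, 10, 10))
  expect_warning(mask <- voxelize_surface(mesh, ref), "empty")
  expect_identical(mask$voxel_count, 0L)
})

test_that("non-watertight meshes are rejected", {
  tpl <- ray_template(1)
  mesh <- template_mesh(tpl)
  mesh$faces <- mesh$faces[-1, ]
  ref <- uniform_volume(0, dim = c(10, 10, 10))
  expect_error(voxelize_surface(mesh, ref), "watertight")
})

test_that("contour voxelization: exact square fill, disjoint slices, orientation-free", {
  ref <- uniform_volume(0, dim = c(20, 20, 5))
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(0, 0))
  m1 <- voxelize_contours(list(list(slice = 2, points = sq)), ref)
  expect_identical(m1$voxel_count, 100L)
  expect_true(all(which(m1$grid, arr.ind = TRUE)[, 3] == 2L))

  # clockwise orientation gives the identical mask
  m2 <- voxelize_contours(list(list(slice = 2, points = sq[5:1, ])), ref)
  expect_identical(m1$grid, m2$grid)

  # two disjoint slices merge by union
  tri <- rbind(c(2, 2), c(9, 2), c(2, 9), c(2, 2))
  m3 <- voxelize_contours(list(list(slice = 1, points = sq),
                               list(slice = 4, points = tri)), ref)
  m_tri <- voxelize_contours(list(list(slice = 4, points = tri)), ref)
  expect_identical(m3$voxel_count, 100L + m_tri$voxel_count)

  expect_error(voxelize_contours(list(list(slice = 1, points = sq[1:4, ])),
                                 ref), "open polygon")
  expect_error(voxelize_contours(list(list(slice = 9, points = sq)), ref),
               "slice")
})

test_that("mask volume identity and re-voxelization stability", {
  g <- array(FALSE, c(10, 10, 10)); g[3:7, 3:7, 3:7] <- TRUE
  m <- segmentation_mask(g, spacing = c(1, 1, 2))
  expect_equal(m$volume_mm3, m$voxel_count * 2)

  # voxelizing a sphere mesh twice on the same grid is idempotent
  tpl <- ray_template(2)
  ref <- uniform_volume(0, dim = c(31, 31, 31))
  mesh <- template_mesh(tpl)
  mesh$vertices <- sweep(mesh$vertices * 10, 2, c(15, 15, 15), "+")
  a <- voxelize_surface(mesh, ref)
  b <- voxelize_surface(mesh, ref)
  expect_identical(a$grid, b$grid)
})
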