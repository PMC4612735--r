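test_that("parameter validation enforces the documented ranges", {
  expect_error(graph_cut_params(delta_r = -1), "non-negative")
  expect_error(graph_cut_params(nodes_per_ray = 1), ">= 2")
  expect_error(graph_cut_params(delta_r = 40, nodes_per_ray = 40), "smaller")
  expect_error(graph_cut_params(max_radius_mm = 0), "positive")
  expect_error(graph_cut_params(template_level = 6), "between 0 and 5")
})

test_that("node sampling: radial rule, costs, out-of-bounds flagging", {
  tpl <- ray_template(1)
  v <- uniform_volume(100, dim = c(41, 41, 41), spacing = c(1, 1, 1))
  p <- graph_cut_params(delta_r = 1, nodes_per_ray = 40, max_radius_mm = 40,
                        template_level = 1)
  g <- sample_node_grid(v, c(20, 20, 20), tpl, p, reference_value = 100)
  # nodes at 1, 2, ..., 40 mm
  expect_equal(g$radii, 1:40)
  expect_true(all(diff(g$radii) > 0))
  # constant volume at the reference: all in-bounds costs numerically zero
  expect_lt(max(g$cost[g$in_bounds]), 1e-9)
  expect_true(all(g$cost >= 0))

  # seed 5 mm from a face: some nodes out of bounds, all values finite
  g2 <- sample_node_grid(v, c(5, 20, 20), tpl, p, reference_value = 100)
  expect_gt(sum(!g2$in_bounds), 0)
  expect_true(all(is.finite(g2$gray)))
  expect_true(all(g2$cost[!g2$in_bounds] > max(g2$cost[g2$in_bounds])))
  expect_error(sample_node_grid(v, c(-5, 0, 0), tpl, p, 100), "out-of-bounds")
})

test_that("inter-edges respect delta_r level shifts and the seed is forced foreground", {
  tpl <- ray_template(0)
  J <- 4L
  cost <- matrix(runif(12 * J), 12, J)
  for (dr in 0:1) {
    p <- graph_cut_params(delta_r = dr, nodes_per_ray = J, max_radius_mm = J,
                          template_level = 0)
    net <- build_flow_network(cost_grid(cost, tpl), tpl, p)
    n_nodes <- 12L * J
    inter <- net$from <= n_nodes & net$to <= n_nodes &
      net$capacity == net$infinity &
      ((net$from - 1L) %/% J) != ((net$to - 1L) %/% J)
    lev_from <- (net$from[inter] - 1L) %% J + 1L
    lev_to <- (net$to[inter] - 1L) %% J + 1L
    # inter-edges go from level j to max(1, j - delta_r)
    expect_true(all(lev_to == pmax(1L, lev_from - dr)))
  }
  p <- graph_cut_params(delta_r = 1, nodes_per_ray = J, max_radius_mm = J,
                        template_level = 0)
  net <- build_flow_network(cost_grid(cost, tpl), tpl, p)
  # innermost s-links exceed each ray's other terminal capacities, so the
  # seed node is always foreground
  s_caps <- net$capacity[net$from == net$s & (net$to - 1L) %% J == 0L]
  expect_identical(length(s_caps), 12L)
  W <- cost[, -1] - cost[, -J]
  expect_true(all(s_caps > rowSums(abs(W))))
  # infinity stand-in exceeds the sum of all finite terminal capacities
  finite_caps <- net$capacity[net$capacity < net$infinity]
  expect_gt(net$infinity, sum(finite_caps))
  expect_error(build_flow_network(cost_grid(cost[1:6, ], tpl), tpl, p),
               "rays")
})

test_that("single-ray cut lands on the cost minimum", {
  tpl1 <- structure(list(level = 0L,
                         directions = matrix(c(1, 0, 0), 1),
                         faces = matrix(integer(0), 0, 3),
                         adjacency = matrix(integer(0), 0, 2)),
                    class = "ray_template")
  cut <- solve_cost_grid(matrix(c(5, 1, 7, 9), 1), tpl1, delta_r = 0)
  expect_identical(cut$cut_index, 2L)
  expect_equal(cut$boundary_cost, 1)
})

test_that("delta_r = 0 forces a sphere; flow equals boundary cost plus offset", {
  tpl <- ray_template(0)
  set.seed(5)
  cost <- matrix(runif(12 * 6, 0, 10), 12, 6)
  cut <- solve_cost_grid(cost, tpl, delta_r = 0)
  expect_identical(length(unique(cut$cut_index)), 1L)
  expect_equal(cut$flow_value, cut$boundary_cost + cut$offset)
  expect_true(cut$feasible)
  # the common level is the one minimizing the column sums
  expect_identical(unique(cut$cut_index), which.min(colSums(cost)))
})

test_that("min-cut equals the brute-force optimum on random instances", {
  tpl <- ray_template(0)
  set.seed(99)
  for (i in 1:40) {
    J <- sample(4:7, 1)
    dr <- sample(0:2, 1)
    cost <- matrix(sample.int(50, 12 * J, replace = TRUE), 12, J)
    mc <- solve_cost_grid(cost, tpl, dr)
    bf <- brute_force_cut(cost, tpl, dr)
    expect_identical(mc$boundary_cost, bf$boundary_cost)
    expect_true(cut_feasible(mc, tpl, dr))
  }
})

test_that("optimal cost is non-increasing in delta_r and no infinite edge is cut", {
  tpl <- ray_template(0)
  set.seed(7)
  for (i in 1:10) {
    cost <- matrix(runif(12 * 6, 0, 10), 12, 6)
    prev <- Inf
    for (dr in 0:3) {
      g <- cost_grid(cost, tpl)
      p <- graph_cut_params(delta_r = dr, nodes_per_ray = 6,
                            max_radius_mm = 6, template_level = 0)
      net <- build_flow_network(g, tpl, p)
      cut <- solve_min_cut(net)
      expect_lte(cut$boundary_cost, prev + 1e-9)
      expect_lt(cut$flow_value, net$infinity)
      prev <- cut$boundary_cost
    }
  }
})

test_that("brute force: tie-break, unconstrained minima, size guard", {
  tpl <- ray_template(0)
  # all costs equal: lexicographically smallest vector = all ones
  bf <- brute_force_cut(matrix(1, 12, 5), tpl, 1)
  expect_identical(bf$cut_index, rep(1L, 12))
  # delta_r >= nodes - 1: per-ray independent minima
  set.seed(3)
  cost <- matrix(runif(12 * 5), 12, 5)
  bf2 <- brute_force_cut(cost, tpl, 4)
  expect_identical(bf2$cut_index, unname(apply(cost, 1, which.min)))
  expect_error(brute_force_cut(matrix(1, 13, 4), tpl, 1), "12")
})

test_that("boundary constraints pin the cut and conflicts are detected", {
  tpl <- ray_template(0)
  v <- uniform_volume(100, dim = c(41, 41, 41))
  ctr <- c(20, 20, 20)
  p <- graph_cut_params(delta_r = 0, nodes_per_ray = 10, max_radius_mm = 10,
                        template_level = 0)
  g <- sample_node_grid(v, ctr, tpl, p, reference_value = 100)
  # uniform volume: without constraints every cut is equally cheap
  net <- build_flow_network(g, tpl, p)
  cst <- boundary_constraint(ctr + 3 * tpl$directions[1, ])
  net_c <- apply_boundary_constraints(net, g, list(cst), volume = v)
  cut <- solve_min_cut(net_c)
  expect_identical(cut$cut_index[1], 3L)
  # delta_r = 0 propagates the constrained level to every ray
  expect_true(all(cut$cut_index == 3L))

  # conflicting constraints on adjacent rays with delta_r = 0
  pair <- tpl$adjacency[1, ]
  c1 <- boundary_constraint(ctr + 2 * tpl$directions[pair[1], ])
  c2 <- boundary_constraint(ctr + 8 * tpl$directions[pair[2], ])
  net2 <- apply_boundary_constraints(net, g, list(c1, c2), volume = v)
  expect_error(solve_min_cut(net2), "infeasible|conflict")

  # unreachable constraint
  far <- boundary_constraint(ctr + c(15, 0, 0))
  expect_error(apply_boundary_constraints(net, g, list(far), volume = v),
               "unreachable")
})

test_that("region cost profile matches its definition and estimates the background", {
  tpl <- ray_template(0)
  # dark 4 mm ball around the center, bright surround
  d <- c(31, 31, 31)
  idx <- expand.grid(x = 0:30, y = 0:30, z = 0:30)
  r2 <- (idx$x - 15)^2 + (idx$y - 15)^2 + (idx$z - 15)^2
  v <- image_volume(array(ifelse(r2 <= 16, 40, 110), dim = d))
  p <- graph_cut_params(delta_r = 1, nodes_per_ray = 8, max_radius_mm = 8,
                        template_level = 0)
  g <- sample_node_grid(v, c(15, 15, 15), tpl, p, reference_value = 40)
  prof <- region_cost_profile(g)
  expect_equal(prof$bg_reference, 110)
  # direct evaluation of the cumulative definition on one ray
  r <- 1L
  fg <- abs(g$gray[r, ] - 40)
  bg <- abs(g$gray[r, ] - 110)
  direct <- vapply(1:8, function(k)
    sum(fg[1:k]) + if (k < 8) sum(bg[(k + 1):8]) else 0, numeric(1))
  expect_equal(prof$cost[r, ], direct)
  expect_true(all(prof$cost >= 0))
  # the minimum of every ray's profile sits at the 4 mm boundary
  opt <- apply(prof$cost, 1, which.min)
  expect_true(all(abs(g$radii[opt] - 4) <= 1))
})
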