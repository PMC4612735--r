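# shared fixtures, all generated in code

# uniform-intensity volume
uniform_volume <- function(value = 100, dim = c(20, 20, 20),
                           spacing = c(1, 1, 1)) {
  image_volume(array(value, dim = dim), spacing = spacing)
}

# wrap a bare cost matrix (rays x nodes) as a node grid so it can be fed to
# build_flow_network / solve_min_cut directly
cost_grid <- function(cost, template, step = 1) {
  cost <- as.matrix(cost)
  structure(list(
    cost = cost, gray = cost, n_rays = nrow(cost), n_nodes = ncol(cost),
    radii = step * seq_len(ncol(cost)),
    in_bounds = matrix(TRUE, nrow(cost), ncol(cost)),
    directions = template$directions, seed_world = c(0, 0, 0),
    step = step, reference_value = 0),
    class = "node_grid")
}

solve_cost_grid <- function(cost, template, delta_r) {
  g <- cost_grid(cost, template)
  p <- graph_cut_params(delta_r = delta_r, nodes_per_ray = ncol(as.matrix(cost)),
                        max_radius_mm = ncol(as.matrix(cost)),
                        template_level = template$level)
  solve_min_cut(build_flow_network(g, template, p))
}
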