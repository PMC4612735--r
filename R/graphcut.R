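#' Parameters of the ray-graph construction
#'
#' @param delta_r Non-negative integer smoothness constraint: the cut level of
#'   two adjacent rays may differ by at most `delta_r` nodes. `0` forces the
#'   segmentation to be a sphere; larger values admit more irregular surfaces.
#' @param nodes_per_ray Number of nodes sampled along every ray (>= 2,
#'   default 40).
#' @param max_radius_mm Radius of the outermost node in mm (default 40); the
#'   radial sampling step is `max_radius_mm / nodes_per_ray`.
#' @param template_level Subdivision level of the spherical ray template
#'   (0 to 5, i.e. 12 to 2432 rays; default 4 = 812 rays).
#' @return An object of class `graph_cut_params`.
#' @export
graph_cut_params <- function(delta_r = 2L, nodes_per_ray = 40L,
                             max_radius_mm = 40, template_level = 4L) {
  delta_r <- as.integer(delta_r)
  nodes_per_ray <- as.integer(nodes_per_ray)
  template_level <- as.integer(template_level)
  if (is.na(delta_r) || delta_r < 0L) {
    stop("'delta_r' must be a non-negative integer", call. = FALSE)
  }
  if (is.na(nodes_per_ray) || nodes_per_ray < 2L) {
    stop("'nodes_per_ray' must be an integer >= 2", call. = FALSE)
  }
  if (delta_r >= nodes_per_ray) {
    stop("'delta_r' must be smaller than 'nodes_per_ray'", call. = FALSE)
  }
  if (!is.numeric(max_radius_mm) || length(max_radius_mm) != 1L ||
      !is.finite(max_radius_mm) || max_radius_mm <= 0) {
    stop("'max_radius_mm' must be a single positive number", call. = FALSE)
  }
  if (is.na(template_level) || template_level < 0L || template_level > 5L) {
    stop("'template_level' must be between 0 and 5", call. = FALSE)
  }
  structure(list(delta_r = delta_r, nodes_per_ray = nodes_per_ray,
                 max_radius_mm = as.numeric(max_radius_mm),
                 template_level = template_level),
            class = "graph_cut_params")
}

#' @export
print.graph_cut_params <- function(x, ...) {
  cat(sprintf(
    "Graph-cut parameters: delta_r = %d, %d nodes/ray, max radius %.4g mm, template level %d\n",
    x$delta_r, x$nodes_per_ray, x$max_radius_mm, x$template_level))
  invisible(x)
}

#' Sample graph nodes along the template rays
#'
#' Node `j` of every ray lies at radius `j * max_radius_mm / nodes_per_ray`
#' from the seed (1-based; the seed voxel itself is represented by the forced
#' innermost node). Gray values are obtained by trilinear interpolation; the
#' node cost is `|reference_value - gray|`. Nodes falling outside the volume
#' are flagged and given a large background penalty (one plus the total
#' in-bounds cost) so that an avoidable cut never crosses the volume border.
#'
#' @param volume An [image_volume()].
#' @param seed A [seed_point()] or world-mm coordinate strictly inside the
#'   volume.
#' @param template A [ray_template()]; defaults to the level requested in
#'   `params`.
#' @param params A [graph_cut_params()].
#' @param reference_value Average ablation-zone intensity, typically from
#'   [estimate_reference_value()].
#' @return An object of class `node_grid` with matrices `gray`, `cost`,
#'   `in_bounds` (rays x nodes), the per-node `radii`, the world `positions`
#'   (rays*nodes x 3), the seed and sampling geometry.
#' @export
sample_node_grid <- function(volume, seed, template = NULL,
                             params = graph_cut_params(), reference_value) {
  stopifnot(inherits(params, "graph_cut_params"))
  if (is.null(template)) template <- ray_template(params$template_level)
  stopifnot(inherits(template, "ray_template"))
  seed_world <- seed_to_world(seed, volume, require_inside = TRUE)

  dirs <- template$directions
  n_rays <- nrow(dirs)
  J <- params$nodes_per_ray
  step <- params$max_radius_mm / J
  radii <- step * seq_len(J)

  # positions ordered ray-fastest: row index = (j-1)*n_rays + r
  pos <- kronecker(radii, dirs)
  pos <- sweep(pos, 2L, seed_world, "+")
  smp <- sample_trilinear(volume, pos)

  gray <- matrix(smp$values, nrow = n_rays, ncol = J)
  in_bounds <- matrix(smp$in_bounds, nrow = n_rays, ncol = J)
  cost <- abs(reference_value - gray)
  penalty <- 1 + sum(cost[in_bounds])
  cost[!in_bounds] <- penalty

  structure(list(
    positions = pos, radii = radii, gray = gray, cost = cost,
    in_bounds = in_bounds, seed_world = seed_world, step = step,
    reference_value = reference_value, n_rays = n_rays, n_nodes = J,
    oob_penalty = penalty, directions = dirs),
    class = "node_grid")
}

#' @export
print.node_grid <- function(x, ...) {
  cat(sprintf("Node grid: %d rays x %d nodes (step %.4g mm)\n",
              x$n_rays, x$n_nodes, x$step))
  cat(sprintf("  reference value: %.4g; out-of-bounds nodes: %d\n",
              x$reference_value, sum(!x$in_bounds)))
  invisible(x)
}

# flat node id of ray r, level j (1-based both); s and t follow after.
node_id <- function(r, j, n_nodes) (r - 1L) * n_nodes + j

#' Build the s-t flow network from a node grid
#'
#' Three edge families are created:
#' \describe{
#'   \item{intra-edges}{directed infinite-capacity edges from node `j` to node
#'     `j - 1` along every ray, so that the source-bound set along a ray is
#'     always a contiguous prefix (the interior of the lesion forms a closed
#'     set);}
#'   \item{inter-edges}{for every pair of adjacent rays `(r, r')` (edges of the
#'     template triangulation) and every level `j`, infinite-capacity edges
#'     from `(r, j)` to `(r', max(1, j - delta_r))` and symmetrically,
#'     enforcing the smoothness constraint `|cut level difference| <= delta_r`;}
#'   \item{terminal edges}{per ray, from the cost differences
#'     `w(j) = c(j) - c(j-1)`: negative differences become source edges with
#'     capacity `|w|`, positive ones sink edges with capacity `w`. The
#'     innermost node is tied to the source with a capacity exceeding the sum
#'     of the ray's other terminal capacities, so the seed is always
#'     foreground.}
#' }
#' The finite stand-in for infinity is one plus the sum of all finite terminal
#' capacities, so an infinite edge is never part of a minimum cut in an
#' unconstrained problem. With this construction, the minimum s-t cut selects
#' exactly the smoothness-feasible cut-level vector minimizing the total
#' boundary cost `sum_r c(r, cut_index[r])` (up to a constant offset stored in
#' the network).
#'
#' @param grid A [sample_node_grid()] result.
#' @param template The [ray_template()] the grid was sampled with.
#' @param params The [graph_cut_params()] (provides `delta_r`).
#' @return An object of class `flow_network`.
#' @export
build_flow_network <- function(grid, template, params) {
  stopifnot(inherits(grid, "node_grid"), inherits(template, "ray_template"),
            inherits(params, "graph_cut_params"))
  R <- grid$n_rays
  J <- grid$n_nodes
  if (nrow(template$directions) != R) {
    stop("template has ", nrow(template$directions),
         " rays but the node grid was sampled with ", R, call. = FALSE)
  }
  dr <- params$delta_r
  C <- grid$cost

  # intra-edges: (r, j) -> (r, j - 1)
  jj <- rep(2:J, times = R)
  rr <- rep(seq_len(R), each = J - 1L)
  intra_from <- node_id(rr, jj, J)
  intra_to <- intra_from - 1L

  # inter-edges, both directions for every adjacency pair
  A <- template$adjacency
  E <- nrow(A)
  lev <- rep(seq_len(J), each = E)
  a <- rep(A[, 1], times = J)
  b <- rep(A[, 2], times = J)
  tgt <- pmax(1L, lev - dr)
  inter_from <- c(node_id(a, lev, J), node_id(b, lev, J))
  inter_to <- c(node_id(b, tgt, J), node_id(a, tgt, J))

  # terminal edges from cost differences
  s <- R * J + 1L
  t <- R * J + 2L
  W <- C[, -1L, drop = FALSE] - C[, -J, drop = FALSE]  # rays x (J-1)
  wr <- rep(seq_len(R), times = J - 1L)
  wj <- rep(2:J, each = R)
  wv <- as.vector(W)
  neg <- wv < 0
  pos <- wv > 0
  # seed-forcing source links: one per ray, strictly exceeding the sum of
  # that ray's other terminal capacities, so the innermost node can never
  # profitably change sides (kept per-ray rather than global to keep the
  # capacity range narrow for the double-precision solver)
  w0 <- 1 + rowSums(abs(W))
  term_from <- c(rep(s, R), rep(s, sum(neg)), node_id(wr[pos], wj[pos], J))
  term_to <- c(node_id(seq_len(R), 1L, J), node_id(wr[neg], wj[neg], J),
               rep(t, sum(pos)))
  term_cap <- c(w0, -wv[neg], wv[pos])

  infinity <- 1 + sum(term_cap)
  n_infinite <- length(intra_from) + length(inter_from)
  from <- c(intra_from, inter_from, term_from)
  to <- c(intra_to, inter_to, term_to)
  capacity <- c(rep(infinity, n_infinite), term_cap)

  # flow value = boundary cost + offset (telescoped terminal capacities)
  offset <- sum(rowSums(pmax(-W, 0))) - sum(C[, 1L])

  structure(list(
    from = from, to = to, capacity = capacity,
    n_rays = R, n_nodes = J, s = s, t = t,
    infinity = infinity, offset = offset, n_infinite = n_infinite,
    delta_r = dr,
    cost = C, radii = grid$radii, directions = grid$directions,
    adjacency = template$adjacency,
    seed_world = grid$seed_world, constrained = FALSE),
    class = "flow_network")
}

#' @export
print.flow_network <- function(x, ...) {
  cat(sprintf("Flow network: %d rays x %d nodes (+ source, sink)\n",
              x$n_rays, x$n_nodes))
  cat(sprintf("  edges: %d, delta_r = %d, infinity stand-in = %.4g\n",
              length(x$from), x$delta_r, x$infinity))
  if (x$constrained) cat("  boundary constraints applied\n")
  invisible(x)
}

#' Boundary constraint point
#'
#' A point placed on the border of the ablation zone. The cut on the ray
#' nearest to the point is forced to the constraint's radius; the smoothness
#' constraint propagates the influence to neighbouring rays.
#'
#' @param position Numeric length-3 coordinate.
#' @param frame `"world"` (mm) or `"voxel"` (0-based indices).
#' @return An object of class `boundary_constraint`.
#' @export
boundary_constraint <- function(position, frame = c("world", "voxel")) {
  frame <- match.arg(frame)
  position <- as.numeric(position)
  if (length(position) != 3L || any(!is.finite(position))) {
    stop("'position' must be three finite coordinates", call. = FALSE)
  }
  structure(list(position = position, frame = frame),
            class = "boundary_constraint")
}

#' Pin the cut to user-placed border points
#'
#' For the ray nearest to each constraint point, every node at a radius up to
#' the constraint's radius receives an infinite-capacity source edge and the
#' next node an infinite-capacity sink edge, forcing the cut to the
#' constrained level on that ray. Two constraints whose forced levels on
#' adjacent rays differ by more than `delta_r` are mutually infeasible; the
#' solver detects this (an infinite edge would have to be cut) and raises an
#' error.
#'
#' @param network A [build_flow_network()] result.
#' @param grid The [sample_node_grid()] the network was built from.
#' @param constraints A list of [boundary_constraint()] points (bare numeric
#'   vectors are taken as world mm). Constraints in the voxel frame require
#'   `volume`.
#' @param volume The [image_volume()], only needed to convert voxel-frame
#'   constraints.
#' @return The network with the additional terminal edges.
#' @export
apply_boundary_constraints <- function(network, grid, constraints,
                                       volume = NULL) {
  stopifnot(inherits(network, "flow_network"), inherits(grid, "node_grid"))
  if (length(constraints) == 0L) return(network)
  if (inherits(constraints, "boundary_constraint")) {
    constraints <- list(constraints)
  }
  J <- grid$n_nodes
  for (cst in constraints) {
    if (!inherits(cst, "boundary_constraint")) {
      cst <- boundary_constraint(cst, frame = "world")
    }
    world <- if (cst$frame == "voxel") {
      if (is.null(volume)) {
        stop("voxel-frame constraints need the 'volume' argument",
             call. = FALSE)
      }
      volume$origin + cst$position * volume$spacing
    } else {
      cst$position
    }
    v <- world - grid$seed_world
    radius <- sqrt(sum(v^2))
    if (radius > max(grid$radii) + grid$step / 2) {
      stop(sprintf(
        "unreachable constraint: point at radius %.4g mm exceeds the maximum ray radius %.4g mm",
        radius, max(grid$radii)), call. = FALSE)
    }
    ray <- which.max(grid$directions %*% (v / max(radius, 1e-12)))
    k <- min(J, max(1L, as.integer(round(radius / grid$step))))

    network$from <- c(network$from, rep(network$s, k))
    network$to <- c(network$to, node_id(ray, seq_len(k), J))
    network$capacity <- c(network$capacity, rep(network$infinity, k))
    if (k < J) {
      network$from <- c(network$from, node_id(ray, k + 1L, J))
      network$to <- c(network$to, network$t)
      network$capacity <- c(network$capacity, network$infinity)
    }
  }
  network$constrained <- TRUE
  network
}

#' Solve the minimum s-t cut of the flow network
#'
#' Computes the maximum flow (Boykov-Kolmogorov style solver from
#' \pkg{igraph}) and derives the per-ray cut level. Following the convention
#' that the segmentation consists of the last nodes of every ray still bound
#' to the seed, the source-bound set is taken as the *maximal* minimum cut:
#' all nodes that can no longer reach the sink in the residual network. On
#' cost plateaus (for example a homogeneous lesion interior) this places the
#' boundary at the outermost of the equally cheap levels.
#'
#' @param network A [build_flow_network()] result, optionally with boundary
#'   constraints applied.
#' @return An object of class `cut_result` with `cut_index` (per-ray level of
#'   the last source-bound node, 1-based), `flow_value`, `boundary_cost`
#'   (`sum_r cost[r, cut_index[r]]`, equal to `flow_value - offset`),
#'   `boundary_points` (rays x 3 world mm), `radii_at_cut` and `feasible`.
#' @export
solve_min_cut <- function(network) {
  stopifnot(inherits(network, "flow_network"))
  R <- network$n_rays
  J <- network$n_nodes
  n_total <- R * J + 2L
  g <- igraph::make_empty_graph(n = n_total, directed = TRUE)
  g <- igraph::add_edges(g, rbind(network$from, network$to))
  mf <- igraph::max_flow(g, source = network$s, target = network$t,
                         capacity = network$capacity)

  if (mf$value > network$infinity - 0.5) {
    stop("infeasible cut: an infinite-capacity edge had to be cut ",
         "(conflicting boundary constraints within delta_r reach)",
         call. = FALSE)
  }

  # residual reachability towards t; maximal minimum cut
  flow <- mf$flow
  # Residual edges. Infinite-capacity edges are never saturated in a feasible
  # solution (total flow < infinity stand-in by construction), so their
  # forward residual always exists regardless of floating-point noise in the
  # reported flow. Finite (terminal) edges use a per-edge relative
  # saturation tolerance because capacities span many orders of magnitude.
  # Backward residuals exist wherever an edge carries flow; flows are
  # compositions of finite terminal capacities, so an absolute tolerance at
  # the resolution of meaningful costs is used.
  fwd <- network$capacity - flow > 1e-9 * pmax(1, network$capacity)
  fwd[seq_len(network$n_infinite)] <- TRUE
  bwd <- flow > 1e-7
  res_from <- c(network$from[fwd], network$to[bwd])
  res_to <- c(network$to[fwd], network$from[bwd])
  gres <- igraph::make_empty_graph(n = n_total, directed = TRUE)
  gres <- igraph::add_edges(gres, rbind(res_from, res_to))
  reaches_t <- as.integer(
    igraph::subcomponent(gres, v = network$t, mode = "in"))
  on_sink_side <- rep(FALSE, n_total)
  on_sink_side[reaches_t] <- TRUE

  src <- matrix(!on_sink_side[seq_len(R * J)], nrow = J, ncol = R)
  cut_index <- as.integer(colSums(src))
  if (any(cut_index < 1L)) {
    stop("solver error: a ray lost its forced innermost node", call. = FALSE)
  }

  radii_at_cut <- network$radii[cut_index]
  boundary_points <- network$directions * radii_at_cut
  boundary_points <- sweep(boundary_points, 2L, network$seed_world, "+")
  boundary_cost <- as.numeric(sum(network$cost[cbind(seq_len(R), cut_index)]))

  A <- network$adjacency
  feasible <- nrow(A) == 0L ||
    all(abs(cut_index[A[, 1]] - cut_index[A[, 2]]) <= network$delta_r)

  structure(list(
    cut_index = cut_index, flow_value = mf$value,
    boundary_cost = boundary_cost, boundary_points = boundary_points,
    radii_at_cut = radii_at_cut, delta_r = network$delta_r,
    offset = network$offset, feasible = feasible),
    class = "cut_result")
}

#' @export
print.cut_result <- function(x, ...) {
  cat(sprintf("Min-cut result over %d rays\n", length(x$cut_index)))
  cat(sprintf("  cut levels: %d .. %d (median %.4g)\n",
              min(x$cut_index), max(x$cut_index), median(x$cut_index)))
  cat(sprintf("  cut radii:  %.4g .. %.4g mm\n",
              min(x$radii_at_cut), max(x$radii_at_cut)))
  cat(sprintf("  flow value: %.6g (boundary cost %.6g)\n",
              x$flow_value, x$boundary_cost))
  invisible(x)
}

#' Check a cut against the smoothness constraint
#'
#' @param cut A [solve_min_cut()] or [brute_force_cut()] result.
#' @param template The [ray_template()] providing ray adjacency.
#' @param delta_r The smoothness parameter to check against (defaults to the
#'   cut's own).
#' @return `TRUE` when every pair of adjacent rays differs by at most
#'   `delta_r` cut levels.
#' @export
cut_feasible <- function(cut, template, delta_r = cut$delta_r) {
  stopifnot(inherits(template, "ray_template"))
  A <- template$adjacency
  all(abs(cut$cut_index[A[, 1]] - cut$cut_index[A[, 2]]) <= delta_r)
}
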