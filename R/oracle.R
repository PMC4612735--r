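#' Brute-force optimal cut (test oracle)
#'
#' Enumerates, by depth-first search with branch-and-bound pruning, the
#' smoothness-feasible cut-level vector minimizing the total boundary cost
#' `sum_r cost[r, cut_index[r]]`, independent of the flow-network machinery.
#' Ties are broken towards the lexicographically smallest index vector. Only
#' intended for small instances (at most 12 rays); it exists to verify
#' [solve_min_cut()].
#'
#' @param grid A [sample_node_grid()] result, or a plain numeric cost matrix
#'   (rays x nodes).
#' @param template A [ray_template()], or a plain 2-column integer matrix of
#'   adjacent ray index pairs.
#' @param delta_r Non-negative integer smoothness constraint.
#' @return An object of class `cut_result` with `cut_index` (1-based) and
#'   `boundary_cost`.
#' @export
brute_force_cut <- function(grid, template, delta_r) {
  cost <- if (inherits(grid, "node_grid")) grid$cost else as.matrix(grid)
  adjacency <- if (inherits(template, "ray_template")) {
    template$adjacency
  } else {
    template <- as.matrix(template)
    storage.mode(template) <- "integer"
    template
  }
  delta_r <- as.integer(delta_r)
  stopifnot(length(delta_r) == 1L, delta_r >= 0L)
  R <- nrow(cost)
  if (R > 12L) {
    stop("instance too large for the brute-force oracle (", R,
         " rays; at most 12 are enumerable)", call. = FALSE)
  }
  if (nrow(adjacency) > 0L &&
      (max(adjacency) > R || min(adjacency) < 1L)) {
    stop("adjacency refers to rays outside the cost matrix", call. = FALSE)
  }
  res <- bf_cut_cpp(cost, adjacency, delta_r)
  structure(list(
    cut_index = res$cut_index, boundary_cost = res$total_cost,
    flow_value = NA_real_, delta_r = delta_r, feasible = TRUE),
    class = "cut_result")
}
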