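#' Per-ray region-misfit cost profile
#'
#' Converts the sampled gray values of a [sample_node_grid()] into the
#' cumulative two-region cost profile that the flow network minimizes. For a
#' cut at level `k` on ray `r` (nodes `1..k` labelled ablation zone, the rest
#' background) the profile value is
#' \deqn{C(r, k) = \sum_{j \le k} |g(r,j) - m| + \sum_{j > k} |g(r,j) - M|,}
#' where `m` is the average ablation-zone intensity around the seed and `M` a
#' background reference intensity. Minimizing `sum_r C(r, cut_r)` under the
#' smoothness constraint therefore labels every node by the region average it
#' resembles more, which places the cut at the lesion border and is robust to
#' noise: a node's misfit enters the total wherever the cut lies, so
#' individual noisy nodes cannot attract the whole surface. In the flow
#' network the profile turns, via the cost-difference terminal scheme, into
#' exactly one source or sink edge per node with capacity
#' `||g - m| - |g - M||`, bound to the terminal whose region average the node
#' resembles more.
#'
#' Out-of-bounds nodes are definite background: their foreground misfit is a
#' penalty exceeding the total in-bounds misfit and their background misfit
#' is zero, so an avoidable cut never crosses the volume border.
#'
#' When `bg_reference` is `NULL` it is estimated as the median, over rays, of
#' the gray value at each ray's outermost in-bounds node — the far end of the
#' rays, which lies in the surrounding tissue whenever `max_radius_mm`
#' exceeds the lesion radius (a prerequisite of the ray construction anyway).
#'
#' @param grid A [sample_node_grid()] result.
#' @param bg_reference Background reference intensity, or `NULL` to estimate
#'   it from the outer ends of the rays.
#' @return A `node_grid` whose `cost` matrix holds the cumulative region
#'   profile (fields `fg_misfit`, `bg_misfit` and `bg_reference` are added);
#'   feed it to [build_flow_network()] or [brute_force_cut()].
#' @export
region_cost_profile <- function(grid, bg_reference = NULL) {
  stopifnot(inherits(grid, "node_grid"))
  G <- grid$gray
  R <- grid$n_rays
  J <- grid$n_nodes
  m <- grid$reference_value

  if (is.null(bg_reference)) {
    outer_gray <- vapply(seq_len(R), function(r) {
      inb <- which(grid$in_bounds[r, ])
      G[r, if (length(inb)) max(inb) else 1L]
    }, numeric(1))
    bg_reference <- median(outer_gray)
  }
  if (abs(bg_reference - m) < 1e-6) {
    warning("background reference equals the ablation-zone reference; ",
            "the region profile is uninformative (is max_radius_mm larger ",
            "than the lesion?)")
  }

  b <- abs(G - m)            # misfit when labelled ablation zone
  a <- abs(G - bg_reference) # misfit when labelled background
  # one out-of-bounds node labelled foreground outweighs a whole ray of
  # in-bounds misfit; kept at that scale (not the global cost sum) so the
  # flow capacities stay well-conditioned for the double-precision solver
  penalty <- 1 + J * (1 + max(b[grid$in_bounds], 0))
  b[!grid$in_bounds] <- penalty
  a[!grid$in_bounds] <- 0

  Bc <- t(apply(b, 1L, cumsum))
  Ac <- t(apply(a, 1L, cumsum))
  if (J == 1L) { Bc <- matrix(Bc, ncol = 1L); Ac <- matrix(Ac, ncol = 1L) }
  profile <- Bc + (rowSums(a) - Ac)

  out <- grid
  out$cost <- profile
  out$fg_misfit <- abs(G - m)
  out$bg_misfit <- a
  out$bg_reference <- bg_reference
  out$oob_penalty <- penalty
  out
}
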