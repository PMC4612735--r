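#' Segment an ablation zone from a seed point
#'
#' Runs the full semi-automatic pipeline: (1) estimate the average
#' ablation-zone intensity in a ~1 cm^3 region around the seed, (2) sample
#' graph nodes along the spherical ray template, (3) form the per-ray region
#' cost profile ([region_cost_profile()]), (4) build the s-t flow network
#' with the smoothness constraint and optional boundary-constraint points,
#' (5) solve the minimum cut, (6) reconstruct the closed surface and (7)
#' voxelize it into a solid binary mask on the input grid. The pipeline
#' contains no randomness: identical inputs give identical outputs.
#'
#' @param volume An [image_volume()].
#' @param seed A [seed_point()] (or world-mm numeric vector) inside the
#'   lesion.
#' @param params A [graph_cut_params()].
#' @param constraints Optional list of [boundary_constraint()] points on the
#'   lesion border.
#' @param reference_value Optional fixed average ablation-zone intensity;
#'   when `NULL` (default) it is estimated with [estimate_reference_value()].
#' @param reference_mode `"median"` (default) or `"mean"` for the reference
#'   estimate. The pipeline defaults to the median: the point of integrating
#'   over ~1 cm^3 is robustness against the bright RFA needle, and when the
#'   seed lands on or near the needle hub the needle can fill a substantial
#'   fraction of the averaging cube, which a mean cannot reject.
#' @param reference_volume_mm3 Region volume for the reference estimate.
#' @param bg_reference Optional fixed background reference intensity; when
#'   `NULL` it is estimated from the outer ends of the rays (see
#'   [region_cost_profile()]).
#' @param template Optional pre-built [ray_template()] (otherwise built from
#'   `params$template_level`).
#' @param keep_grid Keep the sampled node grid in the result (default FALSE).
#' @return An object of class `rfa_segmentation` with components `mask`
#'   ([segmentation_mask()]), `mesh` (`triangle_mesh`), `cut`
#'   (`cut_result`), `reference_value`, `seed_world`, `params` and `timings`
#'   (seconds per stage).
#' @examples
#' ph <- generate_phantom(phantom_spec(lesion_radii = c(12, 12, 12)))
#' seg <- segment_ablation_zone(
#'   ph$volume, seed_point(ph$spec$lesion_center),
#'   params = graph_cut_params(template_level = 2, nodes_per_ray = 20,
#'                             max_radius_mm = 25))
#' summary(seg)
#' @export
segment_ablation_zone <- function(volume, seed,
                                  params = graph_cut_params(),
                                  constraints = NULL,
                                  reference_value = NULL,
                                  reference_mode = c("median", "mean"),
                                  reference_volume_mm3 = 1000,
                                  bg_reference = NULL,
                                  template = NULL,
                                  keep_grid = FALSE) {
  stopifnot(inherits(volume, "image_volume"),
            inherits(params, "graph_cut_params"))
  reference_mode <- match.arg(reference_mode)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  if (is.null(template)) template <- ray_template(params$template_level)
  timings["template"] <- tic() - t0

  t0 <- tic()
  if (is.null(reference_value)) {
    reference_value <- estimate_reference_value(
      volume, seed, region_volume_mm3 = reference_volume_mm3,
      mode = reference_mode)
  }
  timings["reference"] <- tic() - t0

  t0 <- tic()
  grid <- sample_node_grid(volume, seed, template, params, reference_value)
  profile <- region_cost_profile(grid, bg_reference = bg_reference)
  timings["sampling"] <- tic() - t0

  t0 <- tic()
  network <- build_flow_network(profile, template, params)
  if (!is.null(constraints) && length(constraints) > 0L) {
    network <- apply_boundary_constraints(network, grid, constraints,
                                          volume = volume)
  }
  timings["graph"] <- tic() - t0

  t0 <- tic()
  cut <- solve_min_cut(network)
  timings["mincut"] <- tic() - t0

  t0 <- tic()
  mesh <- cut_to_surface(cut, template)
  mask <- voxelize_surface(mesh, volume)
  timings["surface"] <- tic() - t0

  structure(list(
    mask = mask, mesh = mesh, cut = cut,
    reference_value = reference_value,
    bg_reference = profile$bg_reference,
    seed_world = grid$seed_world,
    params = params, timings = timings,
    grid = if (keep_grid) profile else NULL),
    class = "rfa_segmentation")
}

#' @export
print.rfa_segmentation <- function(x, ...) {
  cat("Ablation-zone segmentation\n")
  cat(sprintf("  seed (world): (%.4g, %.4g, %.4g) mm\n",
              x$seed_world[1], x$seed_world[2], x$seed_world[3]))
  cat(sprintf("  reference value: %.4g\n", x$reference_value))
  cat(sprintf("  volume: %.1f mm^3 (%.2f cm^3) in %d voxels\n",
              x$mask$volume_mm3, x$mask$volume_mm3 / 1000,
              x$mask$voxel_count))
  cat(sprintf("  cut radii: %.4g .. %.4g mm (delta_r = %d)\n",
              min(x$cut$radii_at_cut), max(x$cut$radii_at_cut),
              x$params$delta_r))
  invisible(x)
}

#' @export
summary.rfa_segmentation <- function(object, ...) {
  print(object)
  cat(sprintf("  rays: %d, nodes/ray: %d, max radius: %.4g mm\n",
              length(object$cut$cut_index), object$params$nodes_per_ray,
              object$params$max_radius_mm))
  cat(sprintf("  flow value: %.6g, boundary cost: %.6g\n",
              object$cut$flow_value, object$cut$boundary_cost))
  cat(sprintf("  total time: %.2f s (%s)\n", sum(object$timings),
              paste(sprintf("%s %.2fs", names(object$timings),
                            object$timings), collapse = ", ")))
  invisible(object)
}

#' Plot a segmentation overlay on an axial slice
#'
#' Shows the gray-value slice through (by default) the seed with the mask
#' boundary contour and the seed position.
#'
#' @param x An `rfa_segmentation`.
#' @param volume The segmented [image_volume()].
#' @param slice 1-based z index; defaults to the seed's slice.
#' @param ... Passed to [graphics::image()].
#' @export
plot.rfa_segmentation <- function(x, volume, slice = NULL, ...) {
  stopifnot(inherits(volume, "image_volume"))
  d <- dim(volume$values)
  if (is.null(slice)) {
    slice <- 1L + round((x$seed_world[3] - volume$origin[3]) /
                          volume$spacing[3])
  }
  slice <- max(1L, min(d[3], as.integer(slice)))
  xs <- volume$origin[1] + (seq_len(d[1]) - 1L) * volume$spacing[1]
  ys <- volume$origin[2] + (seq_len(d[2]) - 1L) * volume$spacing[2]
  graphics::image(xs, ys, volume$values[, , slice],
                  col = grDevices::gray.colors(128), asp = 1,
                  xlab = "x (mm)", ylab = "y (mm)",
                  main = sprintf("slice %d", slice), ...)
  graphics::contour(xs, ys, x$mask$grid[, , slice] + 0, levels = 0.5,
                    add = TRUE, drawlabels = FALSE, col = "red", lwd = 2)
  graphics::points(x$seed_world[1], x$seed_world[2], col = "blue", pch = 3,
                   lwd = 2)
  invisible(x)
}

#' JSON run summary of a segmentation
#'
#' @param seg An `rfa_segmentation`.
#' @param path Output JSON file.
#' @return The path, invisibly.
#' @export
write_run_summary <- function(seg, path) {
  stopifnot(inherits(seg, "rfa_segmentation"))
  jsonlite::write_json(list(
    reference_value = seg$reference_value,
    bg_reference = seg$bg_reference,
    seed_world_mm = seg$seed_world,
    flow_value = seg$cut$flow_value,
    boundary_cost = seg$cut$boundary_cost,
    cut_radii_mm = list(min = min(seg$cut$radii_at_cut),
                        median = median(seg$cut$radii_at_cut),
                        max = max(seg$cut$radii_at_cut)),
    volume_mm3 = seg$mask$volume_mm3,
    voxel_count = seg$mask$voxel_count,
    delta_r = seg$params$delta_r,
    rays = length(seg$cut$cut_index),
    nodes_per_ray = seg$params$nodes_per_ray,
    max_radius_mm = seg$params$max_radius_mm,
    timings_s = as.list(seg$timings)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
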