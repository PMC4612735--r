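#' 3D scalar image volume
#'
#' Container for a 3D scalar grid with anisotropic voxel spacing. Voxel
#' `(i, j, k)` (1-based R indices) has its center at world position
#' `origin + (c(i, j, k) - 1) * spacing` (mm). Volumes are assumed axis
#' aligned; direction cosines are not modelled.
#'
#' @param values Numeric 3D array of intensities (HU-like units).
#' @param spacing Numeric length-3 vector, per-axis voxel size in mm
#'   (strictly positive).
#' @param origin Numeric length-3 vector, world position (mm) of the center of
#'   voxel `(1, 1, 1)`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) {
    stop("'values' must be a 3D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("'spacing' must be three strictly positive values (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("'origin' must be three finite values (mm)", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("all voxel values must be finite", call. = FALSE)
  }
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Image volume %d x %d x %d\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing: %.4g x %.4g x %.4g mm\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin:  (%.4g, %.4g, %.4g) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  range:   [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Seed point inside a volume
#'
#' A user-supplied point, either in world coordinates (mm) or as 0-based voxel
#' indices (the convention of slice-pixel clicks).
#'
#' @param position Numeric length-3 coordinate.
#' @param frame Either `"world"` (mm, default) or `"voxel"` (0-based indices).
#' @return An object of class `seed_point`.
#' @export
seed_point <- function(position, frame = c("world", "voxel")) {
  frame <- match.arg(frame)
  position <- as.numeric(position)
  if (length(position) != 3L || any(!is.finite(position))) {
    stop("'position' must be three finite coordinates", call. = FALSE)
  }
  structure(list(position = position, frame = frame), class = "seed_point")
}

#' @export
print.seed_point <- function(x, ...) {
  cat(sprintf("Seed point (%s frame): (%.4g, %.4g, %.4g)\n",
              x$frame, x$position[1], x$position[2], x$position[3]))
  invisible(x)
}

#' Convert a seed point to world coordinates
#'
#' @param seed A [seed_point()] (or bare numeric length-3 vector, taken as
#'   world mm).
#' @param volume The [image_volume()] the seed refers to.
#' @param require_inside Error when the seed lies outside the voxel-center
#'   hull of the volume.
#' @return Numeric length-3 world coordinate in mm.
#' @export
seed_to_world <- function(seed, volume, require_inside = TRUE) {
  if (!inherits(seed, "seed_point")) {
    seed <- seed_point(seed, frame = "world")
  }
  world <- if (seed$frame == "voxel") {
    volume$origin + seed$position * volume$spacing
  } else {
    seed$position
  }
  if (require_inside && !point_in_volume(world, volume)) {
    stop("seed point is out-of-bounds: (",
         paste(signif(world, 6), collapse = ", "),
         ") mm lies outside the volume", call. = FALSE)
  }
  world
}

# TRUE when a world point lies inside the voxel-center hull of the grid.
point_in_volume <- function(world, volume) {
  u <- (world - volume$origin) / volume$spacing
  all(u >= 0 & u <= dim(volume$values) - 1L)
}

#' Trilinear interpolation of a volume at world points
#'
#' Samples the volume at arbitrary world positions by trilinear interpolation
#' between the eight surrounding voxel centers. Query positions outside the
#' voxel-center hull are clamped to it for the interpolation and flagged.
#'
#' @param volume An [image_volume()].
#' @param points Numeric matrix (n x 3) of world coordinates in mm.
#' @return A list with `values` (numeric n) and `in_bounds` (logical n).
#' @export
sample_trilinear <- function(volume, points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  d <- dim(volume$values)
  # continuous 0-based voxel index
  u <- sweep(sweep(points, 2L, volume$origin, "-"), 2L, volume$spacing, "/")
  in_bounds <- u[, 1] >= 0 & u[, 1] <= d[1] - 1L &
               u[, 2] >= 0 & u[, 2] <= d[2] - 1L &
               u[, 3] >= 0 & u[, 3] <= d[3] - 1L
  u[, 1] <- pmin(pmax(u[, 1], 0), d[1] - 1L)
  u[, 2] <- pmin(pmax(u[, 2], 0), d[2] - 1L)
  u[, 3] <- pmin(pmax(u[, 3], 0), d[3] - 1L)

  i0 <- pmin(floor(u[, 1]), d[1] - 2L); i0[d[1] == 1L] <- 0
  j0 <- pmin(floor(u[, 2]), d[2] - 2L); j0[d[2] == 1L] <- 0
  k0 <- pmin(floor(u[, 3]), d[3] - 2L); k0[d[3] == 1L] <- 0
  fx <- u[, 1] - i0; fy <- u[, 2] - j0; fz <- u[, 3] - k0
  if (d[1] == 1L) fx[] <- 0
  if (d[2] == 1L) fy[] <- 0
  if (d[3] == 1L) fz[] <- 0
  i1 <- pmin(i0 + 1, d[1] - 1L)
  j1 <- pmin(j0 + 1, d[2] - 1L)
  k1 <- pmin(k0 + 1, d[3] - 1L)

  vox <- function(i, j, k) volume$values[1L + i + d[1] * (j + d[2] * k)]
  v000 <- vox(i0, j0, k0); v100 <- vox(i1, j0, k0)
  v010 <- vox(i0, j1, k0); v110 <- vox(i1, j1, k0)
  v001 <- vox(i0, j0, k1); v101 <- vox(i1, j0, k1)
  v011 <- vox(i0, j1, k1); v111 <- vox(i1, j1, k1)

  values <-
    v000 * (1 - fx) * (1 - fy) * (1 - fz) + v100 * fx * (1 - fy) * (1 - fz) +
    v010 * (1 - fx) * fy * (1 - fz)       + v110 * fx * fy * (1 - fz) +
    v001 * (1 - fx) * (1 - fy) * fz       + v101 * fx * (1 - fy) * fz +
    v011 * (1 - fx) * fy * fz             + v111 * fx * fy * fz

  list(values = values, in_bounds = in_bounds)
}
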