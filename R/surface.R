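#' Binary segmentation mask aligned to a reference volume
#'
#' @param grid Logical (or 0/1) 3D array, same shape as the reference volume.
#' @param spacing Numeric length-3 voxel size in mm.
#' @param origin Numeric length-3 world position of voxel `(1,1,1)` in mm.
#' @return An object of class `segmentation_mask` with `grid`, `spacing`,
#'   `origin`, `voxel_count` and `volume_mm3`
#'   (`voxel_count * prod(spacing)`).
#' @export
segmentation_mask <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(grid)) != 3L) {
    stop("'grid' must be a 3D array", call. = FALSE)
  }
  grid <- array(as.logical(grid), dim = dim(grid))
  if (any(is.na(grid))) stop("mask values must be TRUE/FALSE", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("'spacing' must be three strictly positive values", call. = FALSE)
  }
  voxel_count <- sum(grid)
  structure(list(grid = grid, spacing = spacing, origin = as.numeric(origin),
                 voxel_count = voxel_count,
                 volume_mm3 = voxel_count * prod(spacing)),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("Segmentation mask %d x %d x %d\n", d[1], d[2], d[3]))
  cat(sprintf("  voxels: %d, volume: %.1f mm^3 (%.2f cm^3)\n",
              x$voxel_count, x$volume_mm3, x$volume_mm3 / 1000))
  invisible(x)
}

#' Closed surface mesh from a cut result
#'
#' The mesh vertices are the per-ray boundary points (the last source-bound
#' node of every ray) and the faces are the template triangulation, so the
#' mesh is watertight by construction. A cut with `delta_r = 0` yields the
#' template sphere scaled to the common cut radius and centered at the seed.
#'
#' @param cut A [solve_min_cut()] result with boundary points.
#' @param template The [ray_template()] used for the cut.
#' @param seed Seed position; only used when `cut` lacks boundary points
#'   (e.g. an oracle result), in which case they are reconstructed from
#'   `radii`.
#' @param radii Optional per-level radii for reconstruction.
#' @return A `triangle_mesh`.
#' @export
cut_to_surface <- function(cut, template, seed = NULL, radii = NULL) {
  stopifnot(inherits(cut, "cut_result"), inherits(template, "ray_template"))
  pts <- cut$boundary_points
  if (is.null(pts)) {
    if (is.null(seed) || is.null(radii)) {
      stop("incomplete cut: no boundary points; supply 'seed' and 'radii' ",
           "to reconstruct them", call. = FALSE)
    }
    pts <- template$directions * radii[cut$cut_index]
    pts <- sweep(pts, 2L, as.numeric(seed), "+")
  }
  if (nrow(pts) != nrow(template$directions) || anyNA(pts)) {
    stop("incomplete cut: boundary points missing for some rays",
         call. = FALSE)
  }
  triangle_mesh(pts, template$faces)
}

# every undirected edge of a closed triangle mesh is shared by exactly two
# faces
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Voxelize a watertight surface into a solid mask
#'
#' A voxel belongs to the mask when its center lies inside the closed surface;
#' the inside test casts a ray per voxel row and counts intersection parity.
#'
#' @param mesh A watertight `triangle_mesh`.
#' @param reference An [image_volume()] (or `segmentation_mask`) providing the
#'   grid shape, spacing and origin.
#' @return A [segmentation_mask()] on the reference grid.
#' @export
voxelize_surface <- function(mesh, reference) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  ref <- reference_geometry(reference)
  if (!mesh_is_watertight(mesh)) {
    stop("voxelization error: the mesh is not watertight", call. = FALSE)
  }
  inside <- voxelize_mesh_cpp(mesh$vertices, mesh$faces,
                              as.integer(ref$dim), ref$spacing, ref$origin)
  grid <- array(inside, dim = ref$dim)
  if (!any(grid)) {
    warning("voxelized mask is empty: no voxel center lies inside the surface")
  }
  segmentation_mask(grid, ref$spacing, ref$origin)
}

reference_geometry <- function(reference) {
  if (inherits(reference, "image_volume")) {
    list(dim = dim(reference$values), spacing = reference$spacing,
         origin = reference$origin)
  } else if (inherits(reference, "segmentation_mask")) {
    list(dim = dim(reference$grid), spacing = reference$spacing,
         origin = reference$origin)
  } else {
    stop("'reference' must be an image_volume or segmentation_mask",
         call. = FALSE)
  }
}

#' Voxelize manual slice contours into a 3D mask
#'
#' Emulates slice-by-slice manual segmentation: each closed polygon is filled
#' on its slice (a pixel belongs to the fill when its center is inside the
#' polygon under the even-odd rule with a half-open boundary convention, so
#' clockwise and counter-clockwise contours give identical masks), and all
#' filled slices are merged into one 3D mask by union.
#'
#' @param contours A list of contours; each contour is a list with `slice`
#'   (1-based slice index along z), `points` (n x 2 matrix of closed polygon
#'   vertices, first point equal to last) and optional `frame` (`"pixel"`,
#'   0-based pixel coordinates, the default, or `"world"`, mm).
#' @param reference An [image_volume()] (or mask) providing the grid.
#' @return A [segmentation_mask()].
#' @export
voxelize_contours <- function(contours, reference) {
  ref <- reference_geometry(reference)
  grid <- array(FALSE, dim = ref$dim)
  for (cnt in contours) {
    if (is.null(cnt$slice) || is.null(cnt$points)) {
      stop("contour-format error: each contour needs 'slice' and 'points'",
           call. = FALSE)
    }
    k <- as.integer(cnt$slice)
    if (k < 1L || k > ref$dim[3]) {
      stop("contour-format error: slice index ", k, " outside the grid",
           call. = FALSE)
    }
    p <- as.matrix(cnt$points)
    if (ncol(p) != 2L || nrow(p) < 4L) {
      stop("contour-format error: 'points' must be an n x 2 matrix of a ",
           "closed polygon", call. = FALSE)
    }
    if (any(p[1, ] != p[nrow(p), ])) {
      stop("contour-format error: open polygon (first point must equal ",
           "the last point)", call. = FALSE)
    }
    frame <- if (is.null(cnt$frame)) "pixel" else cnt$frame
    if (frame == "world") {
      p[, 1] <- (p[, 1] - ref$origin[1]) / ref$spacing[1]
      p[, 2] <- (p[, 2] - ref$origin[2]) / ref$spacing[2]
    }
    grid[, , k] <- grid[, , k] | fill_polygon(p, ref$dim[1], ref$dim[2])
  }
  segmentation_mask(grid, ref$spacing, ref$origin)
}

# even-odd scanline fill on the pixel-center lattice (0-based pixel coords);
# half-open rule: a center is inside when the number of edge crossings at
# x <= center is odd, which makes the fill orientation-free.
fill_polygon <- function(p, nx, ny) {
  out <- matrix(FALSE, nrow = nx, ncol = ny)
  xs <- p[-nrow(p), 1]; ys <- p[-nrow(p), 2]
  xe <- p[-1, 1]; ye <- p[-1, 2]
  for (jc in seq_len(ny) - 1L) {
    crosses <- (ys <= jc & ye > jc) | (ye <= jc & ys > jc)
    if (!any(crosses)) next
    xc <- xs[crosses] + (jc - ys[crosses]) *
      (xe[crosses] - xs[crosses]) / (ye[crosses] - ys[crosses])
    centers <- seq_len(nx) - 1L
    counts <- vapply(centers, function(x) sum(xc <= x), integer(1))
    out[, jc + 1L] <- (counts %% 2L) == 1L
  }
  out
}
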