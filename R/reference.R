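#' Estimate the average ablation-zone intensity around the seed
#'
#' Averages the image over an axis-aligned cube centered at the seed whose
#' physical volume is `region_volume_mm3` (about one cubic centimeter by
#' default). The cube edge length is the cube root of the region volume; it is
#' converted per axis into an odd-ish voxel count via the spacing, with a
#' minimum of one voxel per axis, and clipped to the grid. The median mode
#' rejects bright outliers such as the RFA needle when the seed is placed on
#' or near it; the mean only dilutes them.
#'
#' @param volume An [image_volume()].
#' @param seed A [seed_point()] (or world-mm numeric vector) inside the volume.
#' @param region_volume_mm3 Physical volume of the averaging cube in mm^3
#'   (default 1000 = 1 cm^3).
#' @param mode `"mean"` (default) or `"median"`.
#' @return A single numeric intensity.
#' @export
estimate_reference_value <- function(volume, seed, region_volume_mm3 = 1000,
                                     mode = c("mean", "median")) {
  mode <- match.arg(mode)
  if (!is.numeric(region_volume_mm3) || length(region_volume_mm3) != 1L ||
      !is.finite(region_volume_mm3) || region_volume_mm3 <= 0) {
    stop("'region_volume_mm3' must be a single positive number", call. = FALSE)
  }
  world <- seed_to_world(seed, volume, require_inside = TRUE)
  d <- dim(volume$values)
  edge <- region_volume_mm3^(1 / 3)

  # per-axis half window in voxels, at least one voxel per axis total
  center <- round((world - volume$origin) / volume$spacing)  # 0-based
  n <- pmax(1L, as.integer(round(edge / volume$spacing)))
  lo <- pmax(0L, as.integer(center - floor((n - 1L) / 2L)))
  hi <- pmin(d - 1L, as.integer(center + ceiling((n - 1L) / 2L)))
  if (any(lo > hi)) {
    stop("degenerate region: the averaging cube clipped to the volume ",
         "contains no voxel", call. = FALSE)
  }
  block <- volume$values[(lo[1]:hi[1]) + 1L,
                         (lo[2]:hi[2]) + 1L,
                         (lo[3]:hi[3]) + 1L]
  if (mode == "mean") mean(block) else median(block)
}
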