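#' Specification of a synthetic CT-like ablation phantom
#'
#' Describes a piecewise-constant volume emulating a post-ablation CT: a dark
#' ellipsoidal ablation zone in brighter background tissue, an optional bright
#' enhancing rim shell around the zone, an optional bright umbrella-shaped RFA
#' needle (a shaft entering the lesion plus tines fanning out from a hub), and
#' additive Gaussian noise. Intensities are abstract HU-like units with
#' defaults lesion 40, background 110, rim 160, needle 1000; the required
#' ordering is lesion < background < rim < needle.
#'
#' @param shape Grid dimensions `c(nx, ny, nz)`; `NULL` (default) fits the
#'   grid to the lesion plus `margin_mm` on every side.
#' @param spacing Voxel size in mm (defaults to an in-plane spacing of 0.7 mm
#'   and an inter-slice spacing of 2 mm, inside the typical CT ranges
#'   0.679-0.777 mm and 1-3 mm).
#' @param background Background tissue intensity.
#' @param lesion_center Lesion center in world mm; `NULL` centers it in the
#'   grid.
#' @param lesion_radii Per-axis ellipsoid radii in mm.
#' @param lesion_intensity Ablation-zone intensity.
#' @param rim_thickness Thickness in mm of the bright rim shell, or `NULL`
#'   for no rim.
#' @param rim_intensity Rim intensity.
#' @param needle `TRUE` to add the umbrella needle.
#' @param needle_entry World point where the shaft enters the grid; `NULL`
#'   places it on the low-x face at the lesion center height.
#' @param needle_shaft_radius,needle_tine_radius Cylinder radii in mm.
#' @param needle_tines Number of umbrella tines.
#' @param needle_tine_length Tine length in mm.
#' @param needle_tine_angle_deg Angle between shaft axis and tines.
#' @param needle_intensity Needle intensity.
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param rng_seed Seed for the noise generator (the phantom is deterministic
#'   for a fixed spec).
#' @param margin_mm Margin around the lesion for the auto-fitted grid.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = NULL,
                         spacing = c(0.7, 0.7, 2),
                         background = 110,
                         lesion_center = NULL,
                         lesion_radii = c(15, 15, 15),
                         lesion_intensity = 40,
                         rim_thickness = NULL,
                         rim_intensity = 160,
                         needle = FALSE,
                         needle_entry = NULL,
                         needle_shaft_radius = 0.75,
                         needle_tine_radius = 0.5,
                         needle_tines = 6L,
                         needle_tine_length = 12,
                         needle_tine_angle_deg = 45,
                         needle_intensity = 1000,
                         noise_sigma = 0,
                         rng_seed = 1L,
                         margin_mm = 10) {
  spacing <- as.numeric(spacing)
  lesion_radii <- rep_len(as.numeric(lesion_radii), 3L)
  if (any(spacing <= 0) || any(lesion_radii <= 0)) {
    stop("spacing and lesion radii must be positive", call. = FALSE)
  }
  if (!(lesion_intensity < background)) {
    stop("spec error: intensity ordering must be lesion < background",
         call. = FALSE)
  }
  if (!is.null(rim_thickness) && !(background < rim_intensity)) {
    stop("spec error: intensity ordering must be background < rim",
         call. = FALSE)
  }
  if (needle) {
    upper <- if (is.null(rim_thickness)) background else rim_intensity
    if (!(upper < needle_intensity)) {
      stop("spec error: the needle must be the brightest structure",
           call. = FALSE)
    }
  }
  if (is.null(shape)) {
    shape <- as.integer(ceiling(2 * (lesion_radii + margin_mm) / spacing)) + 1L
  } else {
    shape <- as.integer(rep_len(shape, 3L))
  }
  extent <- (shape - 1L) * spacing
  if (is.null(lesion_center)) lesion_center <- extent / 2
  lo <- lesion_center - lesion_radii
  hi <- lesion_center + lesion_radii
  if (any(lo < 0) || any(hi > extent)) {
    stop("spec error: the lesion does not fit inside the grid", call. = FALSE)
  }
  structure(list(
    shape = shape, spacing = spacing, background = background,
    lesion_center = as.numeric(lesion_center), lesion_radii = lesion_radii,
    lesion_intensity = lesion_intensity,
    rim_thickness = rim_thickness, rim_intensity = rim_intensity,
    needle = isTRUE(needle), needle_entry = needle_entry,
    needle_shaft_radius = needle_shaft_radius,
    needle_tine_radius = needle_tine_radius,
    needle_tines = as.integer(needle_tines),
    needle_tine_length = needle_tine_length,
    needle_tine_angle_deg = needle_tine_angle_deg,
    needle_intensity = needle_intensity,
    noise_sigma = noise_sigma, rng_seed = as.integer(rng_seed)),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Phantom spec: grid %s, spacing %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x")))
  cat(sprintf("  lesion radii %s mm (%.2f cm^3), rim: %s, needle: %s, noise sigma %.3g\n",
              paste(signif(x$lesion_radii, 4), collapse = "/"),
              4 / 3 * pi * prod(x$lesion_radii) / 1000,
              if (is.null(x$rim_thickness)) "none" else
                paste0(signif(x$rim_thickness, 3), " mm"),
              if (x$needle) "yes" else "no", x$noise_sigma))
  invisible(x)
}

# logical mask of voxels within 'radius' of the segment p-q, evaluated only
# inside the segment's bounding box
segment_voxels <- function(xg, yg, zg, p, q, radius) {
  d <- c(length(xg), length(yg), length(zg))
  out <- array(FALSE, dim = d)
  lo <- pmin(p, q) - radius
  hi <- pmax(p, q) + radius
  ii <- which(xg >= lo[1] & xg <= hi[1])
  jj <- which(yg >= lo[2] & yg <= hi[2])
  kk <- which(zg >= lo[3] & zg <= hi[3])
  if (!length(ii) || !length(jj) || !length(kk)) return(out)
  X <- xg[ii][slice.index(array(0, c(length(ii), length(jj), length(kk))), 1)]
  Y <- yg[jj][slice.index(array(0, c(length(ii), length(jj), length(kk))), 2)]
  Z <- zg[kk][slice.index(array(0, c(length(ii), length(jj), length(kk))), 3)]
  v <- q - p
  L2 <- sum(v^2)
  t <- ((X - p[1]) * v[1] + (Y - p[2]) * v[2] + (Z - p[3]) * v[3]) /
    max(L2, 1e-12)
  t <- pmin(pmax(t, 0), 1)
  d2 <- (X - (p[1] + t * v[1]))^2 + (Y - (p[2] + t * v[2]))^2 +
    (Z - (p[3] + t * v[3]))^2
  out[ii, jj, kk] <- array(d2 <= radius^2, dim = c(length(ii), length(jj),
                                                   length(kk)))
  out
}

#' Generate a synthetic ablation phantom with ground truth
#'
#' Renders the [phantom_spec()] into an intensity volume and the ground-truth
#' lesion mask. A voxel belongs to a structure when its center lies inside
#' the structure's analytic shape; structures are painted in the order
#' background, lesion, rim, needle (the needle overwrites whatever it
#' crosses). The ground truth is the lesion ellipsoid with needle voxels
#' excluded — the needle is an artifact, not ablated tissue. Gaussian noise is
#' generated from `rng_seed` without disturbing the caller's RNG state, so a
#' fixed spec always renders bit-identical volumes.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `volume` ([image_volume()]), `truth`
#'   ([segmentation_mask()]) and the `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  xg <- (seq_len(d[1]) - 1L) * spec$spacing[1]
  yg <- (seq_len(d[2]) - 1L) * spec$spacing[2]
  zg <- (seq_len(d[3]) - 1L) * spec$spacing[3]

  ellipsoid <- function(radii) {
    ex <- ((xg - spec$lesion_center[1]) / radii[1])^2
    ey <- ((yg - spec$lesion_center[2]) / radii[2])^2
    ez <- ((zg - spec$lesion_center[3]) / radii[3])^2
    inplane <- outer(ex, ey, "+")
    vapply(ez, function(e) inplane + e <= 1,
           matrix(TRUE, d[1], d[2])) |> array(dim = d)
  }

  lesion <- ellipsoid(spec$lesion_radii)
  values <- array(spec$background, dim = d)
  if (!is.null(spec$rim_thickness)) {
    shell <- ellipsoid(spec$lesion_radii + spec$rim_thickness) & !lesion
    values[shell] <- spec$rim_intensity
  }
  values[lesion] <- spec$lesion_intensity

  needle_mask <- array(FALSE, dim = d)
  if (spec$needle) {
    hub <- spec$lesion_center
    entry <- spec$needle_entry
    if (is.null(entry)) entry <- c(0, hub[2], hub[3])
    axis <- hub - entry
    axis <- axis / sqrt(sum(axis^2))
    needle_mask <- segment_voxels(xg, yg, zg, entry, hub,
                                  spec$needle_shaft_radius)
    # orthonormal frame around the shaft axis for the umbrella tines
    ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    p1 <- ref - sum(ref * axis) * axis
    p1 <- p1 / sqrt(sum(p1^2))
    p2 <- c(axis[2] * p1[3] - axis[3] * p1[2],
            axis[3] * p1[1] - axis[1] * p1[3],
            axis[1] * p1[2] - axis[2] * p1[1])
    a <- spec$needle_tine_angle_deg * pi / 180
    for (i in seq_len(spec$needle_tines)) {
      phi <- 2 * pi * (i - 1) / spec$needle_tines + 0.3
      dir <- cos(a) * axis + sin(a) * (cos(phi) * p1 + sin(phi) * p2)
      tip <- hub + spec$needle_tine_length * dir
      needle_mask <- needle_mask |
        segment_voxels(xg, yg, zg, hub, tip, spec$needle_tine_radius)
    }
    values[needle_mask] <- spec$needle_intensity
  }

  if (spec$noise_sigma > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(spec$rng_seed)
    values <- values + array(rnorm(prod(d), sd = spec$noise_sigma), dim = d)
  }

  truth <- lesion & !needle_mask
  list(volume = image_volume(values, spec$spacing, origin = c(0, 0, 0)),
       truth = segmentation_mask(truth, spec$spacing, origin = c(0, 0, 0)),
       spec = spec)
}

#' Draw a suite of phantom specs emulating a clinical case series
#'
#' Lesion volumes are drawn log-uniformly across the 6.25-122.62 cm^3 range
#' typical of post-RFA ablation zones, with mild random anisotropy; in-plane
#' spacings are drawn from 0.679-0.777 mm and inter-slice spacings from
#' 1-3 mm. Half of the cases (rounded up) carry the retained umbrella needle,
#' mirroring series in which the electrode was still in place in half of the
#' scans; every case has a bright enhancing rim.
#'
#' @param n_cases Number of specs (>= 1).
#' @param rng_seed Seed driving all draws; also used to derive each case's
#'   noise seed, so the suite is fully reproducible.
#' @param noise_sigma Noise level for every case (default 10).
#' @return A list of [phantom_spec()] objects.
#' @export
phantom_case_suite <- function(n_cases, rng_seed = 1L, noise_sigma = 10) {
  stopifnot(n_cases >= 1L)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(rng_seed)

  specs <- vector("list", n_cases)
  with_needle <- seq_len(n_cases) %% 2L == 1L
  for (i in seq_len(n_cases)) {
    vol_cm3 <- exp(runif(1, log(6.25), log(122.62)))
    r0 <- (3 * vol_cm3 * 1000 / (4 * pi))^(1 / 3)
    f <- exp(runif(3, log(0.85), log(1.2)))
    f <- f / prod(f)^(1 / 3)  # keep the analytic volume exact
    spacing <- c(rep(runif(1, 0.679, 0.777), 2), runif(1, 1, 3))
    specs[[i]] <- phantom_spec(
      spacing = spacing,
      lesion_radii = r0 * f,
      rim_thickness = runif(1, 1.5, 3),
      needle = with_needle[i],
      noise_sigma = noise_sigma,
      rng_seed = (rng_seed * 1009L + i) %% 2147483647L)
  }
  specs
}

#' Serialize a phantom spec to YAML (and back)
#'
#' @param spec A [phantom_spec()].
#' @param path Output (input) file path.
#' @return `write_phantom_spec` returns the path invisibly;
#'   `read_phantom_spec` returns the [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$rim_thickness <- raw$rim_thickness  # may be NULL
  do.call(phantom_spec, raw[intersect(names(raw),
                                      names(formals(phantom_spec)))])
}
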