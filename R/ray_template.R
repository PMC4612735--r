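#' Spherical ray template from a recursively refined icosahedron
#'
#' Builds the set of unit ray directions used for the polar graph construction.
#' The template starts from the regular icosahedron (12 vertices, 20 faces) and
#' is refined by repeatedly inserting every triangle's centroid, projected back
#' onto the unit sphere, and replacing the triangle by three smaller ones
#' ("kis" subdivision). The vertex count therefore follows
#' \eqn{V_{k+1} = V_k + F_k}, \eqn{F_{k+1} = 3 F_k}, i.e. 12, 32, 92, 272, 812,
#' 2432 directions for levels 0 to 5.
#'
#' The raw refinement recursion fixes the direction *counts* but clusters the
#' points (centroids of increasingly skinny triangles accumulate near old
#' vertices; the nearest-neighbour distance ratio exceeds 10 at level 4),
#' and its triangulation keeps every coarse edge — an original icosahedron
#' edge spans 63 degrees at all levels. Both properties break the smoothness
#' constraint, which assumes adjacent rays at a single angular scale. The
#' directions are therefore relaxed to a quasi-uniform configuration by a
#' deterministic tangential electrostatic (Thomson-style) repulsion, and the
#' triangulation — and with it the ray adjacency — is the convex hull of the
#' relaxed directions, whose edges are locally uniform.
#'
#' @param level Integer subdivision depth between 0 and 5.
#'
#' @return An object of class `ray_template` with components
#'   \describe{
#'     \item{level}{the subdivision depth}
#'     \item{directions}{numeric matrix (rays x 3) of unit vectors}
#'     \item{faces}{integer matrix (faces x 3) of 1-based vertex indices}
#'     \item{adjacency}{integer matrix (edges x 2), each row an unordered pair
#'       of adjacent ray indices with `adjacency[,1] < adjacency[,2]`}
#'   }
#'
#' @examples
#' tpl <- ray_template(2)
#' nrow(tpl$directions)  # 92
#'
#' @export
ray_template <- function(level) {
  if (length(level) != 1L || is.na(level) || level != as.integer(level) ||
      level < 0L || level > 5L) {
    stop("'level' must be a single integer between 0 and 5 ",
         "(12, 32, 92, 272, 812 or 2432 rays)", call. = FALSE)
  }
  level <- as.integer(level)

  cached <- .template_cache[[as.character(level)]]
  if (!is.null(cached)) return(cached)

  mesh <- icosahedron()
  for (k in seq_len(level)) {
    mesh <- kis_subdivide(mesh)
  }
  directions <- mesh$vertices
  if (level > 0L) {
    # deterministic quasi-uniform redistribution; the icosahedron (level 0)
    # is already the uniform optimum
    directions <- relax_directions_cpp(directions, iters = 300L,
                                       step_factor = 0.05)
  }
  faces <- convex_hull_cpp(directions)

  template <- structure(
    list(level = level,
         directions = directions,
         faces = faces,
         adjacency = faces_to_edges(faces)),
    class = "ray_template")
  .template_cache[[as.character(level)]] <- template
  template
}

# templates are deterministic per level; cache them for the session
.template_cache <- new.env(parent = emptyenv())

#' @export
print.ray_template <- function(x, ...) {
  cat(sprintf("Spherical ray template (level %d)\n", x$level))
  cat(sprintf("  rays (vertices): %d\n", nrow(x$directions)))
  cat(sprintf("  faces:           %d\n", nrow(x$faces)))
  cat(sprintf("  adjacency edges: %d\n", nrow(x$adjacency)))
  invisible(x)
}

#' Triangle mesh of the unit-sphere template
#'
#' Exposes the template's triangulation as a watertight triangle mesh on the
#' unit sphere, mainly for inspection and export.
#'
#' @param template A [ray_template()].
#' @return An object of class `triangle_mesh` with `vertices` (n x 3) and
#'   `faces` (m x 3, 1-based indices).
#' @export
template_mesh <- function(template) {
  stopifnot(inherits(template, "ray_template"))
  triangle_mesh(template$directions, template$faces)
}

#' Construct a triangle mesh object
#'
#' @param vertices Numeric matrix (n x 3) of vertex coordinates.
#' @param faces Integer matrix (m x 3) of 1-based vertex indices.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L) {
    stop("vertices and faces must have three columns", call. = FALSE)
  }
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("Triangle mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Canonical regular icosahedron (golden-ratio construction), vertices on the
# unit sphere. Fixed coordinates so every template is reproducible.
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6),  c(1, 6, 2),   c(1, 2, 8),   c(1, 8, 11),  c(1, 11, 12),
    c(2, 6, 10),  c(6, 12, 5),  c(12, 11, 3), c(11, 8, 7),  c(8, 2, 9),
    c(4, 10, 5),  c(4, 5, 3),   c(4, 3, 7),   c(4, 7, 9),   c(4, 9, 10),
    c(5, 10, 6),  c(3, 5, 12),  c(7, 3, 11),  c(9, 7, 8),   c(10, 9, 2))
  storage.mode(f) <- "integer"
  list(vertices = v, faces = f)
}

# One "kis" refinement step: insert each face centroid (projected to the unit
# sphere) and split the face into three. V' = V + F, F' = 3F. The edges
# introduced by the step (centroid to the three corners) are returned
# separately; they are the finest-scale edges used for ray adjacency.
kis_subdivide <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  nf <- nrow(f)
  centroids <- (v[f[, 1], , drop = FALSE] +
                v[f[, 2], , drop = FALSE] +
                v[f[, 3], , drop = FALSE]) / 3
  centroids <- centroids / sqrt(rowSums(centroids^2))
  cidx <- nv + seq_len(nf)
  newf <- rbind(
    cbind(f[, 1], f[, 2], cidx),
    cbind(f[, 2], f[, 3], cidx),
    cbind(f[, 3], f[, 1], cidx))
  storage.mode(newf) <- "integer"
  new_edges <- cbind(c(f[, 1], f[, 2], f[, 3]), rep(cidx, 3L))
  new_edges <- cbind(pmin(new_edges[, 1], new_edges[, 2]),
                     pmax(new_edges[, 1], new_edges[, 2]))
  new_edges <- new_edges[order(new_edges[, 1], new_edges[, 2]), ,
                         drop = FALSE]
  storage.mode(new_edges) <- "integer"
  list(vertices = rbind(v, centroids), faces = newf, new_edges = new_edges)
}

# Undirected edge list (unique, sorted pairs) of a triangulation.
faces_to_edges <- function(faces) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  storage.mode(e) <- "integer"
  e
}
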