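# closed triangulated vesicle meshes

#' Generate a closed, genus-0 triangulated vesicle mesh
#'
#' An icosahedron is subdivided to just below the requested vertex count,
#' brought to the exact count by longest-edge splits, and relaxed on the
#' sphere (Delaunay flips plus edge-length springs, with a simulated-
#' annealing fallback for stubborn defect configurations) until every bond
#' length lies strictly inside `(l_min, 1.7 l_min)` and every non-bonded
#' vertex pair is at least `l_min` apart. Lengths are in units of `l_min`.
#'
#' @param n_vertices number of vertices (>= 12). A closed genus-0
#'   triangulation then has exactly `2 * n_vertices - 4` faces.
#' @param radius optional target sphere radius in `l_min` units; when given,
#'   the implied mean bond length must be realizable inside the hard window,
#'   otherwise the function errors.
#' @param seed integer seed (the relaxation fallback draws random jitter).
#' @param relax_iters relaxation iterations.
#' @return object of class `tri_mesh`: list with `positions` (`V x 3`),
#'   `faces` (`F x 3`, 1-based, outward CCW), `edges` (`E x 2`), and the
#'   bond window.
#' @export
generate_vesicle_mesh <- function(n_vertices, radius = NULL, seed = 1,
                                  relax_iters = 600) {
  stopifnot(n_vertices >= 12)
  l_min <- 1
  l_max <- 1.7
  l0 <- (l_min + l_max) / 2
  if (!is.null(radius)) {
    # mean bond length implied by the requested radius at this face count
    nf <- 2 * n_vertices - 4
    implied <- sqrt(16 * pi * radius^2 / (sqrt(3) * nf))
    if (implied <= 1.1 * l_min || implied >= 1.6 * l_min) {
      stop(sprintf(
        "radius %.3g implies mean bond length %.3g l_min at %d vertices, outside the realizable window",
        radius, implied, n_vertices
      ))
    }
    l0 <- implied
  }
  raw <- local_seed(seed, cpp_build_sphere_mesh(n_vertices, l0, relax_iters))
  geo <- cpp_mesh_geometry(raw$positions, raw$faces)
  nb <- cpp_min_nonbonded_dist(raw$positions, raw$faces)
  if (raw$edge_min <= l_min || raw$edge_max >= l_max || nb < l_min) {
    stop(sprintf(
      paste0(
        "could not satisfy edge constraints at %d vertices: bond lengths ",
        "[%.3f, %.3f] (need (%.2f, %.2f)), min non-bonded distance %.3f ",
        "(need >= %.2f); try a different seed or more relax_iters"
      ),
      n_vertices, raw$edge_min, raw$edge_max, l_min, l_max, nb, l_min
    ))
  }
  structure(
    list(
      positions = raw$positions, faces = raw$faces, edges = geo$edges,
      l_min = l_min, l_max = l_max,
      edge_range = c(raw$edge_min, raw$edge_max)
    ),
    class = "tri_mesh"
  )
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf(
    "<tri_mesh> V=%d F=%d E=%d, bond lengths [%.3f, %.3f] l_min\n",
    nrow(x$positions), nrow(x$faces), nrow(x$edges),
    x$edge_range[1], x$edge_range[2]
  ))
  invisible(x)
}

#' Discrete mean curvature at every vertex
#'
#' Cotangent Laplace-Beltrami construction with barycentric dual areas;
#' the sign is positive for a sphere with outward normals. On a
#' well-relaxed sphere of radius R every vertex is close to `1/R`.
#'
#' @param mesh a `tri_mesh` (or any list with `positions` and `faces`).
#' @return tibble with per-vertex `H` (1/l_min), `area` (l_min^2), and the
#'   outward unit normal components.
#' @export
mean_curvature <- function(mesh) {
  g <- cpp_mesh_geometry(mesh$positions, mesh$faces)
  tibble(
    vertex = seq_len(nrow(mesh$positions)),
    H = g$H, area = g$vertex_area,
    nx = g$normals[, 1], ny = g$normals[, 2], nz = g$normals[, 3]
  )
}

#' Gyration-tensor eigenvalues and asphericity
#'
#' The gyration tensor of the (unweighted) vertex positions about their
#' centroid is diagonalized; with eigenvalues `l1 >= l2 >= l3` the
#' asphericity is
#' `A = ((l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2) / (2 (l1+l2+l3)^2)`,
#' which is 0 for a sphere, 1/4 for a flat axisymmetric disk, and 1 for a
#' one-dimensional rod.
#'
#' @param mesh a `tri_mesh`, a `sim_state`, or a numeric `V x 3` position
#'   matrix.
#' @return a list with `lambda` (sorted eigenvalues) and `asphericity`.
#' @export
asphericity <- function(mesh) {
  pos <- if (is.matrix(mesh)) mesh else mesh$positions
  stopifnot(is.matrix(pos), ncol(pos) == 3, nrow(pos) >= 3)
  lam <- cpp_gyration_eigen(pos)
  if (all(lam <= 1e-300)) stop("all vertices coincide")
  tr <- sum(lam)
  asph <- ((lam[1] - lam[2])^2 + (lam[2] - lam[3])^2 + (lam[3] - lam[1])^2) /
    (2 * tr^2)
  list(lambda = lam, asphericity = asph)
}

#' Write a mesh as ASCII PLY
#'
#' @param mesh a `tri_mesh` or `sim_state`; a per-vertex `protein` flag, if
#'   present, is stored as a scalar property.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_mesh_ply <- function(mesh, path) {
  pos <- mesh$positions
  faces <- mesh$faces
  prot <- mesh$protein %||% rep(0L, nrow(pos))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(pos)),
    "property float x", "property float y", "property float z",
    "property uchar protein",
    sprintf("element face %d", nrow(faces)),
    "property list uchar int vertex_indices", "end_header"
  ), con)
  writeLines(sprintf("%.6f %.6f %.6f %d", pos[, 1], pos[, 2], pos[, 3],
                     as.integer(prot)), con)
  writeLines(sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L,
                     faces[, 3] - 1L), con)
  invisible(path)
}

#' Write a mesh as OFF
#'
#' @inheritParams write_mesh_ply
#' @export
write_mesh_off <- function(mesh, path) {
  pos <- mesh$positions
  faces <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(pos), nrow(faces)), con)
  writeLines(sprintf("%.6f %.6f %.6f", pos[, 1], pos[, 2], pos[, 3]), con)
  writeLines(sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L,
                     faces[, 3] - 1L), con)
  invisible(path)
}
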