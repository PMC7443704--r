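#' Neuropil volumes
#'
#' A volume is a named spatial region with a point-membership test: either an
#' axis-aligned box (two corner points, nanometres) or a closed triangle
#' mesh. Boxes are how the synthetic generator lays out neuropils (antennal
#' lobe, calyx, lateral accessory calyx, ...); meshes support regions traced
#' from real neuron axons.
#'
#' @param name volume name, e.g. `"lACA_R"`.
#' @param min,max numeric length-3 box corners in nanometres; corners are
#'   reordered so `min <= max` per axis.
#' @return A `consat_volume` object.
#' @examples
#' v <- box_volume("lACA_R", c(0, 0, 0), c(10e3, 10e3, 10e3))
#' point_in_volume(c(5e3, 5e3, 5e3), v)
#' @export
box_volume <- function(name, min, max) {
  stopifnot(length(min) == 3, length(max) == 3)
  lo <- pmin(min, max)
  hi <- pmax(min, max)
  check_that(all(is.finite(c(lo, hi))), "non-finite box corners", "invalid_volume")
  structure(list(name = name, kind = "box", min = lo, max = hi),
    class = "consat_volume")
}

#' @rdname box_volume
#' @param vertices V x 3 numeric matrix of mesh vertices (nanometres).
#' @param faces F x 3 integer matrix of 1-based vertex indices (triangles).
#' @export
mesh_volume <- function(name, vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  check_that(ncol(vertices) == 3 && all(is.finite(vertices)),
    "mesh vertices must be a finite V x 3 matrix", "invalid_volume")
  check_that(nrow(faces) >= 4 && all(faces >= 1) && all(faces <= nrow(vertices)),
    "degenerate mesh: need >= 4 triangles with resolving vertex indices",
    "invalid_volume")
  # a closed orientable surface has every edge shared by exactly two triangles
  edges <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  if (any(table(key) != 2L)) {
    consat_abort("degenerate mesh: surface is not closed (open or non-manifold edges)",
      "invalid_volume")
  }
  structure(list(name = name, kind = "mesh", vertices = vertices, faces = faces),
    class = "consat_volume")
}

#' @export
print.consat_volume <- function(x, ...) {
  if (x$kind == "box") {
    cat(sprintf("<volume %s: box [%s] - [%s] nm>\n", x$name,
      paste(format(x$min, trim = TRUE), collapse = ", "),
      paste(format(x$max, trim = TRUE), collapse = ", ")))
  } else {
    cat(sprintf("<volume %s: mesh, %d vertices, %d triangles>\n",
      x$name, nrow(x$vertices), nrow(x$faces)))
  }
  invisible(x)
}

#' Triangulate an axis-aligned box into a closed mesh
#'
#' Mainly useful for cross-checking the box and mesh membership paths against
#' each other.
#'
#' @param volume a box volume.
#' @return a mesh `consat_volume` covering the same region.
#' @export
box_to_mesh <- function(volume) {
  stopifnot(volume$kind == "box")
  lo <- volume$min; hi <- volume$max
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]), z = c(lo[3], hi[3])))
  # 12 triangles, outward-consistent enough for a parity test
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = lo
    c(5, 6, 7), c(6, 8, 7),   # z = hi
    c(1, 2, 5), c(2, 6, 5),   # y = lo
    c(3, 7, 4), c(4, 7, 8),   # y = hi
    c(1, 5, 3), c(3, 5, 7),   # x = lo
    c(2, 4, 6), c(4, 8, 6)    # x = hi
  )
  mesh_volume(volume$name, v, f)
}

#' Read a triangle mesh volume from a Wavefront OBJ file
#'
#' Parses `v` and triangular `f` records (`f` vertex indices may carry
#' `/texture/normal` suffixes, which are ignored).
#'
#' @param path OBJ file path.
#' @param name volume name; defaults to the file name without extension.
#' @param unit_scale nanometres per file coordinate unit.
#' @return a mesh `consat_volume`.
#' @export
read_obj <- function(path, name = NULL, unit_scale = 1) {
  lines <- readLines(path, warn = FALSE)
  vs <- strsplit(trimws(grep("^v ", lines, value = TRUE)), "[[:space:]]+")
  fs <- strsplit(trimws(grep("^f ", lines, value = TRUE)), "[[:space:]]+")
  check_that(length(vs) > 0 && length(fs) > 0, "OBJ file without v/f records",
    "invalid_volume")
  vertices <- t(vapply(vs, function(f) as.numeric(f[2:4]), numeric(3))) * unit_scale
  faces <- t(vapply(fs, function(f) {
    idx <- as.integer(sub("/.*$", "", f[-1]))
    check_that(length(idx) == 3, "non-triangular OBJ face", "invalid_volume")
    idx
  }, integer(3)))
  mesh_volume(name %||% sub("\\.[oO][bB][jJ]$", "", basename(path)), vertices, faces)
}

#' Point-in-volume membership test
#'
#' For boxes, membership is `min <= coord <= max` on every axis (the boundary
#' counts as inside). For meshes, a ray-parity test along a fixed irrational
#' direction is used; points lying on the surface (ray origin on a triangle)
#' count as inside.
#'
#' @param points a length-3 numeric vector, an N x 3 matrix, or a data frame
#'   with columns `x`, `y`, `z` (nanometres).
#' @param volume a `consat_volume`.
#' @return logical vector of length N.
#' @export
point_in_volume <- function(points, volume) {
  p <- as_point_matrix(points)
  check_that(all(is.finite(p)), "non-finite query point", "invalid_volume")
  if (volume$kind == "box") {
    lo <- volume$min; hi <- volume$max
    return(p[, 1] >= lo[1] & p[, 1] <= hi[1] &
           p[, 2] >= lo[2] & p[, 2] <= hi[2] &
           p[, 3] >= lo[3] & p[, 3] <= hi[3])
  }
  vapply(seq_len(nrow(p)), function(i) mesh_contains(p[i, ], volume), logical(1))
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) {
    p <- as.matrix(points[, c("x", "y", "z")])
  } else if (is.matrix(points)) {
    p <- points
  } else {
    p <- matrix(points, ncol = 3, byrow = TRUE)
  }
  storage.mode(p) <- "double"
  p
}

# Ray-parity containment with a fixed quasi-random direction; falls back to
# alternative fixed directions when a ray grazes an edge or vertex.
mesh_contains <- function(point, volume) {
  dirs <- rbind(
    c(0.57735026918962573, 0.21132486540518713, 0.78867513459481287),
    c(0.31622776601683794, 0.83205029433784372, 0.45573539334676282),
    c(0.90453403373329089, 0.30151134457776363, 0.30151134457776363)
  )
  v <- volume$vertices; f <- volume$faces
  scale <- max(abs(v)) + 1
  eps <- 1e-9 * scale
  for (d in seq_len(nrow(dirs))) {
    hit <- ray_triangle_hits(point, dirs[d, ], v, f, eps)
    if (hit$on_surface) return(TRUE)
    if (!hit$degenerate) return(hit$count %% 2L == 1L)
  }
  # all rays grazed; treat as boundary
  TRUE
}

ray_triangle_hits <- function(orig, dir, v, f, eps) {
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  # Moeller-Trumbore, vectorised over triangles
  pv <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
              dir[3] * e2[, 1] - dir[1] * e2[, 3],
              dir[1] * e2[, 2] - dir[2] * e2[, 1])
  det <- rowSums(e1 * pv)
  ok <- abs(det) > 1e-12
  tv <- matrix(orig, nrow(a), 3, byrow = TRUE) - a
  u <- rowSums(tv * pv) / det
  qv <- cbind(tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
              tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
              tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1])
  vv <- (qv[, 1] * dir[1] + qv[, 2] * dir[2] + qv[, 3] * dir[3]) / det
  tt <- rowSums(e2 * qv) / det
  inside_tri <- ok & u >= 0 & vv >= 0 & (u + vv) <= 1
  on_surface <- any(inside_tri & abs(tt) <= eps)
  forward <- inside_tri & tt > eps
  # a hit essentially on a triangle edge/vertex makes parity unreliable
  edge_tol <- 1e-9
  degenerate <- any(forward &
    (u < edge_tol | vv < edge_tol | (1 - u - vv) < edge_tol))
  list(count = sum(forward), on_surface = on_surface, degenerate = degenerate)
}
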