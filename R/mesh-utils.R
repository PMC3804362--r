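#' Surface area of a triangle mesh
#'
#' @param surface a [Surface-class].
#' @return total area (mm^2).
#' @export
meshArea <- function(surface) {
  v <- surface@vertices
  f <- surface@faces
  a <- v[f[, 1], , drop = FALSE]
  u <- v[f[, 2], , drop = FALSE] - a
  w <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Enclosed volume of a closed oriented mesh
#'
#' Signed tetrahedron sum (divergence theorem); positive for outward
#' orientation.
#'
#' @param surface a [Surface-class].
#' @return volume (mm^3).
#' @export
meshVolume <- function(surface) {
  v <- surface@vertices
  f <- surface@faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  det3 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
          a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
          a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(det3) / 6
}

#' Euler characteristic V - E + F
#'
#' Equals 2 for a closed genus-0 surface.
#'
#' @param surface a [Surface-class].
#' @return integer Euler characteristic.
#' @export
eulerCharacteristic <- function(surface) {
  f <- surface@faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  nE <- nrow(unique(e))
  nrow(surface@vertices) - nE + nrow(f)
}

#' Is the mesh closed (every edge shared by exactly two faces)?
#'
#' @param surface a [Surface-class].
#' @return logical.
#' @export
isClosedSurface <- function(surface) {
  f <- surface@faces
  if (nrow(f) == 0) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Bounding-box diagonal of a surface
#'
#' @param surface a [Surface-class].
#' @return diagonal length (mm).
#' @export
boundingBoxDiagonal <- function(surface) {
  r <- apply(surface@vertices, 2, range)
  sqrt(sum((r[2, ] - r[1, ])^2))
}

#' Symmetric Hausdorff distance between two surfaces
#'
#' Max over both directions of the largest vertex-to-surface distance
#' (vertices of one mesh against the triangles of the other).
#'
#' @param a,b [Surface-class] objects.
#' @return distance (mm).
#' @export
hausdorffDistance <- function(a, b) {
  dab <- cpp_point_mesh_dist(a@vertices, b@vertices, b@faces)
  dba <- cpp_point_mesh_dist(b@vertices, a@vertices, a@faces)
  max(max(dab), max(dba))
}

#' Keep the largest connected component of a mesh
#'
#' @param vertices,faces raw mesh arrays (1-based faces).
#' @return list with `vertices`, `faces`, and `nComponents` found.
#' @keywords internal
largestComponent <- function(vertices, faces) {
  g <- igraph::graph_from_edgelist(
    rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)]),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(vertices) - igraph::vcount(g)))
  comp <- igraph::components(g)
  if (comp$no <= 1L)
    return(list(vertices = vertices, faces = faces, nComponents = 1L))
  keep <- which.max(comp$csize)
  vKeep <- which(comp$membership == keep)
  remap <- integer(nrow(vertices))
  remap[vKeep] <- seq_along(vKeep)
  fKeep <- faces[faces[, 1] %in% vKeep, , drop = FALSE]
  fKeep[] <- remap[fKeep]
  list(vertices = vertices[vKeep, , drop = FALSE], faces = fKeep,
       nComponents = comp$no)
}

# rotation angle (radians) of a 3x3 rotation matrix
rotationAngle <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))
}
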