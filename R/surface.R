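# Surface reconstruction from a binary mask and minimal (Taubin) smoothing.
#
# The mask is isosurfaced at level 0.5 by marching tetrahedra (a
# marching-cubes-style method on a 6-tetrahedron cell split), after the
# paper's order of operations: segment first, then reconstruct. Smoothing is
# the volume-preserving lambda/mu pair of Taubin, which damps the voxel
# staircase without simplifying the surface.

#' Extract the isosurface of a binary mask
#'
#' Marching-tetrahedra isosurface at level 0.5 on the 0/1 grid; vertices are
#' mapped to physical millimetres through the mask geometry. Face winding is
#' outward (normals point away from the segmented bone).
#'
#' @param mask a non-empty [binary_mask()].
#' @return A [surface_mesh()].
#' @export
extract_isosurface <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$voxels)) stop("mask is empty; no surface to extract")
  d <- dim(mask$voxels)
  # pad with a background layer so solids touching the boundary stay closed
  padded <- array(0, dim = d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.numeric(mask$voxels)
  iso <- .mt_isosurface(as.numeric(padded), dim(padded), 0.5)
  Vidx <- iso$vertices - 1  # un-pad back to 0-based grid indices
  A <- mask$direction %*% diag(mask$spacing)
  V <- sweep(Vidx %*% t(A), 2, mask$origin, `+`)
  F <- iso$faces
  # marching tetrahedra can emit zero-area slivers when a corner sits
  # exactly on the level; drop them to honour the no-degenerate-face rule
  mesh <- surface_mesh(V, F)
  areas <- sqrt(rowSums(face_normals_area(mesh)^2)) / 2
  keep <- areas > 1e-12
  if (!all(keep)) mesh <- surface_mesh(V, F[keep, , drop = FALSE])
  if (det(mask$direction) < 0) # index-space winding flips in physical space
    mesh <- surface_mesh(mesh$vertices, mesh$faces[, c(1, 3, 2), drop = FALSE])
  mesh
}

# row-normalised vertex adjacency operator (sparse), from face edges
mesh_adjacency <- function(mesh) {
  F <- mesh$faces
  i <- c(F[, 1], F[, 2], F[, 2], F[, 3], F[, 3], F[, 1])
  j <- c(F[, 2], F[, 1], F[, 3], F[, 2], F[, 1], F[, 3])
  W <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = rep(nrow(mesh$vertices), 2))
  W@x[] <- 1  # duplicate edges collapse to weight 1
  W <- methods::as(W, "CsparseMatrix")
  deg <- Matrix::rowSums(W)
  deg[deg == 0] <- 1
  list(W = W, deg = deg)
}

#' Smooth a mesh without changing its topology
#'
#' Taubin lambda/mu smoothing: alternating shrink (`lambda`) and inflate
#' (`mu`) Laplacian steps, volume-preserving in intent. Vertex and face
#' counts are never changed (no simplification); `iterations = 0` is the
#' identity.
#'
#' @param mesh a [surface_mesh()].
#' @param iterations number of lambda/mu pairs (default 10).
#' @param lambda,mu Taubin coefficients (defaults 0.5 / -0.53).
#' @return The smoothed [surface_mesh()] with identical topology.
#' @export
smooth_mesh <- function(mesh, iterations = 10, lambda = 0.5, mu = -0.53) {
  stopifnot(inherits(mesh, "surface_mesh"), iterations >= 0)
  if (iterations == 0) return(mesh)
  adj <- mesh_adjacency(mesh)
  V <- mesh$vertices
  for (it in seq_len(iterations)) {
    V <- V + lambda * (as.matrix(adj$W %*% V) / adj$deg - V)
    V <- V + mu * (as.matrix(adj$W %*% V) / adj$deg - V)
  }
  surface_mesh(V, mesh$faces)
}
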