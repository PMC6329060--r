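# Acetabular sphere fitting and the hip axis.
#
# The acetabular fossa is fitted as a surrogate for the femoral-head
# center: an algebraic least-squares sphere initialises a geometric
# (orthogonal-distance) Gauss-Newton refinement, and an inlier band around
# the current sphere surface rejects rim/lunate-margin vertices.

#' Least-squares sphere fit
#'
#' Algebraic linear fit (Pratt-style normal equations) followed by
#' geometric Gauss-Newton refinement of `sum((|p - c| - R)^2)`. Exact for
#' points sampled exactly on a sphere.
#'
#' @param points n x 3 matrix of points (mm), n >= 4, not coplanar.
#' @return An object of class `sphere_fit` with `center`, `radius`,
#'   `rms_residual`, `n_inliers`.
#' @export
fit_sphere <- function(points) {
  P <- as_points(points)
  n <- nrow(P)
  if (n < 4) stop("need at least 4 points to fit a sphere, got ", n)
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  qrA <- qr(A)
  if (qrA$rank < 4)
    stop("degenerate point set (coplanar or coincident); cannot fit a sphere")
  sol <- qr.coef(qrA, b)
  center <- sol[1:3]
  r2 <- sol[4] + sum(center^2)
  if (r2 <= 0) stop("degenerate sphere fit (non-positive squared radius)")
  radius <- sqrt(r2)
  # geometric refinement
  for (it in 1:50) {
    d <- sweep(P, 2, center)
    dist <- sqrt(rowSums(d^2))
    if (any(dist < 1e-12)) dist[dist < 1e-12] <- 1e-12
    r <- dist - radius
    J <- cbind(-d / dist, -1)          # d residual / d (center, radius)
    step <- tryCatch(qr.solve(J, -r), error = function(e) rep(0, 4))
    center <- center + step[1:3]
    radius <- radius + step[4]
    if (sqrt(sum(step^2)) < 1e-12) break
  }
  d <- sweep(P, 2, center)
  res <- sqrt(rowSums(d^2)) - radius
  structure(list(center = as.numeric(center), radius = radius,
                 rms_residual = sqrt(mean(res^2)), n_inliers = n),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("<sphere_fit> center (%.2f, %.2f, %.2f), radius %.2f mm, rms %.3f mm, n %d\n",
              x$center[1], x$center[2], x$center[3], x$radius,
              x$rms_residual, x$n_inliers))
  invisible(x)
}

#' Fit a sphere to an acetabular cup on a mesh
#'
#' Starting from a seed near the cup, vertices within `capture_radius` of
#' the seed are sphere-fitted; then vertices whose distance to the current
#' sphere surface is within `band * radius` are re-selected and re-fitted
#' until the center converges. The band rejects the acetabular rim and
#' other structures.
#'
#' @param mesh a [surface_mesh()].
#' @param seed approximate cup location (mm).
#' @param capture_radius initial capture radius around the seed (mm).
#' @param band inlier half-width as a fraction of the radius (default 0.1).
#' @param min_inliers abort threshold (default 50): below this the cup is
#'   considered not found.
#' @param max_rms_frac final quality gate: the converged rms residual must
#'   not exceed this fraction of the radius (default 0.03), otherwise the
#'   neighbourhood is declared not cup-like.
#' @return A [fit_sphere()] result (class `sphere_fit`).
#' @export
fit_acetabulum <- function(mesh, seed, capture_radius = 30, band = 0.1,
                           min_inliers = 50, max_rms_frac = 0.03) {
  stopifnot(inherits(mesh, "surface_mesh"))
  V <- mesh$vertices
  N <- mesh$normals
  # the fossa is the concave side: keep vertices whose outward normal faces
  # the current center estimate, rejecting the cup's convex outer wall
  facing <- function(center) rowSums(N * sweep(-V, 2, -center)) > 0
  d2 <- rowSums(sweep(V, 2, seed)^2)
  sel <- which(d2 <= capture_radius^2 & facing(seed))
  if (length(sel) < min_inliers)
    stop(sprintf("only %d vertices within %.0f mm of the seed; cup not found",
                 length(sel), capture_radius))
  fit <- fit_sphere(V[sel, , drop = FALSE])
  if (fit$radius > 4 * capture_radius)
    stop(sprintf(paste0("fitted radius %.0f mm is far beyond the capture ",
                        "radius; surface near the seed is not cup-like"),
                 fit$radius))
  for (it in 1:50) {
    dist <- sqrt(rowSums(sweep(V, 2, fit$center)^2))
    sel <- which(abs(dist - fit$radius) <= band * fit$radius &
                   facing(fit$center))
    if (length(sel) < min_inliers)
      stop(sprintf("inlier count fell to %d (< %d); cup not found",
                   length(sel), min_inliers))
    new_fit <- fit_sphere(V[sel, , drop = FALSE])
    moved <- vnorm(new_fit$center - fit$center)
    fit <- new_fit
    if (moved < 1e-6) break
  }
  if (fit$rms_residual > max_rms_frac * fit$radius)
    stop(sprintf(paste0("converged fit is not cup-like (rms %.2f mm at ",
                        "radius %.1f mm); cup not found"),
                 fit$rms_residual, fit$radius))
  fit
}

#' Hip axis from two acetabular sphere fits
#'
#' The arithmetic midpoint of the two sphere centers.
#'
#' @param left,right `sphere_fit` objects (or lists with a `center`).
#' @return 3-d point (mm).
#' @export
hip_axis <- function(left, right) {
  (as.numeric(left$center) + as.numeric(right$center)) / 2
}
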