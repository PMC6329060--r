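# Small 3-d vector / rigid-transform helpers shared across modules.
# Points are length-3 numeric vectors or n x 3 matrices, in millimetres.

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps * 1e3) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# angle between two vectors, degrees, robust to rounding at +-1
angle_between <- function(a, b) {
  ca <- sum(unitv(a) * unitv(b))
  rad2deg(acos(max(-1, min(1, ca))))
}

as_points <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
}

# rotation about a unit axis by angle in degrees (Rodrigues)
rotation_about_axis <- function(axis, angle_deg) {
  u <- unitv(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Create a rigid transform
#'
#' A rigid transform maps a point `x` to `rotation %*% x + translation`.
#' Used to express mesh alignment, phantom pose perturbations, and the
#' transforms returned by [align_to_app()].
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1; det -1 is
#'   accepted for reflections and flagged in the object).
#' @param translation length-3 numeric vector (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  dt <- det(rotation)
  if (abs(abs(dt) - 1) > 1e-6) stop("rotation matrix is not orthonormal")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 proper = dt > 0),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points length-3 vector or n x 3 matrix of points (mm).
#' @param vector logical; if `TRUE` the translation is omitted (for
#'   transforming directions/normals).
#' @return Transformed points with the same shape as the input.
#' @export
apply_rigid <- function(transform, points, vector = FALSE) {
  stopifnot(inherits(transform, "rigid_transform"))
  single <- is.null(dim(points))
  P <- as_points(points)
  out <- P %*% t(transform$rotation)
  if (!vector) out <- sweep(out, 2, transform$translation, `+`)
  if (single) as.numeric(out) else out
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
invert_rigid <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Compose two rigid transforms
#'
#' `compose_rigid(a, b)` applies `b` first, then `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return The composed `rigid_transform`.
#' @export
compose_rigid <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Draw a random rigid transform
#'
#' Uniform random rotation (via QR of a Gaussian matrix, sign-corrected)
#' plus a uniform translation. Used by the invariance tests.
#'
#' @param max_translation maximum absolute translation per axis (mm).
#' @return A [rigid_transform()].
#' @export
random_rigid_transform <- function(max_translation = 50) {
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  Q <- Q %*% diag(sign(d))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  rigid_transform(Q, stats::runif(3, -max_translation, max_translation))
}
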