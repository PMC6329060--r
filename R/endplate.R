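# Mid-sagittal plane (ICP symmetry), sacral-endplate point extraction,
# projection, orthogonal line fitting, and concavity-type classification.

#' Construct a plane
#'
#' @param point a 3-d point on the plane (mm).
#' @param normal plane normal (normalised internally).
#' @return An object of class `plane3`.
#' @export
plane3 <- function(point, normal) {
  structure(list(point = as.numeric(point), normal = unitv(normal)),
            class = "plane3")
}

#' @export
print.plane3 <- function(x, ...) {
  cat(sprintf("<plane3> point (%.2f, %.2f, %.2f), normal (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

plane_signed_distance <- function(plane, pts) {
  single <- is.null(dim(pts))
  d <- as.numeric(sweep(as_points(pts), 2, plane$point) %*% plane$normal)
  if (single) d[1] else d
}

mirror_points <- function(plane, pts) {
  d <- plane_signed_distance(plane, pts)
  as_points(pts) - 2 * outer(d, plane$normal)
}

#' Initial mid-sagittal plane from the pelvic frame
#'
#' Plane with normal along the left-right axis, through the midpoint of the
#' two ASISs; the starting point for the ICP symmetry refinement.
#'
#' @param frame a [pelvic_frame()].
#' @param asis_l,asis_r optional ASIS positions; when omitted the plane
#'   passes through the frame origin shifted onto the ASIS midpoint is not
#'   available, so the frame origin is used.
#' @return A [plane3()].
#' @export
initial_msp <- function(frame, asis_l = NULL, asis_r = NULL) {
  stopifnot(inherits(frame, "pelvic_frame"))
  pt <- if (!is.null(asis_l) && !is.null(asis_r)) (asis_l + asis_r) / 2
        else frame$origin
  plane3(pt, frame$lr)
}

#' Refine the mid-sagittal plane by ICP symmetry
#'
#' A fixed subsample of the vertices is mirrored across the current plane
#' and matched to its nearest original vertices (point-to-point ICP, no
#' trimming). The optimal improper rigid map from the subsample to its
#' matches is estimated by constrained Kabsch (det = -1); its -1
#' eigenvector is the refined symmetry normal and the translation fixes the
#' plane offset. Iterates until the plane moves by less than `tol`.
#'
#' @param mesh a [surface_mesh()].
#' @param initial a [plane3()] intersecting the mesh bounding box.
#' @param max_iter maximum iterations (default 30).
#' @param tol convergence threshold on the plane motion (mm at the mesh
#'   scale, default 1e-3).
#' @param subsample number of vertices in the fixed ICP subsample
#'   (default 5000; deterministic uniform stride).
#' @return A [plane3()] with the normal oriented like `initial`.
#' @export
refine_msp_icp <- function(mesh, initial, max_iter = 30, tol = 1e-3,
                           subsample = 5000) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(initial, "plane3"))
  V <- mesh$vertices
  bb <- apply(V, 2, range)
  corners <- as.matrix(expand.grid(bb[, 1], bb[, 2], bb[, 3]))
  dc <- plane_signed_distance(initial, corners)
  if (all(dc > 0) || all(dc < 0))
    stop("initial plane does not intersect the mesh bounding box")
  nv <- nrow(V)
  idx <- unique(round(seq(1, nv, length.out = min(subsample, nv))))
  X <- V[idx, , drop = FALSE]
  plane <- plane3(initial$point, initial$normal)
  best_mean <- Inf
  prev_mean <- Inf
  rising <- 0L
  for (it in seq_len(max_iter)) {
    Xm <- mirror_points(plane, X)
    nn <- .nn_match(V, Xm)
    Y <- V[nn$idx, , drop = FALSE]
    mean_d <- mean(nn$dist)
    # divergence = a sustained strict rise well above the best mean seen;
    # relaxation overshoot toward the fixed point is not divergence
    if (mean_d > prev_mean && mean_d > best_mean * 1.2 + 1e-6) {
      rising <- rising + 1L
      if (rising >= 3L)
        stop(sprintf(paste0("ICP diverged: mean closest-point distance rose ",
                            "for 3 iterations (%.3f mm at iteration %d)"),
                     mean_d, it))
    } else rising <- 0L
    prev_mean <- mean_d
    best_mean <- min(best_mean, mean_d)
    # optimal improper map X -> Y (reflection + residual rigid motion)
    cx <- colMeans(X)
    cy <- colMeans(Y)
    H <- crossprod(sweep(X, 2, cx), sweep(Y, 2, cy))
    sv <- svd(H)
    s3 <- det(sv$v %*% t(sv$u))          # sign making det(R) = +1
    D <- diag(c(1, 1, -s3))              # force det(R) = -1
    Rm <- sv$v %*% D %*% t(sv$u)
    tv <- cy - as.numeric(Rm %*% cx)
    ev <- eigen(Rm)
    k <- which.min(abs(ev$values + 1))
    normal <- Re(ev$vectors[, k])
    normal <- unitv(normal)
    if (sum(normal * plane$normal) < 0) normal <- -normal
    offset <- sum(normal * tv) / 2
    new_plane <- plane3(offset * normal, normal)
    # plane motion measured at the subsample centroid
    move <- abs(plane_signed_distance(new_plane, cx) -
                plane_signed_distance(plane, cx)) +
      vnorm(cross3(new_plane$normal, plane$normal)) * 100
    plane <- new_plane
    if (move < tol) break
  }
  if (sum(plane$normal * initial$normal) < 0)
    plane <- plane3(plane$point, -plane$normal)
  plane
}

#' Extract sacral-endplate surface points
#'
#' Region-grows over the mesh from the vertex nearest the seed, keeping
#' upward-facing vertices (normal within 45 degrees of the superior axis),
#' and adapts the growth radius until the point count falls inside
#' `[n_min, n_max]` (the operating window of the source method,
#' 5000-8000 points at ~1 mm resolution).
#'
#' @param mesh a [surface_mesh()].
#' @param seed a point within 10 mm of the endplate surface (mm).
#' @param frame a [pelvic_frame()] supplying the superior axis.
#' @param n_min,n_max target point-count window (defaults 5000 / 8000).
#' @param max_angle normal-to-superior threshold in degrees (default 45).
#' @param normal_smooth smoothing rounds applied to the normal field before
#'   the angle test (default 20); per-vertex normals on reconstructed
#'   surfaces carry voxel-staircase noise of tens of degrees, so the
#'   criterion is evaluated on the locally averaged surface direction.
#' @return An n x 3 matrix of endplate surface points (mesh vertices), with
#'   the filter normals in attribute `filter_normals`.
#' @export
extract_endplate_points <- function(mesh, seed, frame,
                                    n_min = 5000, n_max = 8000,
                                    max_angle = 45, normal_smooth = 20) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(frame, "pelvic_frame"))
  V <- mesh$vertices
  d2seed <- rowSums(sweep(V, 2, seed)^2)
  root <- which.min(d2seed)
  if (sqrt(d2seed[root]) > 10)
    stop(sprintf("seed is %.1f mm from the mesh (must be within 10 mm)",
                 sqrt(d2seed[root])))
  adjacency <- mesh_adjacency(mesh)
  normals <- mesh$normals
  for (it in seq_len(normal_smooth)) {
    normals <- as.matrix(adjacency$W %*% normals) / adjacency$deg
    len <- sqrt(rowSums(normals^2)); len[len == 0] <- 1
    normals <- normals / len
  }
  upward <- as.numeric(normals %*% frame$sup) > cos(deg2rad(max_angle))
  if (!upward[root]) {
    # move the root to the nearest upward-facing vertex
    cand <- which(upward)
    if (length(cand) == 0) stop("no upward-facing vertices near the seed")
    root <- cand[which.min(d2seed[cand])]
    if (sqrt(d2seed[root]) > 10)
      stop("no upward-facing vertex within 10 mm of the seed")
  }
  adj <- adjacency$W
  grow <- function(radius) {
    ok <- upward & (d2seed <= radius^2)
    if (!ok[root]) return(integer(0))
    reached <- logical(nrow(V))
    reached[root] <- TRUE
    frontier <- root
    while (length(frontier) > 0) {
      nb <- unique(adj@i[unlist(lapply(frontier, function(v)
        seq.int(adj@p[v] + 1L, length.out = adj@p[v + 1L] - adj@p[v])),
        use.names = FALSE)] + 1L)
      nb <- nb[ok[nb] & !reached[nb]]
      reached[nb] <- TRUE
      frontier <- nb
    }
    which(reached)
  }
  r_lo <- 2; r_hi <- 200
  # count at the upper radius bounds what is attainable at all
  max_set <- grow(r_hi)
  if (length(max_set) < n_min)
    stop(sprintf(paste0("only %d upward-facing connected vertices available ",
                        "(need >= %d); increase mesh resolution"),
                 length(max_set), n_min))
  result <- function(set) structure(V[set, , drop = FALSE],
                                    filter_normals = normals[set, , drop = FALSE])
  if (length(max_set) <= n_max) return(result(max_set))
  for (it in 1:60) {
    r <- (r_lo + r_hi) / 2
    set <- grow(r)
    n <- length(set)
    if (n >= n_min && n <= n_max) return(result(set))
    if (n < n_min) r_lo <- r else r_hi <- r
  }
  # fall back to the closest bracket end
  set <- grow(r_hi)
  if (length(set) >= n_min) return(result(set[head(order(d2seed[set]), n_max)]))
  stop("could not reach the requested endplate point-count window")
}

#' Project points onto a plane in frame coordinates
#'
#' Orthogonal projection onto `plane`, expressed as 2-d (anterior,
#' superior) coordinates: the frame's `ant` and `sup` axes are projected
#' into the plane and orthonormalised, with the plane point as 2-d origin.
#'
#' @param points n x 3 matrix (mm).
#' @param plane a [plane3()] (typically the mid-sagittal plane).
#' @param frame a [pelvic_frame()].
#' @return n x 2 matrix of in-plane (anterior, superior) coordinates, with
#'   the basis stored in attributes `basis` (3 x 2) and `origin3d`.
#' @export
project_to_plane <- function(points, plane, frame) {
  stopifnot(inherits(plane, "plane3"), inherits(frame, "pelvic_frame"))
  n <- plane$normal
  a <- frame$ant - sum(frame$ant * n) * n
  a <- unitv(a)
  s <- frame$sup - sum(frame$sup * n) * n - sum(frame$sup * a) * a
  s <- unitv(s)
  P <- as_points(points)
  rel <- sweep(P, 2, plane$point)
  out <- cbind(anterior = as.numeric(rel %*% a),
               superior = as.numeric(rel %*% s))
  attr(out, "basis") <- cbind(a, s)
  attr(out, "origin3d") <- plane$point
  out
}

#' Fit the sagittal endplate line segment
#'
#' Orthogonal (total) least squares: the line direction is the principal
#' axis of the centered 2-d points; the endpoints are the extreme
#' projections of the points onto the line; the midpoint is the mean of the
#' endpoints. The anterior end is the endpoint with the larger anterior
#' coordinate.
#'
#' @param points2d n x 2 matrix of in-plane (anterior, superior) points.
#' @param min_axis_ratio minimum sd ratio of the principal axes below which
#'   the cloud is rejected as isotropic (default 1.5).
#' @return An object of class `endplate_profile` with `points2d`,
#'   `line_dir`, `anterior_end`, `posterior_end`, `midpoint`, `n_points`.
#' @export
fit_endplate_line <- function(points2d, min_axis_ratio = 1.5) {
  P <- as.matrix(points2d)
  if (nrow(P) < 10) stop("need at least 10 points to fit the endplate line")
  ctr <- unname(colMeans(P))
  C <- sweep(P, 2, ctr)
  ev <- eigen(crossprod(C) / nrow(C), symmetric = TRUE)
  if (ev$values[1] <= 0 || sqrt(ev$values[1] / max(ev$values[2], 1e-300)) <
      min_axis_ratio)
    stop("point cloud has no line-like structure (principal-axis ratio < ",
         min_axis_ratio, ")")
  dir <- ev$vectors[, 1]
  if (dir[1] < 0) dir <- -dir          # anterior-positive by convention
  t <- as.numeric(C %*% dir)
  p_lo <- ctr + min(t) * dir
  p_hi <- ctr + max(t) * dir
  if (p_hi[1] >= p_lo[1]) {
    anterior_end <- p_hi; posterior_end <- p_lo
  } else {
    anterior_end <- p_lo; posterior_end <- p_hi
  }
  structure(list(points2d = P, line_dir = dir,
                 anterior_end = anterior_end, posterior_end = posterior_end,
                 midpoint = (anterior_end + posterior_end) / 2,
                 n_points = nrow(P)),
            class = "endplate_profile")
}

#' @export
print.endplate_profile <- function(x, ...) {
  cat(sprintf("<endplate_profile> %d points, dir (%.4f, %.4f)\n",
              x$n_points, x$line_dir[1], x$line_dir[2]))
  cat(sprintf("  anterior end (%.2f, %.2f), posterior end (%.2f, %.2f), midpoint (%.2f, %.2f)\n",
              x$anterior_end[1], x$anterior_end[2],
              x$posterior_end[1], x$posterior_end[2],
              x$midpoint[1], x$midpoint[2]))
  invisible(x)
}

#' Classify the sacral-endplate concavity type
#'
#' A quadratic is fitted to the signed orthogonal residuals along the line
#' parameter. A dish opening toward the anterior-superior side (positive
#' quadratic coefficient) with sag depth beyond the dead band is type 1
#' (concave anteriorly); the opposite curvature is type 2 (concave
#' posteriorly); anything within the dead band is flat.
#'
#' @param points2d n x 2 matrix of in-plane points (defaults to the
#'   profile's own points).
#' @param profile an [fit_endplate_line()] result.
#' @param dead_band flatness threshold on the sag depth (mm, default 0.5).
#' @return An object of class `endplate_type` with `label` (`"type1"`,
#'   `"type2"` or `"flat"`), `curvature_coeff` (1/mm) and `sag_depth` (mm,
#'   signed; positive = type-1 dish).
#' @export
classify_endplate <- function(points2d = profile$points2d, profile,
                              dead_band = 0.5) {
  stopifnot(inherits(profile, "endplate_profile"))
  P <- as.matrix(points2d)
  dir <- profile$line_dir
  perp <- c(-dir[2], dir[1])           # +90 deg: toward the superior side
  rel <- sweep(P, 2, profile$midpoint)
  t <- as.numeric(rel %*% dir)
  r <- as.numeric(rel %*% perp)
  fit <- lm(r ~ t + I(t^2))
  a <- coef(fit)[["I(t^2)"]]
  span <- diff(range(t))
  sag <- a * span^2 / 4                # extremal deviation from the chord
  label <- if (abs(sag) <= dead_band) "flat"
           else if (a > 0) "type1" else "type2"
  structure(list(label = label, curvature_coeff = a, sag_depth = sag,
                 dead_band = dead_band),
            class = "endplate_type")
}

#' @export
print.endplate_type <- function(x, ...) {
  cat(sprintf("<endplate_type> %s (curvature %.5f 1/mm, sag %.2f mm, dead band %.2f mm)\n",
              x$label, x$curvature_coeff, x$sag_depth, x$dead_band))
  invisible(x)
}
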