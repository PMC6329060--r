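# Anterior pelvic plane (APP): landmark refinement, anatomical frame
# construction, and realignment of the mesh so the APP is perpendicular to
# the horizontal plane (Lewinnek positioning, with both pubic tubercles
# collapsed to their midpoint as in the source method).

#' Construct a pelvic frame
#'
#' Orthonormal right-handed anatomical frame: `lr` (left-right), `ant`
#' (anterior, the APP normal), `sup` (superior), with origin at the
#' pubic-tubercle midpoint.
#'
#' @param origin 3-d point (mm).
#' @param lr,ant,sup unit axis vectors.
#' @return An object of class `pelvic_frame`.
#' @export
pelvic_frame <- function(origin, lr, ant, sup) {
  axes <- cbind(lr = lr, ant = ant, sup = sup)
  if (max(abs(crossprod(axes) - diag(3))) > 1e-9)
    stop("frame axes are not orthonormal")
  if (det(axes) < 0) stop("frame axes are not right-handed")
  structure(list(origin = as.numeric(origin), lr = as.numeric(lr),
                 ant = as.numeric(ant), sup = as.numeric(sup)),
            class = "pelvic_frame")
}

#' @export
print.pelvic_frame <- function(x, ...) {
  cat("<pelvic_frame>\n")
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  for (ax in c("lr", "ant", "sup"))
    cat(sprintf("  %-4s (%.4f, %.4f, %.4f)\n", ax,
                x[[ax]][1], x[[ax]][2], x[[ax]][3]))
  invisible(x)
}

#' Refine a landmark to the most ventral surface point
#'
#' Fixed-point iteration of "take the vertex with the largest anterior
#' coordinate among vertices within `radius` of the current estimate".
#' The anterior coordinate is non-decreasing and the vertex set finite, so
#' the iteration terminates. Ties are broken by the lowest vertex index.
#'
#' @param mesh a [surface_mesh()].
#' @param seed initial 3-d point (mm), within `radius` of the surface.
#' @param current_frame a [pelvic_frame()] supplying the anterior direction.
#' @param radius search radius (mm), default 10.
#' @return The refined 3-d landmark (a mesh vertex).
#' @export
refine_landmark_ventral <- function(mesh, seed, current_frame, radius = 10) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(current_frame, "pelvic_frame"))
  V <- mesh$vertices
  ant_coord <- as.numeric(V %*% current_frame$ant)
  est <- as.numeric(seed)
  prev_idx <- -1L
  for (it in seq_len(nrow(V) + 1L)) {
    d2 <- (V[, 1] - est[1])^2 + (V[, 2] - est[2])^2 + (V[, 3] - est[3])^2
    near <- which(d2 <= radius^2)
    if (length(near) == 0)
      stop(sprintf("no mesh vertices within %.1f mm of (%.1f, %.1f, %.1f)",
                   radius, est[1], est[2], est[3]))
    best <- near[which.max(ant_coord[near])]  # which.max: lowest index on ties
    if (best == prev_idx) break
    prev_idx <- best
    est <- V[best, ]
  }
  est
}

#' Build the anterior pelvic plane frame
#'
#' The APP is the plane through both ASISs and the pubic-tubercle midpoint.
#' `lr = unit(asis_l - asis_r)`; `ant` is the plane's unit normal oriented
#' ventrally (away from `centroid` when supplied, otherwise so that `sup`
#' points from the PT midpoint toward the ASIS midpoint); `sup` completes
#' the right-handed frame. The origin is the PT midpoint.
#'
#' @param asis_l,asis_r,pt_l,pt_r landmark positions (mm).
#' @param centroid optional mesh centroid used to orient `ant` ventrally.
#' @return A [pelvic_frame()].
#' @export
compute_app <- function(asis_l, asis_r, pt_l, pt_r, centroid = NULL) {
  if (isTRUE(all.equal(asis_l, asis_r))) stop("ASIS landmarks coincide")
  if (isTRUE(all.equal(pt_l, pt_r))) stop("PT landmarks coincide")
  origin <- (pt_l + pt_r) / 2
  lr <- unitv(asis_l - asis_r)
  a <- asis_l - origin
  b <- asis_r - origin
  n <- cross3(a, b)
  if (vnorm(n) < 1e-9 * max(vnorm(a), vnorm(b), 1))
    stop("ASISs and PT midpoint are collinear; APP is undefined")
  ant <- unitv(n)            # already perpendicular to lr (lr lies in the plane)
  up_hint <- (asis_l + asis_r) / 2 - origin
  orient_ok <- function(ant) {
    if (!is.null(centroid)) sum(ant * (origin - centroid)) > 0
    else sum(cross3(lr, ant) * up_hint) > 0
  }
  if (!orient_ok(ant)) ant <- -ant
  sup <- unitv(cross3(lr, ant))
  ant <- cross3(sup, lr)     # exact re-orthogonalisation
  pelvic_frame(origin, lr, ant, sup)
}

#' Realign a mesh to the anterior pelvic plane
#'
#' Rigidly moves the mesh so that `lr` lies along world x, `ant` along
#' world y and `sup` along world z (vertical), with the PT midpoint at the
#' origin — the APP (the x-z plane) is then perpendicular to the horizontal
#' x-y plane.
#'
#' @param mesh a [surface_mesh()].
#' @param frame a [pelvic_frame()].
#' @return A list with the aligned `mesh` and the `transform`
#'   (a [rigid_transform()]) that was applied.
#' @export
align_to_app <- function(mesh, frame) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(frame, "pelvic_frame"))
  Rm <- t(cbind(frame$lr, frame$ant, frame$sup))
  tr <- rigid_transform(Rm, -as.numeric(Rm %*% frame$origin))
  list(mesh = transform_mesh(mesh, tr), transform = tr)
}

# Iterated refinement: bootstrap the frame from the raw seeds, refine all
# four APP landmarks ventrally, rebuild the frame; repeat to convergence.
refine_app_landmarks <- function(mesh, landmarks, radius = 10,
                                 max_rounds = 5, tol = 1e-3) {
  centroid <- mesh_centroid(mesh)
  lm <- landmarks
  frame <- compute_app(lm[["ASIS_L"]], lm[["ASIS_R"]],
                       lm[["PT_L"]], lm[["PT_R"]], centroid = centroid)
  for (round in seq_len(max_rounds)) {
    new <- lm
    for (nm in c("ASIS_L", "ASIS_R", "PT_L", "PT_R"))
      new[[nm]] <- refine_landmark_ventral(mesh, lm[[nm]], frame, radius)
    shift <- max(vapply(c("ASIS_L", "ASIS_R", "PT_L", "PT_R"),
                        function(nm) vnorm(new[[nm]] - lm[[nm]]), 0))
    lm <- new
    frame <- compute_app(lm[["ASIS_L"]], lm[["ASIS_R"]],
                         lm[["PT_L"]], lm[["PT_R"]], centroid = centroid)
    if (shift < tol) break
  }
  list(landmarks = lm, frame = frame)
}

# ---- landmark file I/O -------------------------------------------------

LANDMARK_NAMES <- c("ASIS_L", "ASIS_R", "PT_L", "PT_R",
                    "acetab_seed_L", "acetab_seed_R", "endplate_seed")

#' Read or write a landmark/seed file
#'
#' JSON schema: an object mapping landmark names (`ASIS_L`, `ASIS_R`,
#' `PT_L`, `PT_R`, `acetab_seed_L`, `acetab_seed_R`, `endplate_seed`) to
#' `[x, y, z]` positions in mm, mesh/volume physical coordinates.
#'
#' @param path JSON file path.
#' @param landmarks named list (or matrix with named rows) of 3-d points.
#' @return `read_landmarks()` returns a named list of 3-d points;
#'   `write_landmarks()` returns `path` invisibly.
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(LANDMARK_NAMES, names(obj))
  if (length(missing) > 0)
    stop("landmark file is missing: ", paste(missing, collapse = ", "))
  lapply(obj[LANDMARK_NAMES], as.numeric)
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  if (is.matrix(landmarks))
    landmarks <- apply(landmarks, 1, identity, simplify = FALSE)
  jsonlite::write_json(landmarks, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

landmarks_from_truth <- function(truth) {
  apply(truth$landmarks, 1, identity, simplify = FALSE)
}
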