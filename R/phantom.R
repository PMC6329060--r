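# Parametric pelvis phantom with analytically known pelvic incidence.
#
# The phantom is a union of simple solids: two concentric-shell acetabular
# cups (the generative sphere of each cup is the ground-truth "femoral head"
# center), a rectangular sacral-endplate shell whose sagittal section is
# flat or a circular arc (signed concavity), spherical ASIS/PT landmark
# prominences whose most ventral point is exactly the landmark, and capsule
# struts that connect everything into one component. PI is induced by
# rotating the endplate patch about the left-right axis so that the angle
# between the patch perpendicular at its midpoint and the midpoint-to-hip-
# axis line equals pi_true in closed form.

#' Specify a pelvis phantom
#'
#' All geometry is in an anatomical frame: +x left, +y anterior, +z
#' superior, millimetres. Defaults give a pelvis-sized phantom with
#' `pi_true = 45` degrees and 24 mm cups at 0.98 x 0.98 x 1.00 mm spacing.
#'
#' @param pi_true ground-truth pelvic incidence, degrees, in (0, 90).
#' @param acetab_radius acetabular cup (generative sphere) radius, mm.
#' @param acetab_centers 2 x 3 matrix, rows `L` and `R`: cup centers (mm).
#' @param endplate_width,endplate_depth endplate patch extent (mm) along the
#'   left-right and sagittal directions.
#' @param endplate_concavity signed sagittal sag depth (mm): 0 flat,
#'   positive = dish opening anterior-superiorly (type 1), negative = hump
#'   (concave posteriorly, type 2).
#' @param endplate_midpoint 3-d point (mm): midpoint of the endplate patch.
#' @param asis,pt 2 x 3 matrices (rows `L`, `R`): ASIS and pubic-tubercle
#'   landmark positions (the apex of each prominence).
#' @param landmark_radius radius of the landmark prominences, mm.
#' @param shell_thickness wall thickness of cup and endplate shells, mm.
#' @param strut_radius radius of the connecting capsule struts, mm.
#' @param voxel_spacing length-3 voxel spacing, mm.
#' @param noise_sd additive Gaussian HU noise (sd), applied under `rng_seed`.
#' @param bone_hu,background_hu HU values inside/outside the solids.
#' @param rng_seed integer seed for the noise generator.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(pi_true = 45,
                         acetab_radius = 24,
                         acetab_centers = rbind(L = c(85, 0, 0),
                                                R = c(-85, 0, 0)),
                         endplate_width = 50,
                         endplate_depth = 35,
                         endplate_concavity = 0,
                         endplate_midpoint = c(0, -60, 104),
                         asis = rbind(L = c(115, 35, 5),
                                      R = c(-115, 35, 5)),
                         pt = rbind(L = c(25, 35, -65),
                                    R = c(-25, 35, -65)),
                         landmark_radius = 6,
                         shell_thickness = 4,
                         strut_radius = 5,
                         voxel_spacing = c(0.98, 0.98, 1.00),
                         noise_sd = 0,
                         bone_hu = 700,
                         background_hu = -1000,
                         rng_seed = 1L) {
  spec <- structure(list(
    pi_true = pi_true, acetab_radius = acetab_radius,
    acetab_centers = as.matrix(acetab_centers),
    endplate_width = endplate_width, endplate_depth = endplate_depth,
    endplate_concavity = endplate_concavity,
    endplate_midpoint = as.numeric(endplate_midpoint),
    asis = as.matrix(asis), pt = as.matrix(pt),
    landmark_radius = landmark_radius, shell_thickness = shell_thickness,
    strut_radius = strut_radius,
    voxel_spacing = as.numeric(voxel_spacing),
    noise_sd = noise_sd, bone_hu = bone_hu, background_hu = background_hu,
    rng_seed = as.integer(rng_seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (!(spec$pi_true > 0 && spec$pi_true < 90))
    stop("pi_true must lie in (0, 90) degrees")
  if (spec$acetab_radius <= 0) stop("acetab_radius must be positive")
  if (any(spec$voxel_spacing <= 0)) stop("voxel_spacing must be positive")
  if (2 * spec$acetab_radius / max(spec$voxel_spacing) < 5)
    stop("voxel spacing too coarse: a cup would span fewer than 5 voxels")
  tr <- phantom_truth(spec)
  # cups must not intrude into the endplate patch
  g <- phantom_geometry(spec)
  corners <- expand.grid(s = c(-1, 1) * spec$endplate_depth / 2,
                         u = c(-1, 1) * spec$endplate_width / 2,
                         w = c(-spec$shell_thickness - abs(spec$endplate_concavity),
                               abs(spec$endplate_concavity)))
  pts <- t(apply(corners, 1, function(r)
    tr$endplate_midpoint + r[["s"]] * g$e + r[["u"]] * g$u_lr + r[["w"]] * g$n_up))
  reach <- spec$acetab_radius + spec$shell_thickness + 1
  for (side in 1:2) {
    d <- sqrt(rowSums(sweep(pts, 2, spec$acetab_centers[side, ])^2))
    if (any(d < reach))
      stop("inconsistent spec: an acetabular cup overlaps the endplate patch")
  }
  err <- abs(pi_closed_form(tr) - spec$pi_true)
  if (err > 1e-9)
    stop("internal construction error: closed-form PI differs from pi_true by ",
         format(err), " degrees")
  invisible(spec)
}

# geometric scaffolding shared by truth, primitives and validation
phantom_geometry <- function(spec) {
  H <- colMeans(spec$acetab_centers)
  M <- spec$endplate_midpoint
  n_lr <- unitv(spec$acetab_centers["L", ] - spec$acetab_centers["R", ])
  v <- unitv(H - M)
  if (abs(sum(v * n_lr)) > 1e-9)
    stop("inconsistent spec: the hip axis must lie in the endplate's sagittal plane")
  # bootstrap anterior direction from the APP landmarks
  ptm <- colMeans(spec$pt)
  n_app <- cross3(spec$asis["L", ] - ptm, spec$asis["R", ] - ptm)
  app_centroid <- (spec$asis["L", ] + spec$asis["R", ] + ptm) / 3
  if (sum(n_app * (app_centroid - H)) < 0) n_app <- -n_app
  ant0 <- unitv(n_app)
  # rotate the midpoint-to-hip direction about the LR axis by pi_true;
  # the sign is fixed by requiring an anterior-facing endplate top normal
  pick <- NULL
  for (s in c(1, -1)) {
    n_hip <- as.numeric(rotation_about_axis(n_lr, -s * spec$pi_true) %*% v)
    if (sum(-n_hip * ant0) > 0) { pick <- n_hip; break }
  }
  if (is.null(pick)) pick <- as.numeric(
    rotation_about_axis(n_lr, -spec$pi_true) %*% v)
  n_hip <- unitv(pick)
  n_up <- -n_hip
  e <- cross3(n_lr, n_hip)
  if (sum(e * ant0) < 0) e <- -e
  e <- unitv(e)
  list(H = H, M = M, n_lr = n_lr, v = v, n_hip = n_hip, n_up = n_up, e = e,
       u_lr = n_lr, ant0 = ant0)
}

#' Ground truth of a phantom
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_truth` with the true PI, hip axis,
#'   endplate midpoint/direction, mid-sagittal-plane normal and the landmark
#'   table (ASIS L/R, PT L/R, acetabular seeds, endplate seed).
#' @export
phantom_truth <- function(spec) {
  g <- phantom_geometry(spec)
  # the endplate seed sits on the top surface (the chord midpoint lies off
  # the surface when the patch is curved)
  surf_seed <- g$M + endplate_sag(0, spec$endplate_depth,
                                  spec$endplate_concavity) * g$n_up
  landmarks <- rbind(ASIS_L = spec$asis["L", ], ASIS_R = spec$asis["R", ],
                     PT_L = spec$pt["L", ], PT_R = spec$pt["R", ],
                     acetab_seed_L = spec$acetab_centers["L", ],
                     acetab_seed_R = spec$acetab_centers["R", ],
                     endplate_seed = surf_seed)
  structure(list(pi_true = spec$pi_true, hip_axis = g$H,
                 endplate_midpoint = g$M, endplate_direction = g$e,
                 endplate_up = g$n_up, msp_normal = g$n_lr,
                 landmarks = landmarks),
            class = "phantom_truth")
}

#' Closed-form PI from truth fields
#'
#' Angle (degrees) between the endplate perpendicular at the midpoint
#' (in the sagittal plane, oriented toward the hip axis) and the line from
#' the endplate midpoint to the hip axis. Exact for any rigidly transformed
#' truth object.
#'
#' @param truth a [phantom_truth()], or any list with `endplate_midpoint`,
#'   `endplate_direction`, `msp_normal`, `hip_axis`.
#' @return PI in degrees.
#' @export
pi_closed_form <- function(truth) {
  v <- truth$hip_axis - truth$endplate_midpoint
  n <- cross3(truth$msp_normal, truth$endplate_direction)
  if (sum(n * v) < 0) n <- -n
  angle_between(n, v)
}

#' Rigidly transform a phantom truth object
#'
#' @param truth a [phantom_truth()].
#' @param transform a [rigid_transform()].
#' @return The transformed `phantom_truth`.
#' @export
transform_truth <- function(truth, transform) {
  tr <- truth
  tr$hip_axis <- apply_rigid(transform, truth$hip_axis)
  tr$endplate_midpoint <- apply_rigid(transform, truth$endplate_midpoint)
  tr$endplate_direction <- apply_rigid(transform, truth$endplate_direction,
                                       vector = TRUE)
  tr$endplate_up <- apply_rigid(transform, truth$endplate_up, vector = TRUE)
  tr$msp_normal <- apply_rigid(transform, truth$msp_normal, vector = TRUE)
  tr$landmarks <- apply_rigid(transform, truth$landmarks)
  rownames(tr$landmarks) <- rownames(truth$landmarks)
  tr
}

# sagittal top-surface height of the endplate patch: 0 when flat, a
# circular arc through (+-depth/2, 0) with extremum -concavity at s = 0
endplate_sag <- function(s, depth, concavity) {
  if (abs(concavity) < 1e-12) return(rep(0, length(s)))
  cmag <- abs(concavity)
  rho <- ((depth / 2)^2 + cmag^2) / (2 * cmag)
  arc <- sqrt(pmax(rho^2 - s^2, 0))
  if (concavity > 0) (rho - cmag) - arc else arc - (rho - cmag)
}

#' Primitive solids of a phantom
#'
#' Parameter table of the solids that make up the phantom (cup shells,
#' endplate shell, landmark balls, capsule struts), exposed so tests can
#' build independent geometry oracles.
#'
#' @param spec a [phantom_spec()].
#' @return A list of primitive descriptors, each a list with a `type`
#'   (`"shell"`, `"ball"`, `"capsule"`, `"endplate"`) and its parameters.
#' @export
phantom_primitives <- function(spec) {
  g <- phantom_geometry(spec)
  t <- spec$shell_thickness
  rs <- spec$strut_radius
  rb <- spec$landmark_radius
  cl <- spec$acetab_centers["L", ]
  cr <- spec$acetab_centers["R", ]
  ball_center <- function(apex) apex - rb * g$ant0
  seg_point <- function(p) { # closest point to p on the cup-to-cup axis
    d <- cr - cl
    tt <- max(0, min(1, sum((p - cl) * d) / sum(d * d)))
    cl + tt * d
  }
  prims <- list(
    list(type = "shell", center = cl, r_inner = spec$acetab_radius,
         r_outer = spec$acetab_radius + t),
    list(type = "shell", center = cr, r_inner = spec$acetab_radius,
         r_outer = spec$acetab_radius + t),
    list(type = "endplate", midpoint = g$M, e = g$e, u = g$u_lr, n = g$n_up,
         width = spec$endplate_width, depth = spec$endplate_depth,
         thickness = t, concavity = spec$endplate_concavity),
    list(type = "ball", center = ball_center(spec$asis["L", ]), r = rb),
    list(type = "ball", center = ball_center(spec$asis["R", ]), r = rb),
    list(type = "ball", center = ball_center(spec$pt["L", ]), r = rb),
    list(type = "ball", center = ball_center(spec$pt["R", ]), r = rb),
    list(type = "capsule", p1 = cl, p2 = cr, r = rs),
    list(type = "capsule", p1 = g$H,
         p2 = g$M - (0.75 * t + rs) * g$n_up, r = rs),
    list(type = "capsule", p1 = cl, p2 = ball_center(spec$asis["L", ]), r = rs),
    list(type = "capsule", p1 = cr, p2 = ball_center(spec$asis["R", ]), r = rs),
    list(type = "capsule", p1 = seg_point(spec$pt["L", ]),
         p2 = ball_center(spec$pt["L", ]), r = rs),
    list(type = "capsule", p1 = seg_point(spec$pt["R", ]),
         p2 = ball_center(spec$pt["R", ]), r = rs))
  prims
}

primitive_bbox <- function(p) {
  switch(p$type,
    shell = rbind(p$center - p$r_outer, p$center + p$r_outer),
    ball = rbind(p$center - p$r, p$center + p$r),
    capsule = rbind(pmin(p$p1, p$p2) - p$r, pmax(p$p1, p$p2) + p$r),
    endplate = {
      ext <- abs(p$e) * p$depth / 2 + abs(p$u) * p$width / 2 +
        abs(p$n) * (p$thickness + abs(p$concavity))
      pad <- abs(p$n) * abs(p$concavity) + 1e-9
      rbind(p$midpoint - ext - pad, p$midpoint + ext + pad)
    })
}

primitive_inside <- function(p, pts) {
  switch(p$type,
    shell = {
      d2 <- rowSums(sweep(pts, 2, p$center)^2)
      d2 >= p$r_inner^2 & d2 <= p$r_outer^2
    },
    ball = rowSums(sweep(pts, 2, p$center)^2) <= p$r^2,
    capsule = {
      d <- p$p2 - p$p1
      len2 <- sum(d * d)
      rel <- sweep(pts, 2, p$p1)
      tt <- pmin(pmax(as.numeric(rel %*% d) / len2, 0), 1)
      prox <- outer(tt, d)
      rowSums((rel - prox)^2) <= p$r^2
    },
    endplate = {
      rel <- sweep(pts, 2, p$midpoint)
      s <- as.numeric(rel %*% p$e)
      u <- as.numeric(rel %*% p$u)
      w <- as.numeric(rel %*% p$n)
      top <- endplate_sag(s, p$depth, p$concavity)
      abs(s) <= p$depth / 2 & abs(u) <= p$width / 2 &
        w <= top & w >= top - p$thickness
    })
}

#' Voxelize a phantom into a CT volume
#'
#' Signed-membership sampling at voxel centers (no anti-aliasing, for
#' determinism): `bone_hu` inside the solids, `background_hu` outside, plus
#' optional Gaussian HU noise generated under `rng_seed`.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (a [ct_volume()], identity
#'   orientation) and `truth` (a [phantom_truth()]).
#' @export
generate_phantom_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  prims <- phantom_primitives(spec)
  boxes <- lapply(prims, primitive_bbox)
  lo <- Reduce(pmin, lapply(boxes, function(b) b[1, ])) - 5
  hi <- Reduce(pmax, lapply(boxes, function(b) b[2, ])) + 5
  sp <- spec$voxel_spacing
  nd <- as.integer(ceiling((hi - lo) / sp)) + 1L
  vox <- array(spec$background_hu, dim = nd)
  xs <- lo[1] + sp[1] * (0:(nd[1] - 1))
  ys <- lo[2] + sp[2] * (0:(nd[2] - 1))
  zs <- lo[3] + sp[3] * (0:(nd[3] - 1))
  for (k in seq_along(prims)) {
    b <- boxes[[k]]
    ir <- which(xs >= b[1, 1] - sp[1] & xs <= b[2, 1] + sp[1])
    jr <- which(ys >= b[1, 2] - sp[2] & ys <= b[2, 2] + sp[2])
    kr <- which(zs >= b[1, 3] - sp[3] & zs <= b[2, 3] + sp[3])
    if (!length(ir) || !length(jr) || !length(kr)) next
    pts <- as.matrix(expand.grid(x = xs[ir], y = ys[jr], z = zs[kr]))
    inside <- primitive_inside(prims[[k]], pts)
    if (any(inside)) {
      sub <- vox[ir, jr, kr]
      sub[inside] <- spec$bone_hu
      vox[ir, jr, kr] <- sub
    }
  }
  if (spec$noise_sd > 0) {
    has_seed <- exists(".Random.seed", envir = globalenv())
    if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
    set.seed(spec$rng_seed)
    vox <- vox + array(rnorm(length(vox), 0, spec$noise_sd), dim = dim(vox))
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
  }
  list(volume = ct_volume(vox, spacing = sp, origin = lo),
       truth = phantom_truth(spec))
}

#' Generate a phantom surface mesh
#'
#' Voxelizes the (noise-free) phantom at `spec$voxel_spacing`, thresholds at
#' the bone/background midpoint, isosurfaces and applies minimal Taubin
#' smoothing — the same reconstruction chain the measurement pipeline uses,
#' so mesh-path and volume-path results are directly comparable.
#'
#' @param spec a [phantom_spec()].
#' @param smooth_iterations Taubin iterations (default 10).
#' @return A list with elements `mesh` (a [surface_mesh()]) and `truth`
#'   (a [phantom_truth()]).
#' @export
generate_phantom_mesh <- function(spec, smooth_iterations = 10) {
  stopifnot(inherits(spec, "phantom_spec"))
  clean <- spec
  clean$noise_sd <- 0
  gen <- generate_phantom_volume(clean)
  mask <- threshold_mask(gen$volume,
                         hu_low = (spec$bone_hu + spec$background_hu) / 2)
  mesh <- smooth_mesh(extract_isosurface(mask), iterations = smooth_iterations)
  list(mesh = mesh, truth = gen$truth)
}

#' Write a phantom truth sidecar as JSON
#'
#' @param truth a [phantom_truth()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(pi_true = truth$pi_true,
              hip_axis = truth$hip_axis,
              endplate_midpoint = truth$endplate_midpoint,
              endplate_direction = truth$endplate_direction,
              msp_normal = truth$msp_normal,
              landmarks = apply(truth$landmarks, 1, identity, simplify = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
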