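# The pelvic-incidence angle and the end-to-end measurement pipeline.

PI_PLAUSIBLE_RANGE <- c(30.49, 70.12)  # observed cohort range; a flag, not a constraint

#' Pipeline configuration
#'
#' All tunable parameters of [measure_pi_pipeline()] in one object, which is
#' serialized into the result for provenance.
#'
#' @param hu_low,hu_high segmentation HU window (defaults 200 / Inf).
#' @param removal_seeds optional list of physical points whose connected
#'   components are deleted after region growing (femur/vertebra removal).
#' @param seed_snap_radius tolerance (mm) for snapping segmentation seeds
#'   onto the mask (default 5).
#' @param smooth_iterations,smooth_lambda,smooth_mu Taubin smoothing
#'   parameters (defaults 10, 0.5, -0.53).
#' @param refine_radius landmark ventral-refinement radius (mm, default 10).
#' @param capture_radius,band,min_inliers acetabular fit parameters
#'   (defaults 30 mm, 0.1, 50).
#' @param msp_max_iter,msp_tol,msp_subsample ICP symmetry-plane parameters
#'   (defaults 30, 1e-3, 5000).
#' @param n_min,n_max endplate point-count window (defaults 5000 / 8000).
#' @param normal_max_angle endplate upward-normal threshold (degrees, 45).
#' @param dead_band endplate-type flatness threshold (mm, default 0.5).
#' @return A named list of class `pi_config`.
#' @export
pi_config <- function(hu_low = 200, hu_high = Inf,
                      removal_seeds = NULL,
                      seed_snap_radius = 5,
                      smooth_iterations = 10, smooth_lambda = 0.5,
                      smooth_mu = -0.53,
                      refine_radius = 10,
                      capture_radius = 30, band = 0.1, min_inliers = 50,
                      msp_max_iter = 30, msp_tol = 1e-3, msp_subsample = 5000,
                      n_min = 5000, n_max = 8000, normal_max_angle = 45,
                      dead_band = 0.5) {
  structure(list(hu_low = hu_low, hu_high = hu_high,
                 removal_seeds = removal_seeds,
                 seed_snap_radius = seed_snap_radius,
                 smooth_iterations = smooth_iterations,
                 smooth_lambda = smooth_lambda, smooth_mu = smooth_mu,
                 refine_radius = refine_radius,
                 capture_radius = capture_radius, band = band,
                 min_inliers = min_inliers,
                 msp_max_iter = msp_max_iter, msp_tol = msp_tol,
                 msp_subsample = msp_subsample,
                 n_min = n_min, n_max = n_max,
                 normal_max_angle = normal_max_angle,
                 dead_band = dead_band),
            class = "pi_config")
}

#' Compute the pelvic incidence angle
#'
#' The hip axis is projected onto the mid-sagittal plane; PI is the angle
#' between the in-plane perpendicular to the endplate line at its midpoint
#' (oriented toward the hip-axis side) and the unit vector from the
#' midpoint to the projected hip axis.
#'
#' @param profile an [fit_endplate_line()] result.
#' @param hip_axis 3-d hip-axis point (mm).
#' @param msp the mid-sagittal [plane3()].
#' @param frame a [pelvic_frame()].
#' @return PI in degrees, with attribute `hip_axis_2d`.
#' @export
compute_pi <- function(profile, hip_axis, msp, frame) {
  stopifnot(inherits(profile, "endplate_profile"))
  if (any(!is.finite(hip_axis))) stop("hip axis is not finite")
  h2 <- as.numeric(project_to_plane(matrix(hip_axis, 1), msp, frame))
  m <- profile$midpoint
  v <- h2 - m
  if (vnorm(v) < 1e-9) stop("hip axis coincides with the endplate midpoint")
  v <- v / vnorm(v)
  dir <- profile$line_dir
  perp <- c(-dir[2], dir[1])
  if (sum(perp * v) < 0) perp <- -perp
  pi_deg <- rad2deg(acos(max(-1, min(1, sum(perp * v)))))
  attr(pi_deg, "hip_axis_2d") <- h2
  pi_deg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Measure pelvic incidence end to end
#'
#' Runs segmentation (volume input only), surface reconstruction and
#' smoothing, APP landmark refinement and alignment, acetabular sphere
#' fitting, mid-sagittal-plane estimation, endplate extraction/projection/
#' line fitting and typing, and finally the PI angle. Deterministic for
#' fixed inputs and configuration.
#'
#' @param input a [ct_volume()], a [surface_mesh()], or a path to a volume
#'   (`.nii`/`.nii.gz`/`.nrrd`), mesh (`.ply`/`.stl`) or DICOM directory.
#' @param landmarks named list of seeds (see [read_landmarks()]), in the
#'   input's physical coordinates.
#' @param config a [pi_config()].
#' @return An object of class `pi_result`.
#' @export
measure_pi_pipeline <- function(input, landmarks, config = pi_config()) {
  if (is.character(input)) {
    input <- if (dir.exists(input)) read_dicom_series(input)
             else if (grepl("\\.(ply|stl)$", tolower(input))) read_mesh(input)
             else read_volume(input)
  }
  if (is.matrix(landmarks))
    landmarks <- apply(landmarks, 1, identity, simplify = FALSE)
  missing <- setdiff(LANDMARK_NAMES, names(landmarks))
  if (length(missing) > 0)
    stop("missing landmarks: ", paste(missing, collapse = ", "))
  diag_info <- list()

  if (inherits(input, "ct_volume")) {
    mask <- stage("segmentation", {
      m <- threshold_mask(input, config$hu_low, config$hu_high)
      m <- region_grow(m, landmarks$endplate_seed,
                       snap_radius = config$seed_snap_radius)
      for (rs in config$removal_seeds)
        m <- remove_component(m, rs, snap_radius = config$seed_snap_radius)
      m
    })
    diag_info$mask_voxels <- sum(mask$voxels)
    mesh <- stage("surface", {
      smooth_mesh(extract_isosurface(mask),
                  iterations = config$smooth_iterations,
                  lambda = config$smooth_lambda, mu = config$smooth_mu)
    })
  } else if (inherits(input, "surface_mesh")) {
    mesh <- input
  } else stop("input must be a ct_volume, surface_mesh, or file path")
  diag_info$n_vertices <- nrow(mesh$vertices)
  diag_info$n_faces <- nrow(mesh$faces)

  app <- stage("frame", refine_app_landmarks(mesh, landmarks,
                                             radius = config$refine_radius))
  aligned <- stage("frame", align_to_app(mesh, app$frame))
  mesh_a <- aligned$mesh
  tr <- aligned$transform
  lm_a <- lapply(landmarks, function(p) apply_rigid(tr, p))
  ref_a <- lapply(app$landmarks, function(p) apply_rigid(tr, p))
  frame_a <- pelvic_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))

  fit_l <- stage("hip", fit_acetabulum(mesh_a, lm_a$acetab_seed_L,
                                       capture_radius = config$capture_radius,
                                       band = config$band,
                                       min_inliers = config$min_inliers))
  fit_r <- stage("hip", fit_acetabulum(mesh_a, lm_a$acetab_seed_R,
                                       capture_radius = config$capture_radius,
                                       band = config$band,
                                       min_inliers = config$min_inliers))
  hip <- hip_axis(fit_l, fit_r)

  msp0 <- initial_msp(frame_a, ref_a$ASIS_L, ref_a$ASIS_R)
  msp <- stage("msp", refine_msp_icp(mesh_a, msp0,
                                     max_iter = config$msp_max_iter,
                                     tol = config$msp_tol,
                                     subsample = config$msp_subsample))
  ep_pts <- stage("endplate", extract_endplate_points(
    mesh_a, lm_a$endplate_seed, frame_a,
    n_min = config$n_min, n_max = config$n_max,
    max_angle = config$normal_max_angle))
  p2 <- project_to_plane(ep_pts, msp, frame_a)
  profile <- stage("endplate", fit_endplate_line(p2))
  ep_type <- classify_endplate(profile = profile, dead_band = config$dead_band)

  pi_deg <- stage("pi", compute_pi(profile, hip, msp, frame_a))
  flagged <- pi_deg < PI_PLAUSIBLE_RANGE[1] | pi_deg > PI_PLAUSIBLE_RANGE[2]

  structure(list(
    pi = as.numeric(pi_deg),
    plausible = !flagged,
    hip_axis = hip,
    hip_axis_2d = attr(pi_deg, "hip_axis_2d"),
    midpoint_2d = profile$midpoint,
    line_dir_2d = profile$line_dir,
    msp = msp,
    frame = app$frame,
    alignment = tr,
    sphere_fit_left = fit_l,
    sphere_fit_right = fit_r,
    endplate_type = ep_type,
    endplate_n_points = profile$n_points,
    profile = profile,
    diagnostics = diag_info,
    config = config),
    class = "pi_result")
}

#' @export
print.pi_result <- function(x, ...) {
  cat(sprintf("<pi_result> PI = %.2f degrees%s\n", x$pi,
              if (x$plausible) "" else
                sprintf("  [flagged: outside %.2f-%.2f]",
                        PI_PLAUSIBLE_RANGE[1], PI_PLAUSIBLE_RANGE[2])))
  cat(sprintf("  hip axis (%.2f, %.2f, %.2f) mm; endplate %s, %d points\n",
              x$hip_axis[1], x$hip_axis[2], x$hip_axis[3],
              x$endplate_type$label, x$endplate_n_points))
  cat(sprintf("  sphere radii %.2f / %.2f mm (rms %.3f / %.3f mm)\n",
              x$sphere_fit_left$radius, x$sphere_fit_right$radius,
              x$sphere_fit_left$rms_residual, x$sphere_fit_right$rms_residual))
  invisible(x)
}

#' Serialize a PI result to JSON
#'
#' Deterministic JSON rendering of the result (schema version 1): repeated
#' runs on identical input and configuration produce bit-identical output.
#'
#' @param result a `pi_result`.
#' @param path optional output path; when omitted the JSON string is
#'   returned.
#' @return The JSON string (invisibly when `path` is given).
#' @export
pi_result_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "pi_result"))
  obj <- list(
    schema = "pelvinc/pi_result/v1",
    pi_deg = result$pi,
    plausible = result$plausible,
    hip_axis_mm = result$hip_axis,
    hip_axis_2d_mm = result$hip_axis_2d,
    endplate_midpoint_2d_mm = as.numeric(result$midpoint_2d),
    endplate_line_dir = as.numeric(result$line_dir_2d),
    endplate_n_points = result$endplate_n_points,
    endplate_type = result$endplate_type$label,
    endplate_sag_depth_mm = result$endplate_type$sag_depth,
    msp = list(point = result$msp$point, normal = result$msp$normal),
    sphere_left = list(center = result$sphere_fit_left$center,
                       radius = result$sphere_fit_left$radius,
                       rms = result$sphere_fit_left$rms_residual,
                       n = result$sphere_fit_left$n_inliers),
    sphere_right = list(center = result$sphere_fit_right$center,
                        radius = result$sphere_fit_right$radius,
                        rms = result$sphere_fit_right$rms_residual,
                        n = result$sphere_fit_right$n_inliers),
    diagnostics = result$diagnostics,
    config = unclass(result$config))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}
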