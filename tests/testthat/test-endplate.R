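aligned_small_phantom <- function(concavity = 0) {
  key <- paste0("aligned_small_", concavity)
  cached(key, {
    spec <- small_spec(endplate_concavity = concavity)
    bundle <- generate_phantom_mesh(spec)
    app <- pelvinc:::refine_app_landmarks(bundle$mesh,
                                          truth_landmark_list(bundle$truth))
    al <- align_to_app(bundle$mesh, app$frame)
    list(spec = spec, mesh = al$mesh, transform = al$transform,
         truth = pelvinc:::transform_truth(bundle$truth, al$transform),
         refined = lapply(app$landmarks, function(p)
           apply_rigid(al$transform, p)))
  })
}

test_that("initial_msp builds the LR-normal plane through the ASIS midpoint", {
  fr <- identity_frame()
  pl <- initial_msp(fr, c(10, 2, 3), c(-4, 2, 3))
  expect_equal(pl$normal, c(1, 0, 0))
  expect_equal(pl$point, c(3, 2, 3))
  # equivariance: a rotated frame gives the rotated plane
  Rm <- pelvinc:::rotation_about_axis(c(0, 1, 1), 25)
  fr2 <- pelvic_frame(c(0, 0, 0), as.numeric(Rm[, 1]), as.numeric(Rm[, 2]),
                      as.numeric(Rm[, 3]))
  pl2 <- initial_msp(fr2)
  expect_equal(pl2$normal, as.numeric(Rm[, 1]), tolerance = 1e-12)
})

test_that("ICP refinement is a fixed point at the true symmetry plane", {
  ph <- aligned_small_phantom()
  true_plane <- plane3(ph$truth$endplate_midpoint, ph$truth$msp_normal)
  out <- refine_msp_icp(ph$mesh, true_plane, subsample = 3000)
  expect_lt(acos(min(1, abs(sum(out$normal * true_plane$normal)))) * 180 / pi,
            0.05)
  expect_lt(abs(pelvinc:::plane_signed_distance(out, ph$truth$hip_axis)), 0.3)
})

test_that("ICP recovers a 5-degree initial tilt on the symmetric phantom", {
  ph <- aligned_small_phantom()
  tilt <- pelvinc:::rotation_about_axis(c(0, 0.4, 1), 5)
  init <- plane3(ph$truth$endplate_midpoint + c(2, 0, 0),
                 as.numeric(tilt %*% ph$truth$msp_normal))
  out <- refine_msp_icp(ph$mesh, init, subsample = 3000)
  expect_lt(acos(min(1, abs(sum(out$normal * ph$truth$msp_normal)))) *
              180 / pi, 0.25)
  expect_lt(abs(pelvinc:::plane_signed_distance(out, ph$truth$hip_axis)), 0.5)
  expect_error(refine_msp_icp(ph$mesh, plane3(c(1e4, 0, 0), c(1, 0, 0))),
               "does not intersect")
})

test_that("an asymmetric perturbation moves the plane less than itself", {
  ph <- aligned_small_phantom()
  base <- refine_msp_icp(ph$mesh,
                         plane3(ph$truth$endplate_midpoint,
                                ph$truth$msp_normal), subsample = 3000)
  # shift the left cup's vertices 2 mm laterally (mesh surgery)
  V <- ph$mesh$vertices
  ctr <- ph$truth$landmarks["acetab_seed_L", ]
  sel <- rowSums(sweep(V, 2, ctr)^2) < (ph$spec$acetab_radius +
                                          ph$spec$shell_thickness + 2)^2
  V[sel, 1] <- V[sel, 1] + 2
  pert_mesh <- surface_mesh(V, ph$mesh$faces)
  pert <- refine_msp_icp(pert_mesh,
                         plane3(ph$truth$endplate_midpoint,
                                ph$truth$msp_normal), subsample = 3000)
  shift <- abs(pelvinc:::plane_signed_distance(pert, ph$truth$hip_axis) -
                 pelvinc:::plane_signed_distance(base, ph$truth$hip_axis))
  expect_lt(shift, 2)
  expect_gt(shift, 0)
})

test_that("endplate extraction respects the count window and the filter", {
  ph <- aligned_small_phantom()
  fr <- identity_frame()
  seed <- ph$truth$landmarks["endplate_seed", ]
  pts <- extract_endplate_points(ph$mesh, seed, fr, n_min = 800, n_max = 2000)
  expect_gte(nrow(pts), 800)
  expect_lte(nrow(pts), 2000)
  # filter postcondition on the (smoothed) filter normals
  fn <- attr(pts, "filter_normals")
  expect_true(all(fn %*% fr$sup > cos(pi / 4)))
  # every returned point lies on the generative patch (within 1 voxel)
  rel <- sweep(pts, 2, ph$truth$endplate_midpoint)
  w <- as.numeric(rel %*% ph$truth$endplate_up)
  s <- as.numeric(rel %*% ph$truth$endplate_direction)
  u <- as.numeric(rel %*% ph$truth$msp_normal)
  vox <- max(ph$spec$voxel_spacing)
  expect_true(all(abs(w) <= vox))
  expect_true(all(abs(s) <= ph$spec$endplate_depth / 2 + vox))
  expect_true(all(abs(u) <= ph$spec$endplate_width / 2 + vox))
  # unreachable window errors with a remediation hint
  expect_error(extract_endplate_points(ph$mesh, seed, fr,
                                       n_min = 5e5, n_max = 6e5),
               "resolution")
  expect_error(extract_endplate_points(ph$mesh, seed + c(0, 0, 50), fr),
               "within 10 mm")
})

test_that("projection is an in-plane isometry with zero lifted residual", {
  fr <- identity_frame()
  pl <- plane3(c(0, 1, 2), pelvinc:::unitv(c(1, 0.2, -0.1)))
  set.seed(31)
  pts <- matrix(rnorm(90, sd = 30), ncol = 3)
  p2 <- project_to_plane(pts, pl, fr)
  basis <- attr(p2, "basis")
  lifted <- sweep(p2 %*% t(basis), 2, pl$point, `+`)
  expect_lt(max(abs(pelvinc:::plane_signed_distance(pl, lifted))), 1e-9)
  # points already in the plane: distances preserved exactly
  inplane <- lifted[1:10, ]
  q2 <- project_to_plane(inplane, pl, fr)
  d3 <- as.matrix(dist(inplane))
  d2 <- as.matrix(dist(q2))
  expect_equal(d2, d3, tolerance = 1e-9)
  # a symmetric point pair projects identically
  pair <- rbind(pl$point + 5 * pl$normal, pl$point - 5 * pl$normal)
  pp <- project_to_plane(pair, pl, fr)
  expect_equal(pp[1, ], pp[2, ], tolerance = 1e-12)
})

test_that("orthogonal line fit matches exact lines and beats OLS residuals", {
  a <- seq(-20, 20, length.out = 60)
  exact <- cbind(anterior = a, superior = 0.2 * a + 3)
  prof <- fit_endplate_line(exact)
  expect_equal(prof$line_dir, c(1, 0.2) / sqrt(1.04), tolerance = 1e-9)
  expect_equal(prof$midpoint, c(0, 3), tolerance = 1e-9)
  expect_equal(prof$midpoint, (prof$anterior_end + prof$posterior_end) / 2,
               tolerance = 1e-12)
  expect_gt(prof$anterior_end[1], prof$posterior_end[1])
  # orthogonal residuals <= vertical residuals of ordinary regression
  set.seed(8)
  noisy <- exact + matrix(rnorm(120, 0, 0.8), ncol = 2)
  pr <- fit_endplate_line(noisy)
  perp <- c(-pr$line_dir[2], pr$line_dir[1])
  orth_ss <- sum((sweep(noisy, 2, pr$midpoint) %*% perp)^2)
  ols <- lm(noisy[, 2] ~ noisy[, 1])
  expect_lte(orth_ss, sum(residuals(ols)^2))
  # degenerate inputs
  expect_error(fit_endplate_line(noisy[1:5, ]), "at least 10")
  set.seed(9)
  iso <- matrix(rnorm(200), ncol = 2)
  expect_error(fit_endplate_line(iso), "line-like")
})

test_that("classification follows the signed curvature with a dead band", {
  t <- seq(-17, 17, length.out = 400)
  mk <- function(sag) {
    pts <- cbind(anterior = t, superior = sag * ((t / 17)^2 - 1))
    prof <- fit_endplate_line(pts)
    classify_endplate(profile = prof)
  }
  expect_equal(mk(3)$label, "type1")       # dish opening upward
  expect_equal(mk(-3)$label, "type2")      # hump
  expect_equal(mk(0.1)$label, "flat")      # inside the dead band
  expect_equal(mk(3)$sag_depth, 3, tolerance = 0.1)
  expect_equal(mk(-3)$sag_depth, -3, tolerance = 0.1)
})

test_that("phantom endplate line tilt matches the constructed tilt", {
  ph <- aligned_small_phantom()
  fr <- identity_frame()
  pts <- extract_endplate_points(ph$mesh, ph$truth$landmarks["endplate_seed", ],
                                 fr, n_min = 800, n_max = 2000)
  msp <- refine_msp_icp(ph$mesh, initial_msp(fr, ph$refined$ASIS_L,
                                             ph$refined$ASIS_R),
                        subsample = 3000)
  prof <- fit_endplate_line(project_to_plane(pts, msp, fr))
  tilt <- atan2(abs(prof$line_dir[2]), abs(prof$line_dir[1])) * 180 / pi
  e <- ph$truth$endplate_direction
  true_tilt <- atan2(abs(e[3]), abs(e[2])) * 180 / pi
  expect_lt(abs(tilt - true_tilt), 0.5)
})
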