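# frame whose anterior axis is +z (for height-field fixtures)
zup_frame <- function() pelvic_frame(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1),
                                     c(0, -1, 0))

test_that("ventral refinement climbs to the bump apex (global-max oracle)", {
  xs <- seq(-15, 15, by = 1)
  # plane at z = 0 with a spherical cap peaking at z = 3 over the origin
  f <- function(x, y) ifelse(x^2 + y^2 <= 39,
                             sqrt(pmax(64 - x^2 - y^2, 0)) - 5, 0)
  mesh <- heightfield_mesh(xs, xs, f)
  frame <- zup_frame()
  apex_oracle <- mesh$vertices[which.max(mesh$vertices[, 3]), ]
  for (seed in list(c(3, 2, 1), c(-4, 1, 0.5), apex_oracle)) {
    est <- refine_landmark_ventral(mesh, seed, frame, radius = 10)
    expect_equal(est, apex_oracle, tolerance = 1e-12)
  }
  expect_error(refine_landmark_ventral(mesh, c(100, 100, 0), frame, 10),
               "no mesh vertices")
})

test_that("equal-height apexes tie-break to the lowest vertex index", {
  V <- rbind(c(0, 0, 0), c(1, 0, 5), c(2, 0, 5), c(3, 0, 0), c(1.5, 2, 0))
  F <- rbind(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5), c(1, 5, 4))
  mesh <- surface_mesh(V, F)
  est <- refine_landmark_ventral(mesh, c(1.5, 0, 4), zup_frame(), radius = 5)
  expect_equal(est, V[2, ])   # index 2 beats equal-height index 3
})

test_that("compute_app builds the documented axis-aligned frame", {
  fr <- compute_app(asis_l = c(120, 0, 0), asis_r = c(-120, 0, 0),
                    pt_l = c(20, 0, -100), pt_r = c(-20, 0, -100),
                    centroid = c(0, -50, -40))
  expect_equal(fr$lr, c(1, 0, 0))
  expect_equal(fr$ant, c(0, 1, 0))
  expect_equal(fr$sup, c(0, 0, 1))
  expect_equal(fr$origin, c(0, 0, -100))
})

test_that("compute_app is equivariant under rigid transforms", {
  set.seed(12)
  lm <- list(al = c(120, 0, 5), ar = c(-120, 0, 5),
             pl = c(20, 2, -95), pr = c(-20, 2, -95))
  fr0 <- compute_app(lm$al, lm$ar, lm$pl, lm$pr, centroid = c(0, -60, -30))
  for (rep in 1:5) {
    tr <- random_rigid_transform()
    fr1 <- compute_app(apply_rigid(tr, lm$al), apply_rigid(tr, lm$ar),
                       apply_rigid(tr, lm$pl), apply_rigid(tr, lm$pr),
                       centroid = apply_rigid(tr, c(0, -60, -30)))
    for (ax in c("lr", "ant", "sup"))
      expect_equal(fr1[[ax]], apply_rigid(tr, fr0[[ax]], vector = TRUE),
                   tolerance = 1e-9)
    expect_equal(fr1$origin, apply_rigid(tr, fr0$origin), tolerance = 1e-9)
  }
})

test_that("phantom truth landmarks reproduce the constructed frame", {
  tr <- phantom_truth(phantom_spec())
  fr <- compute_app(tr$landmarks["ASIS_L", ], tr$landmarks["ASIS_R", ],
                    tr$landmarks["PT_L", ], tr$landmarks["PT_R", ],
                    centroid = tr$hip_axis)
  expect_lt(acos(min(1, sum(fr$sup * c(0, 0, 1)))), 1e-6)   # radians
  expect_lt(acos(min(1, sum(fr$ant * c(0, 1, 0)))), 1e-6)
})

test_that("degenerate landmark configurations are rejected", {
  expect_error(compute_app(c(1, 0, 0), c(1, 0, 0), c(0, 0, -1), c(0, 0, 1)),
               "coincide")
  expect_error(compute_app(c(2, 0, 0), c(-2, 0, 0), c(1, 0, 0), c(-1, 0, 0)),
               "collinear")
})

test_that("align_to_app maps the frame onto the world basis", {
  lm <- list(al = c(120, 10, 5), ar = c(-120, 10, 5),
             pl = c(20, 12, -95), pr = c(-20, 12, -95))
  tr0 <- rigid_transform(pelvinc:::rotation_about_axis(c(2, 1, 1), 40),
                         c(30, -20, 10))
  lmt <- lapply(lm, function(p) apply_rigid(tr0, p))
  fr <- compute_app(lmt$al, lmt$ar, lmt$pl, lmt$pr,
                    centroid = apply_rigid(tr0, c(0, -60, -30)))
  mesh <- surface_mesh(rbind(lmt$al, lmt$ar, lmt$pl, lmt$pr),
                       rbind(c(1, 2, 3), c(2, 3, 4)))
  out <- align_to_app(mesh, fr)
  # ASISs end up at y = 0 with equal z; PT midpoint at the origin
  A <- out$mesh$vertices
  expect_equal(A[1, 2], 0, tolerance = 1e-9)
  expect_equal(A[2, 2], 0, tolerance = 1e-9)
  expect_equal(A[1, 3], A[2, 3], tolerance = 1e-9)
  expect_equal((A[3, ] + A[4, ]) / 2, c(0, 0, 0), tolerance = 1e-9)
  # applying the transform to the frame axes yields the world basis
  expect_equal(apply_rigid(out$transform, fr$lr, vector = TRUE), c(1, 0, 0),
               tolerance = 1e-9)
  expect_equal(apply_rigid(out$transform, fr$sup, vector = TRUE), c(0, 0, 1),
               tolerance = 1e-9)
})

test_that("landmark JSON files round-trip and validate", {
  lm <- truth_landmark_list(phantom_truth(small_spec()))
  path <- withr::local_tempfile(fileext = ".json")
  write_landmarks(lm, path)
  back <- read_landmarks(path)
  expect_equal(back, lm, tolerance = 1e-12)
  bad <- lm; bad$ASIS_L <- NULL
  path2 <- withr::local_tempfile(fileext = ".json")
  write_landmarks(bad, path2)
  expect_error(read_landmarks(path2), "ASIS_L")
})
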