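test_that("closed-form PI equals pi_true across angles and concavities", {
  for (p in c(20, 35, 45, 53, 65, 80)) {
    for (cc in c(-5, -3, 0, 3, 5)) {
      tr <- phantom_truth(phantom_spec(pi_true = p, endplate_concavity = cc))
      expect_lt(abs(pi_closed_form(tr) - p), 1e-9)
      # truth invariants
      expect_lt(abs(sum(tr$msp_normal * tr$endplate_direction)), 1e-12)
      expect_lt(abs(sum((tr$hip_axis - tr$endplate_midpoint) * tr$msp_normal)),
                1e-9)
    }
  }
})

test_that("closed-form PI is invariant under rigid transforms", {
  set.seed(7)
  tr <- phantom_truth(phantom_spec(pi_true = 53))
  for (rep in 1:5) {
    rt <- random_rigid_transform()
    expect_lt(abs(pi_closed_form(transform_truth(tr, rt)) - 53), 1e-9)
  }
})

test_that("inconsistent or under-resolved specs are rejected", {
  expect_error(phantom_spec(pi_true = 0), "pi_true")
  expect_error(phantom_spec(pi_true = 95), "pi_true")
  expect_error(phantom_spec(voxel_spacing = c(12, 12, 12)), "5 voxels")
  # cup placed into the endplate patch
  expect_error(phantom_spec(endplate_midpoint = c(0, -60, 104),
                            acetab_centers = rbind(L = c(10, -60, 100),
                                                   R = c(-10, -60, 100))),
               "overlap")
})

test_that("volume generation is deterministic and noise has the stated sd", {
  spec <- small_spec(noise_sd = 20, rng_seed = 42)
  v1 <- generate_phantom_volume(spec)$volume
  v2 <- generate_phantom_volume(spec)$volume
  expect_identical(v1$voxels, v2$voxels)
  clean <- generate_phantom_volume(small_spec())$volume
  noise <- v1$voxels - clean$voxels
  expect_lt(abs(sd(noise) - 20) / 20, 0.05)      # sample-sd oracle
})

test_that("thresholded mask volume matches a Monte-Carlo union oracle", {
  spec <- small_spec()
  prims <- phantom_primitives(spec)
  gen <- small_volume_bundle()
  mask <- threshold_mask(gen$volume, hu_low = 200, hu_high = 3000)
  vol_measured <- sum(mask$voxels) * prod(spec$voxel_spacing)
  # MC estimate of the union volume with independently re-derived membership
  boxes <- lapply(prims, pelvinc:::primitive_bbox)
  lo <- Reduce(pmin, lapply(boxes, function(b) b[1, ]))
  hi <- Reduce(pmax, lapply(boxes, function(b) b[2, ]))
  set.seed(2024)
  n <- 4e5
  pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
               runif(n, lo[3], hi[3]))
  vol_oracle <- mean(oracle_inside_any(prims, pts)) * prod(hi - lo)
  expect_lt(abs(vol_measured - vol_oracle) / vol_oracle, 0.05)
})

test_that("isosurfacing the thresholded phantom recovers the cup radius", {
  spec <- small_spec()
  gen <- small_volume_bundle()
  mask <- threshold_mask(gen$volume,
                         hu_low = (spec$bone_hu + spec$background_hu) / 2)
  mesh <- extract_isosurface(mask)
  ctr <- spec$acetab_centers["L", ]
  d <- sqrt(rowSums(sweep(mesh$vertices, 2, ctr)^2))
  inner <- mesh$vertices[abs(d - spec$acetab_radius) < spec$shell_thickness / 2, ]
  fit <- fit_sphere(inner)
  expect_lt(abs(fit$radius - spec$acetab_radius), max(spec$voxel_spacing))
  expect_lt(sqrt(sum((fit$center - ctr)^2)), max(spec$voxel_spacing))
})

test_that("concave phantom endplate has the expected quadratic curvature", {
  # independent oracle: direct quadratic regression on patch-top vertices
  spec <- small_spec(pi_true = 53, endplate_concavity = -3)
  bundle <- cached("small_concave_mesh", generate_phantom_mesh(spec))
  tr <- bundle$truth
  rel <- sweep(bundle$mesh$vertices, 2, tr$endplate_midpoint)
  s <- as.numeric(rel %*% tr$endplate_direction)
  u <- as.numeric(rel %*% tr$msp_normal)
  w <- as.numeric(rel %*% tr$endplate_up)
  top <- abs(s) < spec$endplate_depth / 2 - 2 &
    abs(u) < spec$endplate_width / 2 - 2 & w > 0.5 & w < abs(spec$endplate_concavity) + 2
  expect_gt(sum(top), 100)
  quad <- lm(w[top] ~ s[top] + I(s[top]^2))
  expect_lt(coef(quad)[[3]], 0)   # hump: negative (posterior-concave) sign
})

test_that("the symmetric phantom's hip axis lies in the mid-sagittal plane", {
  tr <- phantom_truth(phantom_spec())
  msp_dist <- sum((tr$hip_axis - tr$endplate_midpoint) * tr$msp_normal)
  expect_equal(msp_dist, 0, tolerance = 1e-12)
})

test_that("truth sidecar JSON round-trips the key fields", {
  tr <- phantom_truth(small_spec())
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(tr, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$pi_true, tr$pi_true)
  expect_equal(as.numeric(back$hip_axis), tr$hip_axis, tolerance = 1e-12)
  expect_equal(as.numeric(back$landmarks$ASIS_L),
               unname(tr$landmarks["ASIS_L", ]), tolerance = 1e-12)
})
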