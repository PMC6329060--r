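voxel_sphere_mask <- function(r = 25, spacing = c(1, 1, 1), pad = 3) {
  half <- ceiling(r / spacing) + pad
  d <- 2 * half + 1
  ctr_idx <- half
  g <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  pts <- sweep(g %*% diag(spacing), 2, ctr_idx * spacing)
  arr <- array(rowSums(pts^2) <= r^2, dim = d)
  vol <- ct_volume(array(as.numeric(arr) * 1700 - 1000, dim = d),
                   spacing = spacing)
  list(mask = threshold_mask(vol, 0), center = ctr_idx * spacing)
}

test_that("isosurface of a voxelized sphere has the right radius", {
  vs <- voxel_sphere_mask(25, c(1, 1, 1))
  mesh <- extract_isosurface(vs$mask)
  d <- sqrt(rowSums(sweep(mesh$vertices, 2, vs$center)^2))
  expect_gt(mean(d), 24)
  expect_lt(mean(d), 26)
  # watertight: every edge shared by exactly two faces
  F <- mesh$faces
  edges <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_true(all(table(key) == 2))
  # outward normals: positive dot with the radial direction
  rad <- sweep(mesh$vertices, 2, vs$center)
  expect_gt(mean(rowSums(mesh$normals * rad) > 0), 0.99)
})

test_that("anisotropic spacing still yields a spherical surface", {
  vs <- voxel_sphere_mask(25, c(0.98, 0.98, 2.0))
  mesh <- extract_isosurface(vs$mask)
  d <- sqrt(rowSums(sweep(mesh$vertices, 2, vs$center)^2))
  expect_lt(sd(d), sqrt(sum(c(0.98, 0.98, 2.0)^2)))  # < 1 voxel diagonal
})

test_that("a single-voxel mask produces a closed surface with area", {
  arr <- array(FALSE, c(3, 3, 3)); arr[2, 2, 2] <- TRUE
  vol <- ct_volume(array(as.numeric(arr), c(3, 3, 3)), spacing = c(1, 1, 1))
  mesh <- extract_isosurface(threshold_mask(vol, 0.5))
  areas <- sqrt(rowSums(pelvinc:::face_normals_area(mesh)^2)) / 2
  expect_gt(sum(areas), 0)
  F <- mesh$faces
  edges <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_true(all(table(key) == 2))
  expect_error(extract_isosurface(threshold_mask(vol, 2)), "empty")
})

test_that("isosurface commutes with rigid changes of the mask geometry", {
  vs <- voxel_sphere_mask(8, c(1, 1, 1))
  mesh0 <- extract_isosurface(vs$mask)
  Rm <- pelvinc:::rotation_about_axis(c(1, 1, 0), 33)
  shifted <- binary_mask(vs$mask$voxels,
                         ct_volume(array(0, dim(vs$mask$voxels)),
                                   spacing = vs$mask$spacing,
                                   origin = c(5, -7, 11), direction = Rm))
  mesh1 <- extract_isosurface(shifted)
  expected <- sweep(mesh0$vertices %*% t(Rm), 2, c(5, -7, 11), `+`)
  expect_equal(mesh1$vertices, expected, tolerance = 1e-6)
})

test_that("smoothing keeps topology and reduces the radius spread", {
  vs <- voxel_sphere_mask(15, c(1, 1, 1))
  mesh <- extract_isosurface(vs$mask)
  expect_identical(smooth_mesh(mesh, 0), mesh)            # identity
  sm <- smooth_mesh(mesh, 10)
  expect_identical(dim(sm$faces), dim(mesh$faces))        # no simplification
  expect_identical(nrow(sm$vertices), nrow(mesh$vertices))
  d0 <- sd(sqrt(rowSums(sweep(mesh$vertices, 2, vs$center)^2)))
  d1 <- sd(sqrt(rowSums(sweep(sm$vertices, 2, vs$center)^2)))
  expect_lt(d1, d0)                                       # strictly smoother
})

test_that("PLY and STL round trips preserve the mesh", {
  vs <- voxel_sphere_mask(6, c(1, 1, 1))
  mesh <- extract_isosurface(vs$mask)
  for (args in list(list(ext = ".ply", binary = TRUE),
                    list(ext = ".ply", binary = FALSE),
                    list(ext = ".stl", binary = TRUE),
                    list(ext = ".stl", binary = FALSE))) {
    path <- withr::local_tempfile(fileext = args$ext)
    write_mesh(mesh, path, binary = args$binary)
    back <- read_mesh(path)
    expect_equal(nrow(back$faces), nrow(mesh$faces))
    tol <- if (args$ext == ".stl" && args$binary) 1e-5 else
           if (args$binary) 1e-5 else 1e-6
    if (args$ext == ".ply") {
      expect_equal(back$vertices, mesh$vertices, tolerance = tol)
    } else {
      # STL loses shared topology; compare the vertex sets geometrically
      nn <- pelvinc:::.nn_match(mesh$vertices, back$vertices)
      expect_lt(max(nn$dist), 1e-4)
    }
  }
  expect_error(write_mesh(mesh, "mesh.obj"), "\\.ply or \\.stl")
})
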