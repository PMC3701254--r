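test_that("slab phantom analytics and voxelization are consistent", {
  ph <- make_phantom(phantom_spec("slab", size = c(740, 370, 60),
                                  spacing = c(3.7, 3.7, 20)))
  expect_equal(ph$truth$midsurface_area, 740 * 370)
  expect_equal(ph$truth$mean_curvature, 0)
  expect_equal(ph$truth$expected_hole_count, 0L)
  # center-sampled voxel count x voxel volume approximates the solid volume
  vol <- sum(ph$mask$voxels) * prod(ph$mask$spacing)
  expect_equal(vol, 740 * 370 * 60, tolerance = 0.02)
  # mid-surface point test vanishes on the mid-plane
  expect_equal(ph$truth$midsurface_point_test(cbind(10, -20, 0)), 0)
})

test_that("sphere voxel count converges to the analytic volume with spacing", {
  err <- vapply(c(4, 2), function(h) {
    ph <- make_phantom(phantom_spec("sphere", radius = 100,
                                    spacing = c(h, h, h)))
    abs(sum(ph$mask$voxels) * h^3 / (4 / 3 * pi * 100^3) - 1)
  }, 0)
  expect_lt(err[1], 0.02)
  expect_lt(err[2], err[1])  # halving the pitch at least halves the error
})

test_that("shell sector truth uses the spherical-cap closed forms", {
  ph <- make_phantom(phantom_spec("shell_sector", radius = 250,
                                  thickness = 40, half_angle = 45,
                                  spacing = c(4, 4, 4)))
  expect_equal(ph$truth$mean_curvature, 1 / 250)
  expect_equal(ph$truth$midsurface_area, 2 * pi * 250^2 * (1 - cos(pi / 4)))
  # radial point test: zero on the mid-sphere, signed off it
  expect_equal(ph$truth$midsurface_point_test(cbind(0, 0, 250)), 0)
  expect_gt(ph$truth$midsurface_point_test(cbind(0, 0, 260)), 0)
})

test_that("rotating the pose preserves voxel count and analytic truth", {
  base <- phantom_spec("slab", size = c(300, 200, 60), spacing = c(5, 5, 20))
  rot <- phantom_spec("slab", size = c(300, 200, 60), spacing = c(5, 5, 20),
                      angles = c(0.5, 0.3, 0.7), translate = c(40, -20, 10))
  ph0 <- make_phantom(base)
  ph1 <- make_phantom(rot)
  expect_equal(sum(ph1$mask$voxels) / sum(ph0$mask$voxels), 1,
               tolerance = 0.05)
  expect_equal(ph1$truth$midsurface_area, ph0$truth$midsurface_area)
  expect_equal(ph1$truth$mean_curvature, ph0$truth$mean_curvature)
  # the rotated point test vanishes on the rotated mid-plane
  R <- sasmorph:::rot_matrix(c(0.5, 0.3, 0.7))
  p <- t(R %*% c(30, -10, 0)) + c(40, -20, 10)
  expect_equal(as.numeric(ph1$truth$midsurface_point_test(p)), 0,
               tolerance = 1e-9)
})

test_that("csg_combine satisfies boolean identities and disjoint additivity", {
  a <- make_phantom(phantom_spec("box", size = c(100, 80, 60),
                                 spacing = c(5, 5, 10)))$mask
  expect_equal(sum(csg_combine(a, a, "union")$voxels), sum(a$voxels))
  expect_equal(sum(csg_combine(a, a, "intersection")$voxels), sum(a$voxels))
  expect_equal(sum(csg_combine(a, a, "difference")$voxels), 0L)
  b <- make_phantom(phantom_spec("box", size = c(100, 80, 60),
                                 spacing = c(5, 5, 10),
                                 translate = c(400, 0, 0)))$mask
  expect_warning(u <- csg_combine(a, b, "union"), "26-connected")
  expect_equal(sum(u$voxels), sum(a$voxels) + sum(b$voxels))
  # differing spacings need explicit resampling
  cheap <- make_phantom(phantom_spec("box", size = c(100, 80, 60),
                                     spacing = c(10, 10, 10)))$mask
  expect_error(csg_combine(a, cheap, "union"), "resample")
})

test_that("perforated sheets count holes and subtract their area", {
  spec1 <- phantom_spec("perforated_sheet", size = c(500, 500, 60),
                        holes = list(list(center = c(0, 0), radius = 50)),
                        spacing = c(5, 5, 20))
  ph <- make_perforated_sheet(spec1)
  expect_equal(ph$truth$expected_hole_count, 1L)
  expect_equal(ph$truth$midsurface_area, 250000 - pi * 2500)
  # the hole really is carved out
  slab <- make_phantom(phantom_spec("slab", size = c(500, 500, 60),
                                    spacing = c(5, 5, 20)))
  expect_lt(sum(ph$mask$voxels), sum(slab$mask$voxels))
  # 0 holes degenerates to the slab
  spec0 <- phantom_spec("perforated_sheet", size = c(500, 500, 60),
                        spacing = c(5, 5, 20))
  expect_equal(sum(make_perforated_sheet(spec0)$mask$voxels),
               sum(slab$mask$voxels))
  # 3 disjoint holes
  spec3 <- phantom_spec("perforated_sheet", size = c(500, 500, 60),
                        holes = list(list(center = c(0, 0), radius = 50),
                                     list(center = c(150, 150), radius = 30),
                                     list(center = c(-150, -100), radius = 40)),
                        spacing = c(5, 5, 20))
  expect_equal(make_perforated_sheet(spec3)$truth$expected_hole_count, 3L)
  # invalid holes rejected
  expect_error(make_perforated_sheet(
    phantom_spec("perforated_sheet", size = c(500, 500, 60),
                 holes = list(list(center = c(240, 0), radius = 50)),
                 spacing = c(5, 5, 20))), "boundary")
  expect_error(make_perforated_sheet(
    phantom_spec("perforated_sheet", size = c(500, 500, 60),
                 holes = list(list(center = c(0, 0), radius = 50),
                              list(center = c(60, 0), radius = 30)),
                 spacing = c(5, 5, 20))), "touch|overlap")
})

test_that("too-thin phantoms are rejected at spec time", {
  expect_error(phantom_spec("slab", size = c(100, 100, 30),
                            spacing = c(3.7, 3.7, 20)), "2-voxel minimum")
})
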