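# Shared fixtures: the instrument-spacing slab and its distance maps.
slab_ph <- make_phantom(phantom_spec("slab", size = c(740, 370, 60),
                                     spacing = c(3.7, 3.7, 20)))
slab_raw <- signed_distance_map(slab_ph$mask)
slab_sm <- gaussian_smooth(slab_raw, 0.67)
slab_obb <- compute_obb(slab_ph$mask)
slab_seed <- seed_point(slab_sm)

test_that("template spans the inflated OBB face at the voxel-count pitch", {
  templ <- build_template(slab_obb, slab_seed, spacing = c(3.7, 3.7, 20))
  # ~ (740 * 1.1 / 3.7) x (370 * 1.1 / 3.7) vertices
  expect_equal(templ$grid_shape[1], 740 * 1.1 / 3.7, tolerance = 0.02)
  expect_equal(templ$grid_shape[2], 370 * 1.1 / 3.7, tolerance = 0.02)
  expect_equal(nrow(templ$vertices), prod(templ$grid_shape))
  # planarity through the seed
  resid <- sweep(templ$vertices, 2, slab_seed) %*% slab_obb$normal
  expect_lt(max(abs(resid)), 1e-9)
  # consistent facet count for a structured grid
  expect_equal(nrow(templ$facets),
               2 * prod(templ$grid_shape - 1L))
})

test_that("template construction is equivariant under rotation", {
  R <- sasmorph:::rot_matrix(c(0, 0, 25 * pi / 180))
  obb0 <- structure(list(center = c(0, 0, 0), axes = diag(3),
                         extents = c(400, 200, 60), normal = c(0, 0, 1)),
                    class = "oriented_bbox")
  obb1 <- obb0
  obb1$axes <- R %*% obb0$axes
  obb1$normal <- obb1$axes[, 3]
  t0 <- build_template(obb0, c(0, 0, 0), c(5, 5, 10))
  t1 <- build_template(obb1, c(0, 0, 0), c(5, 5, 10))
  expect_equal(t1$grid_shape, t0$grid_shape)
  expect_equal(t1$facets, t0$facets)
  expect_equal(t1$vertices, t0$vertices %*% t(R), tolerance = 1e-6)
})

test_that("a template on the slab mid-plane is a fixed point", {
  templ <- build_template(slab_obb, slab_seed, spacing = c(3.7, 3.7, 20))
  res <- deform_template(templ, slab_sm, slab_obb$normal)
  expect_true(res$converged)
  expect_lte(res$iterations, 11L)  # s + 1
  disp <- max(abs(res$mesh$vertices - templ$vertices))
  expect_lt(disp, 1e-3)
})

test_that("an offset template recovers the slab mid-plane", {
  templ <- build_template(slab_obb, slab_seed, spacing = c(3.7, 3.7, 20))
  offset <- templ
  offset$vertices <- sweep(templ$vertices, 2, c(0, 0, 30), "-")
  res <- deform_template(offset, slab_sm, slab_obb$normal)
  expect_true(res$converged)
  sas <- clip_to_mask(res$mesh, slab_raw)
  resid <- abs(slab_ph$truth$midsurface_point_test(sas$vertices))
  expect_lt(max(resid), 10)  # half a z-spacing
})

test_that("deformation converges onto the shell sector mid-sphere", {
  sh <- make_phantom(phantom_spec("shell_sector", radius = 150,
                                  thickness = 40, half_angle = 45,
                                  spacing = c(4, 4, 4)))
  res <- extract_sas(sh$mask)
  expect_true(res$deform$converged)
  expect_lt(res$deform$final_error, res$params$c)
  V <- res$sas$vertices
  rho <- sqrt(V[, 1]^2 + V[, 2]^2)
  cap <- rho <= (150 - 20) * sin(pi / 4)  # footprint inside the sector
  resid <- abs(sh$truth$midsurface_point_test(V[cap, , drop = FALSE]))
  expect_lt(mean(resid), 4)  # one voxel pitch
})

test_that("clipping removes protrusions, keeps interior meshes intact,
           and opens perforations", {
  # slab: clipped area close to the analytic footprint
  templ <- build_template(slab_obb, slab_seed, spacing = c(3.7, 3.7, 20))
  res <- deform_template(templ, slab_sm, slab_obb$normal)
  sas <- clip_to_mask(res$mesh, slab_raw)
  expect_equal(surface_area(sas), 740 * 370, tolerance = 0.05)
  expect_lt(nrow(sas$vertices), nrow(res$mesh$vertices))

  # a mesh strictly inside the mask is returned unchanged
  inner <- flat_grid_mesh(100, 60, n1 = 8, n2 = 6, z0 = 0)
  inner$vertices <- sweep(inner$vertices, 2, c(-50, -30, 0), "+")
  clipped <- clip_to_mask(inner, slab_raw)
  expect_equal(clipped$vertices, inner$vertices)
  expect_equal(clipped$facets, inner$facets)

  # one through-hole yields an annulus: exactly 2 boundary loops
  sheet <- make_perforated_sheet(
    phantom_spec("perforated_sheet", size = c(400, 400, 60),
                 holes = list(list(center = c(0, 0), radius = 60)),
                 spacing = c(5, 5, 20)))
  rs <- extract_sas(sheet$mask)
  expect_equal(boundary_loops(rs$sas), 2L)

  # clipping everything is an error
  far <- flat_grid_mesh(50, 50, z0 = 1e5)
  expect_error(clip_to_mask(far, slab_raw), "SAS empty")
})

test_that("extract_sas stages report their provenance on failure", {
  v <- array(FALSE, c(4, 4, 4))
  m <- binary_mask(v, c(1, 1, 1), check_connectivity = FALSE)
  expect_error(extract_sas(m), "compute_obb|empty")
})
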