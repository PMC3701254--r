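test_that("signed EDT matches brute-force nearest-neighbour search exactly", {
  set.seed(11)
  shapes <- list(
    {v <- array(FALSE, c(9, 7, 5)); v[3:7, 3:5, 2:4] <- TRUE; v},
    {v <- array(FALSE, c(12, 6, 6)); v[4:9, 3:4, 3:4] <- TRUE
     v[6:7, 3:4, 3:5] <- TRUE; v},
    {v <- array(FALSE, c(8, 8, 8))
     v[3:6, 3:6, 3:6] <- array(runif(64) > 0.4, c(4, 4, 4))
     if (!any(v)) v[4, 4, 4] <- TRUE
     v})
  spacings <- list(c(1, 1, 1), c(3.7, 3.7, 20), c(2, 5, 9))
  for (i in seq_along(shapes)) {
    m <- binary_mask(shapes[[i]], spacings[[i]], check_connectivity = FALSE)
    dm <- signed_distance_map(m)
    expect_equal(dm$values, brute_signed_edt(m), tolerance = 1e-12)
  }
})

test_that("signed EDT sign convention and simple closed forms", {
  v <- array(FALSE, c(5, 5, 5))
  v[3, 3, 3] <- TRUE
  dm <- signed_distance_map(binary_mask(v, c(1, 1, 1)))
  expect_equal(dm$values[3, 3, 3], 1)  # one step to the nearest bg center
  expect_true(all(dm$values[v] > 0))
  expect_true(all(dm$values[!v] < 0))

  # 220 nm slab at 20 nm sections voxelizes to 12 layers; the deepest layer
  # is 6 center-to-center steps from background, so max(DM) = 120 nm
  ph <- make_phantom(phantom_spec("slab", size = c(400, 400, 220),
                                  spacing = c(3.7, 3.7, 20)))
  dm2 <- signed_distance_map(ph$mask)
  expect_equal(dm2$max_value, 6 * 20)

  # masks touching the border are rejected
  vb <- array(TRUE, c(4, 4, 4))
  expect_error(signed_distance_map(
    binary_mask(vb, c(1, 1, 1), check_connectivity = FALSE)), "border")
})

test_that("gaussian smoothing: identity at c_s = 0, mean preservation,
           bounds enforced", {
  ph <- small_slab()
  dm <- signed_distance_map(ph$mask)
  expect_identical(gaussian_smooth(dm, 0)$values, dm$values)
  sm <- gaussian_smooth(dm, 0.5)
  expect_true(sm$smoothed)
  expect_equal(sm$c_s_used, 0.5)
  expect_equal(mean(sm$values), mean(dm$values), tolerance = 1e-3)
  expect_error(gaussian_smooth(dm, 0.7), "c_s")
  expect_error(gaussian_smooth(dm, -0.1), "c_s")
  expect_error(gaussian_smooth(sm, 0.1), "already smoothed")
})

test_that("smoothed sphere center value strictly decreases with c_s", {
  ph <- make_phantom(phantom_spec("sphere", radius = 30, spacing = c(2, 2, 2)))
  raw <- signed_distance_map(ph$mask)
  ctr <- which(raw$values == raw$max_value, arr.ind = TRUE)[1, ]
  vals <- vapply(c(0.1, 0.3, 0.5, 0.67), function(cs)
    gaussian_smooth(raw, cs)$values[ctr[1], ctr[2], ctr[3]], 0)
  expect_true(all(diff(vals) < 0))
})

test_that("seed point sits on the symmetry locus of simple phantoms", {
  ph <- small_slab()
  sm <- gaussian_smooth(signed_distance_map(ph$mask), 0.67)
  seed <- seed_point(sm)
  # brute-force maximum over the array agrees with the recorded max
  expect_equal(sm$max_value, max(sm$values))
  expect_equal(abs(ph$truth$midsurface_point_test(rbind(seed))),
               0, tolerance = 10)  # within half a z-spacing of the mid-plane
  sph <- make_phantom(phantom_spec("sphere", radius = 60,
                                   spacing = c(4, 4, 4)))
  sms <- gaussian_smooth(signed_distance_map(sph$mask), 0.3)
  expect_equal(as.numeric(seed_point(sms)), c(0, 0, 0), tolerance = 4)

  # mean-of-ties: two equal-value voxels average to their midpoint
  v <- array(FALSE, c(7, 5, 5))
  v[3:4, 3, 3] <- TRUE
  dm2 <- signed_distance_map(binary_mask(v, c(1, 1, 1),
                                         check_connectivity = FALSE))
  dm2$smoothed <- TRUE
  expect_equal(as.numeric(seed_point(dm2)), c(2.5, 2, 2))
})

test_that("tricubic sampling reproduces grid values and projects gradients", {
  ph <- small_slab()
  sm <- gaussian_smooth(signed_distance_map(ph$mask), 0.67)
  g <- sasmorph:::gradient_field(sm)
  d <- dim(sm$values)
  # sampling at voxel centers reproduces the central-difference arrays
  set.seed(3)
  ii <- cbind(sample(2:(d[1] - 1), 40, TRUE), sample(2:(d[2] - 1), 40, TRUE),
              sample(2:(d[3] - 1), 40, TRUE))
  pts <- sweep(sweep(ii - 1, 2, sm$spacing, "*"), 2, sm$origin, "+")
  got <- sample_normal_gradient(sm, pts, c(0, 0, 1))
  expect_equal(as.numeric(got), g[[3]][ii], tolerance = 1e-9)

  # slab symmetry: positive push below the mid-plane, negative above, zero on
  mid <- 0  # phantom is centered at the origin
  p_below <- cbind(runif(20, -60, 60), runif(20, -40, 40), mid - 22)
  p_above <- cbind(p_below[, 1:2], mid + 22)
  p_on <- cbind(p_below[, 1:2], mid)
  expect_true(all(sample_normal_gradient(sm, p_below, c(0, 0, 1)) > 0))
  expect_true(all(sample_normal_gradient(sm, p_above, c(0, 0, 1)) < 0))
  expect_equal(max(abs(sample_normal_gradient(sm, p_on, c(0, 0, 1)))), 0,
               tolerance = 1e-6)
  # gradient of a distance field never projects much beyond unit magnitude
  expect_lt(max(abs(sample_normal_gradient(sm, p_below, c(0, 0, 1)))), 1.05)

  # out-of-bounds points return 0 and are counted
  far <- rbind(c(1e5, 1e5, 1e5))
  out <- sample_normal_gradient(sm, far, c(0, 0, 1))
  expect_equal(as.numeric(out), 0)
  expect_equal(attr(out, "n_oob"), 1L)
})
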