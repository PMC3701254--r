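test_that("surface area and perimeter: closed forms and additivity", {
  sq <- flat_grid_mesh(1, 1, n1 = 2, n2 = 2)
  expect_equal(surface_area(sq), 1)
  expect_equal(perimeter(sq), 4)
  cap <- sphere_cap_mesh(100, pi / 3)
  expect_equal(surface_area(cap), 2 * pi * 100^2 * (1 - cos(pi / 3)),
               tolerance = 0.01)
  # additivity over disjoint components
  two <- surface_mesh(rbind(sq$vertices, sq$vertices +
                              matrix(c(10, 0, 0), nrow(sq$vertices), 3,
                                     byrow = TRUE)),
                      rbind(sq$facets, sq$facets + nrow(sq$vertices)))
  expect_equal(surface_area(two), 2 * surface_area(sq))
  expect_equal(perimeter(two), 2 * perimeter(sq))
  expect_equal(boundary_loops(two), 2L)
})

test_that("area ratio: flat zero, hemisphere half, shell monotonicity,
           rigid-motion invariance", {
  flat <- flat_grid_mesh(200, 150, n1 = 30, n2 = 25)
  expect_equal(area_ratio(flat, fake_obb(c(100, 75, 0))), 0)

  hemi <- sphere_cap_mesh(100, pi / 2 - 1e-3, nth = 80, nph = 160)
  expect_equal(area_ratio(hemi, fake_obb()), 0.5, tolerance = 0.03)

  # closed form 1 - sin^2(t)/(2(1-cos t)) = sin^2(t/2) increases with angle
  ar <- vapply(c(15, 45, 75) * pi / 180, function(t)
    area_ratio(sphere_cap_mesh(100, t, nth = 60, nph = 120), fake_obb()), 0)
  expect_true(all(diff(ar) > 0))
  expect_equal(ar, sin(c(15, 45, 75) * pi / 360)^2, tolerance = 0.05)

  # rotating mesh + OBB together leaves AR unchanged
  R <- sasmorph:::rot_matrix(c(0.4, 0.2, 0.6))
  hemi_r <- surface_mesh(hemi$vertices %*% t(R), hemi$facets)
  obb_r <- fake_obb()
  obb_r$axes <- R %*% obb_r$axes
  obb_r$normal <- obb_r$axes[, 3]
  expect_equal(area_ratio(hemi_r, obb_r), area_ratio(hemi, fake_obb()),
               tolerance = 1e-3)
})

test_that("curvature estimators recover plane, sphere and cylinder", {
  flat <- flat_grid_mesh(100, 80, n1 = 15, n2 = 12)
  cf <- vertex_curvatures(flat)
  int <- cf[cf$interior_mask, ]
  expect_lt(max(abs(int$H)), 1e-6)
  expect_lt(max(abs(int$K)), 1e-6)
  expect_lt(max(abs(int$k1)), 1e-6)

  cap <- sphere_cap_mesh(100, pi / 3, nth = 60, nph = 120)
  cs <- curvature_summary(vertex_curvatures(cap))
  expect_equal(abs(cs$mean_H), 1 / 100, tolerance = 0.1)
  expect_equal(cs$mean_K, 1e-4, tolerance = 0.2)

  cyl <- cylinder_mesh(50, 200, nz = 40, nph = 100)
  cs2 <- curvature_summary(vertex_curvatures(cyl))
  expect_equal(abs(cs2$mean_H), 1 / (2 * 50), tolerance = 0.15)
  expect_lt(abs(cs2$mean_K), 0.1 / 50^2)
})

test_that("curvature field invariants hold on an irregular surface", {
  # bumpy graph surface
  set.seed(7)
  n1 <- 25; n2 <- 20
  m <- flat_grid_mesh(200, 160, n1 = n1, n2 = n2)
  m$vertices[, 3] <- 10 * sin(m$vertices[, 1] / 30) *
    cos(m$vertices[, 2] / 25)
  cf <- vertex_curvatures(m)
  expect_true(all(cf$k1 <= cf$k2 + 1e-12))
  expect_true(all(cf$H^2 >= cf$K - 1e-12))
  expect_equal(cf$H, (cf$k1 + cf$k2) / 2, tolerance = 1e-12)
  expect_equal(cf$K, cf$k1 * cf$k2, tolerance = 1e-12)
})

test_that("curvature summary matches a two-pass oracle and population sd", {
  set.seed(42)
  n <- 1000
  field <- tibble::tibble(k1 = rnorm(n), k2 = rnorm(n) + 2,
                          H = rnorm(n), K = rnorm(n),
                          interior_mask = rep(c(TRUE, FALSE), c(800, 200)))
  s <- curvature_summary(field)
  x <- field$H[field$interior_mask]
  mu <- sum(x) / length(x)
  sigma <- sqrt(sum((x - mu)^2) / length(x))  # denominator n
  expect_equal(s$mean_H, mu, tolerance = 1e-12)
  expect_equal(s$sd_H, sigma, tolerance = 1e-12)

  const <- tibble::tibble(k1 = rep(0.3, 5), k2 = rep(0.3, 5),
                          H = rep(0.3, 5), K = rep(0.09, 5),
                          interior_mask = TRUE)
  sc <- curvature_summary(const)
  expect_equal(sc$mean_k1, 0.3)
  expect_equal(sc$sd_k1, 0)
})

test_that("Feret diameter: closed forms and brute-force equivalence", {
  # two voxels 100 nm apart
  v <- array(FALSE, c(13, 3, 3))
  v[2, 2, 2] <- TRUE
  v[12, 2, 2] <- TRUE
  m <- binary_mask(v, c(10, 10, 10), check_connectivity = FALSE)
  expect_equal(feret_diameter(m), 100)

  # box lattice: within one (diagonal) voxel pitch of the corner diagonal,
  # since Feret works on voxel centers, each half a pitch inside its face
  ph <- make_phantom(phantom_spec("box", size = c(200, 150, 100),
                                  spacing = c(10, 10, 10)))
  expect_lt(abs(feret_diameter(ph$mask) - sqrt(200^2 + 150^2 + 100^2)),
            sqrt(3 * 10^2) + 1e-6)

  # random point sets vs exhaustive support-set search
  set.seed(123)
  for (rep in 1:20) {
    n <- sample(4:18, 1)
    pts <- matrix(rnorm(3 * n, sd = 50), ncol = 3)
    got <- sasmorph:::cpp_miniball(pts)
    want <- brute_miniball(pts)
    expect_equal(got$radius, want$radius, tolerance = 1e-6)
    # enclosing-sphere property and lower bound by max pairwise distance
    expect_true(all(sqrt(colSums((t(pts) - got$center)^2)) <=
                      got$radius + 1e-6))
    expect_gte(2 * got$radius + 1e-9, max(dist(pts)))
  }
})

test_that("mask features recover volume and equivalent ellipsoid", {
  v <- array(FALSE, c(14, 14, 14))
  v[3:12, 3:12, 3:12] <- TRUE
  m <- binary_mask(v, c(1, 1, 1))
  f <- mask_features(m)
  expect_equal(f$volume_nm3, 1000)

  sph <- make_phantom(phantom_spec("sphere", radius = 50,
                                   spacing = c(2, 2, 2)))
  fs <- mask_features(sph$mask)
  expect_equal(fs$ellipsoid_semiaxes, rep(50, 3), tolerance = 0.05)

  # solid ellipsoid voxelized directly: semiaxes (100, 50, 20)
  ax <- c(100, 50, 20)
  n <- ceiling(ax / 2) * 2 + 5
  gr <- expand.grid(x = seq(-n[1], n[1]) * 2, y = seq(-n[2], n[2]) * 2,
                    z = seq(-n[3], n[3]) * 2)
  inside <- (gr$x / ax[1])^2 + (gr$y / ax[2])^2 + (gr$z / ax[3])^2 <= 1
  vox <- array(inside, c(2 * n[1] + 1, 2 * n[2] + 1, 2 * n[3] + 1))
  me <- binary_mask(vox, c(2, 2, 2), check_connectivity = FALSE)
  fe <- mask_features(me)
  expect_equal(fe$ellipsoid_semiaxes, ax, tolerance = 0.05)
})

test_that("morphometry assembles a tidy one-row record", {
  ph <- small_slab()
  res <- extract_sas(ph$mask)
  rec <- morphometry(res)
  expect_s3_class(rec, "tbl_df")
  expect_equal(nrow(rec), 1L)
  expect_true(all(sasmorph:::feature_columns %in% names(rec)))
  expect_gt(rec$sas_area_nm2, 0)
  expect_true(rec$area_ratio >= 0 && rec$area_ratio < 1)
  expect_true(rec$converged)
  td <- tidy(res)
  expect_equal(td$sas_area_nm2, rec$sas_area_nm2)
  gl <- glance(res)
  expect_equal(gl$n_facets, nrow(res$sas$facets))
})
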