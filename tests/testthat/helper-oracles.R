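# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's computational paths.

# Brute-force signed EDT between voxel centers: for every voxel, scan all
# voxels of the opposite phase. O(n^2); only for tiny grids.
brute_signed_edt <- function(mask) {
  d <- dim(mask$voxels)
  idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  cen <- sweep(sweep(idx - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
  fg <- as.vector(mask$voxels)
  out <- numeric(nrow(cen))
  fgc <- cen[fg, , drop = FALSE]
  bgc <- cen[!fg, , drop = FALSE]
  mindist <- function(p, set) {
    sqrt(min(colSums((t(set) - p)^2)))
  }
  for (i in seq_len(nrow(cen))) {
    out[i] <- if (fg[i]) mindist(cen[i, ], bgc) else -mindist(cen[i, ], fgc)
  }
  array(out, d)
}

# Exhaustive minimum enclosing sphere over all 2-, 3- and 4-point support
# sets. O(n^4); only for n <= ~30.
brute_miniball <- function(pts) {
  n <- nrow(pts)
  encloses <- function(c, r) all(sqrt(colSums((t(pts) - c)^2)) <= r + 1e-9)
  best_r <- Inf
  best_c <- NULL
  consider <- function(c, r) {
    if (!is.null(c) && r < best_r && encloses(c, r)) {
      best_r <<- r
      best_c <<- c
    }
  }
  for (pair in utils::combn(n, 2, simplify = FALSE)) {
    c <- colMeans(pts[pair, , drop = FALSE])
    consider(c, sqrt(sum((pts[pair[1], ] - c)^2)))
  }
  if (n >= 3) for (tri in utils::combn(n, 3, simplify = FALSE)) {
    p1 <- pts[tri[1], ]; a <- pts[tri[2], ] - p1; b <- pts[tri[3], ] - p1
    M <- rbind(c(sum(a * a), sum(a * b)), c(sum(a * b), sum(b * b)))
    if (abs(det(M)) < 1e-12) next
    ab <- solve(M, c(sum(a * a) / 2, sum(b * b) / 2))
    c <- p1 + ab[1] * a + ab[2] * b
    consider(c, sqrt(sum((p1 - c)^2)))
  }
  if (n >= 4) for (qd in utils::combn(n, 4, simplify = FALSE)) {
    p0 <- pts[qd[1], ]
    A <- 2 * (pts[qd[2:4], , drop = FALSE] -
              matrix(p0, 3, 3, byrow = TRUE))
    rhs <- rowSums(pts[qd[2:4], , drop = FALSE]^2) - sum(p0^2)
    if (abs(det(A)) < 1e-9) next
    c <- solve(A, rhs)
    consider(c, sqrt(sum((p0 - c)^2)))
  }
  list(center = best_c, radius = best_r)
}

# Structured parametric mesh of a spherical cap of radius R up to polar angle
# theta_max (radians); used as an analytic curvature / area-ratio fixture.
sphere_cap_mesh <- function(R, theta_max, nth = 40, nph = 80,
                            theta_min = 0.03) {
  th <- seq(theta_min, theta_max, length.out = nth)
  ph <- seq(0, 2 * pi, length.out = nph + 1)[-(nph + 1)]
  g <- expand.grid(i = seq_len(nth), j = seq_len(nph))
  V <- cbind(R * sin(th[g$i]) * cos(ph[g$j]),
             R * sin(th[g$i]) * sin(ph[g$j]),
             R * cos(th[g$i]))
  vid <- function(i, j) i + nth * ((j - 1) %% nph)
  f <- matrix(0L, 2 * (nth - 1) * nph, 3)
  r <- 0L
  for (j in seq_len(nph)) for (i in seq_len(nth - 1)) {
    f[r + 1L, ] <- c(vid(i, j), vid(i + 1, j), vid(i + 1, j + 1))
    f[r + 2L, ] <- c(vid(i, j), vid(i + 1, j + 1), vid(i, j + 1))
    r <- r + 2L
  }
  surface_mesh(V, f)
}

# Open cylinder mesh of radius R and height h along z.
cylinder_mesh <- function(R, h, nz = 30, nph = 80) {
  zz <- seq(0, h, length.out = nz)
  ph <- seq(0, 2 * pi, length.out = nph + 1)[-(nph + 1)]
  g <- expand.grid(i = seq_len(nz), j = seq_len(nph))
  V <- cbind(R * cos(ph[g$j]), R * sin(ph[g$j]), zz[g$i])
  vid <- function(i, j) i + nz * ((j - 1) %% nph)
  f <- matrix(0L, 2 * (nz - 1) * nph, 3)
  r <- 0L
  for (j in seq_len(nph)) for (i in seq_len(nz - 1)) {
    f[r + 1L, ] <- c(vid(i, j), vid(i + 1, j), vid(i + 1, j + 1))
    f[r + 2L, ] <- c(vid(i, j), vid(i + 1, j + 1), vid(i, j + 1))
    r <- r + 2L
  }
  surface_mesh(V, f)
}

# Flat structured grid mesh spanning [0, Lx] x [0, Ly] at z = z0.
flat_grid_mesh <- function(Lx, Ly, n1 = 12, n2 = 10, z0 = 0) {
  a <- seq(0, Lx, length.out = n1)
  b <- seq(0, Ly, length.out = n2)
  g <- expand.grid(a = a, b = b)
  V <- cbind(g$a, g$b, z0)
  i <- rep(seq_len(n1 - 1L), n2 - 1L)
  j <- rep(seq_len(n2 - 1L), each = n1 - 1L)
  v00 <- i + n1 * (j - 1L)
  f <- rbind(cbind(v00, v00 + 1L, v00 + n1 + 1L),
             cbind(v00, v00 + n1 + 1L, v00 + n1))
  surface_mesh(V, f, grid_shape = c(n1, n2))
}

# Small slab phantom used by several unit tests (fast: ~40 x 25 x 3 voxels).
small_slab <- function() {
  make_phantom(phantom_spec("slab", size = c(200, 120, 60),
                            spacing = c(5, 5, 20)))
}

# Synthetic axis-aligned OBB for meshes built directly in world coordinates.
fake_obb <- function(center = c(0, 0, 0)) {
  structure(list(center = center, axes = diag(3),
                 extents = c(1, 1, 1) * Inf, normal = c(0, 0, 1)),
            class = "oriented_bbox")
}
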