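#' Discrete per-vertex curvatures of a triangle mesh
#'
#' Estimates the classical curvature quantities at every vertex of a
#' manifold-with-boundary triangle mesh: Gaussian curvature `K` by the angle
#' defect over the barycentric vertex area, mean curvature `H` from the
#' cotangent Laplace-Beltrami operator (`H = 0.5 * (L p) . N` with `N` the
#' area-weighted vertex normal from the facet orientation), and the
#' principal curvatures `k1 <= k2` recovered as `H -/+ sqrt(max(H^2 - K, 0))`.
#' Discrete curvature operators are undefined on the boundary, so boundary
#' vertices are flagged out of `interior_mask` and excluded from summaries.
#'
#' @param mesh a [surface_mesh()] forming a manifold with boundary.
#' @return A `curvature_field` tibble with columns `k1`, `k2`, `H` (1/nm),
#'   `K` (1/nm^2) and `interior_mask`.
#' @seealso [curvature_summary()]
#' @export
vertex_curvatures <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  V <- mesh$vertices
  f <- mesh$facets
  nv <- nrow(V)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt > 2L)) stop("non-manifold edge (more than two incident facets)")

  # per-corner interior angles and cotangents
  p1 <- V[f[, 1], , drop = FALSE]
  p2 <- V[f[, 2], , drop = FALSE]
  p3 <- V[f[, 3], , drop = FALSE]
  ang <- function(a, b) {
    # angle between row vectors a and b
    dot <- rowSums(a * b)
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    atan2(sqrt(rowSums(cr^2)), dot)
  }
  a1 <- ang(p2 - p1, p3 - p1)
  a2 <- ang(p3 - p2, p1 - p2)
  a3 <- ang(p1 - p3, p2 - p3)
  areas <- facet_areas(mesh)

  # barycentric vertex areas and angle sums
  Av <- accum(as.vector(f), rep(areas / 3, 3L), nv)
  angsum <- accum(as.vector(f), c(a1, a2, a3), nv)

  # area-weighted vertex normals from facet orientation
  fn <- cbind((p2 - p1)[, 2] * (p3 - p1)[, 3] - (p2 - p1)[, 3] * (p3 - p1)[, 2],
              (p2 - p1)[, 3] * (p3 - p1)[, 1] - (p2 - p1)[, 1] * (p3 - p1)[, 3],
              (p2 - p1)[, 1] * (p3 - p1)[, 2] - (p2 - p1)[, 2] * (p3 - p1)[, 1])
  N <- matrix(0, nv, 3)
  for (d in 1:3) N[, d] <- accum(as.vector(f), rep(fn[, d], 3L), nv)
  nn <- sqrt(rowSums(N^2))
  nn[nn == 0] <- 1
  N <- N / nn

  # cotangent Laplacian: each facet contributes cot(opposite angle) *
  # (p_i - p_j) for its three edges in both directions, so summing gives
  # sum_j (cot a_ij + cot b_ij) (p_i - p_j); dividing by 2 A_v yields the
  # mean curvature normal of magnitude 2|H|
  cot1 <- 1 / tan(pmax(a1, 1e-12))  # opposite edge (2, 3)
  cot2 <- 1 / tan(pmax(a2, 1e-12))  # opposite edge (3, 1)
  cot3 <- 1 / tan(pmax(a3, 1e-12))  # opposite edge (1, 2)
  ei <- c(f[, 2], f[, 3], f[, 3], f[, 1], f[, 1], f[, 2])
  ej <- c(f[, 3], f[, 2], f[, 1], f[, 3], f[, 2], f[, 1])
  w <- c(cot1, cot1, cot2, cot2, cot3, cot3)
  Lp <- matrix(0, nv, 3)
  diff <- V[ei, , drop = FALSE] - V[ej, , drop = FALSE]
  for (d in 1:3) Lp[, d] <- accum(ei, w * diff[, d], nv)
  Lp <- Lp / pmax(2 * Av, 1e-300)  # mean curvature normal, magnitude 2|H|

  Hs <- 0.5 * rowSums(Lp * N)
  boundary <- logical(nv)
  be <- boundary_edges(mesh)
  boundary[unique(as.vector(be))] <- TRUE
  Ks <- ifelse(boundary, 0, (2 * pi - angsum) / pmax(Av, 1e-300))

  disc <- sqrt(pmax(Hs^2 - Ks, 0))
  k1 <- Hs - disc
  k2 <- Hs + disc
  tibble::tibble(k1 = k1, k2 = k2, H = Hs, K = k1 * k2,
                 interior_mask = !boundary)
}

# sum 'vals' into bins 'idx' (1..n)
accum <- function(idx, vals, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Summary statistics of a curvature field
#'
#' Mean and standard deviation of `k1`, `k2`, `H` and `K` over interior
#' vertices only. The standard deviation is the population form (denominator
#' `n`).
#'
#' @param field a `curvature_field` from [vertex_curvatures()].
#' @return One-row tibble with columns `mean_k1`, `sd_k1`, `mean_k2`,
#'   `sd_k2`, `mean_H`, `sd_H`, `mean_K`, `sd_K`, `n_interior`.
#' @export
curvature_summary <- function(field) {
  stopifnot(is.data.frame(field), "interior_mask" %in% names(field))
  f <- field[field$interior_mask, , drop = FALSE]
  if (nrow(f) == 0L) stop("no interior vertices to summarize")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  tibble::tibble(
    mean_k1 = mean(f$k1), sd_k1 = pop_sd(f$k1),
    mean_k2 = mean(f$k2), sd_k2 = pop_sd(f$k2),
    mean_H = mean(f$H), sd_H = pop_sd(f$H),
    mean_K = mean(f$K), sd_K = pop_sd(f$K),
    n_interior = nrow(f))
}
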