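#' Signed Euclidean distance map of a segmentation
#'
#' Computes, for every voxel, the exact Euclidean distance between voxel
#' centers to the opposite phase, using the physical anisotropic spacing:
#' positive inside the mask (distance to the nearest background voxel
#' center), negative outside (distance to the nearest foreground center).
#' The deepest interior value, `max_value = max(DM)`, scales the subsequent
#' Gaussian smoothing and locates the template seed.
#'
#' @param mask a non-empty [binary_mask()] whose foreground does not touch
#'   the array border (crop with a pad first; [extract_labels()] and
#'   [make_phantom()] already do).
#' @return A `distance_map`: list with `values` (3D nm array), `spacing`,
#'   `origin`, `max_value`, `smoothed` flag and `c_s_used`.
#' @seealso [gaussian_smooth()], [seed_point()]
#' @export
signed_distance_map <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  v <- mask$voxels
  if (!any(v)) stop("empty mask: no foreground voxels")
  d <- dim(v)
  if (any(v[c(1, d[1]), , ]) || any(v[, c(1, d[2]), ]) ||
      any(v[, , c(1, d[3])]))
    stop("mask foreground touches the array border; pad with background first")
  dm <- array(cpp_signed_edt(as.logical(v), d, mask$spacing), d)
  structure(list(values = dm, spacing = mask$spacing, origin = mask$origin,
                 max_value = max(dm), smoothed = FALSE, c_s_used = NULL),
            class = "distance_map")
}

#' Upper bound for the smoothing coefficient
#'
#' Magnitude of the standard normal quantile at 0.25 (equivalently the 0.75
#' quantile), bounding the smoothing coefficient `c_s` so that distance-map
#' smoothing with `sigma = c_s * max(DM)` does not erase the interior of a
#' sphere-like object.
#'
#' @return `abs(qnorm(0.25))`, approximately 0.674489.
#' @export
cs_upper_bound <- function() abs(stats::qnorm(0.25))

#' Gaussian smoothing of a distance map
#'
#' Smooths a raw distance map with an isotropic physical-scale Gaussian of
#' `sigma = c_s * max(DM)` nm, applied as a separable convolution with
#' per-axis voxel sigmas `sigma / spacing`. The kernel is truncated at
#' `4 * sigma` and renormalized to unit sum; boundaries are handled by edge
#' reflection. Smoothing suppresses the voxelization staircase that would
#' otherwise make the extracted surface crooked; `c_s = 0` performs no
#' smoothing at all.
#'
#' @param dm an unsmoothed `distance_map`.
#' @param c_s smoothing coefficient in `[0, 0.674489]` (see
#'   [cs_upper_bound()]); default 0.67.
#' @return A `distance_map` flagged `smoothed`, with `c_s_used` recorded and
#'   `max_value` recomputed.
#' @export
gaussian_smooth <- function(dm, c_s = 0.67) {
  stopifnot(inherits(dm, "distance_map"))
  if (isTRUE(dm$smoothed)) stop("distance map is already smoothed")
  if (!is.finite(c_s) || c_s < 0 || c_s > cs_upper_bound())
    stop("c_s must lie in [0, ", format(cs_upper_bound(), digits = 7), "]")
  out <- dm
  if (c_s > 0) {
    sigma <- c_s * dm$max_value
    sm <- cpp_gauss_blur3(as.numeric(dm$values), dim(dm$values),
                          sigma / dm$spacing)
    out$values <- array(sm, dim(dm$values))
  }
  out$max_value <- max(out$values)
  out$smoothed <- TRUE
  out$c_s_used <- c_s
  out
}

#' @export
print.distance_map <- function(x, ...) {
  cat("<distance_map> ", paste(dim(x$values), collapse = " x "),
      ", max ", signif(x$max_value, 5), " nm",
      if (isTRUE(x$smoothed)) paste0(", smoothed (c_s = ", x$c_s_used, ")")
      else ", raw", "\n", sep = "")
  invisible(x)
}

#' Template seed point
#'
#' The geometric center of the deepest voxels of the (smoothed) distance map:
#' the unweighted mean of the physical centers of all voxels whose value is
#' within half the smallest spacing component of `max(DM)`. The tolerance
#' absorbs discretization ties.
#'
#' @param dm a `distance_map` with `max_value > 0`.
#' @return Length-3 nm point.
#' @export
seed_point <- function(dm) {
  stopifnot(inherits(dm, "distance_map"))
  if (!is.finite(dm$max_value) || dm$max_value <= 0)
    stop("distance map has no positive voxels (empty or over-smoothed mask)")
  tol <- min(dm$spacing) / 2
  idx <- which(dm$values >= dm$max_value - tol, arr.ind = TRUE)
  colMeans(sweep(sweep(idx - 1, 2, dm$spacing, "*"), 2, dm$origin, "+"))
}

# central-difference gradient arrays (physical spacing), one-sided at borders
gradient_field <- function(dm) {
  v <- dm$values
  d <- dim(v)
  g <- list()
  for (ax in 1:3) {
    n <- d[ax]
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    denom <- (ip - im) * dm$spacing[ax]
    if (ax == 1) {
      gr <- (v[ip, , , drop = FALSE] - v[im, , , drop = FALSE]) / denom
    } else if (ax == 2) {
      gr <- aperm(aperm(v, c(2, 1, 3))[ip, , , drop = FALSE] -
                  aperm(v, c(2, 1, 3))[im, , , drop = FALSE], c(2, 1, 3)) /
            rep(denom, each = d[1])
      dim(gr) <- d
    } else {
      gr <- aperm(aperm(v, c(3, 2, 1))[ip, , , drop = FALSE] -
                  aperm(v, c(3, 2, 1))[im, , , drop = FALSE], c(3, 2, 1)) /
            rep(denom, each = d[1] * d[2])
      dim(gr) <- d
    }
    g[[ax]] <- gr
  }
  g
}

#' Sample the normal-projected distance gradient
#'
#' Computes the gradient of the (smoothed) distance map by central
#' differences with physical spacing, samples its three components at the
#' query points by tricubic (Catmull-Rom) interpolation, and projects onto
#' the unit direction `n`. Points outside the array bounding box return 0
#' (their count is reported via the `"n_oob"` attribute): distant overhang
#' vertices simply stay put and are clipped later.
#'
#' @param dm a (typically smoothed) `distance_map`.
#' @param points n x 3 matrix of nm points.
#' @param n unit length-3 direction (the template normal).
#' @return Numeric vector of `grad(d) . n` values (nm/nm, dimensionless),
#'   with attribute `n_oob`.
#' @export
sample_normal_gradient <- function(dm, points, n) {
  stopifnot(inherits(dm, "distance_map"))
  n <- as.numeric(n)
  if (abs(sqrt(sum(n^2)) - 1) > 1e-8) stop("'n' must be a unit vector")
  g <- gradient_field(dm)
  idx <- phys_to_index(points, dm$spacing, dm$origin)
  d <- dim(dm$values)
  sx <- cpp_tricubic(as.numeric(g[[1]]), d, idx)
  sy <- cpp_tricubic(as.numeric(g[[2]]), d, idx)
  sz <- cpp_tricubic(as.numeric(g[[3]]), d, idx)
  out <- sx$values * n[1] + sy$values * n[2] + sz$values * n[3]
  out[sx$oob] <- 0
  attr(out, "n_oob") <- sum(sx$oob)
  out
}

# tricubic sample of the distance map itself; oob flagged
sample_distance <- function(dm, points) {
  idx <- phys_to_index(points, dm$spacing, dm$origin)
  s <- cpp_tricubic(as.numeric(dm$values), dim(dm$values), idx)
  list(values = s$values, oob = s$oob)
}
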