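#' Oriented bounding box of a segmentation
#'
#' Principal-axes box of the foreground voxel centers: axes are the
#' eigenvectors of their covariance, ordered by decreasing extent of the
#' projected point cloud; extents are max minus min projection plus one voxel
#' pitch of inflation (half a voxel on each side), so every foreground voxel
#' center lies inside the box. The normal of the largest face (third axis)
#' gives the deformation direction of the template. Masks with fewer than 4
#' non-coplanar voxels fall back to an axis-aligned box.
#'
#' Axis signs are fixed deterministically (largest-magnitude component
#' positive) and the third axis is completed by the cross product, so the
#' frame is right-handed and reproducible.
#'
#' @param mask a non-empty [binary_mask()].
#' @return An `oriented_bbox`: list with `center` (nm), `axes` (3 x 3 matrix,
#'   columns u1, u2, u3), `extents` (nm, sorted decreasing) and `normal`
#'   (= u3).
#' @export
compute_obb <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  pts <- mask_centers(mask)
  if (nrow(pts) == 0L) stop("empty mask")
  if (nrow(pts) < 4L || coplanar(pts)) {
    axes <- diag(3)
  } else {
    cv <- stats::cov(pts)
    axes <- eigen(cv, symmetric = TRUE)$vectors
  }
  # deterministic signs
  for (j in 1:2) {
    k <- which.max(abs(axes[, j]))
    if (axes[k, j] < 0) axes[, j] <- -axes[, j]
  }
  axes[, 3] <- cross3v(axes[, 1], axes[, 2])
  proj <- pts %*% axes
  ranges <- apply(proj, 2, range)
  # one voxel pitch of inflation along each box axis: use the spacing of the
  # world axis best aligned with that box axis
  infl <- vapply(1:3, function(j) mask$spacing[which.max(abs(axes[, j]))], 0)
  extents <- (ranges[2, ] - ranges[1, ]) + infl
  ord <- order(extents, decreasing = TRUE)
  axes <- axes[, ord, drop = FALSE]
  extents <- extents[ord]
  axes[, 3] <- cross3v(axes[, 1], axes[, 2])  # keep right-handed after sort
  k <- which.max(abs(axes[, 3]))
  if (axes[k, 3] < 0) {
    axes[, 3] <- -axes[, 3]
    axes[, 2] <- -axes[, 2]
  }
  proj <- pts %*% axes
  ranges <- apply(proj, 2, range)
  center <- colMeans(ranges) %*% t(axes)
  structure(list(center = as.numeric(center), axes = axes,
                 extents = as.numeric(extents), normal = axes[, 3]),
            class = "oriented_bbox")
}

coplanar <- function(pts, tol = 1e-9) {
  if (nrow(pts) < 4L) return(TRUE)
  cv <- stats::cov(pts)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  ev[3] <= tol * max(ev[1], 1)
}

cross3v <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.oriented_bbox <- function(x, ...) {
  cat("<oriented_bbox> extents (", paste(signif(x$extents, 5),
      collapse = ", "), ") nm, normal (",
      paste(signif(x$normal, 4), collapse = ", "), ")\n", sep = "")
  invisible(x)
}
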