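#' Area ratio of a surface against its bounding-box face
#'
#' `AR = 1 - projected_area / surface_area`, where the projected area is the
#' footprint of the mesh on the plane of the largest OBB face (axes u1, u2).
#' The footprint is rasterized at the given pitch with exact triangle-to-cell
#' clipping and per-cell coverage capped at the cell area, i.e. a true union
#' area that does not double count folded surfaces; for fold-free meshes it
#' is exact, so a perfectly flat SAS has AR = 0. The ratio is clamped to
#' `[0, 1)`. AR grows with curvature: a hemisphere has AR = 0.5.
#'
#' @param mesh a [surface_mesh()] with positive area.
#' @param obb the `oriented_bbox` defining the projection plane.
#' @param pitch raster pitch in nm; defaults to the median projected edge
#'   length of the mesh (the template pitch for pipeline meshes).
#' @return Dimensionless ratio in `[0, 1)`.
#' @export
area_ratio <- function(mesh, obb, pitch = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(obb, "oriented_bbox"))
  area <- surface_area(mesh)
  if (area <= 0) stop("zero mesh area")
  uv <- sweep(mesh$vertices, 2, obb$center) %*% obb$axes[, 1:2]
  f <- mesh$facets
  if (is.null(pitch)) {
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    el <- sqrt(rowSums((uv[e[, 1], , drop = FALSE] -
                        uv[e[, 2], , drop = FALSE])^2))
    pitch <- stats::median(el[el > 0])
  }
  tri <- cbind(uv[f[, 1], , drop = FALSE], uv[f[, 2], , drop = FALSE],
               uv[f[, 3], , drop = FALSE])
  projected <- cpp_raster_union_area(tri, pitch)
  min(max(1 - projected / area, 0), 1 - 1e-12)
}

#' Feret's diameter of a segmentation
#'
#' Diameter of the smallest sphere circumscribing the foreground voxel
#' centers, computed exactly (Welzl's minimum enclosing sphere, deterministic
#' result). Working on voxel centers rather than voxel corners makes the
#' result accurate to one voxel pitch.
#'
#' @param mask a non-empty [binary_mask()].
#' @return Diameter in nm.
#' @export
feret_diameter <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  pts <- mask_centers(mask)
  if (nrow(pts) == 0L) stop("empty mask")
  2 * cpp_miniball(pts)$radius
}

#' Segmentation-level features
#'
#' Voxel-count volume, oriented bounding-box extents, binary principal
#' moments (eigenvalues of the foreground voxel-center covariance), the
#' corresponding principal axes, and the equivalent ellipsoid semiaxes
#' `a_i = sqrt(5 * lambda_i)` — the uniform solid ellipsoid relation, which
#' recovers the true semiaxes of a homogeneously filled ellipsoid.
#'
#' @param mask a non-empty [binary_mask()].
#' @return List with `volume_nm3`, `bbox_extents` (nm, decreasing),
#'   `principal_moments` (nm^2, decreasing), `principal_axes` (3 x 3 matrix,
#'   columns matching the moments) and `ellipsoid_semiaxes` (nm, decreasing).
#' @export
mask_features <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  pts <- mask_centers(mask)
  if (nrow(pts) == 0L) stop("empty mask")
  volume <- nrow(pts) * prod(mask$spacing)
  obb <- compute_obb(mask)
  if (nrow(pts) >= 2L) {
    ev <- eigen(stats::cov(pts) * (nrow(pts) - 1) / nrow(pts),
                symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    axes <- ev$vectors
  } else {
    lam <- c(0, 0, 0)
    axes <- diag(3)
  }
  list(volume_nm3 = volume,
       bbox_extents = obb$extents,
       principal_moments = lam,
       principal_axes = axes,
       ellipsoid_semiaxes = sqrt(5 * lam))
}

#' Full per-junction morphometry record
#'
#' Combines SAS-level quantities (area, perimeter, area ratio, curvature
#' statistics over interior vertices) with segmentation-level features
#' (volume, Feret's diameter, principal moments, equivalent ellipsoid) into
#' one tidy row per junction.
#'
#' @param result a `sas_result` from [extract_sas()].
#' @param mask the source [binary_mask()]; defaults to the mask stored on the
#'   result.
#' @return One-row tibble; see [write_feature_table()] for the documented
#'   column order of the exported CSV.
#' @export
morphometry <- function(result, mask = result$mask) {
  stopifnot(inherits(result, "sas_result"))
  curv <- curvature_summary(vertex_curvatures(result$sas))
  feats <- mask_features(mask)
  tibble::tibble(
    label_id = result$source_label,
    sas_area_nm2 = surface_area(result$sas),
    sas_perimeter_nm = perimeter(result$sas),
    area_ratio = area_ratio(result$sas, result$obb),
    feret_nm = feret_diameter(mask),
    volume_nm3 = feats$volume_nm3,
    mean_H = curv$mean_H, sd_H = curv$sd_H,
    mean_K = curv$mean_K, sd_K = curv$sd_K,
    mean_k1 = curv$mean_k1, sd_k1 = curv$sd_k1,
    mean_k2 = curv$mean_k2, sd_k2 = curv$sd_k2,
    ellipsoid_a = feats$ellipsoid_semiaxes[1],
    ellipsoid_b = feats$ellipsoid_semiaxes[2],
    ellipsoid_c = feats$ellipsoid_semiaxes[3],
    converged = result$deform$converged,
    iterations = result$deform$iterations,
    bbox_extent_1 = feats$bbox_extents[1],
    bbox_extent_2 = feats$bbox_extents[2],
    bbox_extent_3 = feats$bbox_extents[3],
    moment_1 = feats$principal_moments[1],
    moment_2 = feats$principal_moments[2],
    moment_3 = feats$principal_moments[3])
}

feature_columns <- c(
  "label_id", "sas_area_nm2", "sas_perimeter_nm", "area_ratio", "feret_nm",
  "volume_nm3", "mean_H", "sd_H", "mean_K", "sd_K", "mean_k1", "sd_k1",
  "mean_k2", "sd_k2", "ellipsoid_a", "ellipsoid_b", "ellipsoid_c",
  "converged", "iterations")

#' Write the per-junction feature table
#'
#' CSV with one row per junction in a stable documented column order:
#' `label_id, sas_area_nm2, sas_perimeter_nm, area_ratio, feret_nm,
#' volume_nm3, mean_H, sd_H, mean_K, sd_K, mean_k1, sd_k1, mean_k2, sd_k2,
#' ellipsoid_a, ellipsoid_b, ellipsoid_c, converged, iterations`. An empty
#' record list yields a header-only file; zeros are serialized as numbers,
#' never blanks.
#'
#' @param records list of one-row tibbles from [morphometry()] (or a single
#'   tibble of such rows).
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(records, path) {
  if (is.data.frame(records)) records <- list(records)
  if (length(records) == 0L) {
    writeLines(paste(feature_columns, collapse = ","), path)
    return(invisible(path))
  }
  tab <- do.call(rbind, lapply(records, function(r) r[, feature_columns]))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
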