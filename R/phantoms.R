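#' Specify a voxelized test phantom
#'
#' Phantoms are analytically defined solids (slabs, spheres, spherical-shell
#' sectors, perforated sheets and CSG combinations of these) voxelized onto an
#' anisotropic grid by center sampling: a voxel is foreground iff its center
#' lies inside the solid, matching the binary output of threshold-based
#' segmentation tools. Each phantom carries analytic ground truth for the
#' mid-surface the extraction pipeline should recover, so the whole algorithm
#' can be validated without tissue data. Dimensions are at the scale of real
#' synaptic junctions (hundreds of nm).
#'
#' @param shape one of `"slab"`, `"box"`, `"sphere"`, `"shell_sector"`,
#'   `"perforated_sheet"`.
#' @param size length-3 nm (slab/box/perforated_sheet): x/y footprint and
#'   thickness along the local z axis.
#' @param radius nm (sphere: ball radius; shell_sector: mid-surface radius).
#' @param thickness nm radial thickness of the shell sector.
#' @param half_angle degrees, polar half-opening of the shell sector about
#'   its local +z axis.
#' @param holes for `perforated_sheet`: list of `list(center = c(x, y),
#'   radius = r)` through-thickness cylindrical holes, in local nm
#'   coordinates centered on the sheet; all must lie strictly inside the
#'   footprint and not touch each other.
#' @param spacing length-3 nm voxel pitch. The default mirrors the FIB/SEM
#'   instrument, (3.7, 3.7, 20) nm, so anisotropy bugs surface in tests.
#' @param angles length-3 rotation (radians) about x, y, z applied in that
#'   order (pose of the solid in the world grid).
#' @param translate length-3 nm world translation.
#' @param rng_seed integer recorded for reproducibility of randomized poses
#'   (the generator itself is deterministic).
#' @return A `phantom_spec` list.
#' @seealso [make_phantom()], [csg_combine()], [make_perforated_sheet()]
#' @export
phantom_spec <- function(shape = c("slab", "box", "sphere", "shell_sector",
                                   "perforated_sheet"),
                         size = NULL, radius = NULL, thickness = NULL,
                         half_angle = NULL, holes = list(),
                         spacing = c(3.7, 3.7, 20),
                         angles = c(0, 0, 0), translate = c(0, 0, 0),
                         rng_seed = 1L) {
  shape <- match.arg(shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  spec <- structure(list(shape = shape, size = size, radius = radius,
                         thickness = thickness, half_angle = half_angle,
                         holes = holes, spacing = spacing,
                         angles = as.numeric(angles),
                         translate = as.numeric(translate),
                         rng_seed = as.integer(rng_seed)),
                    class = "phantom_spec")
  min_thick <- 2 * max(spacing)
  th <- switch(shape,
    slab = , box = , perforated_sheet = size[3],
    sphere = 2 * radius,
    shell_sector = thickness)
  if (is.null(th) || !is.finite(th) || th <= 0)
    stop("phantom dimensions must be positive")
  if (th < min_thick)
    stop("phantom thickness ", th, " nm is below the 2-voxel minimum (",
         min_thick, " nm) for spacing (", paste(spacing, collapse = ", "), ")")
  spec
}

rot_matrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

# local-frame inside() predicate and local bounding box per shape
phantom_solid <- function(spec) {
  switch(spec$shape,
    slab = , box = {
      h <- spec$size / 2
      list(inside = function(p) abs(p[, 1]) <= h[1] & abs(p[, 2]) <= h[2] &
                                abs(p[, 3]) <= h[3],
           bbox = rbind(-h, h))
    },
    sphere = {
      R <- spec$radius
      list(inside = function(p) rowSums(p^2) <= R^2,
           bbox = rbind(c(-R, -R, -R), c(R, R, R)))
    },
    shell_sector = {
      R <- spec$radius; t2 <- spec$thickness / 2
      th <- spec$half_angle * pi / 180
      list(inside = function(p) {
             r <- sqrt(rowSums(p^2))
             ok <- r >= R - t2 & r <= R + t2
             # polar angle about +z; guard r = 0
             ang <- acos(pmin(1, pmax(-1, ifelse(r > 0, p[, 3] / r, 1))))
             ok & ang <= th
           },
           bbox = rbind(c(-(R + t2) * sin(th), -(R + t2) * sin(th),
                          (R - t2) * cos(th)),
                        c((R + t2) * sin(th), (R + t2) * sin(th), R + t2)))
    },
    perforated_sheet = {
      h <- spec$size / 2
      holes <- spec$holes
      list(inside = function(p) {
             ok <- abs(p[, 1]) <= h[1] & abs(p[, 2]) <= h[2] &
                   abs(p[, 3]) <= h[3]
             for (hl in holes)
               ok <- ok & ((p[, 1] - hl$center[1])^2 +
                           (p[, 2] - hl$center[2])^2 > hl$radius^2)
             ok
           },
           bbox = rbind(-h, h))
    })
}

phantom_truth <- function(spec) {
  R3 <- rot_matrix(spec$angles)
  tr <- spec$translate
  to_local <- function(p) t(crossprod(R3, t(sweep(matrix(p, ncol = 3), 2, tr))))
  switch(spec$shape,
    slab = , box = {
      list(midsurface_point_test = function(p) to_local(p)[, 3],
           midsurface_area = spec$size[1] * spec$size[2],
           expected_hole_count = 0L,
           mean_curvature = 0, gaussian_curvature = 0,
           footprint_area = spec$size[1] * spec$size[2])
    },
    sphere = {
      # the template-normal mid-surface of a ball is its equatorial disc
      list(midsurface_point_test = function(p) to_local(p)[, 3],
           midsurface_area = pi * spec$radius^2,
           expected_hole_count = 0L,
           mean_curvature = 0, gaussian_curvature = 0,
           footprint_area = pi * spec$radius^2)
    },
    shell_sector = {
      R <- spec$radius
      th <- spec$half_angle * pi / 180
      list(midsurface_point_test = function(p)
             sqrt(rowSums(to_local(p)^2)) - R,
           midsurface_area = 2 * pi * R^2 * (1 - cos(th)),
           expected_hole_count = 0L,
           mean_curvature = 1 / R, gaussian_curvature = 1 / R^2,
           footprint_area = pi * (R * sin(th))^2)
    },
    perforated_sheet = {
      hole_area <- sum(vapply(spec$holes, function(h) pi * h$radius^2, 0))
      list(midsurface_point_test = function(p) to_local(p)[, 3],
           midsurface_area = spec$size[1] * spec$size[2] - hole_area,
           expected_hole_count = length(spec$holes),
           mean_curvature = 0, gaussian_curvature = 0,
           footprint_area = spec$size[1] * spec$size[2] - hole_area)
    })
}

#' Voxelize a phantom and return its analytic ground truth
#'
#' @param spec a [phantom_spec()].
#' @param label_id label tag for the resulting mask.
#' @return A list with `mask` (a [binary_mask()]) and `truth`, a list holding
#'   `midsurface_point_test` (world nm point matrix -> signed distance to the
#'   analytic mid-surface), `midsurface_area` (nm^2), `expected_hole_count`,
#'   `mean_curvature` (1/nm, where constant), `gaussian_curvature` (1/nm^2)
#'   and `footprint_area` (nm^2).
#' @examples
#' ph <- make_phantom(phantom_spec("slab", size = c(740, 370, 60)))
#' ph$truth$midsurface_area  # 740 * 370
#' @export
make_phantom <- function(spec, label_id = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$shape == "perforated_sheet") validate_holes(spec)
  solid <- phantom_solid(spec)
  R3 <- rot_matrix(spec$angles)
  # world-space bbox of the rotated solid
  corners <- as.matrix(expand.grid(solid$bbox[, 1], solid$bbox[, 2],
                                   solid$bbox[, 3]))
  wc <- t(R3 %*% t(corners)) + matrix(spec$translate, nrow(corners), 3,
                                      byrow = TRUE)
  # stagger the lattice by half a pitch so voxel centers never sit exactly on
  # an analytic face (which would over/under-count a whole boundary layer)
  lo <- apply(wc, 2, min) - 2.5 * spec$spacing
  hi <- apply(wc, 2, max) + 2 * spec$spacing
  n <- pmax(ceiling((hi - lo) / spec$spacing) + 1L, 3L)
  origin <- lo
  ax <- origin[1] + (seq_len(n[1]) - 1) * spec$spacing[1]
  ay <- origin[2] + (seq_len(n[2]) - 1) * spec$spacing[2]
  az <- origin[3] + (seq_len(n[3]) - 1) * spec$spacing[3]
  # evaluate slice by slice to bound memory
  vox <- array(FALSE, n)
  xy <- as.matrix(expand.grid(ax, ay))
  for (k in seq_len(n[3])) {
    p <- cbind(xy, az[k])
    pl <- t(crossprod(R3, t(sweep(p, 2, spec$translate))))
    vox[, , k] <- solid$inside(pl)
  }
  mask <- binary_mask(vox, spec$spacing, origin, label_id,
                      check_connectivity = FALSE)
  list(mask = mask, truth = phantom_truth(spec))
}

validate_holes <- function(spec) {
  h <- spec$size / 2
  holes <- spec$holes
  for (hl in holes) {
    if (abs(hl$center[1]) + hl$radius >= h[1] ||
        abs(hl$center[2]) + hl$radius >= h[2])
      stop("hole at (", paste(hl$center, collapse = ", "),
           ") overlaps the sheet boundary")
  }
  if (length(holes) > 1) {
    for (i in seq_len(length(holes) - 1))
      for (j in seq((i + 1), length(holes))) {
        d <- sqrt(sum((holes[[i]]$center - holes[[j]]$center)^2))
        if (d <= holes[[i]]$radius + holes[[j]]$radius)
          stop("holes ", i, " and ", j, " touch or overlap")
      }
  }
  invisible(TRUE)
}

#' Perforated sheet phantom
#'
#' A slab minus through-thickness cylinders, emulating perforated synaptic
#' junctions. Shorthand for [make_phantom()] on a `"perforated_sheet"` spec.
#'
#' @inheritParams make_phantom
#' @return As [make_phantom()]; `truth$expected_hole_count` equals the number
#'   of holes and `truth$midsurface_area` is the footprint minus the hole
#'   discs.
#' @export
make_perforated_sheet <- function(spec, label_id = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$shape != "perforated_sheet")
    stop("spec$shape must be 'perforated_sheet'")
  make_phantom(spec, label_id)
}

#' Combine two masks with constructive solid geometry
#'
#' Voxelwise boolean union, intersection or difference. The two masks must
#' share voxel spacing; when their grids are offset, `b` is resampled onto the
#' output lattice by nearest neighbor (requires `resample = TRUE` if spacings
#' differ).
#'
#' @param a,b [binary_mask()] objects.
#' @param op `"union"`, `"intersection"` or `"difference"` (a minus b).
#' @param resample allow nearest-neighbor resampling of `b` when the spacings
#'   differ (default `FALSE`: differing spacings are an error).
#' @return A [binary_mask()] on a lattice compatible with `a` (label from `a`).
#' @export
csg_combine <- function(a, b, op = c("union", "intersection", "difference"),
                        resample = FALSE) {
  op <- match.arg(op)
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!resample && any(abs(a$spacing - b$spacing) > 1e-9))
    stop("masks have different spacings; set resample = TRUE to resample b")
  # output lattice: a's frame, covering both bounding boxes
  lo <- pmin(a$origin, b$origin)
  hi <- pmax(a$origin + (dim(a$voxels) - 1) * a$spacing,
             b$origin + (dim(b$voxels) - 1) * b$spacing)
  # snap to a's lattice
  lo <- a$origin + floor((lo - a$origin) / a$spacing) * a$spacing
  n <- ceiling((hi - lo) / a$spacing) + 1L
  va <- lookup_mask(a, lo, n, a$spacing)
  vb <- lookup_mask(b, lo, n, a$spacing)
  out <- switch(op, union = va | vb, intersection = va & vb,
                difference = va & !vb)
  if (!any(out))
    return(binary_mask(array(FALSE, pmax(dim(out), 3L)), a$spacing, lo,
                       a$label_id, check_connectivity = FALSE))
  g <- voxel_grid(array(as.integer(out), dim(out)), a$spacing, lo)
  crop_mask(out, g, a$label_id)
}

# sample mask on a regular lattice (origin lo, count n, pitch sp) by NN lookup
lookup_mask <- function(m, lo, n, sp) {
  ijk <- as.matrix(expand.grid(seq_len(n[1]), seq_len(n[2]), seq_len(n[3])))
  p <- sweep(sweep(ijk - 1, 2, sp, "*"), 2, lo, "+")
  idx <- round(sweep(sweep(p, 2, m$origin, "-"), 2, m$spacing, "/")) + 1
  d <- dim(m$voxels)
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
        idx[, 2] >= 1 & idx[, 2] <= d[2] &
        idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- logical(nrow(idx))
  out[ok] <- m$voxels[idx[ok, , drop = FALSE]]
  array(out, n)
}
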