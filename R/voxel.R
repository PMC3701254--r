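#' Voxel grid with physical anisotropic spacing
#'
#' A `voxel_grid` wraps a 3D scalar array (gray levels or integer labels)
#' together with its physical voxel spacing and origin, both in nanometres.
#' Arrays are indexed `(x, y, z)` with `z` the section (milling) axis, and the
#' physical position of the *center* of voxel `(i, j, k)` (1-based) is
#' `origin + ((i, j, k) - 1) * spacing`. All downstream geometry operates in
#' physical nm because FIB/SEM voxels are strongly anisotropic (e.g.
#' 3.7 x 3.7 x 20 nm): index-space geometry would be wrong.
#'
#' @param values 3D numeric array.
#' @param spacing numeric length-3, nm per voxel along x, y, z; all > 0.
#' @param origin numeric length-3, physical nm coordinate of the center of
#'   voxel `(1, 1, 1)`.
#' @return An object of class `voxel_grid` with fields `values`, `spacing`,
#'   `origin`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 4, 2)), spacing = c(3.7, 3.7, 20))
#' dim(g$values)
#' @export
voxel_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3D array, got ", length(dim(values)), " dims")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive numbers (nm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite numbers (nm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' Binary segmentation mask
#'
#' A `binary_mask` is a [voxel_grid()]-like container holding one segmented
#' junction: a 3D logical array plus spacing/origin in nm and the integer
#' label of the source junction. The core pipeline expects at least one
#' foreground voxel; a warning is emitted when the foreground is not a single
#' 26-connected component (the SAS of a multi-component blob is undefined).
#'
#' @param voxels 3D logical array (foreground = `TRUE`).
#' @param spacing,origin as in [voxel_grid()].
#' @param label_id integer tag of the source junction.
#' @param check_connectivity warn when foreground splits into several
#'   26-connected components (default `TRUE`).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing, origin = c(0, 0, 0), label_id = 1L,
                        check_connectivity = TRUE) {
  if (length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array")
  storage.mode(voxels) <- "logical"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive numbers (nm)")
  m <- structure(list(voxels = voxels, spacing = spacing,
                      origin = as.numeric(origin),
                      label_id = as.integer(label_id)),
                 class = "binary_mask")
  if (check_connectivity && any(voxels)) {
    lab <- cpp_label26(as.logical(voxels), dim(voxels))
    k <- attr(lab, "n_components")
    if (k > 1L)
      warning("foreground of mask ", label_id, " has ", k,
              " 26-connected components; the SAS assumes a single junction")
  }
  m
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat("<voxel_grid> ", paste(d, collapse = " x "),
      " voxels, spacing (", paste(x$spacing, collapse = ", "),
      ") nm, origin (", paste(signif(x$origin, 6), collapse = ", "), ") nm\n",
      sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<binary_mask> label ", x$label_id, ": ", sum(x$voxels), " / ",
      prod(d), " voxels foreground, ", paste(d, collapse = " x "),
      " grid, spacing (", paste(x$spacing, collapse = ", "), ") nm\n",
      sep = "")
  invisible(x)
}

# physical centers (nm) of the foreground voxels, n x 3 matrix
mask_centers <- function(mask) {
  idx <- which(mask$voxels, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
}

# physical nm -> continuous 0-based voxel index coordinates
phys_to_index <- function(points, spacing, origin) {
  points <- matrix(points, ncol = 3)
  sweep(sweep(points, 2, origin, "-"), 2, spacing, "/")
}
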