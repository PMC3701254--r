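#' Deformation parameters
#'
#' Tunables of the template deformation. `c_s` scales the distance-map
#' smoothing (`sigma = c_s * max(DM)` nm) and is bounded by the 0.75 standard
#' normal quantile magnitude, 0.674489 (see [cs_upper_bound()]); the default
#' 0.67 gives the strongest smoothing that keeps a sphere-like interior
#' positive in the original formulation. Convergence is declared when the
#' mean Euclidean vertex error against any of the last `s` recorded template
#' states drops below `epsilon = c * |n|` with `n` the unit template normal,
#' i.e. `epsilon = c` nm; recording several states catches period-cycling
#' final states as well as true fixed points. `max_iters` is a safety cap —
#' the stop rule alone cannot bound runtime.
#'
#' @param c_s smoothing coefficient in `[0, 0.674489]`, default 0.67.
#' @param s number of recorded template states, default 10.
#' @param c convergence threshold factor (nm, via `epsilon = c`), default 0.001.
#' @param max_iters iteration cap, default 500.
#' @return A `deform_params` list.
#' @export
deform_params <- function(c_s = 0.67, s = 10L, c = 0.001, max_iters = 500L) {
  if (!is.finite(c_s) || c_s < 0 || c_s > cs_upper_bound())
    stop("c_s must lie in [0, ", format(cs_upper_bound(), digits = 7), "]")
  if (s < 2L) stop("s must be >= 2")
  if (c <= 0) stop("c must be > 0")
  if (max_iters < 1L) stop("max_iters must be >= 1")
  structure(list(c_s = c_s, s = as.integer(s), c = c,
                 max_iters = as.integer(max_iters)),
            class = "deform_params")
}

#' Build the planar template mesh
#'
#' A structured rectangular vertex grid spanning the largest face of the
#' oriented bounding box (axes u1 x u2), inflated by 10% so the template
#' overhangs the junction everywhere before clipping, passing through the
#' seed point with normal u3. The grid pitch is the smallest in-plane voxel
#' spacing, which makes the vertex count comparable to the number of voxels
#' cut by a plane parallel to the largest OBB face. Facets are two
#' consistently oriented triangles per grid cell.
#'
#' @param obb an `oriented_bbox` from [compute_obb()].
#' @param seed length-3 nm point from [seed_point()].
#' @param inflate face inflation factor, default 1.1.
#' @param spacing length-3 nm voxel spacing of the source mask, used to
#'   choose the grid pitch.
#' @return A [surface_mesh()] with `grid_shape` set.
#' @export
build_template <- function(obb, seed, spacing, inflate = 1.1) {
  stopifnot(inherits(obb, "oriented_bbox"))
  if (any(obb$extents[1:2] <= 0)) stop("degenerate OBB extents")
  # in-plane pitch: smallest spacing among the axes not carrying the normal
  drop_axis <- which.max(abs(obb$normal))
  pitch <- min(spacing[-drop_axis])
  L1 <- obb$extents[1] * inflate
  L2 <- obb$extents[2] * inflate
  n1 <- max(2L, ceiling(L1 / pitch) + 1L)
  n2 <- max(2L, ceiling(L2 / pitch) + 1L)
  a <- seq(-L1 / 2, L1 / 2, length.out = n1)
  b <- seq(-L2 / 2, L2 / 2, length.out = n2)
  # template center: seed, re-centered laterally on the OBB center so an
  # off-center seed still leaves overhang on all sides
  dc <- obb$center - seed
  ctr <- seed + sum(dc * obb$axes[, 1]) * obb$axes[, 1] +
                sum(dc * obb$axes[, 2]) * obb$axes[, 2]
  grid <- as.matrix(expand.grid(a = a, b = b))
  verts <- matrix(ctr, nrow(grid), 3, byrow = TRUE) +
    grid[, 1] %o% obb$axes[, 1] + grid[, 2] %o% obb$axes[, 2]
  # facets over the (n1 x n2) grid; vertex index = i + n1 * (j - 1)
  i <- rep(seq_len(n1 - 1L), n2 - 1L)
  j <- rep(seq_len(n2 - 1L), each = n1 - 1L)
  v00 <- i + n1 * (j - 1L)
  v10 <- v00 + 1L
  v01 <- v00 + n1
  v11 <- v01 + 1L
  facets <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  surface_mesh(verts, facets, grid_shape = c(n1, n2))
}

#' Deform the template along the distance-map gradient
#'
#' Iteratively displaces every template vertex along the fixed unit normal
#' `n` by the locally sampled normal-projected gradient of the smoothed
#' distance map: `p(t+1) = p(t) + (grad d . n) n`. The gradient field is
#' static (computed once from the smoothed map) and sampled tricubically at
#' the current vertex positions; out-of-bounds vertices receive zero
#' displacement and are removed later by clipping. After each iteration the
#' mean Euclidean vertex error against each of the last `s` recorded states
#' is computed; the iteration stops when the minimum drops below
#' `epsilon = c` (nm), which detects both fixed points and small periodic
#' oscillations around the medial ridge.
#'
#' @param template planar [surface_mesh()] from [build_template()].
#' @param dm smoothed `distance_map`.
#' @param n unit normal of the template plane.
#' @param params a [deform_params()].
#' @return A `deform_result`: list with `mesh` (deformed, unclipped),
#'   `converged`, `iterations`, `final_error` (nm) and `error_history`.
#' @export
deform_template <- function(template, dm, n, params = deform_params()) {
  stopifnot(inherits(template, "surface_mesh"), inherits(dm, "distance_map"))
  n <- as.numeric(n)
  if (abs(sqrt(sum(n^2)) - 1) > 1e-8) stop("'n' must be a unit vector")
  eps <- params$c * sqrt(sum(n^2))  # |n| = 1, so eps = c (nm)
  # static scalar field grad(d) . n; tricubic sampling is linear in the array
  # values, so sampling this field equals projecting sampled components
  g <- gradient_field(dm)
  gn <- g[[1]] * n[1] + g[[2]] * n[2] + g[[3]] * n[3]
  gn_vec <- as.numeric(gn)
  d <- dim(dm$values)

  V <- template$vertices
  history <- list(V)
  err_hist <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iters) {
    iter <- iter + 1L
    idx <- phys_to_index(V, dm$spacing, dm$origin)
    s <- cpp_tricubic(gn_vec, d, idx)
    step <- s$values
    step[s$oob] <- 0
    V <- V + step %o% n
    if (any(!is.finite(V)))
      stop("deformation produced non-finite vertex coordinates at iteration ",
           iter)
    errs <- vapply(history, function(H)
      mean(sqrt(rowSums((V - H)^2))), 0)
    e <- min(errs)
    err_hist <- c(err_hist, e)
    if (e < eps) {
      converged <- TRUE
      break
    }
    history <- c(history, list(V))
    if (length(history) > params$s)
      history <- history[-1L]
  }
  structure(list(mesh = surface_mesh(V, template$facets, template$grid_shape),
                 converged = converged, iterations = iter,
                 final_error = if (length(err_hist)) tail(err_hist, 1) else NA_real_,
                 error_history = err_hist),
            class = "deform_result")
}

#' Clip a deformed mesh to the segmentation
#'
#' Removes the portions of the deformed template protruding outside the
#' segmented junction: a vertex is inside iff its tricubically interpolated
#' *raw* (unsmoothed) signed distance is >= 0, and any facet with an outside
#' vertex is removed whole (no re-triangulation at the zero crossing; the
#' boundary error is at most one grid pitch). Facets spanning perforations
#' are removed by the same rule — their vertices sample negative distance —
#' so holes survive as interior boundary loops. Unreferenced vertices are
#' dropped and indices compacted.
#'
#' @param mesh deformed [surface_mesh()].
#' @param raw_dm the *unsmoothed* `distance_map` of the same mask.
#' @return Clipped [surface_mesh()].
#' @export
clip_to_mask <- function(mesh, raw_dm) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(raw_dm, "distance_map"))
  if (isTRUE(raw_dm$smoothed))
    stop("clip_to_mask needs the raw (unsmoothed) distance map")
  s <- sample_distance(raw_dm, mesh$vertices)
  inside <- (s$values >= 0) & !s$oob
  keep <- inside[mesh$facets[, 1]] & inside[mesh$facets[, 2]] &
          inside[mesh$facets[, 3]]
  if (!any(keep))
    stop("SAS empty after clipping - check segmentation/params")
  f <- mesh$facets[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap[f], ncol = 3))
}

#' Extract the synaptic apposition surface from a segmentation
#'
#' Runs the full pipeline on one binary mask: oriented bounding box, signed
#' anisotropic distance map, Gaussian smoothing (`sigma = c_s * max(DM)`),
#' seeding at the geometric center of the deepest voxels, planar template on
#' the largest OBB face, gradient-driven deformation along the fixed OBB
#' normal, and clipping against the raw distance map. The smoothed map
#' drives seeding and deformation; the raw map drives clipping, which
#' enforces the containment criterion and keeps perforation geometry
#' unblurred. The algorithm is deterministic.
#'
#' @param mask a [binary_mask()] with at least one foreground voxel.
#' @param params a [deform_params()].
#' @return A `sas_result`: list with `sas` (clipped [surface_mesh()]),
#'   `deform` (`deform_result`), `obb`, `seed`, `params`, `source_label`
#'   and `mask` (kept for downstream morphometry).
#' @examples
#' ph <- make_phantom(phantom_spec("slab", size = c(200, 120, 60),
#'                                 spacing = c(5, 5, 20)))
#' res <- extract_sas(ph$mask)
#' res$deform$converged
#' surface_area(res$sas) / ph$truth$midsurface_area
#' @export
extract_sas <- function(mask, params = deform_params()) {
  stopifnot(inherits(mask, "binary_mask"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("extract_sas stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  obb <- stage("compute_obb", compute_obb(mask))
  raw <- stage("signed_distance_map", signed_distance_map(mask))
  sm <- stage("gaussian_smooth", gaussian_smooth(raw, params$c_s))
  seed <- stage("seed_point", seed_point(sm))
  templ <- stage("build_template",
                 build_template(obb, seed, spacing = mask$spacing))
  def <- stage("deform_template",
               deform_template(templ, sm, obb$normal, params))
  sas <- stage("clip_to_mask", clip_to_mask(def$mesh, raw))
  structure(list(sas = sas, deform = def, obb = obb, seed = seed,
                 params = params, source_label = mask$label_id, mask = mask),
            class = "sas_result")
}

#' @export
print.sas_result <- function(x, ...) {
  cat("<sas_result> label ", x$source_label, ": ",
      nrow(x$sas$vertices), " vertices, ", nrow(x$sas$facets), " facets; ",
      if (x$deform$converged) "converged" else "NOT converged",
      " in ", x$deform$iterations, " iterations (final error ",
      signif(x$deform$final_error, 3), " nm)\n", sep = "")
  cat("  area ", signif(surface_area(x$sas), 6), " nm^2, perimeter ",
      signif(perimeter(x$sas), 6), " nm\n", sep = "")
  invisible(x)
}
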