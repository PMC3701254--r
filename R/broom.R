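#' Tidy a SAS extraction result
#'
#' One row of surface-level quantities: area, perimeter, area ratio and
#' curvature statistics, plus convergence bookkeeping. For the full record
#' including segmentation-level features use [morphometry()].
#'
#' @param x a `sas_result`.
#' @param ... unused.
#' @return A one-row tibble.
#' @export
tidy.sas_result <- function(x, ...) {
  curv <- curvature_summary(vertex_curvatures(x$sas))
  tibble::tibble(
    label_id = x$source_label,
    sas_area_nm2 = surface_area(x$sas),
    sas_perimeter_nm = perimeter(x$sas),
    area_ratio = area_ratio(x$sas, x$obb),
    boundary_loops = boundary_loops(x$sas),
    mean_H = curv$mean_H, sd_H = curv$sd_H,
    mean_K = curv$mean_K, sd_K = curv$sd_K,
    converged = x$deform$converged,
    iterations = x$deform$iterations)
}

#' Glance at a SAS extraction result
#'
#' @param x a `sas_result`.
#' @param ... unused.
#' @return One-row tibble with convergence diagnostics and mesh size.
#' @export
glance.sas_result <- function(x, ...) {
  tibble::tibble(
    converged = x$deform$converged,
    iterations = x$deform$iterations,
    final_error_nm = x$deform$final_error,
    n_vertices = nrow(x$sas$vertices),
    n_facets = nrow(x$sas$facets))
}

#' Plot the deformation error history
#'
#' Minimum mean vertex error against the recorded template states per
#' iteration, on a log scale, with the convergence threshold drawn as a
#' dashed line.
#'
#' @param object a `deform_result` (or a `sas_result`, whose deformation is
#'   plotted).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.deform_result <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$error_history),
                       error_nm = object$error_history)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$error_nm)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration",
                  y = "min mean vertex error vs recorded states (nm)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.deform_result
#' @export
autoplot.sas_result <- function(object, ...) {
  autoplot.deform_result(object$deform, ...)
}

#' Footprint plot of an extracted SAS
#'
#' Projects the SAS vertices onto the largest OBB face and colors them by
#' their height along the normal: a quick visual check of curvature and of
#' perforations (holes appear as empty regions).
#'
#' @param result a `sas_result`.
#' @return A ggplot object.
#' @export
plot_sas_footprint <- function(result) {
  stopifnot(inherits(result, "sas_result"))
  rel <- sweep(result$sas$vertices, 2, result$obb$center)
  uv <- rel %*% result$obb$axes
  df <- tibble::tibble(u = uv[, 1], v = uv[, 2], height_nm = uv[, 3])
  ggplot2::ggplot(df, ggplot2::aes(.data$u, .data$v,
                                   colour = .data$height_nm)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "u1 (nm)", y = "u2 (nm)", colour = "height (nm)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
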